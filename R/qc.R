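#' Spikiness of a count profile
#'
#' Bin-to-bin variation in read density: the sum of absolute differences
#' between consecutive bin counts (in grid order) divided by the total
#' count. Low in good libraries (~0.1 at study depth); the library QC
#' threshold is spikiness < 0.21.
#'
#' @param counts count vector (at least 2 bins).
#' @return a non-negative number, or `NA` (flagged sentinel) for an
#'   all-zero vector.
#' @export
spikiness <- function(counts) {
  if (length(counts) < 2L) stop("spikiness needs at least 2 bins")
  s <- sum(counts)
  if (s == 0) return(NA_real_)
  sum(abs(diff(counts))) / s
}

#' Shannon entropy of a count profile
#'
#' Entropy (nats) of the read distribution over bins,
#' `-sum(p_i * log(p_i))` with `p_i = c_i / sum(c)`. Maximal (`log(n)`) for
#' perfectly even coverage, 0 when all reads fall in one bin.
#'
#' @param counts count vector with positive total.
#' @return entropy in nats, or `NA` for an all-zero vector.
#' @export
profile_entropy <- function(counts) {
  s <- sum(counts)
  if (s == 0) return(NA_real_)
  p <- counts[counts > 0] / s
  -sum(p * log(p))
}

#' Bhattacharyya distance between two negative binomials
#'
#' `-log sum_k sqrt(P1(k) * P2(k))`, summed until the residual tail mass of
#' both distributions is below `tail`. Used as a library quality metric via
#' [bhattacharyya()]: the distance between the fitted monosomy and disomy
#' emissions measures how well adjacent copy-number states are separated
#' (threshold > 1.0 for a good library).
#'
#' @param mu1,var1 mean/variance of the first NB.
#' @param mu2,var2 mean/variance of the second NB.
#' @param tail residual tail-mass bound for truncating the summation.
#' @return a non-negative distance.
#' @export
bhattacharyya_nb <- function(mu1, var1, mu2, var2, tail = 1e-12) {
  if (var1 <= mu1 || var2 <= mu2) stop("NB requires variance > mean")
  size1 <- mu1^2 / (var1 - mu1); size2 <- mu2^2 / (var2 - mu2)
  k_max <- max(stats::qnbinom(tail, size = size1, mu = mu1, lower.tail = FALSE),
               stats::qnbinom(tail, size = size2, mu = mu2, lower.tail = FALSE)) + 1L
  k <- 0:k_max
  bc <- sum(exp(0.5 * (stats::dnbinom(k, size = size1, mu = mu1, log = TRUE) +
                       stats::dnbinom(k, size = size2, mu = mu2, log = TRUE))))
  -log(min(bc, 1))
}

#' Bhattacharyya distance of a copy-number fit
#'
#' Distance between the fitted monosomy (mean `mu1`, variance `var1`) and
#' disomy (mean `2*mu1`, variance `2*var1`) emission distributions.
#'
#' @param fit a `copy_number_fit`.
#' @return the distance, or `NA` (flagged sentinel) for a degenerate fit.
#' @export
bhattacharyya <- function(fit) {
  mu1 <- fit$emission$mu1; var1 <- fit$emission$var1
  if (!is.finite(mu1) || !is.finite(var1) || var1 <= mu1) return(NA_real_)
  bhattacharyya_nb(mu1, var1, 2 * mu1, 2 * var1)
}

#' Estimate library complexity from a saturation curve
#'
#' Downsamples the library at `n_points` evenly spaced depths, counts
#' unique reads at each, and fits the saturation curve
#' `unique = Cmax * s / (K + s)` by least squares (this is the
#' Michaelis-Menten form, fitted with `nls`/`SSmicmen`, with a
#' Levenberg-Marquardt fallback). `Cmax` estimates the theoretical maximum
#' unique reads in the library; `K` is the sequencing depth at which unique
#' reads reach half of `Cmax` (exactly, on the fitted curve).
#'
#' @param total_reads total sequenced reads available.
#' @param unique_counter function mapping a subsample size to the number of
#'   unique reads observed at that depth.
#' @param n_points number of downsampling depths (>= 3).
#' @param points optional precomputed data frame (`seq_reads`,
#'   `unique_reads`); when given, `total_reads`/`unique_counter` are
#'   ignored. The fit depends only on the point set, not its order.
#' @return list of class `complexity_fit`: `cmax`, `k`, `curve_points`
#'   (data frame `seq_reads`, `unique_reads`), `flagged` (TRUE when the
#'   data do not saturate and `cmax` is unbounded).
#' @export
estimate_complexity <- function(total_reads = NULL, unique_counter = NULL,
                                n_points = 10L, points = NULL) {
  if (is.null(points)) {
    if (n_points < 3L) stop("need at least 3 downsampling points")
    if (total_reads < n_points) stop("total_reads must be at least n_points")
    sizes <- unique(round(total_reads * seq_len(n_points) / n_points))
    uniq <- vapply(sizes, function(s) as.numeric(unique_counter(s)), numeric(1))
    pts <- data.frame(seq_reads = sizes, unique_reads = uniq)
  } else {
    if (nrow(points) < 3L) stop("need at least 3 downsampling points")
    pts <- data.frame(seq_reads = points$seq_reads,
                      unique_reads = points$unique_reads)
  }
  pts <- pts[order(pts$seq_reads), , drop = FALSE]
  rownames(pts) <- NULL
  fit <- tryCatch(
    stats::nls(unique_reads ~ SSmicmen(seq_reads, cmax, k), data = pts),
    error = function(e) tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(unique_reads ~ cmax * seq_reads / (k + seq_reads),
                          data = pts,
                          start = list(cmax = max(pts$unique_reads) * 2,
                                       k = max(pts$seq_reads) / 2))),
      error = function(e2) NULL)
  )
  if (is.null(fit)) {
    return(structure(list(cmax = Inf, k = Inf, curve_points = pts,
                          flagged = TRUE), class = "complexity_fit"))
  }
  co <- stats::coef(fit)
  # non-saturating data (unique ~= sequenced everywhere) push K and Cmax
  # far beyond the observed range; flag rather than report a wild asymptote
  flagged <- !is.finite(co[["k"]]) || co[["k"]] > 100 * max(pts$seq_reads) ||
    co[["cmax"]] <= 0
  structure(list(cmax = unname(co[["cmax"]]), k = unname(co[["k"]]),
                 curve_points = pts, flagged = flagged),
            class = "complexity_fit")
}

#' Per-cell quality-control report
#'
#' Computes the five library quality metrics for one cell: genomic coverage
#' (fraction of bins with a nonzero count), spikiness, entropy, number of
#' copy-number segments, and the Bhattacharyya distance between the fitted
#' monosomy and disomy emissions. Spikiness/entropy/coverage are computed on
#' the raw counts (library properties, independent of the model fit).
#'
#' @param cell a `binned_cell`.
#' @param fit the cell's `copy_number_fit`.
#' @param grid the `bin_grid`.
#' @param complexity optional `complexity_fit` for the cell.
#' @return one-row data frame: `cell_id`, `coverage`, `spikiness`,
#'   `entropy`, `n_segments`, `bhattacharyya`, `complexity_cmax`,
#'   `complexity_k`.
#' @export
qc_cell <- function(cell, fit, grid, complexity = NULL) {
  segs <- decode_segments(fit, grid)
  data.frame(
    cell_id = cell$cell_id,
    coverage = mean(cell$counts > 0),
    spikiness = spikiness(cell$counts),
    entropy = profile_entropy(cell$counts),
    n_segments = nrow(segs),
    bhattacharyya = bhattacharyya(fit),
    complexity_cmax = if (is.null(complexity)) NA_real_ else complexity$cmax,
    complexity_k = if (is.null(complexity)) NA_real_ else complexity$k,
    stringsAsFactors = FALSE
  )
}

#' Cluster libraries by quality and select the good cluster
#'
#' Partitions cells on their standardized quality-metric vectors
#' (spikiness, entropy, n_segments, bhattacharyya, coverage) by
#' agglomerative hierarchical clustering with complete linkage. The number
#' of clusters (at most `n_clusters_max`) is chosen by average silhouette
#' width, guarded by a permutation null: a cut is accepted only when its
#' silhouette exceeds the best silhouette obtainable from the same data
#' with independently permuted metric columns (which destroys any joint
#' structure while preserving the marginals). A homogeneous plate therefore
#' stays one cluster instead of being split on noise. The permutations use
#' a fixed internal seed, so the clustering is deterministic.
#' The cluster with the best mean quality
#' score (low spikiness and segment count; high Bhattacharyya distance,
#' coverage and entropy) is selected, and a cell passes QC only if it is in
#' the selected cluster AND satisfies the absolute thresholds
#' `spikiness < spikiness_max` and `bhattacharyya > bhattacharyya_min`
#' (defaults are the study's: 0.21 and 1.0).
#'
#' @param reports data frame of per-cell QC rows (from [qc_cell()]).
#' @param n_clusters_max maximum number of clusters.
#' @param spikiness_max,bhattacharyya_min absolute pass thresholds.
#' @return the reports with `cluster` and `passes` columns appended, plus
#'   attribute `selected_cluster`.
#' @export
cluster_by_quality <- function(reports, n_clusters_max = 4L,
                               spikiness_max = 0.21, bhattacharyya_min = 1.0) {
  if (nrow(reports) < 2L) stop("clustering needs at least 2 cells")
  metrics <- c("spikiness", "entropy", "n_segments", "bhattacharyya", "coverage")
  m <- as.matrix(reports[, metrics])
  m[!is.finite(m)] <- 0
  z <- scale(m)
  z[, apply(m, 2L, stats::sd) == 0] <- 0          # constant metric: no signal
  z[!is.finite(z)] <- 0
  d <- stats::dist(z)
  if (max(d) == 0) {
    cl <- rep(1L, nrow(reports))
  } else {
    sil <- function(cl, dm) {       # average silhouette width of a cutting
      mean(vapply(seq_along(cl), function(i) {
        own <- cl == cl[i]; own[i] <- FALSE
        if (!any(own)) return(0)    # singleton clusters carry no support
        a <- mean(dm[i, own])
        b <- min(vapply(setdiff(unique(cl), cl[i]),
                        function(g) mean(dm[i, cl == g]), numeric(1)))
        (b - a) / max(a, b)
      }, numeric(1)))
    }
    ks <- 2:max(2L, min(n_clusters_max, nrow(reports) - 1L))
    best_cut <- function(z) {
      d <- stats::dist(z)
      hc <- stats::hclust(d, method = "complete")
      dm <- as.matrix(d)
      cuts <- lapply(ks, function(k) stats::cutree(hc, k = k))
      widths <- vapply(cuts, sil, numeric(1), dm = dm)
      list(cut = cuts[[which.max(widths)]], width = max(widths))
    }
    obs <- best_cut(z)
    null_widths <- with_seed(1720, vapply(1:20, function(b) {
      best_cut(apply(z, 2L, sample))$width
    }, numeric(1)))
    cl <- if (obs$width > max(null_widths)) obs$cut else rep(1L, nrow(reports))
  }
  quality <- -z[, "spikiness"] - z[, "n_segments"] +
    z[, "bhattacharyya"] + z[, "coverage"] + z[, "entropy"]
  sel <- which.max(tapply(quality, cl, mean))
  sel <- as.integer(names(sel))
  passes <- cl == sel &
    reports$spikiness < spikiness_max &
    !is.na(reports$bhattacharyya) & reports$bhattacharyya > bhattacharyya_min
  passes[is.na(passes)] <- FALSE
  out <- reports
  out$cluster <- as.integer(cl)
  out$passes <- passes
  attr(out, "selected_cluster") <- sel
  out
}
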