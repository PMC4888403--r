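#' Whole-chromosome copy-number calls from a bin-level fit
#'
#' Assigns each chromosome the most common (modal) decoded state among its
#' bins, with ties broken toward the state nearer 2 and then the smaller
#' state (conservative toward euploidy), and reports the supporting
#' fraction (fraction of the chromosome's bins in the modal state). A
#' chromosome whose majority of bins is gained or lost is thereby called
#' trisomic or monosomic.
#'
#' @param fit a decoded `copy_number_fit`.
#' @param grid the matching `bin_grid`.
#' @param cell_id identifier carried into the result.
#' @param sex recorded sex ("XX"/"XY") if known; inferred downstream
#'   otherwise.
#' @return object of class `chromosome_karyotype`: data frame `chrom`,
#'   `copy_number`, `support`, `n_bins` with attributes `cell_id`, `sex`.
#' @export
call_chromosomes <- function(fit, grid, cell_id = "cell", sex = NA_character_) {
  validate_bin_grid(grid)
  if (length(fit$states) != nrow(grid)) stop("fit does not match grid")
  rows <- lapply(grid_chromosomes(grid), function(ch) {
    s <- fit$states[grid$chrom == ch]
    if (!length(s)) { warning("chromosome ", ch, " has no bins; omitted"); return(NULL) }
    tab <- table(s)
    cand <- as.integer(names(tab)[tab == max(tab)])
    call <- cand[order(abs(cand - 2L), cand)][1L]
    data.frame(chrom = ch, copy_number = call,
               support = max(tab) / length(s), n_bins = length(s),
               stringsAsFactors = FALSE)
  })
  k <- do.call(rbind, rows)
  structure(k, class = c("chromosome_karyotype", "data.frame"),
            cell_id = cell_id, sex = sex)
}

#' Classify a cell as aneuploid from its chromosome calls
#'
#' Compares each chromosome call to its expected euploid copy number:
#' 2 for autosomes; X/Y expectations (2, 0) for XX cells and (1, 1) for XY
#' cells (one X copy is the normal male state). When sex is not recorded it
#' is inferred from the sex-chromosome calls (X = 1 with Y present is XY;
#' X = 2 with Y absent is XX); an irreconcilable pattern yields
#' `sex = "unknown"` and an autosomes-only classification, flagged.
#' A cell is aneuploid iff it gains or loses one or more chromosomes.
#'
#' @param karyotype a `chromosome_karyotype`.
#' @return object of class `aneuploidy_call`: list with `cell_id`, `sex`,
#'   `is_aneuploid`, `gained`, `lost`, `expected_cn`, `flags`.
#' @export
classify_aneuploid <- function(karyotype) {
  stopifnot(inherits(karyotype, "chromosome_karyotype"))
  sex <- attr(karyotype, "sex")
  cn <- stats::setNames(karyotype$copy_number, karyotype$chrom)
  flags <- character(0)
  x <- if ("chrX" %in% names(cn)) cn[["chrX"]] else NA_integer_
  y <- if ("chrY" %in% names(cn)) cn[["chrY"]] else NA_integer_
  if (is.na(sex) || !sex %in% c("XX", "XY")) {
    sex <- if (!is.na(x) && x == 1L && !is.na(y) && y >= 1L) "XY"
    else if (!is.na(x) && x == 2L && (is.na(y) || y == 0L)) "XX"
    else { flags <- c(flags, "sex_unresolved"); "unknown" }
  }
  expected <- stats::setNames(rep(2L, length(cn)), names(cn))
  if (sex == "XX") { expected["chrX"] <- 2L; expected["chrY"] <- 0L }
  if (sex == "XY") { expected["chrX"] <- 1L; expected["chrY"] <- 1L }
  use <- names(cn)
  if (sex == "unknown") use <- setdiff(use, c("chrX", "chrY"))
  expected <- expected[use]
  dev <- cn[use] - expected
  gained <- names(dev)[dev > 0]
  lost <- names(dev)[dev < 0]
  structure(list(cell_id = attr(karyotype, "cell_id"), sex = sex,
                 is_aneuploid = length(gained) + length(lost) > 0,
                 gained = gained, lost = lost, expected_cn = expected,
                 flags = flags),
            class = "aneuploidy_call")
}

#' GRCh37 APP-locus region preset
#'
#' The amyloid precursor protein gene region on chromosome 21
#' (chr21:27,252,861-27,543,446 in GRCh37, 0-based half-open), the locus
#' scanned for focal copy-number gains. `scale` shrinks the coordinates for
#' scaled-down genomes.
#'
#' @param scale multiplicative coordinate factor.
#' @return list `chrom`, `start`, `end`.
#' @export
app_locus <- function(scale = 1) {
  list(chrom = "chr21", start = round(27252861 * scale), end = round(27543446 * scale))
}

#' Parse a "chrom:start-end" region string
#' @param x region string (0-based half-open) or a list already of that form.
#' @return list `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  if (is.list(x)) return(x[c("chrom", "start", "end")])
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region: ", x)
  num <- function(s) as.numeric(gsub(",", "", s))
  list(chrom = m[2], start = num(m[3]), end = num(m[4]))
}

#' Scan a focal region for copy-number deviations
#'
#' Returns the decoded state of every bin overlapping a half-open genomic
#' region, plus the maximum state, to highlight focal gains (e.g. at the
#' APP locus).
#'
#' @param fit a decoded `copy_number_fit`.
#' @param grid the matching `bin_grid`.
#' @param region `list(chrom, start, end)` or a "chrom:start-end" string.
#' @return list with `bins` (data frame `bin`, `chrom`, `start`, `end`,
#'   `state`) and `max_state` (`NA` with a warning when no bin overlaps).
#' @export
focal_scan <- function(fit, grid, region) {
  validate_bin_grid(grid)
  region <- parse_region(region)
  i <- which(grid$chrom == region$chrom &
               grid$start < region$end & grid$end > region$start)
  if (!length(i)) {
    warning("region overlaps no bin")
    return(list(bins = data.frame(), max_state = NA_integer_))
  }
  bins <- data.frame(bin = i, chrom = grid$chrom[i], start = grid$start[i],
                     end = grid$end[i], state = fit$states[i],
                     stringsAsFactors = FALSE)
  list(bins = bins, max_state = max(bins$state))
}

#' Aneuploidy prevalence with an exact binomial confidence interval
#'
#' Prevalence as a percentage with the exact Clopper-Pearson interval
#' (computed by `stats::binom.test`) on the same percent scale. Accepts
#' either a list of `aneuploidy_call` objects or explicit counts.
#'
#' @param calls list of `aneuploidy_call`, or the number of aneuploid cells
#'   when `n` is given.
#' @param n total cells (when `calls` is a count).
#' @param confidence confidence level.
#' @return list `prevalence`, `ci_lower`, `ci_upper` (percent, unrounded),
#'   `x`, `n`.
#' @export
aneuploidy_prevalence <- function(calls, n = NULL, confidence = 0.95) {
  if (is.null(n)) {
    x <- sum(vapply(calls, function(a) isTRUE(a$is_aneuploid), logical(1)))
    n <- length(calls)
  } else {
    x <- as.integer(calls)
  }
  if (n < 1L) stop("need at least one cell")
  ci <- stats::binom.test(x, n, conf.level = confidence)$conf.int
  list(prevalence = 100 * x / n, ci_lower = 100 * ci[1], ci_upper = 100 * ci[2],
       x = x, n = n)
}

#' Per-chromosome gain/loss rates
#'
#' For each chromosome, the percentage of cells gaining it, losing it, and
#' either; a cell gaining several chromosomes contributes to each of them,
#' once each.
#'
#' @param calls list of `aneuploidy_call`.
#' @param chromosomes chromosomes to tabulate (default: all seen in the
#'   calls' expectations).
#' @return data frame `chrom`, `gain_pct`, `loss_pct`, `total_pct`, `n`.
#' @export
per_chromosome_rates <- function(calls, chromosomes = NULL) {
  n <- length(calls)
  if (n < 1L) stop("need at least one cell")
  if (is.null(chromosomes))
    chromosomes <- unique(unlist(lapply(calls, function(a) names(a$expected_cn))))
  g <- vapply(chromosomes, function(ch)
    sum(vapply(calls, function(a) ch %in% a$gained, logical(1))), numeric(1))
  l <- vapply(chromosomes, function(ch)
    sum(vapply(calls, function(a) ch %in% a$lost, logical(1))), numeric(1))
  data.frame(chrom = chromosomes, gain_pct = 100 * g / n, loss_pct = 100 * l / n,
             total_pct = 100 * (g + l) / n, n = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of two rate vectors
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum p-value, as used to compare
#' per-chromosome aneuploidy rates between groups: exact enumeration when
#' both samples have at most 10 values and there are no ties, otherwise the
#' normal approximation with continuity and tie correction. Degenerate
#' all-equal inputs return p = 1.
#'
#' @param rates_a,rates_b non-empty numeric vectors.
#' @return the two-sided p-value.
#' @export
compare_rates_wilcoxon <- function(rates_a, rates_b) {
  if (!length(rates_a) || !length(rates_b)) stop("both vectors must be non-empty")
  pooled <- c(rates_a, rates_b)
  if (length(unique(pooled)) == 1L) return(1)
  exact <- length(rates_a) <= 10L && length(rates_b) <= 10L &&
    !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(rates_a, rates_b, exact = exact, correct = TRUE)$p.value
  )
}

#' Cohort summary tables
#'
#' Builds the per-sample and pooled per-cohort aneuploidy tables from
#' per-cell records. Only QC-passing cells enter any numerator or
#' denominator. Per-sample percentages are reported to 2 decimals and
#' pooled cohort prevalences to 1 decimal (with exact Clopper-Pearson
#' intervals), alongside the unrounded values.
#'
#' @param cells data frame with columns `cell_id`, `sample`, `cohort`,
#'   `qc_pass` (logical), `is_aneuploid` (logical).
#' @param confidence confidence level for the pooled intervals.
#' @return list of class `cohort_summary`: `per_sample` and `pooled` data
#'   frames.
#' @export
build_cohort_summary <- function(cells, confidence = 0.95) {
  req <- c("cell_id", "sample", "cohort", "qc_pass", "is_aneuploid")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cells table missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(cells$cohort))) stop("every cell needs a cohort label")
  kept <- cells[cells$qc_pass, , drop = FALSE]
  empty <- setdiff(unique(cells$sample), unique(kept$sample))
  if (length(empty)) warning("sample(s) with no QC-passing cells excluded: ",
                             paste(empty, collapse = ", "))
  per_sample <- do.call(rbind, lapply(split(kept, kept$sample), function(d) {
    data.frame(sample = d$sample[1], cohort = d$cohort[1],
               n_cells = nrow(d), n_aneuploid = sum(d$is_aneuploid),
               percent = round(100 * sum(d$is_aneuploid) / nrow(d), 2),
               stringsAsFactors = FALSE)
  }))
  per_sample <- per_sample[order(per_sample$cohort, per_sample$sample), ]
  rownames(per_sample) <- NULL
  pooled <- do.call(rbind, lapply(split(kept, kept$cohort), function(d) {
    pr <- aneuploidy_prevalence(sum(d$is_aneuploid), n = nrow(d),
                                confidence = confidence)
    data.frame(cohort = d$cohort[1], n_cells = pr$n, n_aneuploid = pr$x,
               prevalence_pct = round(pr$prevalence, 1),
               ci_lower_pct = round(pr$ci_lower, 1),
               ci_upper_pct = round(pr$ci_upper, 1),
               prevalence_raw = pr$prevalence,
               ci_lower_raw = pr$ci_lower, ci_upper_raw = pr$ci_upper,
               stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  structure(list(per_sample = per_sample, pooled = pooled),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Per-sample aneuploidy:\n")
  print(x$per_sample)
  cat("\nPooled cohorts:\n")
  print(x$pooled[, c("cohort", "n_cells", "n_aneuploid", "prevalence_pct",
                     "ci_lower_pct", "ci_upper_pct")])
  invisible(x)
}
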