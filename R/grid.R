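#' Genomic bin grids
#'
#' A `bin_grid` is an ordered set of non-overlapping genomic bins tiling a
#' genome, the count space for all downstream analysis. Coordinates are
#' 0-based half-open throughout (BED convention). Each bin carries the local
#' GC fraction and mappability; bin widths vary inversely with mappability so
#' every bin holds roughly equal uniquely-mappable sequence, which is what
#' makes per-bin read counts comparable at ~1 Mb mean resolution.
#'
#' @param chrom character vector of chromosome names (one per bin).
#' @param start,end integer-valued bin bounds, 0-based half-open.
#' @param gc per-bin GC fraction in `[0, 1]`.
#' @param mappability per-bin mappability in `(0, 1]`.
#' @param bin_id optional bin identifiers; generated as `chrom:start-end`
#'   when missing.
#' @return A data frame of class `bin_grid` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappability`, `bin_id`, sorted by chromosome block then
#'   start.
#' @export
bin_grid <- function(chrom, start, end, gc, mappability, bin_id = NULL) {
  if (is.null(bin_id)) bin_id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  g <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    gc = as.numeric(gc),
    mappability = as.numeric(mappability),
    bin_id = as.character(bin_id),
    stringsAsFactors = FALSE
  )
  class(g) <- c("bin_grid", "data.frame")
  validate_bin_grid(g)
}

#' Validate a bin grid
#'
#' Checks the structural invariants: chromosomes form contiguous blocks,
#' bins are sorted and non-overlapping within a chromosome, `end > start`,
#' GC in `[0,1]` and mappability in `(0,1]`. Offending rows are named in the
#' error message.
#'
#' @param grid object to validate.
#' @return the validated grid, invisibly usable.
#' @export
validate_bin_grid <- function(grid) {
  req <- c("chrom", "start", "end", "gc", "mappability", "bin_id")
  miss <- setdiff(req, names(grid))
  if (length(miss)) stop("bin grid is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(grid) == 0L) stop("bin grid has no bins")
  bad <- which(grid$end <= grid$start)
  if (length(bad)) stop("bin(s) with end <= start at row(s): ", paste(bad, collapse = ", "))
  if (any(grid$gc < 0 | grid$gc > 1)) stop("gc fraction outside [0, 1]")
  if (any(grid$mappability <= 0 | grid$mappability > 1)) stop("mappability outside (0, 1]")
  # chromosome blocks must be contiguous
  r <- rle(grid$chrom)
  if (anyDuplicated(r$values)) stop("chromosome blocks are not contiguous: ",
                                    paste(unique(r$values[duplicated(r$values)]), collapse = ", "))
  for (ch in r$values) {
    i <- which(grid$chrom == ch)
    s <- grid$start[i]; e <- grid$end[i]
    if (is.unsorted(s, strictly = TRUE)) stop("bins unsorted on ", ch)
    ov <- which(s[-1] < e[-length(e)])
    if (length(ov)) stop("overlapping bins on ", ch, " at row(s): ",
                         paste(i[ov + 1L], collapse = ", "))
  }
  grid
}

#' Chromosome names of a grid, in grid order
#' @param grid a `bin_grid`.
#' @return character vector of chromosome names.
#' @export
grid_chromosomes <- function(grid) rle(grid$chrom)$values

#' GRCh37 chromosome lengths
#'
#' Lengths of the 22 autosomes plus X and Y in GRCh37, optionally scaled
#' down. A scale of 0.1 gives a genome of ~310 Mb (~310 bins at 1 Mb mean),
#' small enough that the full pipeline runs in seconds per cell while keeping
#' realistic chromosome-size proportions (chr21 is still among the smallest).
#'
#' @param scale multiplicative factor applied to every length.
#' @return named numeric vector `chr1` ... `chrY`.
#' @export
grch37_chrom_lengths <- function(scale = 1) {
  len <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
  )
  round(len * scale)
}

#' Simulate a variable-width bin grid
#'
#' Draws per-bin mappability and GC values and tiles each chromosome with
#' bins of width `Q / mappability`, where the global mass quantum `Q` is
#' chosen so the mean bin width equals the target. Every bin therefore
#' holds (to rounding) the same uniquely-mappable content genome-wide,
#' which is what makes per-bin counts comparable across chromosomes; the
#' last bin of each chromosome is truncated at the chromosome end (short
#' remnants are merged into the preceding bin), mirroring how real
#' variable-width binning behaves at telomeres.
#'
#' GC fractions follow a stationary AR(1) field along each chromosome
#' (mean 0.41, sd 0.05, lag-1 correlation 0.8, clipped to a realistic
#' range): Mb-scale GC in real genomes is spatially autocorrelated, and an
#' independent draw per bin would overstate bin-to-bin count variation.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   unnamed vectors are named `chr1..chrN`.
#' @param target_mean_width target mean bin width in bp.
#' @param seed integer seed.
#' @param gc_mean,gc_sd mean and stationary sd of the per-bin GC field.
#' @param mappability either `NULL` (draw from Beta(9, 1.5), mean ~0.86), a
#'   single number used for every bin, or a function `n -> values`.
#' @return a `bin_grid`.
#' @export
simulate_bin_grid <- function(chrom_lengths, target_mean_width = 1e6, seed = 1,
                              gc_mean = 0.41, gc_sd = 0.05, mappability = NULL) {
  if (target_mean_width <= 0) stop("target_mean_width must be positive")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (target_mean_width > min(chrom_lengths))
    stop("target_mean_width exceeds the shortest chromosome")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  draw_map <- if (is.null(mappability)) {
    function(n) stats::rbeta(n, 9, 1.5)
  } else if (is.function(mappability)) {
    mappability
  } else {
    function(n) rep(as.numeric(mappability), n)
  }
  with_seed(seed, {
    # global mass quantum: mean width Q * E[1/m] must equal the target
    pool <- pmin(pmax(draw_map(2000L), 0.05), 1)
    Q <- target_mean_width / mean(1 / pool)
    pieces <- lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      # piecewise-constant mappability field: windows of one mass quantum
      n_guess <- max(1L, ceiling(1.5 * L / Q))
      m <- pmin(pmax(draw_map(n_guess), 0.05), 1)
      w <- pmax(round(Q / m), 1)
      while (sum(w) < L) {
        m2 <- pmin(pmax(draw_map(n_guess), 0.05), 1)
        m <- c(m, m2); w <- c(w, pmax(round(Q / m2), 1))
      }
      nw <- which(cumsum(w) >= L)[1L]
      m <- m[seq_len(nw)]; w <- w[seq_len(nw)]
      wend <- pmin(cumsum(w), L); wstart <- c(0, wend[-nw])
      w <- wend - wstart
      # cut the field into n bins of exactly equal mappability mass, so
      # every bin of a chromosome holds the same expected mappable content
      mass <- m * w
      M <- sum(mass)
      n <- max(1L, as.integer(round(M / Q)))
      cum <- cumsum(mass)
      cuts <- if (n > 1L) vapply(M * seq_len(n - 1L) / n, function(tgt) {
        j <- which(cum >= tgt)[1L]
        prev <- if (j > 1L) cum[j - 1L] else 0
        wstart[j] + (tgt - prev) / m[j]
      }, numeric(1)) else numeric(0)
      bounds <- c(round(cuts), L)
      start <- c(0, bounds[-n])
      keep <- bounds > start
      bounds <- bounds[keep]; start <- start[keep]; n <- length(bounds)
      # recorded mappability = bin mass / bin width, consistent by construction
      mp <- pmin(pmax((M / length(bounds)) / (bounds - start), 0.05), 1)
      # stationary AR(1) GC field along the chromosome
      phi <- 0.8
      gc <- numeric(n)
      gc[1L] <- stats::rnorm(1, gc_mean, gc_sd)
      if (n > 1L) {
        eps <- stats::rnorm(n - 1L, 0, gc_sd * sqrt(1 - phi^2))
        for (t in 2L:n) gc[t] <- gc_mean + phi * (gc[t - 1L] - gc_mean) + eps[t - 1L]
      }
      gc <- pmin(pmax(gc, 0.25), 0.60)
      data.frame(chrom = ch, start = start, end = bounds,
                 gc = gc, mappability = mp, stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, pieces)
    bin_grid(g$chrom, g$start, g$end, g$gc, g$mappability)
  })
}

#' Build variable-width bins from a mappability track
#'
#' Cuts each chromosome into bins of equal summed mappability mass, so that
#' under uniform sampling of mappable positions every bin has the same
#' expected read count. The mass quantum is
#' `target_mean_width * genome-mean mappability`; bin boundaries are placed
#' by linear interpolation of the cumulative mass within track windows, and
#' per-bin GC/mappability are width-weighted averages of the overlapped
#' windows.
#'
#' @param track data frame with columns `chrom`, `start`, `end`,
#'   `mappability` and optionally `gc` (windowed values; 0-based half-open).
#' @param target_mean_width target mean bin width in bp.
#' @param chromosomes chromosomes to bin (default: all in the track); an
#'   absent chromosome is an error.
#' @return a `bin_grid`.
#' @export
build_variable_bins <- function(track, target_mean_width, chromosomes = NULL) {
  if (target_mean_width <= 0) stop("target_mean_width must be positive")
  req <- c("chrom", "start", "end", "mappability")
  if (!all(req %in% names(track))) stop("track needs columns: ", paste(req, collapse = ", "))
  if (is.null(track$gc)) track$gc <- 0.41
  if (is.null(chromosomes)) chromosomes <- unique(track$chrom)
  miss <- setdiff(chromosomes, unique(track$chrom))
  if (length(miss)) stop("chromosome(s) absent from track: ", paste(miss, collapse = ", "))
  w_all <- track$end - track$start
  mean_map <- sum(track$mappability * w_all) / sum(w_all)
  quantum <- target_mean_width * mean_map

  pieces <- lapply(chromosomes, function(ch) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    w <- tr$end - tr$start
    cum_mass <- cumsum(tr$mappability * w)       # mass at each window end
    total <- cum_mass[length(cum_mass)]
    n_bins <- max(1L, ceiling(total / quantum))   # last bin may be short
    cuts <- quantum * seq_len(n_bins - 1L)
    # interpolate cut positions within windows
    cut_pos <- vapply(cuts, function(m) {
      j <- which(cum_mass >= m)[1L]
      prev <- if (j > 1L) cum_mass[j - 1L] else 0
      tr$start[j] + (m - prev) / tr$mappability[j]
    }, numeric(1))
    bounds <- c(round(cut_pos), tr$end[length(w)])
    start <- c(tr$start[1L], bounds[-length(bounds)])
    keep <- bounds > start
    start <- start[keep]; bounds <- bounds[keep]
    # width-weighted window averages per bin
    avg <- function(vals, s, e) {
      ov <- pmin(tr$end, e) - pmax(tr$start, s)
      ov[ov < 0] <- 0
      sum(vals * ov) / sum(ov)
    }
    gc <- mapply(function(s, e) avg(tr$gc, s, e), start, bounds)
    mp <- mapply(function(s, e) avg(tr$mappability, s, e), start, bounds)
    data.frame(chrom = ch, start = start, end = bounds, gc = gc,
               mappability = pmin(pmax(mp, 1e-6), 1), stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  bin_grid(g$chrom, g$start, g$end, g$gc, g$mappability)
}

#' Read / write bin grids as BED-like TSV
#'
#' Six tab-separated columns with a header: `chrom`, `start`, `end`, `gc`,
#' `mappability`, `bin_id` (0-based half-open). Gzip-compressed files are
#' read transparently. The grid is validated on read and offending lines are
#' reported.
#'
#' @param path file path (optionally `.gz`).
#' @return `read_bins` returns a `bin_grid`.
#' @export
read_bins <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tryCatch(
    bin_grid(d$chrom, d$start, d$end, d$gc, d$mappability, d$bin_id),
    error = function(e) stop("invalid bin file '", path, "': ", conditionMessage(e), call. = FALSE)
  )
}

#' @rdname read_bins
#' @param grid a `bin_grid` to write.
#' @export
write_bins <- function(grid, path) {
  validate_bin_grid(grid)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(grid), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so package functions do not perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
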