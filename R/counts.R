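#' Binned cell counts
#'
#' A `binned_cell` holds one cell's per-bin read counts aligned to a
#' `bin_grid`, the GC-corrected counts once computed, and library metadata.
#'
#' @param cell_id cell identifier.
#' @param counts non-negative integer vector, one entry per grid bin.
#' @param corrected optional numeric vector of GC-corrected counts.
#' @param sample,cohort,sex metadata labels.
#' @param reads_sequenced total reads sequenced for the library (before
#'   deduplication/filtering), when known.
#' @param reads_kept reads retained after filtering; defaults to
#'   `sum(counts)`.
#' @param reads_dropped reads passing filters but falling outside all bins.
#' @return an object of class `binned_cell`.
#' @export
binned_cell <- function(cell_id, counts, corrected = NULL, sample = NA_character_,
                        cohort = NA_character_, sex = NA_character_,
                        reads_sequenced = NA_real_, reads_kept = sum(counts),
                        reads_dropped = 0L) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(cell_id = cell_id, counts = counts, corrected = corrected,
                 sample = sample, cohort = cohort, sex = sex,
                 reads_sequenced = reads_sequenced, reads_kept = reads_kept,
                 reads_dropped = reads_dropped, flags = character(0)),
            class = "binned_cell")
}

#' @export
print.binned_cell <- function(x, ...) {
  cat(sprintf("<binned_cell %s: %d bins, %d reads kept%s>\n", x$cell_id,
              length(x$counts), x$reads_kept,
              if (is.null(x$corrected)) "" else ", GC-corrected"))
  invisible(x)
}

#' Count filtered reads into bins
#'
#' Assigns each aligned read to the unique bin whose half-open interval
#' `[start, end)` contains its leftmost mapped position. Reads are excluded
#' when `mapq < mapq_min` (default keeps MAPQ > 10) or when flagged
#' duplicate (default on); excluded reads never appear in any tally. Reads
#' passing the filters but landing on a chromosome absent from the grid, or
#' beyond the binned span, are dropped and counted in `reads_dropped`.
#'
#' @param reads data frame with columns `chrom`, `pos` (0-based leftmost),
#'   `mapq`, and optionally `is_duplicate` (assumed FALSE when absent).
#' @param grid a `bin_grid`.
#' @param mapq_min minimum mapping quality kept (11 keeps MAPQ > 10).
#' @param drop_duplicates drop duplicate-flagged reads.
#' @param cell_id,sample,cohort,sex metadata passed through.
#' @return a `binned_cell` with `reads_sequenced = nrow(reads)`.
#' @export
count_reads <- function(reads, grid, mapq_min = 11L, drop_duplicates = TRUE,
                        cell_id = "cell", sample = NA_character_,
                        cohort = NA_character_, sex = NA_character_) {
  validate_bin_grid(grid)
  if (is.null(reads$is_duplicate)) reads$is_duplicate <- FALSE
  if (any(reads$pos < 0)) stop("read positions must be >= 0")
  keep <- reads$mapq >= mapq_min
  if (drop_duplicates) keep <- keep & !reads$is_duplicate
  r <- reads[keep, , drop = FALSE]
  counts <- integer(nrow(grid))
  dropped <- 0L
  for (ch in unique(r$chrom)) {
    i <- which(grid$chrom == ch)
    pos <- r$pos[r$chrom == ch]
    if (!length(i)) { dropped <- dropped + length(pos); next }
    # bins tile [min(start), max(end)) contiguously within a chromosome
    idx <- findInterval(pos, grid$start[i])
    inside <- idx >= 1L & pos < grid$end[i][pmax(idx, 1L)]
    dropped <- dropped + sum(!inside)
    tab <- tabulate(idx[inside], nbins = length(i))
    counts[i] <- counts[i] + tab
  }
  binned_cell(cell_id = cell_id, counts = counts, sample = sample,
              cohort = cohort, sex = sex, reads_sequenced = nrow(reads),
              reads_kept = sum(counts), reads_dropped = dropped)
}

#' Read aligned records from SAM/BAM
#'
#' Thin reader over Rsamtools returning the minimal record set the pipeline
#' consumes: chromosome, 0-based leftmost position, MAPQ, and the duplicate
#' FLAG bit. Plain-text SAM input is converted on the fly. Unmapped records
#' are skipped.
#'
#' @param path a SAM or BAM file.
#' @return data frame with columns `chrom`, `pos`, `mapq`, `is_duplicate`.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignments() requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(chrom = as.character(x$rname),
             pos = x$pos - 1L,                      # SAM POS is 1-based
             mapq = as.integer(x$mapq),
             is_duplicate = bitwAnd(x$flag, 1024L) > 0L,
             stringsAsFactors = FALSE)
}

#' GC-correct per-bin counts
#'
#' Removes the systematic dependence of counts on bin GC fraction by
#' dividing each count by the fitted count-vs-GC trend, normalized to unit
#' mean over bins and rescaled so total corrected mass equals total raw
#' mass. Zero counts stay exactly zero (the correction is multiplicative),
#' which preserves nullisomy evidence for the caller.
#'
#' The trend must not absorb copy-number signal: a monosomic chromosome
#' whose bins happen to sit at one end of the GC range would otherwise be
#' "corrected" back toward disomy. The estimator therefore backfits two
#' components: per-chromosome median levels (the copy signal, estimated
#' robustly and left untouched) and the GC trend proper, fitted to
#' level-normalized counts by robust local quadratic regression (loess,
#' span 0.3, symmetric family) on grids of at least 200 bins, or by a
#' GC-decile median ratio on smaller grids. Only the GC component is
#' divided out.
#'
#' @param cell a `binned_cell` with raw counts.
#' @param grid the matching `bin_grid`.
#' @param span loess smoother span.
#' @return the cell with `$corrected` populated; an all-zero cell is
#'   returned unchanged with a `"all_zero"` flag.
#' @export
gc_correct <- function(cell, grid, span = 0.3) {
  validate_bin_grid(grid)
  counts <- cell$counts
  if (length(counts) != nrow(grid)) stop("counts length does not match grid")
  if (length(counts) < 20L) stop("GC correction needs at least 20 bins")
  if (sum(counts) == 0) {
    cell$corrected <- numeric(length(counts))
    cell$flags <- union(cell$flags, "all_zero")
    return(cell)
  }
  gc <- grid$gc
  n <- length(counts)
  use <- counts > 0                 # zero bins carry no GC information
  f <- rep(1, n)
  for (iter in 1:3) {
    lev <- tapply((counts / f)[use], grid$chrom[use], stats::median)
    lev <- pmax(lev[grid$chrom], 1e-8)
    y <- counts / lev               # copy-level-normalized observations
    trend <- if (n >= 200L) {
      lo <- stats::loess(y[use] ~ gc[use], span = span, degree = 2,
                         family = "symmetric")
      stats::predict(lo, gc)
    } else {
      dec <- cut(gc, breaks = unique(stats::quantile(gc, probs = seq(0, 1, 0.1))),
                 include.lowest = TRUE)
      med <- tapply(y[use], dec[use], stats::median)
      as.numeric(med[dec])
    }
    trend[!is.finite(trend)] <- 1
    trend <- pmax(trend, 1e-8)
    f <- trend / mean(trend)
  }
  corrected <- counts / f
  corrected <- corrected * sum(counts) / sum(corrected)   # conserve mass
  cell$corrected <- pmax(corrected, 0)
  cell
}

#' Normalize counts to equal mappable content per bin
#'
#' Variable-width bins are built to hold equal mappable content, but the
#' realized grid records each bin's actual `mappability * width` mass, and
#' small deviations (chromosome-end rounding, bins-per-chromosome
#' quantization on scaled genomes) translate directly into per-bin rate
#' offsets that the copy-number caller would mistake for signal. This step
#' divides each (corrected) count by its bin's relative mass and rescales
#' so the total is preserved, putting every bin on a per-equal-mass basis.
#' Zeros stay zero.
#'
#' @param cell a `binned_cell` (uses `$corrected` when present, else raw
#'   counts).
#' @param grid the matching `bin_grid`.
#' @return the cell with `$corrected` replaced by mass-normalized values.
#' @export
normalize_mappable_mass <- function(cell, grid) {
  validate_bin_grid(grid)
  x <- if (is.null(cell$corrected)) cell$counts else cell$corrected
  if (length(x) != nrow(grid)) stop("counts length does not match grid")
  mass <- grid$mappability * (grid$end - grid$start)
  rel <- mass / mean(mass)
  out <- x / rel
  tot <- sum(x)
  if (tot > 0) out <- out * tot / sum(out)
  cell$corrected <- out
  cell
}

#' Read / write cell-by-bin count matrices
#'
#' The on-disk cohort format: a TSV count matrix with cells as rows
#' (`cell_id` first column) and bin ids as column headers in grid order,
#' plus an optional metadata TSV (`cell_id`, `sample`, `cohort`, `sex`,
#' `reads_sequenced`). Column order is validated against the grid and
#' mismatches name the offending bin.
#'
#' @param cells list of `binned_cell`.
#' @param grid the `bin_grid` the counts align to.
#' @param path count-matrix TSV path.
#' @param metadata_path optional metadata TSV path.
#' @return `read_counts` returns a list of `binned_cell`.
#' @export
write_counts <- function(cells, grid, path, metadata_path = NULL) {
  validate_bin_grid(grid)
  m <- do.call(rbind, lapply(cells, function(x) x$counts))
  df <- data.frame(cell_id = vapply(cells, function(x) x$cell_id, character(1)),
                   m, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("cell_id", grid$bin_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(
      cell_id = vapply(cells, function(x) x$cell_id, character(1)),
      sample = vapply(cells, function(x) as.character(x$sample), character(1)),
      cohort = vapply(cells, function(x) as.character(x$cohort), character(1)),
      sex = vapply(cells, function(x) as.character(x$sex), character(1)),
      reads_sequenced = vapply(cells, function(x) as.numeric(x$reads_sequenced), numeric(1)),
      stringsAsFactors = FALSE
    )
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, grid, metadata_path = NULL) {
  validate_bin_grid(grid)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(grid$bin_id, names(df))
  if (length(miss)) stop("count matrix is missing bin column(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  md <- NULL
  if (!is.null(metadata_path))
    md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    counts <- as.integer(df[i, grid$bin_id])
    meta <- list(sample = NA_character_, cohort = NA_character_,
                 sex = NA_character_, reads_sequenced = NA_real_)
    if (!is.null(md)) {
      j <- match(df$cell_id[i], md$cell_id)
      if (!is.na(j)) meta <- as.list(md[j, c("sample", "cohort", "sex", "reads_sequenced")])
    }
    cell <- binned_cell(cell_id = df$cell_id[i], counts = counts,
                        sample = meta$sample, cohort = meta$cohort,
                        sex = meta$sex, reads_sequenced = meta$reads_sequenced)
    if (sum(counts) == 0) {
      cell$flags <- union(cell$flags, "all_zero")
      message("cell ", cell$cell_id, " has all-zero counts")
    }
    cell
  })
}
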