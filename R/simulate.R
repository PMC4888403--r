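#' Karyotype specifications
#'
#' A `karyotype_spec` records the programmed integer copy number of every
#' chromosome of a simulated cell: sex ("XX" or "XY"), per-autosome overrides
#' (default 2), and X/Y copy numbers (defaults 2/0 for XX, 1/1 for XY). Copy
#' numbers are bounded by the caller's state space, 0 (nullisomy) to 10
#' (decasomy).
#'
#' @param sex "XX" or "XY".
#' @param autosome_cn named list/vector of integer copy numbers keyed by
#'   chromosome name (e.g. `c(chr21 = 3)`); unlisted autosomes are disomic.
#' @param x_cn,y_cn sex-chromosome copy numbers; `NULL` takes the default
#'   for `sex`.
#' @return an object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(sex = c("XX", "XY"), autosome_cn = NULL,
                           x_cn = NULL, y_cn = NULL) {
  sex <- match.arg(sex)
  if (is.null(x_cn)) x_cn <- if (sex == "XX") 2L else 1L
  if (is.null(y_cn)) y_cn <- if (sex == "XX") 0L else 1L
  autosome_cn <- as.list(autosome_cn)
  cn <- c(unlist(autosome_cn), chrX = x_cn, chrY = y_cn)
  if (any(cn < 0 | cn > 10)) stop("copy numbers must lie in [0, 10]")
  structure(list(sex = sex, autosome_cn = autosome_cn,
                 x_cn = as.integer(x_cn), y_cn = as.integer(y_cn)),
            class = "karyotype_spec")
}

#' Named karyotype presets
#'
#' Shorthand labels for the karyotypes used throughout the analyses:
#' `euploid_xx`, `euploid_xy`, `trisomy21_xx` (the Down's-syndrome positive
#' control), `trisomy21_xy`, and `monosomyX_xx`. Unknown labels are an error.
#'
#' @param label preset name.
#' @return a `karyotype_spec`.
#' @export
karyotype_preset <- function(label) {
  switch(label,
    euploid_xx   = karyotype_spec("XX"),
    euploid_xy   = karyotype_spec("XY"),
    trisomy21_xx = karyotype_spec("XX", autosome_cn = c(chr21 = 3L)),
    trisomy21_xy = karyotype_spec("XY", autosome_cn = c(chr21 = 3L)),
    monosomyX_xx = karyotype_spec("XX", x_cn = 1L),
    stop("unknown karyotype label: ", label)
  )
}

#' Copy number of each chromosome under a karyotype
#' @param karyotype a `karyotype_spec`.
#' @param chromosomes chromosome names to resolve.
#' @return named integer vector of copy numbers.
#' @export
karyotype_copy_numbers <- function(karyotype, chromosomes) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  cn <- vapply(chromosomes, function(ch) {
    if (ch == "chrX") return(karyotype$x_cn)
    if (ch == "chrY") return(karyotype$y_cn)
    v <- karyotype$autosome_cn[[ch]]
    if (is.null(v)) 2L else as.integer(v)
  }, integer(1))
  names(cn) <- chromosomes
  cn
}

#' Simulation configuration
#'
#' Parameters of the generative model for synthetic single-nucleus
#' libraries. Defaults emulate the study libraries: ~333,000 uniquely mapped
#' reads per cell spread over ~1 Mb bins, negative-binomial overdispersion,
#' and a smooth multiplicative GC bias.
#'
#' `dispersion` is the NB size parameter of the monosomy unit: a bin whose
#' chromosome has copy number s is drawn NB with mean `s * mu` and size
#' `s * dispersion`, i.e. variance `s * mu * (1 + mu/dispersion)` — exactly
#' the tied mean/variance structure the copy-number caller assumes, so
#' parameter recovery is well-posed.
#'
#' `quality_tier = "noisy"` divides the dispersion by 10 and inflates 5 % of
#' bins fivefold, producing cells that fail library QC.
#'
#' @param reads_per_cell_mean expected total (uniquely mapped) reads per cell.
#' @param dispersion NB size of the monosomy unit (> 0).
#' @param gc_bias_coefficients `c(b1, b2)` of the multiplicative quadratic
#'   bias `1 + b1*(gc - 0.41) + b2*(gc - 0.41)^2`, normalized to unit mean
#'   over the grid. The default spans roughly +/-25 % over the realistic
#'   Mb-scale GC range — a clearly detectable confounder, but the moderate
#'   amplitude expected of a library protocol without pre-amplification.
#' @param seed integer master seed.
#' @param quality_tier "good" or "noisy".
#' @param n_cells default cohort cell count (used when a cohort entry omits
#'   its own).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(reads_per_cell_mean = 333000, dispersion = 100,
                       gc_bias_coefficients = c(1.5, -6), seed = 1,
                       quality_tier = c("good", "noisy"), n_cells = 1L) {
  quality_tier <- match.arg(quality_tier)
  if (reads_per_cell_mean <= 0) stop("reads_per_cell_mean must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(reads_per_cell_mean = reads_per_cell_mean,
                 dispersion = dispersion,
                 gc_bias_coefficients = as.numeric(gc_bias_coefficients),
                 seed = as.integer(seed), quality_tier = quality_tier,
                 n_cells = as.integer(n_cells)),
            class = "sim_config")
}

# Multiplicative GC factor over a grid, normalized to unit mean and floored
# at 0.1 so the bias never kills a bin outright.
gc_bias_factor <- function(gc, coefficients) {
  d <- gc - 0.41
  g <- 1 + coefficients[1] * d + coefficients[2] * d^2
  g <- pmax(g, 0.1)
  g / mean(g)
}

#' Simulate one binned cell
#'
#' Draws per-bin read counts for a cell with a programmed karyotype. The
#' expected count of bin i is `u * cn_i * g(gc_i) * map_i * width_i /
#' mean_width`, with the per-haploid-copy unit rate `u` set so the expected
#' total equals `reads_per_cell_mean`; counts are NB with size
#' `cn_i * dispersion` (nullisomic bins are exactly zero). The recorded
#' `reads_sequenced` inflates the mapped total by the study's empirical
#' duplication factor (858,800 sequenced / 333,000 unique) so complexity
#' estimation has a sequenced-read denominator.
#'
#' @param grid a `bin_grid`.
#' @param karyotype a `karyotype_spec` or preset label.
#' @param config a `sim_config`.
#' @param cell_seed integer seed for this cell (defaults to `config$seed`).
#' @param cell_id,sample_id,cohort metadata labels.
#' @return a `binned_cell`.
#' @export
simulate_cell <- function(grid, karyotype, config = sim_config(),
                          cell_seed = config$seed, cell_id = "cell",
                          sample_id = "sample", cohort = "cohort") {
  validate_bin_grid(grid)
  if (nrow(grid) == 0L) stop("empty bin grid")
  if (is.character(karyotype)) karyotype <- karyotype_preset(karyotype)
  chroms <- grid_chromosomes(grid)
  cn_by_chrom <- karyotype_copy_numbers(karyotype, chroms)
  cn <- cn_by_chrom[grid$chrom]
  w <- grid$end - grid$start
  g <- gc_bias_factor(grid$gc, config$gc_bias_coefficients)
  base <- g * grid$mappability * w / mean(w)   # per-copy relative rate
  disp <- config$dispersion
  with_seed(cell_seed, {
    if (config$quality_tier == "noisy") {
      disp <- disp / 10
      out <- stats::runif(nrow(grid)) < 0.05
      base[out] <- base[out] * 5
    }
    u <- config$reads_per_cell_mean / sum(cn * base)
    mu <- u * base                              # monosomy unit mean per bin
    counts <- integer(nrow(grid))
    pos <- cn > 0
    counts[pos] <- stats::rnbinom(sum(pos), mu = cn[pos] * mu[pos],
                                  size = cn[pos] * disp)
    binned_cell(cell_id = cell_id, counts = counts, sample = sample_id,
                cohort = cohort, sex = karyotype$sex,
                reads_sequenced = round(sum(counts) * 858800 / 333000),
                reads_kept = sum(counts))
  })
}

#' Simulate a cohort of cells with known truth
#'
#' Generates cells for a list of samples, each with its own size and
#' karyotype distribution, and returns the per-cell per-chromosome truth
#' table alongside. Per-cell seeds are derived deterministically from the
#' config seed, so the whole cohort is byte-reproducible.
#'
#' @param grid a `bin_grid`.
#' @param cohort_spec list of entries `list(sample_id=, cohort=, n_cells=,
#'   karyotypes=)` where `karyotypes` is either a single preset label /
#'   `karyotype_spec`, or a list of `list(karyotype=, prob=)` mixture
#'   components.
#' @param config a `sim_config`.
#' @return `list(cells = list of binned_cell, truth = data.frame)`; the truth
#'   table has one row per cell and one column per chromosome.
#' @export
simulate_cohort <- function(grid, cohort_spec, config = sim_config()) {
  validate_bin_grid(grid)
  chroms <- grid_chromosomes(grid)
  resolve <- function(k) if (is.character(k)) karyotype_preset(k) else k
  cells <- list(); truth <- list()
  with_seed(config$seed, {
    for (entry in cohort_spec) {
      if (is.null(entry$n_cells) || entry$n_cells < 1) stop("each sample needs n_cells >= 1")
      kd <- entry$karyotypes
      if (inherits(kd, "karyotype_spec") || is.character(kd))
        kd <- list(list(karyotype = kd, prob = 1))
      probs <- vapply(kd, function(x) x$prob, numeric(1))
      cohort <- if (is.null(entry$cohort)) "cohort" else entry$cohort
      for (j in seq_len(entry$n_cells)) {
        pick <- sample.int(length(kd), 1L, prob = probs)
        ks <- resolve(kd[[pick]]$karyotype)
        cell_seed <- sample.int(.Machine$integer.max, 1L)
        cid <- sprintf("%s_c%03d", entry$sample_id, j)
        cell <- simulate_cell(grid, ks, config, cell_seed = cell_seed,
                              cell_id = cid, sample_id = entry$sample_id,
                              cohort = cohort)
        cells[[length(cells) + 1L]] <- cell
        truth[[length(truth) + 1L]] <- c(
          list(cell_id = cid, sample = entry$sample_id, cohort = cohort,
               sex = ks$sex),
          as.list(karyotype_copy_numbers(ks, chroms))
        )
      }
    }
  })
  truth <- do.call(rbind, lapply(truth, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  list(cells = cells, truth = truth)
}

#' Simulate a duplicate-bearing read library
#'
#' Samples `n_sequenced_reads` molecule identifiers with replacement from a
#' pool of `n_unique_molecules`, the generative process behind the
#' saturation of unique reads with sequencing depth. The number of distinct
#' identifiers follows the classical occupancy distribution with expectation
#' `n_unique * (1 - (1 - 1/n_unique)^n_reads)`.
#'
#' @param n_unique_molecules,n_sequenced_reads positive integers.
#' @param seed integer seed.
#' @return integer vector of molecule identifiers, length `n_sequenced_reads`.
#' @export
simulate_duplicate_library <- function(n_unique_molecules, n_sequenced_reads, seed = 1) {
  if (n_unique_molecules < 1 || n_sequenced_reads < 1)
    stop("both n_unique_molecules and n_sequenced_reads must be positive")
  with_seed(seed, sample.int(n_unique_molecules, n_sequenced_reads, replace = TRUE))
}
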