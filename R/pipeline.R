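#' Run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' input paths, output directory, thresholds (defaults are the study's:
#' MAPQ > 10, spikiness < 0.21, Bhattacharyya > 1.0, states up to 10), and
#' the seed recorded in the run manifest. Can be read from a JSON file.
#'
#' @param bins path to the bin-definition TSV.
#' @param counts path to the cell-by-bin count matrix TSV.
#' @param metadata optional path to the cell metadata TSV.
#' @param out_dir output directory (created if absent).
#' @param mapq_min,spikiness_max,bhattacharyya_min,s_max thresholds.
#' @param focal_region optional region (string or list) to scan per cell.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(bins, counts, metadata = NULL, out_dir = "results",
                       mapq_min = 11L, spikiness_max = 0.21,
                       bhattacharyya_min = 1.0, s_max = 10L,
                       focal_region = NULL, seed = 1L) {
  if (spikiness_max <= 0 || bhattacharyya_min <= 0 || s_max <= 0 || mapq_min < 0)
    stop("thresholds must be positive")
  structure(list(bins = bins, counts = counts, metadata = metadata,
                 out_dir = out_dir, mapq_min = mapq_min,
                 spikiness_max = spikiness_max,
                 bhattacharyya_min = bhattacharyya_min, s_max = s_max,
                 focal_region = focal_region, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with the fields of `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full copy-number pipeline
#'
#' Chains the analysis stages over a cohort on disk: read bins and counts,
#' GC-correct each cell, fit the copy-number HMM, compute QC metrics and
#' cluster-select good libraries, call whole-chromosome karyotypes with
#' sex-aware expected ploidies, and write summary tables. Artifacts written
#' under `out_dir`: `profiles/<cell>.bed` (per-bin states), `qc.tsv`,
#' `per_sample.tsv`, `pooled.tsv`, `per_chromosome_rates.tsv`, optionally
#' `focal_scan.tsv`, and `manifest.json` recording the package version,
#' seed and thresholds so a rerun reproduces every output.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the computed objects (`grid`, `cells`,
#'   `fits`, `qc`, `calls`, `summary`) and `artifacts` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$bins)) stop("bins file not found: ", config$bins)
  if (!file.exists(config$counts)) stop("counts file not found: ", config$counts)
  grid <- read_bins(config$bins)
  cells <- read_counts(config$counts, grid, metadata_path = config$metadata)
  message("pipeline: ", length(cells), " cells on ", nrow(grid), " bins")
  dir.create(file.path(config$out_dir, "profiles"), recursive = TRUE, showWarnings = FALSE)

  cells <- lapply(cells, function(cell)
    normalize_mappable_mass(gc_correct(cell, grid), grid))
  fits <- lapply(cells, function(cell)
    fit_copy_number_hmm(cell$corrected, grid, s_max = config$s_max))
  names(fits) <- vapply(cells, function(x) x$cell_id, character(1))

  qc <- do.call(rbind, Map(function(cell, fit) qc_cell(cell, fit, grid), cells, fits))
  # cluster within each sample (one individual, one sex): pooling samples
  # would let sex-linked coverage differences masquerade as quality clusters
  sample_of <- vapply(cells, function(x) as.character(x$sample), character(1))
  qc_parts <- lapply(unique(sample_of), function(s) {
    part <- qc[sample_of == s, , drop = FALSE]
    if (nrow(part) < 2L) {
      part$cluster <- 1L
      part$passes <- part$spikiness < config$spikiness_max &
        !is.na(part$bhattacharyya) & part$bhattacharyya > config$bhattacharyya_min
      part
    } else {
      cluster_by_quality(part, spikiness_max = config$spikiness_max,
                         bhattacharyya_min = config$bhattacharyya_min)
    }
  })
  qc <- do.call(rbind, qc_parts)
  qc <- qc[match(vapply(cells, function(x) x$cell_id, character(1)), qc$cell_id), ]
  rownames(qc) <- NULL
  message("pipeline: QC kept ", sum(qc$passes), "/", nrow(qc), " cells")

  calls <- Map(function(cell, fit)
    classify_aneuploid(call_chromosomes(fit, grid, cell_id = cell$cell_id,
                                        sex = cell$sex)),
    cells, fits)

  cell_table <- data.frame(
    cell_id = vapply(cells, function(x) x$cell_id, character(1)),
    sample = vapply(cells, function(x) as.character(x$sample), character(1)),
    cohort = vapply(cells, function(x) as.character(x$cohort), character(1)),
    qc_pass = qc$passes,
    is_aneuploid = vapply(calls, function(a) a$is_aneuploid, logical(1)),
    stringsAsFactors = FALSE
  )
  summary <- build_cohort_summary(cell_table)
  rates <- per_chromosome_rates(calls[qc$passes], chromosomes = grid_chromosomes(grid))

  paths <- list(
    qc = file.path(config$out_dir, "qc.tsv"),
    per_sample = file.path(config$out_dir, "per_sample.tsv"),
    pooled = file.path(config$out_dir, "pooled.tsv"),
    rates = file.path(config$out_dir, "per_chromosome_rates.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(qc, paths$qc); wt(summary$per_sample, paths$per_sample)
  wt(summary$pooled, paths$pooled); wt(rates, paths$rates)
  for (i in seq_along(cells))
    write_profile(fits[[i]], grid,
                  file.path(config$out_dir, "profiles",
                            paste0(cells[[i]]$cell_id, ".bed")))
  if (!is.null(config$focal_region)) {
    scan <- do.call(rbind, Map(function(cell, fit) {
      fs <- focal_scan(fit, grid, config$focal_region)
      data.frame(cell_id = cell$cell_id, max_state = fs$max_state)
    }, cells, fits))
    paths$focal <- file.path(config$out_dir, "focal_scan.tsv")
    wt(scan, paths$focal)
  }
  manifest <- list(
    package = "scploidy",
    version = as.character(utils::packageVersion("scploidy")),
    seed = config$seed,
    thresholds = list(mapq_min = config$mapq_min,
                      spikiness_max = config$spikiness_max,
                      bhattacharyya_min = config$bhattacharyya_min,
                      s_max = config$s_max),
    inputs = list(bins = config$bins, counts = config$counts,
                  metadata = config$metadata),
    n_cells = length(cells), n_bins = nrow(grid),
    n_pass_qc = sum(qc$passes)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(grid = grid, cells = cells, fits = fits, qc = qc,
                 calls = calls, summary = summary, rates = rates,
                 artifacts = paths))
}
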