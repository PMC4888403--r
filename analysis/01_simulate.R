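#!/usr/bin/env Rscript
# Step 1 -- simulate the study-shaped inputs.
#
# Builds a scaled GRCh37-proportioned variable-width bin grid (~1 Mb mean,
# genome scaled 1/10 so every later step runs in seconds per cell) and three
# seeded cohorts shaped like the study's key samples:
#   * DS      -- 36 trisomy-21 XX nuclei (the positive control),
#   * Control1 -- 81 euploid XY nuclei (the first control sample),
#   * Plate1  -- a 30-cell mixed plate, half good-tier and half noisy-tier,
#               to exercise quality control.
# Writes bins/counts/metadata/truth TSVs under results/sim/.

suppressPackageStartupMessages(library(scploidy))

seed <- 20160531L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- simulate_bin_grid(grch37_chrom_lengths(0.1), 1e6, seed = seed)
message(sprintf("grid: %d bins over 24 chromosomes, mean width %.0f bp",
                nrow(grid), mean(grid$end - grid$start)))
write_bins(grid, file.path(out, "bins.tsv"))

ds <- simulate_cohort(grid, list(list(sample_id = "DS", cohort = "DS",
                                      n_cells = 36, karyotypes = "trisomy21_xx")),
                      sim_config(seed = seed + 1L))
ctl <- simulate_cohort(grid, list(list(sample_id = "Control1", cohort = "control",
                                       n_cells = 81, karyotypes = "euploid_xy")),
                       sim_config(seed = seed + 2L))
good <- simulate_cohort(grid, list(list(sample_id = "Plate1", cohort = "plate",
                                        n_cells = 15, karyotypes = "euploid_xx")),
                        sim_config(seed = seed + 3L, quality_tier = "good"))
noisy <- simulate_cohort(grid, list(list(sample_id = "Plate1", cohort = "plate",
                                         n_cells = 15, karyotypes = "euploid_xx")),
                         sim_config(seed = seed + 4L, quality_tier = "noisy"))
# the noisy plate half gets distinct cell ids
noisy$cells <- lapply(noisy$cells, function(x) { x$cell_id <- sub("_c", "_n", x$cell_id); x })
noisy$truth$cell_id <- sub("_c", "_n", noisy$truth$cell_id)

cells <- c(ds$cells, ctl$cells, good$cells, noisy$cells)
truth <- rbind(ds$truth, ctl$truth, good$truth, noisy$truth)
write_counts(cells, grid, file.path(out, "counts.tsv"),
             metadata_path = file.path(out, "meta.tsv"))
utils::write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
# the plate's noisy half is the planted QC-negative set
tier <- data.frame(cell_id = vapply(cells, `[[`, "", "cell_id"),
                   tier = rep(c("good", "good", "good", "noisy"),
                              times = c(36, 81, 15, 15)))
utils::write.table(tier, file.path(out, "tier.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("simulated %d cells (%d DS, %d control, %d mixed plate); mean %.0f reads/cell",
                length(cells), 36, 81, 30,
                mean(vapply(cells, `[[`, 0, "reads_kept"))))
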