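test_that("simulated bin grids tile each chromosome and hit the target width", {
  lens <- grch37_chrom_lengths(0.1)
  g <- test_grid()
  for (ch in names(lens)) {
    b <- g[g$chrom == ch, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], unname(lens[ch]))
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))   # no gaps, no overlaps
  }
  expect_lt(abs(mean(g$end - g$start) - 1e6) / 1e6, 0.05)
  # uniform mappability forces uniform widths: 100 equal 1 Mb bins
  u <- simulate_bin_grid(c(chrA = 1e8), 1e6, seed = 3, mappability = 1)
  expect_equal(nrow(u), 100L)
  expect_true(all(u$end - u$start == 1e6))
  expect_error(simulate_bin_grid(c(chrA = 1e8), -5), "positive")
  expect_error(simulate_bin_grid(c(chrA = 1e5), 1e6), "shortest")
})

test_that("bin widths scale inversely with mappability, equalizing mappable content", {
  g <- simulate_bin_grid(c(chrA = 2e8), 1e6, seed = 7,
                         mappability = function(n) rep(c(1, 0.5), length.out = n))
  w <- g$end - g$start
  w_hi <- w[g$mappability > 0.9]
  w_lo <- w[g$mappability < 0.6]
  expect_gt(length(w_hi), 10); expect_gt(length(w_lo), 10)
  expect_equal(mean(w_lo) / mean(w_hi), 2, tolerance = 0.05)
  mass <- g$mappability * w
  expect_lt(stats::sd(mass) / mean(mass), 0.02)
})

test_that("per-bin count means are proportional to programmed copy number", {
  grid <- test_grid()
  ks <- karyotype_spec("XX", autosome_cn = c(chr13 = 1L, chr21 = 3L, chr22 = 4L))
  # GC bias off: linearity in copy number is this invariant's concern;
  # GC confounding and its removal are covered separately
  cfg <- sim_config(seed = 40, gc_bias_coefficients = c(0, 0))
  # average counts over cells so the slope test sees the mean structure
  cn <- karyotype_copy_numbers(ks, grid_chromosomes(grid))[grid$chrom]
  acc <- rowMeans(sapply(1:5, function(i)
    simulate_cell(grid, ks, cfg, cell_seed = 500 + i)$counts))
  sl <- summary(stats::lm(acc ~ unname(cn)))
  expect_gt(sl$r.squared, 0.95)
  # trisomy 21 bins average ~1.5x disomic autosome bins
  m21 <- mean(acc[grid$chrom == "chr21"])
  m2 <- mean(acc[grid$chrom %in% paste0("chr", 1:12)])
  expect_equal(m21 / m2, 1.5, tolerance = 0.1)
  # nullisomy is a delta at zero
  k0 <- karyotype_spec("XX", autosome_cn = c(chr9 = 0L))
  c0 <- simulate_cell(grid, k0, cfg, cell_seed = 77)
  expect_true(all(c0$counts[grid$chrom == "chr9"] == 0))
})

test_that("total simulated reads match the configured depth within 3 SD", {
  grid <- simulate_bin_grid(c(chrA = 1e9), 1e6, seed = 9, mappability = 1)
  expect_gte(nrow(grid), 1000L)
  cfg <- sim_config(reads_per_cell_mean = 3e5, dispersion = 100,
                    gc_bias_coefficients = c(0, 0), seed = 1)
  ks <- karyotype_spec("XX", x_cn = 2L)   # chrA defaults to disomy
  cell <- simulate_cell(grid, ks, cfg, cell_seed = 11)
  # analytic total variance: per bin NB(mu = 2u, size = 2*disp)
  mu_bin <- 3e5 / nrow(grid)
  var_tot <- sum(rep(mu_bin + mu_bin^2 / (2 * cfg$dispersion), nrow(grid)))
  expect_lt(abs(sum(cell$counts) - 3e5), 3 * sqrt(var_tot))
})

test_that("simulation is deterministic under a fixed seed", {
  grid <- test_grid()
  spec <- list(list(sample_id = "S1", cohort = "ctl", n_cells = 3,
                    karyotypes = "euploid_xy"))
  cfg <- sim_config(seed = 123)
  a <- simulate_cohort(grid, spec, cfg)
  b <- simulate_cohort(grid, spec, cfg)
  expect_identical(lapply(a$cells, `[[`, "counts"), lapply(b$cells, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
  g2 <- simulate_bin_grid(grch37_chrom_lengths(0.1), 1e6, seed = 101)
  expect_identical(as.data.frame(test_grid()), as.data.frame(g2))
})

test_that("cohort truth tables record the programmed karyotypes", {
  grid <- test_grid()
  cfg <- sim_config(seed = 5, reads_per_cell_mean = 1e4)  # depth irrelevant for truth
  ds <- simulate_cohort(grid, list(list(sample_id = "DS", cohort = "DS",
                                        n_cells = 36, karyotypes = "trisomy21_xx")), cfg)
  expect_equal(nrow(ds$truth), 36L)
  expect_true(all(ds$truth$chr21 == 3))
  expect_true(all(ds$truth$chrX == 2) && all(ds$truth$chrY == 0))
  eu <- simulate_cohort(grid, list(list(sample_id = "C", cohort = "ctl",
                                        n_cells = 81, karyotypes = "euploid_xy")), cfg)
  auto <- as.matrix(eu$truth[, paste0("chr", 1:22)])
  expect_true(all(auto == 2))
  expect_true(all(eu$truth$chrX == 1) && all(eu$truth$chrY == 1))
  expect_error(simulate_cohort(grid, list(list(sample_id = "B", cohort = "x",
                                               n_cells = 1, karyotypes = "nonsense")), cfg),
               "unknown karyotype")
})

test_that("duplicate libraries follow the occupancy curve", {
  expect_equal(length(unique(simulate_duplicate_library(1, 50, seed = 1))), 1L)
  # 10 draws from 1000 molecules: collisions have probability < 5 %
  n_distinct <- sapply(1:20, function(s)
    length(unique(simulate_duplicate_library(1000, 10, seed = s))))
  expect_gte(mean(n_distinct == 10), 0.9)
  # deep sampling approaches the occupancy expectation
  occ <- occupancy_moments(1000, 10000)
  d <- length(unique(simulate_duplicate_library(1000, 10000, seed = 42)))
  expect_lt(abs(d - occ$mean), 3 * sqrt(occ$var) + 1)
  expect_error(simulate_duplicate_library(0, 10), "positive")
  expect_identical(simulate_duplicate_library(50, 100, seed = 9),
                   simulate_duplicate_library(50, 100, seed = 9))
})

test_that("GC confounding is present before correction and removed after", {
  grid <- simulate_bin_grid(c(chrA = 1e9), 1e6, seed = 21)
  ks <- karyotype_spec("XX", x_cn = 2L)
  cfg <- sim_config(seed = 3)
  cell <- simulate_cell(grid, ks, cfg, cell_seed = 31)
  r_raw <- stats::cor(cell$counts, grid$gc)
  expect_gt(abs(r_raw), 0.1)
  cell <- gc_correct(cell, grid)
  expect_lt(abs(stats::cor(cell$corrected, grid$gc)), 0.05)
})
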