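two_bin_grid <- function() {
  bin_grid(chrom = c("chr1", "chr1"), start = c(0, 1e6), end = c(1e6, 2e6),
           gc = c(0.4, 0.42), mappability = c(1, 1))
}

test_that("reads are filtered by MAPQ/duplicate flags and assigned half-open", {
  g <- two_bin_grid()
  reads <- data.frame(chrom = "chr1", pos = c(0, 999999, 1000000),
                      mapq = 30, is_duplicate = FALSE)
  cell <- count_reads(reads, g)
  expect_equal(cell$counts, c(2L, 1L))
  # one of 3 reads below the MAPQ-10 cutoff is excluded
  reads$mapq <- c(30, 5, 30)
  expect_equal(sum(count_reads(reads, g)$counts), 2L)
  # 4 reads, two duplicates of one molecule -> 3 kept
  r4 <- data.frame(chrom = "chr1", pos = c(10, 10, 500, 1.5e6), mapq = 30,
                   is_duplicate = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(count_reads(r4, g)$counts), 3L)
  expect_equal(sum(count_reads(r4, g, drop_duplicates = FALSE)$counts), 4L)
})

test_that("counting conserves reads and ignores input order", {
  g <- test_grid()
  set.seed(77)
  n <- 5000
  reads <- data.frame(
    chrom = sample(c(grid_chromosomes(g), "chrM"), n, replace = TRUE),
    pos = sample.int(3e7, n) - 1L,
    mapq = sample(c(0, 5, 30, 60), n, replace = TRUE),
    is_duplicate = stats::runif(n) < 0.1
  )
  cell <- count_reads(reads, g)
  n_pass <- sum(reads$mapq >= 11 & !reads$is_duplicate)
  expect_equal(sum(cell$counts) + cell$reads_dropped, n_pass)
  expect_equal(cell$reads_kept, sum(cell$counts))
  perm <- count_reads(reads[sample.int(n), ], g)
  expect_identical(perm$counts, cell$counts)
})

test_that("GC correction inverts a planted bias and conserves mass", {
  grid <- simulate_bin_grid(c(chrA = 1e9), 1e6, seed = 13)
  gfac <- 1 + 2 * (grid$gc - 0.41) - 10 * (grid$gc - 0.41)^2
  cell <- binned_cell("planted", round(100 * gfac))
  out <- gc_correct(cell, grid)
  expect_lt(max(abs(out$corrected - mean(out$corrected)) / mean(out$corrected)), 0.05)
  expect_lt(abs(sum(out$corrected) - sum(cell$counts)) / sum(cell$counts), 0.01)
  # GC-independent counts are (nearly) untouched
  set.seed(4)
  flat <- binned_cell("flat", stats::rpois(nrow(grid), 500))
  out2 <- gc_correct(flat, grid)
  expect_lt(max(abs(out2$corrected - flat$counts) / flat$counts), 0.05)
  # all-zero cells come back flagged, still all zero
  z <- gc_correct(binned_cell("zero", integer(nrow(grid))), grid)
  expect_true("all_zero" %in% z$flags)
  expect_true(all(z$corrected == 0))
  expect_error(gc_correct(binned_cell("tiny", rep(1L, 5)),
                          simulate_bin_grid(c(chrA = 5e6), 1e6, seed = 1)),
               "20 bins")
})

test_that("correction never produces negatives and keeps zeros at zero", {
  r <- sim_fit_cell("euploid_xx", cell_seed = 901)
  expect_true(all(r$cell$corrected >= 0))
  expect_true(all(r$cell$corrected[r$cell$counts == 0] == 0))
})

test_that("variable bins from a track hold equal mappability mass", {
  win <- function(ch, m) data.frame(chrom = ch, start = seq(0, 9.9e6, 1e5),
                                    end = seq(1e5, 1e7, 1e5), mappability = m,
                                    gc = 0.4)
  flat <- build_variable_bins(win("chrA", 1), 1e6)
  expect_true(all(flat$end - flat$start == 1e6))
  expect_equal(nrow(flat), 10L)
  expect_error(build_variable_bins(win("chrA", 1), 1e6, chromosomes = "chrZ"),
               "absent")
  # chrom B at half mappability gets ~2x wider bins and equal expected
  # counts per bin under uniform sampling of mappable positions
  tr <- rbind(win("chrA", 1), win("chrB", 0.5))
  bb <- build_variable_bins(tr, 1e6)
  wA <- with(bb[bb$chrom == "chrA", ], mean(end - start))
  wB <- with(bb[bb$chrom == "chrB", ], mean(end - start))
  expect_equal(wB / wA, 2, tolerance = 0.2)
  set.seed(8)
  nA <- 20000; nB <- 10000    # reads proportional to mappable content
  reads <- data.frame(
    chrom = c(rep("chrA", nA), rep("chrB", nB)),
    pos = c(sample.int(1e7, nA, replace = TRUE),
            sample.int(1e7, nB, replace = TRUE)) - 1L,
    mapq = 60, is_duplicate = FALSE
  )
  cell <- count_reads(reads, bb)
  mA <- mean(cell$counts[bb$chrom == "chrA"])
  mB <- mean(cell$counts[bb$chrom == "chrB"])
  expect_equal(mB / mA, 1, tolerance = 0.15)
  # bin count x mean width ~ genome length
  expect_lt(abs(nrow(bb) * mean(bb$end - bb$start) - 2e7), 2e6)
})

test_that("a haploid chromosome at a GC extreme is not corrected toward disomy", {
  # all chrY bins at the low-GC edge: the trend must not absorb their
  # half-depth, or male cells would be called chrY-disomic
  lens <- grch37_chrom_lengths(0.1)
  g <- simulate_bin_grid(lens, 1e6, seed = 7)    # chrY GC 0.28-0.35 here
  expect_lt(max(g$gc[g$chrom == "chrY"]), 0.36)
  cfg <- sim_config(seed = 9)
  ratios <- sapply(1:5, function(i) {
    cell <- simulate_cell(g, "euploid_xy", cfg, cell_seed = 800 + i)
    cell <- normalize_mappable_mass(gc_correct(cell, g), g)
    mean(cell$corrected[g$chrom == "chrY"]) /
      (mean(cell$corrected[g$chrom %in% paste0("chr", 1:12)]) / 2)
  })
  expect_lt(max(ratios), 1.35)   # stays nearer one copy than two
  expect_gt(min(ratios), 0.65)
})
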