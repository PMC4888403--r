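grid_n <- function(n, chrom = "chr1")
  bin_grid(rep(chrom, n), seq(0, (n - 1)) * 1e6, seq_len(n) * 1e6,
           gc = rep(0.4, n), mappability = rep(1, n))

fit_of <- function(states) structure(list(states = as.integer(states)),
                                     class = "copy_number_fit")

test_that("modal chromosome calls use conservative tie-breaking", {
  k <- call_chromosomes(fit_of(rep(3L, 10)), grid_n(10), sex = "XX")
  expect_equal(k$copy_number, 3L)
  expect_equal(k$support, 1.0)
  k2 <- call_chromosomes(fit_of(c(rep(2L, 30), rep(3L, 70))), grid_n(100))
  expect_equal(k2$copy_number, 3L)
  expect_equal(k2$support, 0.7)
  # 50/50 split resolves toward disomy
  k3 <- call_chromosomes(fit_of(c(rep(2L, 5), rep(3L, 5))), grid_n(10))
  expect_equal(k3$copy_number, 2L)
  # equidistant 1 vs 3 tie resolves to the smaller state
  k4 <- call_chromosomes(fit_of(c(rep(1L, 5), rep(3L, 5))), grid_n(10))
  expect_equal(k4$copy_number, 1L)
})

test_that("aneuploidy classification is sex-aware", {
  g <- test_grid()
  mk <- function(per_chrom) {
    states <- rep(2L, nrow(g))
    for (ch in names(per_chrom)) states[g$chrom == ch] <- per_chrom[[ch]]
    states
  }
  # XX cell with trisomy 21
  a <- classify_aneuploid(call_chromosomes(
    fit_of(mk(list(chr21 = 3L, chrY = 0L))), g, sex = "XX"))
  expect_true(a$is_aneuploid)
  expect_equal(a$gained, "chr21")
  expect_length(a$lost, 0)
  # euploid male: one X and one Y is the expected state
  b <- classify_aneuploid(call_chromosomes(
    fit_of(mk(list(chrX = 1L, chrY = 1L))), g, sex = "XY"))
  expect_false(b$is_aneuploid)
  # sex inferred from the calls when not recorded
  b2 <- classify_aneuploid(call_chromosomes(
    fit_of(mk(list(chrX = 1L, chrY = 1L))), g))
  expect_equal(b2$sex, "XY")
  expect_false(b2$is_aneuploid)
  # four simultaneous gains
  d <- classify_aneuploid(call_chromosomes(
    fit_of(mk(list(chr13 = 3L, chr16 = 3L, chr21 = 3L, chr22 = 3L, chrY = 0L))),
    g, sex = "XX"))
  expect_setequal(d$gained, c("chr13", "chr16", "chr21", "chr22"))
  # irreconcilable sex pattern: autosomes-only classification, flagged
  e <- classify_aneuploid(call_chromosomes(
    fit_of(mk(list(chrX = 1L, chrY = 0L, chr7 = 3L))), g))
  expect_equal(e$sex, "unknown")
  expect_true("sex_unresolved" %in% e$flags)
  expect_equal(e$gained, "chr7")
  expect_false(any(c("chrX", "chrY") %in% names(e$expected_cn)))
})

test_that("focal scans report overlapping bins and the maximum state", {
  g <- grid_n(50, "chr21")
  states <- rep(2L, 50); states[30] <- 5L
  hit <- focal_scan(fit_of(states), g, "chr21:29000000-30500000")
  expect_equal(hit$max_state, 5L)
  flat <- focal_scan(fit_of(rep(2L, 50)), g, list(chrom = "chr21", start = 27252861, end = 27543446))
  expect_equal(flat$max_state, 2L)
  # region smaller than a bin overlaps exactly one bin
  sub <- focal_scan(fit_of(states), g, "chr21:100-200")
  expect_equal(nrow(sub$bins), 1L)
  expect_warning(out <- focal_scan(fit_of(states), g, "chr9:0-100"), "no bin")
  expect_true(is.na(out$max_state))
})

test_that("prevalence and exact intervals reproduce printed cohort numbers", {
  ad <- aneuploidy_prevalence(5, n = 893)
  expect_equal(round(ad$prevalence, 1), 0.6)
  expect_equal(round(ad$ci_lower, 1), 0.2)
  expect_equal(round(ad$ci_upper, 1), 1.3)
  z <- aneuploidy_prevalence(0, n = 100)
  expect_equal(z$prevalence, 0)
  expect_equal(z$ci_lower, 0)
  expect_equal(round(aneuploidy_prevalence(4, n = 72)$prevalence, 2), 5.56)
  # also accepts a list of calls
  calls <- c(replicate(3, list(list(is_aneuploid = TRUE)), simplify = FALSE),
             replicate(7, list(list(is_aneuploid = FALSE)), simplify = FALSE))
  calls <- lapply(calls, function(x) structure(x[[1]], class = "aneuploidy_call"))
  expect_equal(aneuploidy_prevalence(calls)$prevalence, 30)
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(2024)
  p <- 0.007; n <- 589
  x <- stats::rbinom(2000, n, p)
  cover <- vapply(x, function(xi) {
    ci <- aneuploidy_prevalence(xi, n = n)
    ci$ci_lower <= 100 * p && 100 * p <= ci$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("per-chromosome rates count each cell once per chromosome", {
  mkcall <- function(g = character(0), l = character(0))
    structure(list(is_aneuploid = length(c(g, l)) > 0, gained = g, lost = l,
                   expected_cn = stats::setNames(rep(2L, 24), c(paste0("chr", 1:22), "chrX", "chrY"))),
              class = "aneuploidy_call")
  calls <- c(list(mkcall(g = "chr16"), mkcall(g = c("chr4", "chr16"))),
             replicate(587, mkcall(), simplify = FALSE))
  r <- per_chromosome_rates(calls)
  expect_equal(round(r$total_pct[r$chrom == "chr16"], 2), 0.34)
  expect_equal(r$total_pct[r$chrom == "chr4"], 100 * 1 / 589)
  expect_equal(r$total_pct[r$chrom == "chr5"], 0)
  expect_true(all(r$n == 589))
})

test_that("rank-sum comparisons: exact, approximate, degenerate", {
  expect_equal(compare_rates_wilcoxon(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_rates_wilcoxon(rep(2, 5), rep(2, 4)), 1)
  # exact two-sided p for a fully separated 3 vs 3
  expect_equal(compare_rates_wilcoxon(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # approximation tracks exhaustive enumeration for n = 8 vs 8
  set.seed(31)
  for (i in 1:3) {
    a <- stats::runif(8); b <- stats::runif(8) + 0.2
    p_enum <- enum_wilcox_p(a, b)
    p_apx <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_apx - p_enum), 0.02)
    expect_equal(compare_rates_wilcoxon(a, b), p_enum, tolerance = 1e-12)
  }
})

test_that("cohort summaries mirror the per-sample table layout", {
  samples <- data.frame(
    sample = paste0("Control ", 1:6),
    n = c(81, 80, 108, 72, 128, 120),
    x = c(0, 0, 0, 4, 0, 0)
  )
  cells <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    data.frame(cell_id = sprintf("%s_%03d", samples$sample[i], seq_len(samples$n[i])),
               sample = samples$sample[i], cohort = "control",
               qc_pass = TRUE,
               is_aneuploid = seq_len(samples$n[i]) <= samples$x[i])
  }))
  s <- build_cohort_summary(cells)
  expect_equal(s$pooled$n_cells, 589L)
  expect_equal(s$pooled$n_aneuploid, 4L)
  expect_equal(s$pooled$prevalence_pct, 0.7)
  expect_equal(s$per_sample$percent[s$per_sample$sample == "Control 4"], 5.56)
  expect_true(all(s$per_sample$percent[s$per_sample$sample != "Control 4"] == 0))
  # QC-failing aneuploid cells enter neither numerator nor denominator
  cells2 <- cells
  cells2$qc_pass[cells2$sample == "Control 1"][1] <- FALSE
  cells2$is_aneuploid[cells2$sample == "Control 1"][1] <- TRUE
  s2 <- build_cohort_summary(cells2)
  expect_equal(s2$pooled$n_cells, 588L)
  expect_equal(s2$pooled$n_aneuploid, 4L)
  # a sample with no passing cells is excluded with a warning
  cells3 <- cells
  cells3$qc_pass[cells3$sample == "Control 2"] <- FALSE
  expect_warning(s3 <- build_cohort_summary(cells3), "Control 2")
  expect_false("Control 2" %in% s3$per_sample$sample)
  expect_error(build_cohort_summary(cells[, -3]), "missing column")
})
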