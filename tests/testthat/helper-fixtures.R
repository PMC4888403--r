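# Shared fixtures and independent oracles. Fixtures are generated in code
# (seeded) and cached so several test files can reuse the expensive ones.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# scaled-down GRCh37-proportioned grid used across the suite (~320 bins)
test_grid <- function() {
  cached("grid", function() simulate_bin_grid(grch37_chrom_lengths(0.1), 1e6, seed = 101))
}

# simulate one cell, GC-correct it and fit the copy-number HMM
sim_fit_cell <- function(karyotype = "euploid_xx", cell_seed = 1,
                         tier = "good", depth = 333000, grid = test_grid(),
                         cell_id = "cell") {
  cfg <- sim_config(reads_per_cell_mean = depth, quality_tier = tier, seed = cell_seed)
  cell <- simulate_cell(grid, karyotype, cfg, cell_seed = cell_seed, cell_id = cell_id)
  cell <- normalize_mappable_mass(gc_correct(cell, grid), grid)
  list(cell = cell, fit = fit_copy_number_hmm(cell$corrected, grid))
}

# mixed-quality plate of QC reports: 8 good-tier + 8 noisy-tier euploid cells
qc_plate <- function() {
  cached("plate", function() {
    grid <- test_grid()
    rows <- lapply(1:16, function(i) {
      tier <- if (i <= 8) "good" else "noisy"
      r <- sim_fit_cell("euploid_xx", cell_seed = 3000 + i, tier = tier,
                        cell_id = sprintf("%s_%02d", tier, i))
      qc_cell(r$cell, r$fit, grid)
    })
    do.call(rbind, rows)
  })
}

# ---- independent oracles -------------------------------------------------

# exhaustive path enumeration of HMM posterior marginals (tiny problems only)
enum_posteriors <- function(counts, mu1, var1, s_max, transition, initial) {
  n <- length(counts)
  states <- 0:s_max
  em <- function(cc, s) {
    if (s == 0) return(as.numeric(cc == 0))
    stats::dnbinom(cc, mu = s * mu1, size = s * mu1^2 / (var1 - mu1))
  }
  paths <- as.matrix(expand.grid(rep(list(states), n)))
  pp <- apply(paths, 1L, function(st) {
    p <- initial[st[1] + 1] * em(counts[1], st[1])
    for (t in seq_len(n)[-1]) p <- p * transition[st[t - 1] + 1, st[t] + 1] * em(counts[t], st[t])
    p
  })
  Z <- sum(pp)
  post <- sapply(seq_len(n), function(t)
    sapply(states, function(s) sum(pp[paths[, t] == s]) / Z))
  list(posteriors = t(post), log_likelihood = log(Z))
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  w_all <- apply(combs, 2L, function(i) sum(r[i]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# mean and variance of the number of occupied cells (distinct molecules)
# when s reads are drawn uniformly with replacement from U molecules
occupancy_moments <- function(U, s) {
  q1 <- (1 - 1 / U)^s
  q2 <- (1 - 2 / U)^s
  mean_occ <- U * (1 - q1)
  var_occ <- U * q1 + U * (U - 1) * q2 - U^2 * q1^2
  list(mean = mean_occ, var = max(var_occ, 0))
}
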