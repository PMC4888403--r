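#' Tied negative-binomial emission parameters
#'
#' The copy-number caller models the count emitted by a bin in hidden state
#' s (s = 1..s_max) as negative binomial with mean `s * mu1` and variance
#' `s * var1` — multiples of the monosomy-state moments — and state 0
#' (nullisomy) as a point mass at zero. Under this tying the NB success
#' probability `p = mu1/var1` is shared by every state and the size
#' parameter scales linearly: `size_s = s * mu1^2 / (var1 - mu1)`.
#'
#' @param mu1 monosomy mean (> 0).
#' @param var1 monosomy variance (> mu1; NB requires overdispersion).
#' @param s_max largest copy-number state.
#' @return data frame with one row per state 0..s_max: `state`, `mu`,
#'   `var`, `size`, `prob`.
#' @export
nb_state_params <- function(mu1, var1, s_max = 10L) {
  if (var1 <= mu1) stop("var1 must exceed mu1 (NB overdispersion)")
  s <- seq_len(s_max)
  data.frame(state = c(0L, s),
             mu = c(0, s * mu1),
             var = c(0, s * var1),
             size = c(NA_real_, s * mu1^2 / (var1 - mu1)),
             prob = c(NA_real_, rep(mu1 / var1, s_max)))
}

# log emission matrix: n bins x (s_max + 1) states (state 0 first)
emission_logdens <- function(counts, mu1, var1, s_max) {
  n <- length(counts)
  E <- matrix(-Inf, n, s_max + 1L)
  E[, 1L] <- ifelse(counts == 0L, 0, -Inf)      # nullisomy: delta at zero
  size1 <- mu1^2 / (var1 - mu1)
  for (s in seq_len(s_max))
    E[, s + 1L] <- stats::dnbinom(counts, mu = s * mu1, size = s * size1, log = TRUE)
  E
}

# Scaled forward-backward. logE: n x S matrix; A: S x S; init: length S.
# Returns gamma (posteriors), log-likelihood, and accumulated transition
# expectations (xi summed over t) for the Baum-Welch M-step.
.forward_backward <- function(logE, A, init) {
  n <- nrow(logE); S <- ncol(logE)
  m <- apply(logE, 1L, max)
  if (any(!is.finite(m))) stop("a bin has zero likelihood under every state")
  Etil <- exp(logE - m)
  alpha <- matrix(0, n, S); beta <- matrix(0, n, S); cs <- numeric(n)
  a <- init * Etil[1L, ]
  cs[1L] <- sum(a)
  alpha[1L, ] <- a / cs[1L]
  for (t in 2L:n) {
    a <- (alpha[t - 1L, ] %*% A) * Etil[t, ]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  beta[n, ] <- 1
  xi_sum <- matrix(0, S, S)
  for (t in (n - 1L):1L) {
    w <- Etil[t + 1L, ] * beta[t + 1L, ]
    xi_sum <- xi_sum + (A * outer(alpha[t, ], w)) / cs[t + 1L]
    beta[t, ] <- (A %*% w) / cs[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, log_likelihood = sum(log(cs)) + sum(m), xi_sum = xi_sum)
}

#' Forward-backward posteriors for the tied-NB copy-number HMM
#'
#' Computes exact per-bin posterior state probabilities and the data
#' log-likelihood for fixed parameters (no fitting). Exposed so small
#' configurations can be checked against independent computations.
#'
#' @param counts non-negative integer vector.
#' @param mu1,var1 monosomy mean and variance (tied emissions).
#' @param s_max largest state.
#' @param transition row-stochastic `(s_max+1)^2` matrix.
#' @param initial initial state distribution.
#' @return `list(posteriors, log_likelihood)`.
#' @export
forward_backward_nb <- function(counts, mu1, var1, s_max, transition, initial) {
  logE <- emission_logdens(as.integer(round(counts)), mu1, var1, s_max)
  fb <- .forward_backward(logE, transition, initial)
  list(posteriors = fb$gamma, log_likelihood = fb$log_likelihood)
}

# log-space Viterbi over the same parameterization
.viterbi <- function(logE, A, init) {
  n <- nrow(logE); S <- ncol(logE)
  logA <- log(A); v <- log(init) + logE[1L, ]
  back <- matrix(0L, n, S)
  for (t in 2L:n) {
    cand <- v + logA                   # S x S: prev state i -> state j
    back[t, ] <- max.col(t(cand), ties.method = "first")
    v <- cand[cbind(back[t, ], seq_len(S))] + logE[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  path - 1L                            # states are 0-based
}

# argmax with ties broken toward the state nearest 2, then the smaller state
.decode_posterior <- function(gamma, states = seq_len(ncol(gamma)) - 1L) {
  pref <- order(abs(states - 2L), states)     # preference order of columns
  apply(gamma, 1L, function(p) {
    cand <- which(p >= max(p) - 1e-12)
    states[pref[pref %in% cand][1L]]
  })
}

#' Fit the 11-state copy-number HMM to one cell
#'
#' Fits, by Baum-Welch, a hidden Markov model over copy-number states 0
#' (nullisomy) to `s_max` (default 10, decasomy) with a delta-at-zero
#' emission for state 0 and tied negative-binomial emissions for the rest:
#' state s has mean `s * mu1` and variance `s * var1`. Corrected counts are
#' rounded to integers for NB evaluation. The M-step re-estimates
#' `(mu1, var1)` by posterior-weighted moment matching of the scaled
#' observations `counts/s` and re-imposes `var1 >= 1.05 * mu1`; transition
#' and initial distributions get the standard Baum-Welch updates.
#' Decoding assigns each bin the state with the highest posterior
#' probability (ties toward the state nearer 2, then the smaller state);
#' Viterbi decoding is available as an option.
#'
#' Initialization assumes a near-diploid cell: `mu1 = mean(nonzero)/2`,
#' `var1 = max(var(nonzero)/2, 1.2*mu1)`, 0.99 self-transition, initial
#' mass concentrated on states 1-4.
#'
#' @param counts per-bin counts (corrected or raw); non-negative.
#' @param grid optional `bin_grid` (length check only; decoding is
#'   grid-free).
#' @param s_max largest copy-number state.
#' @param max_iter,tol Baum-Welch iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param decoding "posterior" (default, per-bin argmax) or "viterbi".
#' @return an object of class `copy_number_fit`: emission parameters,
#'   transition/initial distributions, per-bin posteriors and decoded
#'   states, log-likelihood trace, convergence info.
#' @export
fit_copy_number_hmm <- function(counts, grid = NULL, s_max = 10L,
                                max_iter = 200L, tol = 1e-4,
                                decoding = c("posterior", "viterbi")) {
  decoding <- match.arg(decoding)
  counts <- as.integer(pmax(round(counts), 0))
  n <- length(counts)
  if (!is.null(grid) && n != nrow(grid)) stop("counts length does not match grid")
  if (n < 50L) stop("HMM fitting needs at least 50 bins")
  S <- s_max + 1L
  states <- 0:s_max
  if (sum(counts) == 0L) {
    post <- matrix(0, n, S); post[, 1L] <- 1
    return(structure(list(
      emission = list(mu1 = NA_real_, var1 = NA_real_, s_max = s_max),
      transition = diag(S), initial = c(1, rep(0, s_max)),
      log_likelihood = 0, ll_trace = 0, posteriors = post,
      states = rep(0L, n), counts = counts, converged = TRUE,
      n_iterations = 0L, flags = "all_zero"), class = "copy_number_fit"))
  }
  nz <- counts[counts > 0]
  mu1 <- mean(nz) / 2
  v <- if (length(nz) > 1L) stats::var(nz) / 2 else 1.2 * mu1
  var1 <- max(v, 1.2 * mu1)
  A <- matrix((1 - 0.99) / (S - 1L), S, S); diag(A) <- 0.99
  init <- rep(0.005, S)
  init[2:5] <- (1 - 0.005 * (S - 4L)) / 4
  init <- init / sum(init)

  ll_trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  flags <- character(0)
  gamma <- NULL
  while (it < max_iter) {
    it <- it + 1L
    logE <- emission_logdens(counts, mu1, var1, s_max)
    fb <- .forward_backward(logE, A, init)
    gamma <- fb$gamma
    ll <- fb$log_likelihood
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: transitions and initial
    rs <- rowSums(fb$xi_sum)
    A_new <- fb$xi_sum / ifelse(rs > 0, rs, 1)
    A_new[rs == 0, ] <- A[rs == 0, ]            # unvisited states keep prior row
    A <- A_new
    init <- pmax(gamma[1L, ], 1e-12); init <- init / sum(init)
    # M-step: tied emissions. Moment matching on the scaled observations
    # counts/s is closed-form and almost always optimal, but is not an exact
    # maximizer of the expected complete-data log-likelihood Q; to keep the
    # EM ascent guarantee the update is accepted only if it improves Q, with
    # a numerical refinement as fallback, and the best candidate wins.
    G <- gamma[, -1L, drop = FALSE]
    wsum <- sum(G)
    if (wsum <= 0) { flags <- "degenerate"; break }
    sc <- matrix(seq_len(s_max), n, s_max, byrow = TRUE)
    mm_mu <- max(sum(G * counts / sc) / wsum, 1e-6)
    mm_var <- max(sum(G * (counts - sc * mm_mu)^2 / sc) / wsum, 1.05 * mm_mu)
    qfun <- function(mu, v) {
      lE <- emission_logdens(counts, mu, v, s_max)[, -1L, drop = FALSE]
      sum(G * lE)
    }
    q_cur <- qfun(mu1, var1); q_mm <- qfun(mm_mu, mm_var)
    if (q_mm < q_cur) {
      # refine from the better start; parameterization enforces var > 1.05*mu
      start <- if (q_mm >= q_cur) c(mm_mu, mm_var) else c(mu1, var1)
      par0 <- c(log(start[1]), log(max(start[2] / start[1] - 1.05, 1e-6)))
      opt <- stats::optim(par0, function(p) {
        mu <- exp(p[1]); -qfun(mu, mu * (1.05 + exp(p[2])))
      })
      mu_opt <- exp(opt$par[1]); var_opt <- mu_opt * (1.05 + exp(opt$par[2]))
      cand <- list(c(mu1, var1), c(mm_mu, mm_var), c(mu_opt, var_opt))
      best <- cand[[which.max(c(q_cur, q_mm, -opt$value))]]
      mu1 <- best[1]; var1 <- best[2]
    } else {
      mu1 <- mm_mu; var1 <- mm_var
    }
  }
  if (!converged) {
    # one final E-step so posteriors and likelihood match the final parameters
    fb <- .forward_backward(emission_logdens(counts, mu1, var1, s_max), A, init)
    gamma <- fb$gamma
    ll_trace <- c(ll_trace, fb$log_likelihood)
  }
  decoded <- if (decoding == "viterbi") {
    .viterbi(emission_logdens(counts, mu1, var1, s_max), A, init)
  } else {
    .decode_posterior(gamma, states)
  }
  structure(list(
    emission = list(mu1 = mu1, var1 = var1, s_max = s_max),
    transition = A, initial = init,
    log_likelihood = ll_trace[length(ll_trace)], ll_trace = ll_trace,
    posteriors = gamma, states = as.integer(decoded), counts = counts,
    converged = converged, n_iterations = it, flags = flags),
    class = "copy_number_fit")
}

#' @export
print.copy_number_fit <- function(x, ...) {
  cat(sprintf("<copy_number_fit: %d bins, states 0..%d, mu1=%.1f var1=%.1f, LL=%.1f, %d iter%s>\n",
              length(x$states), x$emission$s_max,
              x$emission$mu1, x$emission$var1, x$log_likelihood,
              x$n_iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Maximal constant-state segments
#'
#' Collapses the decoded per-bin states into maximal runs of constant state
#' that never cross a chromosome boundary. The number of such segments is
#' one of the five library quality metrics (a perfectly flat euploid cell
#' has exactly one segment per chromosome).
#'
#' @param fit a `copy_number_fit`.
#' @param grid the matching `bin_grid`.
#' @return data frame `chrom`, `start_bin`, `end_bin` (1-based inclusive
#'   bin indices into the grid), `start`, `end` (genomic, half-open),
#'   `state`.
#' @export
decode_segments <- function(fit, grid) {
  validate_bin_grid(grid)
  if (length(fit$states) != nrow(grid)) stop("fit does not match grid")
  out <- lapply(grid_chromosomes(grid), function(ch) {
    i <- which(grid$chrom == ch)
    r <- rle(fit$states[i])
    e <- cumsum(r$lengths); s <- c(1L, utils::head(e, -1L) + 1L)
    data.frame(chrom = ch, start_bin = i[s], end_bin = i[e],
               start = grid$start[i[s]], end = grid$end[i[e]],
               state = r$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a per-cell copy-number profile as BED-like TSV
#'
#' Columns: chrom, start, end, state, posterior of the called state
#' (no header, BED convention).
#'
#' @param fit a `copy_number_fit`.
#' @param grid the matching `bin_grid`.
#' @param path output path.
#' @export
write_profile <- function(fit, grid, path) {
  post <- fit$posteriors[cbind(seq_along(fit$states), fit$states + 1L)]
  df <- data.frame(grid$chrom, grid$start, grid$end, fit$states,
                   signif(post, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
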