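# Independent oracles used across tests. These deliberately re-derive results
# from first principles (direct sums, brute-force definitions) rather than
# calling the implementation paths they check.

# direct time-domain Morlet CWT: W[j, n] = sum_m x_m conj(psi((m-n) dt / s))
# * dt / sqrt(s), psi(t) = pi^(-1/4) exp(i w0 t - t^2 / 2)
oracle_cwt <- function(x, grid) {
  x <- x - mean(x)
  n <- length(x)
  dt <- grid$dt
  W <- matrix(0 + 0i, grid$n_scales, n)
  m <- seq_len(n)
  for (j in seq_len(grid$n_scales)) {
    s <- grid$scales[j]
    for (tt in seq_len(n)) {
      u <- (m - tt) * dt / s
      psi <- pi^(-0.25) * exp(1i * grid$omega0 * u - u^2 / 2)
      W[j, tt] <- sum(x * Conj(psi)) * dt / sqrt(s)
    }
  }
  W
}

# brute-force Benjamini-Hochberg step-up straight from the definition
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i * q / m) kmax <- i
  }
  reject <- rep(FALSE, m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}

circ_mean <- function(theta) Arg(mean(exp(1i * theta)))

# small cohort for structural tests (fast: short runs, few trials)
tiny_config <- function(n_dyads = 3, n_rois = 2, coupling = NULL, seed = 11) {
  sim_config(
    n_dyads = n_dyads, n_rois = n_rois,
    n_volumes_per_run = 260, trial_count_per_block = 4,
    coupling = coupling, seed = seed
  )
}
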