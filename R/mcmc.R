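# Affine-invariant ensemble sampler (stretch moves).
#
# A walker ensemble explores the posterior; each walker is updated by
# stretching towards a randomly chosen companion with scale factor
# z ~ g(z) prop. 1/sqrt(z) on [1/a, a], accepted with probability
# min(1, z^(d-1) exp(logp_new - logp_old)). Affine invariance makes the
# sampler insensitive to the very different parameter scales of the
# spectroscopic and thermodynamic parameters.

.stretch_sampler <- function(log_post, init, lo, hi, n_walkers = 24L,
                             n_steps = 3000L, burn_in = 1000L, stretch = 2) {
  d <- length(init)
  # initialize walkers in a small ball around init, clipped to the box
  walkers <- matrix(rep(init, each = n_walkers), n_walkers, d)
  jitter <- matrix(stats::rnorm(n_walkers * d, 0, 0.01), n_walkers, d)
  walkers <- walkers * (1 + jitter)
  walkers <- pmin(pmax(walkers, matrix(lo, n_walkers, d, byrow = TRUE)),
                  matrix(hi, n_walkers, d, byrow = TRUE))
  lp <- apply(walkers, 1L, log_post)
  if (all(!is.finite(lp)))
    stop("sampler initialization outside the prior support", call. = FALSE)

  keep <- n_steps - burn_in
  samples <- matrix(NA_real_, keep * n_walkers, d)
  n_acc <- 0L; n_prop <- 0L; k_out <- 0L
  for (step in seq_len(n_steps)) {
    for (i in seq_len(n_walkers)) {
      j <- sample(seq_len(n_walkers)[-i], 1L)
      z <- (1 + (stretch - 1) * stats::runif(1))^2 / stretch
      prop <- walkers[j, ] + z * (walkers[i, ] - walkers[j, ])
      lp_prop <- log_post(prop)
      log_acc <- (d - 1) * log(z) + lp_prop - lp[i]
      n_prop <- n_prop + 1L
      if (is.finite(lp_prop) && log(stats::runif(1)) < log_acc) {
        walkers[i, ] <- prop
        lp[i] <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    if (step > burn_in) {
      samples[k_out + seq_len(n_walkers), ] <- walkers
      k_out <- k_out + n_walkers
    }
  }
  # crude effective sample size from lag-1 autocorrelation of walker means
  ess <- apply(samples, 2L, function(x) {
    m <- matrix(x, ncol = n_walkers, byrow = TRUE)
    xm <- rowMeans(m)
    rho <- if (length(xm) > 2) stats::cor(xm[-1], xm[-length(xm)]) else 0
    rho <- min(max(rho, 0), 0.999)
    length(x) * (1 - rho) / (1 + rho)
  })
  list(samples = samples, acceptance_rate = n_acc / n_prop, ess = ess)
}
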