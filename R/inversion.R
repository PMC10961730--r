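# Forward melt prediction and inversion of a measured signal to helicity.

# Vectorized ensemble signal over a temperature grid for one chain.
# All three spectroscopic models have a helical contribution linear in the
# infinite-helix ellipticity theta_H_inf(T), with a temperature-independent
# per-class coefficient alpha_i:
#   dichroic : alpha = a (1 - k/6) + b
#   empirical: alpha = n_H - k n_seg
#   linear   : alpha = n_H (1 - k/n_pep)
# so signal(T) = [theta_H_inf(T) <alpha> + theta_C(T) <n_coil>] / n_pep.
.signal_curve <- function(chain, v, w_vec, params, T_vec, model) {
  tab <- .signal_table(chain)
  logw <- log(w_vec)
  # weight matrix: (n_v, m_w) groups x temperatures
  W <- exp(tab$log_om + tab$n_v * log(v) + outer(tab$m_w, logw))
  Q <- as.numeric(crossprod(tab$g1, W))
  alpha <- switch(model,
    dichroic  = tab$ga * (1 - params$k / 6) + tab$gb,
    empirical = tab$gnH - params$k * tab$gns,
    linear    = tab$gnH * (1 - params$k / chain$n_pep))
  EA <- as.numeric(crossprod(alpha, W)) / Q
  EC <- as.numeric(crossprod(tab$gc, W)) / Q
  thI <- params$theta_H_inf + params$dtheta_H_inf_dT * T_vec
  thC <- params$theta_C + params$dtheta_C_dT * T_vec
  (thI * EA + thC * EC) / chain$n_pep
}

# Conformer classes aggregated by their (n_v, m_w) weight exponents: the
# ensemble signal needs only group moments of the spectroscopic unit
# counts, which shrinks the hot-path matrix from the number of run
# partitions to a few hundred exponent pairs. Cached per chain.
.signal_table <- function(chain) {
  key <- sprintf("sig_n%d_b%d", chain$n_res, as.integer(chain$blocked))
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  tab <- .composition_table(chain)
  g <- interaction(tab$n_v, tab$m_w, drop = TRUE)
  agg <- function(x) as.numeric(tapply(x, g, sum))
  om <- agg(tab$omega)
  out <- list(n_v = as.numeric(tapply(tab$n_v, g, `[`, 1L)),
              m_w = as.numeric(tapply(tab$m_w, g, `[`, 1L)),
              log_om = log(om), g1 = rep(1, length(om)),
              ga = agg(tab$omega * tab$a_units) / om,
              gb = agg(tab$omega * tab$b_units) / om,
              gnH = agg(tab$omega * tab$n_H) / om,
              gns = agg(tab$omega * tab$n_seg) / om,
              gc = agg(tab$omega * tab$n_coil) / om)
  .comp_cache[[key]] <- out
  out
}

#' Predict a noiseless thermal melt
#'
#' Forward model for a CD thermal melt: at each temperature the propagation
#' constant `w(T)` follows the Gibbs-Helmholtz relation, the helix-coil
#' ensemble is evaluated by exact composition-resolved enumeration, and the
#' ensemble-averaged ellipticity is computed under the chosen spectroscopic
#' model.
#'
#' @param spectro A [spectro_params()] object.
#' @param thermo A [thermo_params()] object.
#' @param chain A [chain_spec()] object.
#' @param T_grid Temperatures in degC.
#' @param model Spectroscopic model tag: `"dichroic"`, `"empirical"` or
#'   `"linear"`.
#' @return A [melt_curve()] (noiseless; `sigma_222` unset). For a length-1
#'   grid the `"melt_curve"` container is bypassed and a one-row curve-like
#'   list is still returned.
#' @examples
#' sp <- spectro_params(); th <- thermo_params(0.07, -0.22, -1.3, 0.006)
#' predict_melt(sp, th, chain_spec(32), T_grid = seq(0, 95, by = 5))
#' @export
predict_melt <- function(spectro, thermo, chain, T_grid,
                         model = c("dichroic", "empirical", "linear")) {
  stopifnot(inherits(spectro, "spectro_params"),
            inherits(thermo, "thermo_params"),
            inherits(chain, "chain_spec"), is.numeric(T_grid))
  model <- match.arg(model)
  w <- propagation_at_T(thermo, T_grid + .T_ZERO_C)
  theta <- .signal_curve(chain, thermo$v, w, spectro, T_grid, model)
  if (length(T_grid) == 1L)
    return(structure(list(chain = chain, temperature_C = T_grid,
                          theta_222 = theta, sigma_222 = NULL,
                          path_cm = NA_real_, conc_M = NA_real_,
                          label = sprintf("n_res=%d", chain$n_res)),
                     class = "melt_curve"))
  melt_curve(chain, T_grid, theta)
}

#' Helicity from a measured signal via the ensemble model
#'
#' Inverts the dichroic ensemble model: solves
#' `ensemble_signal(w) = theta_obs` for the propagation constant `w` at
#' temperature `T` (the signal is strictly monotone in `w`, so the root is
#' unique), then reports the ensemble mean helicity and the probability of
#' at least one helical segment at the solution.
#'
#' @param theta_obs Observed mean molar ellipticity per peptide unit.
#' @param T Temperature in degC.
#' @param chain A [chain_spec()] object.
#' @param spectro A [spectro_params()] object.
#' @param v Nucleation constant (> 0).
#' @param model Spectroscopic model used in the inversion (default
#'   `"dichroic"`).
#' @param w_range Bracket for the root search on `w`.
#' @return A list with `w_hat`, `mean_helicity`,
#'   `helical_conformer_fraction` (probability of >= 1 helical segment) and
#'   `theta_fit`.
#' @examples
#' sp <- spectro_params()
#' est <- helicity_from_signal_ensemble(-12000, T = 0, chain_spec(32), sp,
#'                                      v = 0.07)
#' est$mean_helicity
#' @export
helicity_from_signal_ensemble <- function(theta_obs, T, chain, spectro, v,
                                          model = c("dichroic", "empirical",
                                                    "linear"),
                                          w_range = c(1e-9, 1e5)) {
  stopifnot(is.numeric(theta_obs), length(theta_obs) == 1L,
            inherits(chain, "chain_spec"), inherits(spectro, "spectro_params"),
            v > 0)
  model <- match.arg(model)
  f <- function(w) .signal_curve(chain, v, w, spectro, T, model) - theta_obs
  flo <- f(w_range[1]); fhi <- f(w_range[2])
  if (sign(flo) == sign(fhi)) {
    rng <- sort(c(flo, fhi) + theta_obs)
    stop(sprintf(paste0("theta_obs = %.1f is outside the attainable range ",
                        "[%.1f, %.1f] at T = %g degC"),
                 theta_obs, rng[1], rng[2], T), call. = FALSE)
  }
  # bisect on log(w) for scale invariance
  g <- function(lw) f(exp(lw))
  root <- stats::uniroot(g, lower = log(w_range[1]), upper = log(w_range[2]),
                         tol = 1e-12)
  w_hat <- exp(root$root)
  dist <- composition_weights(chain, v, w_hat)
  list(w_hat = w_hat,
       mean_helicity = mean_helicity(dist),
       helical_conformer_fraction = sum(dist$comp$prob[dist$comp$n_seg >= 1]),
       theta_fit = theta_obs + f(w_hat))
}

#' Helicity from a measured signal via the linear model
#'
#' Closed-form linear estimate
#' `f_H = (theta_obs - theta_C(T)) / (theta_H(n_pep, T) - theta_C(T))`,
#' where `theta_H(n_pep, T)` is the maximal-length helix ellipticity. The
#' result is clipped to `[0, 1]` with a warning when the signal lies outside
#' the baselines.
#'
#' @inheritParams helicity_from_signal_ensemble
#' @return Mean fractional helicity in `[0, 1]`.
#' @export
helicity_from_signal_linear <- function(theta_obs, T, chain, spectro) {
  stopifnot(inherits(chain, "chain_spec"), inherits(spectro, "spectro_params"))
  thH <- helix_per_unit_empirical(chain$n_pep, spectro, T)
  thC <- coil_baseline(spectro, T)
  if (abs(thH - thC) < 1e-9 * max(abs(thH), abs(thC), 1))
    stop("degenerate baselines: theta_H(n_pep, T) equals theta_C(T)",
         call. = FALSE)
  fH <- (theta_obs - thC) / (thH - thC)
  if (any(fH < 0 | fH > 1)) {
    warning("signal outside the helix/coil baselines; helicity clipped to [0, 1]",
            call. = FALSE)
    fH <- pmin(pmax(fH, 0), 1)
  }
  fH
}
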