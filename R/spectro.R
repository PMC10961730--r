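# Spectroscopic models for mean molar ellipticity at 222 nm.
# All ellipticities are per mole of peptide unit (deg cm^2 dmol^-1);
# temperatures on this layer are degrees Celsius.

#' Spectroscopic baseline parameters
#'
#' CD baseline parameters at 222 nm: the infinite-helix ellipticity
#' `theta_H_inf` and its temperature slope, the dimensionless end-effect
#' parameter `k` (assumed temperature-independent), and the coil ellipticity
#' `theta_C` with its slope. Ellipticities are per peptide unit at 0 degC;
#' slopes are per degC. The derived single-hydrogen-bonded helix-unit
#' ellipticity is `theta_H1 = theta_H_inf (1 - k/6)`, which stays negative
#' only for `k < 6` (a warning is issued otherwise).
#'
#' @param theta_H_inf Infinite-helix ellipticity at 0 degC (< 0).
#' @param dtheta_H_inf_dT Temperature slope of `theta_H_inf`.
#' @param k End-effect parameter (> 0).
#' @param theta_C Coil ellipticity at 0 degC.
#' @param dtheta_C_dT Temperature slope of `theta_C`.
#' @return An object of class `"spectro_params"`.
#' @examples
#' sp <- spectro_params() # global-fit calibration defaults
#' theta_H1(sp, T = 0)
#' @export
spectro_params <- function(theta_H_inf = -41000, dtheta_H_inf_dT = 100,
                           k = 3.4, theta_C = 2100, dtheta_C_dT = -45) {
  vals <- c(theta_H_inf, dtheta_H_inf_dT, k, theta_C, dtheta_C_dT)
  stopifnot(is.numeric(vals), length(vals) == 5L, all(is.finite(vals)))
  if (theta_H_inf >= 0)
    stop("'theta_H_inf' must be negative (helix band at 222 nm)", call. = FALSE)
  if (k <= 0) stop("end-effect parameter 'k' must be positive", call. = FALSE)
  if (k >= 6)
    warning("k >= 6 makes the single-bonded unit ellipticity theta_H1 ",
            "non-negative", call. = FALSE)
  structure(list(theta_H_inf = theta_H_inf,
                 dtheta_H_inf_dT = dtheta_H_inf_dT,
                 k = k, theta_C = theta_C, dtheta_C_dT = dtheta_C_dT),
            class = "spectro_params")
}

#' @export
print.spectro_params <- function(x, ...) {
  cat("CD baseline parameters (per peptide unit, 0 degC)\n")
  cat(sprintf("  theta_H_inf = %g (slope %g /degC), k = %g\n",
              x$theta_H_inf, x$dtheta_H_inf_dT, x$k))
  cat(sprintf("  theta_C     = %g (slope %g /degC)\n",
              x$theta_C, x$dtheta_C_dT))
  cat(sprintf("  theta_H1(0) = %g\n", theta_H1(x, 0)))
  invisible(x)
}

# infinite-helix ellipticity at T (degC)
.theta_H_inf_T <- function(params, T) params$theta_H_inf + params$dtheta_H_inf_dT * T

#' Ellipticity of a singly hydrogen-bonded helical unit
#'
#' The dichroic model assigns ellipticity `theta_H1` to the six peptide units
#' of a helical segment that carry a single backbone hydrogen bond (three at
#' each end) and `theta_H_inf` to the doubly bonded interior units. With a
#' temperature-independent `k`, `theta_H1(T) = theta_H_inf(T) (1 - k/6)`.
#'
#' @param params A [spectro_params()] object.
#' @param T Temperature(s) in degC.
#' @return Ellipticity (deg cm^2 dmol^-1).
#' @export
theta_H1 <- function(params, T) {
  stopifnot(inherits(params, "spectro_params"))
  .theta_H_inf_T(params, T) * (1 - params$k / 6)
}

#' Per-unit helix ellipticity with the empirical length correction
#'
#' `theta_H(n_H, T) = theta_H_inf(T) (1 - k / n_H)` for a helical segment of
#' `n_H` peptide units.
#'
#' @param n_H Helical-segment length(s) in peptide units (>= 1).
#' @inheritParams theta_H1
#' @return Per-unit ellipticity (deg cm^2 dmol^-1).
#' @export
helix_per_unit_empirical <- function(n_H, params, T = 0) {
  stopifnot(inherits(params, "spectro_params"))
  if (any(n_H < 1)) stop("segment length 'n_H' must be >= 1", call. = FALSE)
  .theta_H_inf_T(params, T) * (1 - params$k / n_H)
}

#' Total helical ellipticity of a conformer under the dichroic model
#'
#' Each helical segment contributes `theta_H1` per unit for its (up to six)
#' singly hydrogen-bonded end units and `theta_H_inf` per doubly bonded
#' interior unit: a segment of `n_H <= 6` units contributes
#' `n_H * theta_H1(T)`, a longer one `6 theta_H1(T) + (n_H - 6) theta_H_inf(T)`.
#' End corrections are applied per segment and summed.
#'
#' @param segment_lengths Integer vector of helical-segment lengths in
#'   peptide units (each >= 4); may be empty.
#' @inheritParams theta_H1
#' @return Total ellipticity summed over helical units (deg cm^2 dmol^-1).
#' @export
helix_total_dichroic <- function(segment_lengths, params, T = 0) {
  stopifnot(inherits(params, "spectro_params"))
  if (length(segment_lengths) == 0L) return(0)
  if (any(segment_lengths < 4))
    stop("helical segments span at least 4 peptide units", call. = FALSE)
  a <- sum(pmin(segment_lengths, 6))
  b <- sum(pmax(segment_lengths - 6, 0))
  a * theta_H1(params, T) + b * .theta_H_inf_T(params, T)
}

#' Total helical ellipticity of a conformer under the linear model
#'
#' The linear approximation applies the length correction of the
#' maximal-length helix (`n_H = n_pep`) to every helical unit, regardless of
#' how the units are distributed over segments:
#' `n_H_total * theta_H_inf(T) (1 - k / n_pep)`.
#'
#' @param n_H_total Total helical peptide units of the conformer
#'   (`0 <= n_H_total <= n_pep`).
#' @param chain A [chain_spec()] object.
#' @inheritParams theta_H1
#' @return Total ellipticity (deg cm^2 dmol^-1).
#' @export
helix_total_linear <- function(n_H_total, chain, params, T = 0) {
  stopifnot(inherits(chain, "chain_spec"), inherits(params, "spectro_params"))
  if (any(n_H_total < 0 | n_H_total > chain$n_pep))
    stop("'n_H_total' must lie in [0, n_pep]", call. = FALSE)
  n_H_total * helix_per_unit_empirical(chain$n_pep, params, T)
}

#' Coil baseline ellipticity
#'
#' `theta_C(T) = theta_C + dtheta_C_dT * T`.
#'
#' @inheritParams theta_H1
#' @return Coil per-unit ellipticity (deg cm^2 dmol^-1).
#' @export
coil_baseline <- function(params, T = 0) {
  stopifnot(inherits(params, "spectro_params"))
  params$theta_C + params$dtheta_C_dT * T
}

#' Ensemble-averaged ellipticity at 222 nm
#'
#' Probability-weighted mean molar ellipticity per peptide unit of a
#' helix-coil ensemble:
#' `[theta]_222 = sum_i p_i (theta_helix,i(T) + n_C,i theta_C(T)) / n_pep`,
#' where the helical contribution of conformer class `i` is evaluated under
#' the chosen spectroscopic model (see [helix_total_dichroic()],
#' [helix_per_unit_empirical()], [helix_total_linear()]).
#'
#' @param dist A `"helix_ensemble"` object from [composition_weights()] or
#'   [enumerate_bruteforce()].
#' @param params A [spectro_params()] object.
#' @param T Temperature in degC (scalar).
#' @param model One of `"dichroic"`, `"empirical"`, `"linear"`.
#' @return Mean molar ellipticity per peptide unit (deg cm^2 dmol^-1).
#' @examples
#' d <- composition_weights(chain_spec(32), v = 0.048, w = 1.2)
#' sp <- spectro_params(-40000, 0, 4, 0, 0)
#' ensemble_signal(d, sp, T = 0, model = "dichroic")
#' ensemble_signal(d, sp, T = 0, model = "linear")
#' @export
ensemble_signal <- function(dist, params, T = 0,
                            model = c("dichroic", "empirical", "linear")) {
  stopifnot(inherits(dist, "helix_ensemble"), inherits(params, "spectro_params"),
            is.numeric(T), length(T) == 1L)
  model <- match.arg(model)
  cm <- dist$comp
  thI <- .theta_H_inf_T(params, T)
  h <- switch(model,
    dichroic  = cm$a_units * (thI * (1 - params$k / 6)) + cm$b_units * thI,
    # per segment of n_H units: n_H * theta_H_inf (1 - k/n_H)
    #   = theta_H_inf (n_H - k), summed: theta_H_inf (n_H_tot - k * n_seg)
    empirical = thI * (cm$n_H - params$k * cm$n_seg),
    linear    = cm$n_H * (thI * (1 - params$k / dist$chain$n_pep)))
  sum(cm$prob * (h + cm$n_coil * coil_baseline(params, T))) / dist$chain$n_pep
}

#' Convert a raw CD signal to mean molar ellipticity
#'
#' `[theta] = theta / (10 l c n_pep)`, giving the mean molar ellipticity per
#' peptide unit (deg cm^2 dmol^-1) from the raw ellipticity `theta` in mdeg,
#' the optical path `l` in cm, the molar peptide concentration `c`, and the
#' number of peptide units. Blocked peptides use `n_pep = n_res + 1`.
#'
#' @param theta_mdeg Measured ellipticity in millidegrees.
#' @param path_cm Optical path length in cm (> 0).
#' @param conc_M Peptide concentration in mol/L (> 0).
#' @param chain A [chain_spec()] object (or a number of peptide units).
#' @return Mean molar ellipticity per peptide unit.
#' @examples
#' raw_to_molar(-20, path_cm = 0.1, conc_M = 1e-4, chain = chain_spec(32))
#' @export
raw_to_molar <- function(theta_mdeg, path_cm, conc_M, chain) {
  n_pep <- if (inherits(chain, "chain_spec")) chain$n_pep else as.numeric(chain)
  stopifnot(is.numeric(theta_mdeg), is.numeric(path_cm), is.numeric(conc_M),
            n_pep >= 1)
  if (any(path_cm <= 0)) stop("path length must be positive", call. = FALSE)
  if (any(conc_M <= 0)) stop("concentration must be positive", call. = FALSE)
  theta_mdeg / (10 * path_cm * conc_M * n_pep)
}
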