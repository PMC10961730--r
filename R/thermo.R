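# Gas constant in kcal mol^-1 K^-1
.R_GAS <- 1.987e-3

# 0 degrees Celsius in kelvin; all user-facing temperatures are Celsius,
# thermodynamics is evaluated in kelvin.
.T_ZERO_C <- 273.15

#' Thermodynamic parameters of helix propagation
#'
#' Bundles the Lifson-Roig nucleation constant `v` with the thermodynamic
#' parameters that determine the temperature dependence of the propagation
#' constant `w` via the Gibbs-Helmholtz relation. `dG0`, `dH0` and `dCp` are
#' the per-residue free energy, enthalpy and heat capacity change of helix
#' propagation at the reference temperature `T0`; `v` is assumed
#' temperature-independent.
#'
#' @param v Dimensionless nucleation constant (> 0).
#' @param dG0 Propagation free energy at `T0`, kcal/mol.
#' @param dH0 Propagation enthalpy at `T0`, kcal/mol.
#' @param dCp Heat capacity change, kcal/mol/K (assumed constant).
#' @param T0 Reference temperature in kelvin (default 273.15 K, i.e. 0 degC).
#'
#' @return An object of class `"thermo_params"`.
#' @seealso [propagation_at_T()]
#' @examples
#' th <- thermo_params(v = 0.07, dG0 = -0.22, dH0 = -1.3, dCp = 0.006)
#' propagation_at_T(th, 273.15) # w = 1.50 at 0 degC
#' @export
thermo_params <- function(v, dG0, dH0 = dG0, dCp = 0, T0 = .T_ZERO_C) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v),
            is.numeric(dG0), length(dG0) == 1L, is.finite(dG0),
            is.numeric(dH0), length(dH0) == 1L, is.finite(dH0),
            is.numeric(dCp), length(dCp) == 1L, is.finite(dCp),
            is.numeric(T0), length(T0) == 1L, is.finite(T0))
  if (v <= 0) stop("nucleation constant 'v' must be positive", call. = FALSE)
  if (T0 <= 0) stop("reference temperature 'T0' must be positive (kelvin)",
                    call. = FALSE)
  obj <- structure(list(v = v, dG0 = dG0, dH0 = dH0, dCp = dCp, T0 = T0),
                   class = "thermo_params")
  # w(T) must stay positive and finite over the supported -10..110 degC range
  w_rng <- propagation_at_T(obj, .T_ZERO_C + c(-10, 110))
  if (!all(is.finite(w_rng) & w_rng > 0))
    stop("parameters give non-finite w(T) in the -10..110 degC range",
         call. = FALSE)
  obj
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Helix-coil thermodynamic parameters\n")
  cat(sprintf("  v   = %g\n", x$v))
  cat(sprintf("  dG0 = %g kcal/mol, dH0 = %g kcal/mol, dCp = %g kcal/mol/K (T0 = %g K)\n",
              x$dG0, x$dH0, x$dCp, x$T0))
  cat(sprintf("  w(T0) = %.4f\n", propagation_at_T(x, x$T0)))
  invisible(x)
}

#' Propagation constant at a temperature
#'
#' Evaluates the Lifson-Roig propagation constant
#' `w(T) = exp(-dG(T) / (R T))` with the Gibbs-Helmholtz free energy
#' `dG(T) = dH0 + dCp (T - T0) - T ((dH0 - dG0)/T0 + dCp log(T/T0))`,
#' where all parameters are given at the reference temperature `T0` and
#' `R = 1.987e-3` kcal/mol/K.
#'
#' @param thermo A [thermo_params()] object.
#' @param T_K Temperature(s) in kelvin (> 0).
#'
#' @return Dimensionless propagation constant(s) `w`, same length as `T_K`.
#' @examples
#' th <- thermo_params(v = 0.07, dG0 = -0.22, dH0 = -1.3, dCp = 0.006)
#' propagation_at_T(th, 273.15 + c(0, 25, 60))
#' @export
propagation_at_T <- function(thermo, T_K) {
  stopifnot(inherits(thermo, "thermo_params") || is.list(thermo))
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
  dG <- gibbs_helmholtz(T_K, thermo$dG0, thermo$dH0, thermo$dCp, thermo$T0)
  exp(-dG / (.R_GAS * T_K))
}

#' Gibbs-Helmholtz free energy
#'
#' Free energy at temperature `T_K` from the value `dG0`, enthalpy `dH0` and
#' constant heat capacity change `dCp` given at reference temperature `T0`.
#' With `dCp = 0` this reduces to the two-parameter van 't Hoff form
#' `dG(T) = dH0 - T (dH0 - dG0) / T0`.
#'
#' @inheritParams propagation_at_T
#' @param dG0,dH0 Free energy and enthalpy at `T0`, kcal/mol.
#' @param dCp Heat capacity change, kcal/mol/K.
#' @param T0 Reference temperature, kelvin.
#' @return Free energy (kcal/mol) at each `T_K`.
#' @export
gibbs_helmholtz <- function(T_K, dG0, dH0, dCp = 0, T0 = .T_ZERO_C) {
  dS0 <- (dH0 - dG0) / T0
  dH0 + dCp * (T_K - T0) - T_K * (dS0 + dCp * log(T_K / T0))
}

#' Peptide chain specification
#'
#' Describes a peptide chain by its residue count. Blocked peptides
#' (N-terminal acetyl, C-terminal amide) carry one peptide-unit chromophore
#' more than residues: `n_pep = n_res + 1`; unblocked chains have
#' `n_pep = n_res - 1` amide units.
#'
#' @param n_res Number of amino-acid residues (>= 1).
#' @param blocked Logical; capped termini (default `TRUE`).
#' @return An object of class `"chain_spec"` with fields `n_res`, `n_pep`,
#'   `blocked`.
#' @examples
#' chain_spec(32)   # (AAKAA)6-GY style chain: 33 peptide units
#' @export
chain_spec <- function(n_res, blocked = TRUE) {
  stopifnot(is.numeric(n_res), length(n_res) == 1L, n_res >= 1,
            n_res == round(n_res), is.logical(blocked), length(blocked) == 1L)
  n_pep <- if (blocked) n_res + 1L else n_res - 1L
  if (n_pep < 1L) stop("unblocked chain needs n_res >= 2", call. = FALSE)
  structure(list(n_res = as.integer(n_res), n_pep = as.integer(n_pep),
                 blocked = blocked),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("Peptide chain: %d residues, %d peptide units (%s)\n",
              x$n_res, x$n_pep, if (x$blocked) "blocked" else "free termini"))
  invisible(x)
}
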