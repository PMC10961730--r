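# Global fitting of CD datasets under a Gaussian noise model.
#
# Nine model parameters are shared across all datasets: five spectroscopic
# (theta_H_inf, dtheta_H_inf_dT, k, theta_C, dtheta_C_dT) and four
# helix-coil (dG0, dH0, dCp, v). Melt curves are fit with the full forward
# model; fully-helical reference series are direct observations of
# theta_H(n_pep, T) and pre-transition slope series of
# dtheta_H_inf_dT (1 - k/n_pep).

.PAR_NAMES <- c("theta_H_inf", "dtheta_H_inf_dT", "k", "theta_C",
                "dtheta_C_dT", "dG0", "dH0", "dCp", "v")

#' Default model parameters
#'
#' The package's default calibration: the global-fit point estimates for
#' alanine-rich peptides with the dichroic ensemble model (per peptide unit,
#' at 0 degC).
#'
#' @return Named numeric vector of the nine model parameters.
#' @export
default_parameters <- function() {
  c(theta_H_inf = -41000, dtheta_H_inf_dT = 100, k = 3.4,
    theta_C = 2100, dtheta_C_dT = -45,
    dG0 = -0.22, dH0 = -1.3, dCp = 0.006, v = 0.07)
}

.split_params <- function(p) {
  list(spectro = spectro_params(p[["theta_H_inf"]], p[["dtheta_H_inf_dT"]],
                                p[["k"]], p[["theta_C"]], p[["dtheta_C_dT"]]),
       thermo = thermo_params(p[["v"]], p[["dG0"]], p[["dH0"]], p[["dCp"]]))
}

# Residuals (obs - model) and noise scales for one dataset at parameters p
# (plain named vector; no class validation on the hot path).
.dataset_residuals <- function(ds, p, model) {
  if (inherits(ds, "melt_curve")) {
    w <- exp(-gibbs_helmholtz(ds$temperature_C + .T_ZERO_C,
                              p[["dG0"]], p[["dH0"]], p[["dCp"]]) /
               (.R_GAS * (ds$temperature_C + .T_ZERO_C)))
    sp <- structure(list(theta_H_inf = p[["theta_H_inf"]],
                         dtheta_H_inf_dT = p[["dtheta_H_inf_dT"]],
                         k = p[["k"]], theta_C = p[["theta_C"]],
                         dtheta_C_dT = p[["dtheta_C_dT"]]),
                    class = "spectro_params")
    fit <- .signal_curve(ds$chain, p[["v"]], w, sp, ds$temperature_C, model)
    list(r = ds$theta_222 - fit, sigma = ds$sigma_222, fit = fit)
  } else if (inherits(ds, "helix_reference")) {
    thI <- p[["theta_H_inf"]] + p[["dtheta_H_inf_dT"]] * ds$T
    fit <- thI * (1 - p[["k"]] / ds$n_pep)
    list(r = ds$value - fit, sigma = ds$sigma, fit = fit)
  } else if (inherits(ds, "slope_reference")) {
    fit <- p[["dtheta_H_inf_dT"]] * (1 - p[["k"]] / ds$n_pep)
    list(r = ds$value - fit, sigma = ds$sigma, fit = fit)
  } else stop("unknown dataset type: ", paste(class(ds), collapse = "/"),
              call. = FALSE)
}

# Negative log-likelihood up to additive constants. Datasets carrying a
# noise scale contribute 0.5 sum (r/sigma)^2; those without share one noise
# scale that is profiled out analytically.
.fit_nll <- function(p, datasets, model) {
  ss_known <- 0; ss_free <- 0; n_free <- 0L
  for (ds in datasets) {
    dr <- .dataset_residuals(ds, p, model)
    if (!is.null(dr$sigma)) {
      ss_known <- ss_known + sum((dr$r / dr$sigma)^2)
    } else {
      ss_free <- ss_free + sum(dr$r^2)
      n_free <- n_free + length(dr$r)
    }
  }
  nll <- 0.5 * ss_known
  if (n_free > 0L) nll <- nll + 0.5 * n_free * log(ss_free / n_free)
  nll
}

.default_bounds <- function(start, factor = 5) {
  lower <- pmin(start / factor, start * factor)
  upper <- pmax(start / factor, start * factor)
  # parameters allowed to cross zero would otherwise get a degenerate box
  zero <- start == 0
  lower[zero] <- -1; upper[zero] <- 1
  list(lower = lower, upper = upper)
}

#' Global fit of CD datasets
#'
#' Fits the nine shared spectroscopic and helix-coil parameters to a
#' collection of CD datasets (thermal melts, fully-helical reference series,
#' pre-transition slope series) under a Gaussian noise model, using the
#' chosen spectroscopic model for the melt forward calculation.
#'
#' The default backend (`method = "ml"`) maximizes the likelihood with
#' seeded multi-start box-constrained quasi-Newton optimization
#' ([stats::nlminb()] on unit-scaled parameters) and reports
#' curvature-based (observed-information) uncertainties. `method = "mcmc"`
#' runs an affine-invariant ensemble sampler under uniform priors on the
#' same box and reports posterior means, 2-sigma spreads, and Spearman rank
#' correlations.
#'
#' Datasets that carry a noise scale (`sigma_222` / `sigma`) enter the
#' likelihood with it; datasets without one share a single noise scale that
#' is profiled out analytically.
#'
#' @param datasets A list of [melt_curve()], [helix_reference()] and/or
#'   [slope_reference()] objects (at least one).
#' @param model Spectroscopic model: `"dichroic"`, `"linear"` or
#'   `"empirical"`.
#' @param start Named vector of starting values (defaults to
#'   [default_parameters()]).
#' @param fixed Optional named list/vector of parameters to hold fixed.
#' @param method `"ml"` (deterministic, default) or `"mcmc"`.
#' @param n_starts Number of optimization starts (first is `start`, the rest
#'   jittered; seeded).
#' @param seed Integer seed controlling the start jitter / sampler.
#' @param lower,upper Optional named bounds; default is a sign-preserving
#'   box spanning 1/5 to 5 times the start values (uniform-prior support for
#'   `method = "mcmc"`).
#' @param mcmc_control List: `n_walkers`, `n_steps`, `burn_in`,
#'   `stretch` (see Details in the package vignette).
#' @return An object of class `"helix_fit"` with components `coefficients`,
#'   `two_sigma`, `vcov`, `correlation` (rank correlations for MCMC,
#'   Gaussian-approximation correlations for ML), `sigma_hat`, `logLik`,
#'   `rss`, `model`, `method`, `seed`, `diagnostics`, `datasets`,
#'   `config_hash`, and (for MCMC) `samples`.
#' @seealso [predict.helix_fit()], [simulate.helix_fit()], [write_fit_json()]
#' @export
helix_fit <- function(datasets, model = c("dichroic", "linear", "empirical"),
                      start = default_parameters(), fixed = NULL,
                      method = c("ml", "mcmc"), n_starts = 5, seed = 1,
                      lower = NULL, upper = NULL, mcmc_control = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (inherits(datasets, c("melt_curve", "helix_reference", "slope_reference")))
    datasets <- list(datasets)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  start <- start[.PAR_NAMES]
  if (anyNA(start)) stop("'start' must name all nine parameters", call. = FALSE)

  fixed <- unlist(fixed)
  free_names <- setdiff(.PAR_NAMES, names(fixed))
  if (!length(free_names)) stop("no free parameters", call. = FALSE)
  full_par <- function(z) {
    p <- start
    p[free_names] <- z
    if (length(fixed)) p[names(fixed)] <- fixed
    p
  }

  # identifiability screen: a single isothermal melt point cannot constrain
  # the temperature slopes or thermodynamics
  n_obs <- sum(vapply(datasets, function(d)
    length(if (inherits(d, "melt_curve")) d$theta_222 else d$value), 1L))
  if (n_obs < length(free_names))
    stop(sprintf(paste0("non-identifiable configuration: %d observations for ",
                        "%d free parameters (%s); add datasets or fix ",
                        "parameters"),
                 n_obs, length(free_names),
                 paste(free_names, collapse = ", ")), call. = FALSE)

  b <- .default_bounds(start)
  lo <- b$lower; hi <- b$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  lo <- lo[free_names]; hi <- hi[free_names]
  scale <- pmax(abs(start[free_names]), 1e-6)

  nll_free <- function(z) {
    p <- full_par(z)
    val <- try(.fit_nll(p, datasets, model), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e12 else val
  }
  nll_scaled <- function(zs) nll_free(zs * scale)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  if (method == "ml") {
    starts <- vector("list", n_starts)
    starts[[1]] <- start[free_names]
    for (i in seq_len(n_starts - 1L)) {
      jit <- start[free_names] * stats::runif(length(free_names), 0.6, 1.4)
      starts[[i + 1L]] <- pmin(pmax(jit, lo), hi)
    }
    fits <- lapply(starts, function(s0)
      stats::nlminb(s0 / scale, nll_scaled, lower = lo / scale,
                    upper = hi / scale,
                    control = list(iter.max = 500, eval.max = 2000)))
    objs <- vapply(fits, function(f) f$objective, 1)
    best <- fits[[which.min(objs)]]
    z_hat <- best$par * scale
    p_hat <- full_par(z_hat)

    # observed information on the unit scale, mapped back
    H <- try(stats::optimHess(best$par, nll_scaled), silent = TRUE)
    V <- matrix(NA_real_, length(free_names), length(free_names),
                dimnames = list(free_names, free_names))
    if (!inherits(H, "try-error")) {
      Vz <- try(solve(H), silent = TRUE)
      if (!inherits(Vz, "try-error"))
        V <- diag(scale) %*% Vz %*% diag(scale)
    }
    dimnames(V) <- list(free_names, free_names)
    corr <- if (!anyNA(V) && all(diag(V) > 0)) stats::cov2cor(V) else
      matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
    two_sigma <- 2 * sqrt(pmax(diag(V), 0))
    diagnostics <- list(convergence = best$convergence,
                        message = best$message,
                        multi_start_objectives = unname(objs),
                        evaluations = best$evaluations)
    samples <- NULL
  } else {
    mc <- utils::modifyList(list(n_walkers = max(2L * length(free_names) + 2L,
                                                 20L),
                                 n_steps = 3000L, burn_in = 1000L,
                                 stretch = 2),
                            mcmc_control)
    log_post <- function(z) {
      if (any(z < lo) || any(z > hi)) return(-Inf)
      -nll_free(z)
    }
    sam <- .stretch_sampler(log_post, init = start[free_names], lo = lo,
                            hi = hi, n_walkers = mc$n_walkers,
                            n_steps = mc$n_steps, burn_in = mc$burn_in,
                            stretch = mc$stretch)
    samples <- sam$samples
    colnames(samples) <- free_names
    z_hat <- colMeans(samples)
    p_hat <- full_par(z_hat)
    V <- stats::cov(samples)
    corr <- stats::cor(samples, method = "spearman")
    two_sigma <- 2 * apply(samples, 2, stats::sd)
    names(two_sigma) <- free_names
    diagnostics <- list(acceptance_rate = sam$acceptance_rate,
                        ess = sam$ess, divergences = 0L,
                        n_walkers = mc$n_walkers, n_steps = mc$n_steps,
                        burn_in = mc$burn_in)
  }

  # residual summaries and profiled noise scale at the optimum
  rss <- 0; n_pts <- 0L; ss_free <- 0; n_free <- 0L
  fitted_list <- resid_list <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    dr <- .dataset_residuals(datasets[[i]], p_hat, model)
    fitted_list[[i]] <- dr$fit
    resid_list[[i]] <- dr$r
    rss <- rss + sum(dr$r^2)
    n_pts <- n_pts + length(dr$r)
    if (is.null(dr$sigma)) {
      ss_free <- ss_free + sum(dr$r^2); n_free <- n_free + length(dr$r)
    }
  }
  sigma_hat <- if (n_free > 0L) sqrt(ss_free / n_free) else NA_real_

  cfg <- list(model = model, method = method, start = start, fixed = fixed,
              seed = seed, lower = lo, upper = hi, n_starts = n_starts)
  structure(list(coefficients = p_hat, free = free_names, fixed = fixed,
                 two_sigma = two_sigma, vcov = V, correlation = corr,
                 sigma_hat = sigma_hat, rss = rss, n_obs = n_pts,
                 logLik = -.fit_nll(p_hat, datasets, model),
                 model = model, method = method, seed = seed,
                 diagnostics = diagnostics, datasets = datasets,
                 fitted = fitted_list, residuals = resid_list,
                 samples = samples, config_hash = .config_hash(cfg)),
            class = "helix_fit")
}

# FNV-1a over the serialized configuration; provenance tag for outputs.
# Arithmetic kept in doubles below 2^53 via 16-bit splits.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * m) %% 65536) * 65536 + lo16 * m) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @export
print.helix_fit <- function(x, ...) {
  cat(sprintf("Global CD fit (%s model, %s backend)\n", x$model,
              toupper(x$method)))
  cat(sprintf("  %d datasets, %d points, RSS = %.4g", length(x$datasets),
              x$n_obs, x$rss))
  if (is.finite(x$sigma_hat)) cat(sprintf(", sigma_hat = %.3g", x$sigma_hat))
  cat("\n\nCoefficients:\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.helix_fit <- function(object, ...) object$coefficients

#' @export
vcov.helix_fit <- function(object, ...) object$vcov

#' @export
logLik.helix_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free), class = "logLik")
}

#' @export
confint.helix_fit <- function(object, parm, level = 0.95, ...) {
  se <- object$two_sigma / 2
  est <- object$coefficients[object$free]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.helix_fit <- function(object, ...) {
  est <- object$coefficients[object$free]
  tab <- cbind(Estimate = est, `2-sigma` = object$two_sigma[object$free])
  structure(list(fit = object, table = tab), class = "summary.helix_fit")
}

#' @export
print.summary.helix_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUncertainties (2-sigma):\n")
  print(signif(x$table, 4))
  if (length(x$fit$fixed))
    cat("\nFixed:", paste(names(x$fit$fixed), "=", x$fit$fixed,
                          collapse = ", "), "\n")
  cat(sprintf("\nMean |pairwise correlation| = %.3f\n",
              mean(abs(x$fit$correlation[upper.tri(x$fit$correlation)]))))
  invisible(x)
}

#' @export
residuals.helix_fit <- function(object, ...) object$residuals

#' @export
fitted.helix_fit <- function(object, ...) object$fitted

#' Predict melt curves from a fitted model
#'
#' @param object A `"helix_fit"` object.
#' @param chain A [chain_spec()]; defaults to the first melt in the fit.
#' @param T_grid Temperatures in degC; defaults to the first melt's grid.
#' @param model Spectroscopic model (defaults to the fitted one).
#' @param ... Unused.
#' @return A [melt_curve()] with the noiseless model prediction.
#' @export
predict.helix_fit <- function(object, chain = NULL, T_grid = NULL,
                              model = object$model, ...) {
  melts <- Filter(function(d) inherits(d, "melt_curve"), object$datasets)
  if (is.null(chain))
    chain <- if (length(melts)) melts[[1]]$chain else
      stop("supply 'chain': the fit contains no melt curve", call. = FALSE)
  if (is.null(T_grid))
    T_grid <- if (length(melts)) melts[[1]]$temperature_C else seq(0, 95)
  pr <- .split_params(object$coefficients)
  predict_melt(pr$spectro, pr$thermo, chain, T_grid, model)
}

#' Simulate replicate datasets from a fitted model
#'
#' Parametric bootstrap: regenerates every dataset in the fit from the
#' fitted parameters with Gaussian noise at the dataset's noise scale (or
#' the profiled `sigma_hat`).
#'
#' @param object A `"helix_fit"` object.
#' @param nsim Number of replicate dataset lists.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` dataset lists.
#' @export
simulate.helix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$coefficients
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    out[[s]] <- lapply(seq_along(object$datasets), function(i) {
      ds <- object$datasets[[i]]
      mu <- object$fitted[[i]]
      sg <- (if (inherits(ds, "melt_curve")) ds$sigma_222 else ds$sigma) %||%
        object$sigma_hat
      noisy <- mu + stats::rnorm(length(mu), 0, sg)
      if (inherits(ds, "melt_curve"))
        melt_curve(ds$chain, ds$temperature_C, noisy, sigma_222 = ds$sigma_222,
                   label = ds$label)
      else if (inherits(ds, "helix_reference"))
        helix_reference(ds$n_pep, noisy, T = ds$T, sigma = ds$sigma)
      else slope_reference(ds$n_pep, noisy, sigma = ds$sigma)
    })
  }
  out
}

#' Plot a fitted global model
#'
#' Observed melt curves (points) with the fitted model (lines), one colour
#' per chain.
#'
#' @param x A `"helix_fit"` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.helix_fit <- function(x, ...) {
  melts_i <- which(vapply(x$datasets, inherits, TRUE, what = "melt_curve"))
  if (!length(melts_i)) {
    warning("no melt curves in the fit; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  melts <- x$datasets[melts_i]
  xr <- range(unlist(lapply(melts, `[[`, "temperature_C")))
  yr <- range(unlist(lapply(melts, `[[`, "theta_222")))
  graphics::plot.default(NA, xlim = xr, ylim = yr, xlab = "Temperature (degC)",
       ylab = expression(paste("[", theta, "]"[222],
                               " (deg cm"^2, " dmol"^-1, ")")), ...)
  cols <- grDevices::hcl.colors(length(melts), "Dark 2")
  for (j in seq_along(melts)) {
    graphics::points(melts[[j]]$temperature_C, melts[[j]]$theta_222,
                     col = cols[j], pch = 16, cex = 0.5)
    graphics::lines(melts[[j]]$temperature_C, x$fitted[[melts_i[j]]],
                    col = cols[j], lwd = 2)
  }
  graphics::legend("bottomright", legend = vapply(melts, `[[`, "", "label"),
                   col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes point estimates, 2-sigma uncertainties, the correlation matrix,
#' diagnostics, seed and configuration hash.
#'
#' @param fit A `"helix_fit"` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "helix_fit"))
  out <- list(package = "helixcd",
              version = as.character(utils::packageVersion("helixcd")),
              model = fit$model, method = fit$method, seed = fit$seed,
              config_hash = fit$config_hash,
              coefficients = as.list(fit$coefficients),
              two_sigma = as.list(fit$two_sigma),
              correlation = fit$correlation,
              sigma_hat = fit$sigma_hat, rss = fit$rss, n_obs = fit$n_obs,
              diagnostics = fit$diagnostics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
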