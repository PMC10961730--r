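# Containers for CD datasets and their plain-text serialization.

#' CD thermal-melt curve
#'
#' A thermal melt: mean molar ellipticity at 222 nm per peptide unit versus
#' temperature for one peptide chain.
#'
#' @param chain A [chain_spec()] object.
#' @param temperature_C Strictly increasing temperatures in degC, within
#'   -10..110.
#' @param theta_222 Ellipticities (deg cm^2 dmol^-1 per peptide unit), same
#'   length as `temperature_C` (length >= 2).
#' @param sigma_222 Optional noise scale of the points (scalar or per point).
#' @param path_cm,conc_M Optional acquisition metadata.
#' @param label Optional curve label.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(chain, temperature_C, theta_222, sigma_222 = NULL,
                       path_cm = NA_real_, conc_M = NA_real_, label = NULL) {
  stopifnot(inherits(chain, "chain_spec"),
            is.numeric(temperature_C), is.numeric(theta_222),
            length(temperature_C) == length(theta_222),
            length(temperature_C) >= 2L)
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (any(temperature_C < -10 | temperature_C > 110))
    stop("temperatures must lie within -10..110 degC", call. = FALSE)
  if (!is.null(sigma_222)) {
    stopifnot(is.numeric(sigma_222), all(sigma_222 >= 0))
    if (!length(sigma_222) %in% c(1L, length(theta_222)))
      stop("'sigma_222' must be scalar or one value per point", call. = FALSE)
  }
  structure(list(chain = chain, temperature_C = as.numeric(temperature_C),
                 theta_222 = as.numeric(theta_222), sigma_222 = sigma_222,
                 path_cm = path_cm, conc_M = conc_M,
                 label = label %||% sprintf("n_res=%d", chain$n_res)),
            class = "melt_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("CD melt '%s': %d points, %g..%g degC, theta_222 %.0f..%.0f\n",
              x$label, length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C), min(x$theta_222), max(x$theta_222)))
  invisible(x)
}

#' Fully-helical reference series
#'
#' Observations of the per-unit helix ellipticity `theta_H(n_pep, T)` for
#' peptides known to be fully helical, used to constrain `theta_H_inf` and
#' the end-effect parameter `k` in a global fit.
#'
#' @param n_pep Peptide-unit counts (each >= 7).
#' @param value Observed per-unit ellipticities.
#' @param T Temperature of the series in degC (default 0).
#' @param sigma Optional noise scale.
#' @return An object of class `"helix_reference"`.
#' @export
helix_reference <- function(n_pep, value, T = 0, sigma = NULL) {
  stopifnot(is.numeric(n_pep), is.numeric(value),
            length(n_pep) == length(value), all(n_pep >= 7))
  structure(list(n_pep = as.numeric(n_pep), value = as.numeric(value),
                 T = T, sigma = sigma),
            class = "helix_reference")
}

#' Pre-transition slope reference series
#'
#' Observations of the temperature slope of the fully-helical ellipticity,
#' `d theta_H(n_pep)/dT = dtheta_H_inf_dT (1 - k/n_pep)` under a
#' temperature-independent `k`.
#'
#' @param n_pep Peptide-unit counts.
#' @param value Observed slopes (deg cm^2 dmol^-1 per degC).
#' @param sigma Optional noise scale.
#' @return An object of class `"slope_reference"`.
#' @export
slope_reference <- function(n_pep, value, sigma = NULL) {
  stopifnot(is.numeric(n_pep), is.numeric(value),
            length(n_pep) == length(value))
  structure(list(n_pep = as.numeric(n_pep), value = as.numeric(value),
                 sigma = sigma),
            class = "slope_reference")
}

#' Write a melt curve to CSV
#'
#' Serializes a [melt_curve()] to a CSV file with `# key=value` metadata
#' header lines (`n_res`, `blocked`, and when available `sigma_222`,
#' `conc_M`, `path_cm`, `label`) followed by `temperature_C,theta_222`
#' columns at full precision.
#'
#' @param curve A `"melt_curve"` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @seealso [read_melt_csv()]
#' @export
write_melt_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melt_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("# n_res=%d", curve$chain$n_res),
            sprintf("# blocked=%s", tolower(as.character(curve$chain$blocked))))
  if (!is.null(curve$sigma_222))
    meta <- c(meta, sprintf("# sigma_222=%s",
                            paste(format(curve$sigma_222, digits = 17),
                                  collapse = ";")))
  if (!is.na(curve$path_cm))
    meta <- c(meta, sprintf("# path_cm=%s", format(curve$path_cm, digits = 17)))
  if (!is.na(curve$conc_M))
    meta <- c(meta, sprintf("# conc_M=%s", format(curve$conc_M, digits = 17)))
  if (!is.null(curve$label)) meta <- c(meta, sprintf("# label=%s", curve$label))
  writeLines(meta, con)
  writeLines("temperature_C,theta_222", con)
  writeLines(paste(format(curve$temperature_C, digits = 17),
                   format(curve$theta_222, digits = 17), sep = ","), con)
  invisible(path)
}

.parse_meta <- function(lines, path) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in meta_lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("%s: malformed metadata line '%s' (expected '# key=value')",
                   path, ln), call. = FALSE)
    kv[[trimws(substr(body, 1, eq - 1))]] <- trimws(substr(body, eq + 1,
                                                           nchar(body)))
  }
  kv
}

#' Read a melt curve from CSV
#'
#' Parses the format written by [write_melt_csv()]. The `n_res` and
#' `blocked` metadata lines are required; locale-style decimal commas in the
#' data are rejected.
#'
#' @param path File path.
#' @return A `"melt_curve"` object.
#' @export
read_melt_csv <- function(path) {
  lines <- readLines(path)
  kv <- .parse_meta(lines, path)
  if (is.null(kv$n_res) || is.null(kv$blocked))
    stop(sprintf("%s: missing required metadata header ('# n_res=', '# blocked=')",
                 path), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || trimws(body[1]) != "temperature_C,theta_222")
    stop(sprintf("%s: expected column header 'temperature_C,theta_222' at line %d",
                 path, sum(grepl("^#", lines)) + 1L), call. = FALSE)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("%s: malformed data row at line %d (expected two comma-separated fields; decimal commas are not supported)",
                 path, sum(grepl("^#", lines)) + 1L + bad[1]), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 2L,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1]
    stop(sprintf("%s: non-numeric value at line %d (decimal commas are not supported; use '.')",
                 path, sum(grepl("^#", lines)) + 1L + bad), call. = FALSE)
  }
  sigma <- if (!is.null(kv$sigma_222))
    as.numeric(strsplit(kv$sigma_222, ";", fixed = TRUE)[[1]])
  melt_curve(chain_spec(as.integer(kv$n_res),
                        blocked = tolower(kv$blocked) %in% c("true", "1", "yes")),
             m[, 1], m[, 2], sigma_222 = sigma,
             path_cm = as.numeric(kv$path_cm %||% NA),
             conc_M = as.numeric(kv$conc_M %||% NA),
             label = kv$label)
}

#' Write / read a reference series CSV
#'
#' Reference series (fully-helical ellipticities or pre-transition slopes)
#' are stored as `n_pep,value` CSV with optional `# key=value` metadata
#' (`type`, `T`, `sigma`).
#'
#' @param ref A `"helix_reference"` or `"slope_reference"` object.
#' @param path File path.
#' @return `path` (write) or the reference object (read).
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "helix_reference") || inherits(ref, "slope_reference"))
  con <- file(path, "w")
  on.exit(close(con))
  type <- if (inherits(ref, "helix_reference")) "helix" else "slope"
  meta <- sprintf("# type=%s", type)
  if (type == "helix") meta <- c(meta, sprintf("# T=%s", format(ref$T, digits = 17)))
  if (!is.null(ref$sigma))
    meta <- c(meta, sprintf("# sigma=%s", format(ref$sigma[1], digits = 17)))
  writeLines(meta, con)
  writeLines("n_pep,value", con)
  writeLines(paste(format(ref$n_pep, digits = 17),
                   format(ref$value, digits = 17), sep = ","), con)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  lines <- readLines(path)
  kv <- .parse_meta(lines, path)
  if (is.null(kv$type) || !kv$type %in% c("helix", "slope"))
    stop(sprintf("%s: missing or unknown '# type=' metadata ('helix' or 'slope')",
                 path), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || trimws(body[1]) != "n_pep,value")
    stop(sprintf("%s: expected column header 'n_pep,value'", path),
         call. = FALSE)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 2L,
              byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("%s: non-numeric value in data rows (decimal commas are not supported)",
                 path), call. = FALSE)
  sigma <- if (!is.null(kv$sigma)) as.numeric(kv$sigma)
  if (kv$type == "helix")
    helix_reference(m[, 1], m[, 2], T = as.numeric(kv$T %||% 0), sigma = sigma)
  else
    slope_reference(m[, 1], m[, 2], sigma = sigma)
}
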