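# Composition-resolved Lifson-Roig statistics.
#
# A conformer class ("composition") is the multiset of helical-run lengths
# (in residues) of the chain interior; terminal residues are fixed in the
# coil state and carry neither v nor w. A run of m >= 3 consecutive helical
# residues is a helical segment spanning n_H = m + 1 peptide units; runs of
# one or two helical residues carry their Lifson-Roig weight but are
# spectroscopic coil. Weight of a class: Omega * v^n * w^m with one v per
# isolated helical residue, v^2 w^(m-2) per run of m >= 2, and Omega the
# number of placements of the run multiset along the interior.

.comp_cache <- new.env(parent = emptyenv())

# All multisets of interior run lengths that fit into L interior positions
# (runs separated by >= 1 coil residue), as a list of decreasing integer
# vectors; includes the empty (all-coil) multiset.
.run_multisets <- function(L) {
  out <- vector("list", 1024L)
  n_out <- 0L
  push <- function(x) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- x
  }
  # budget: each run of length m consumes m + 1 positions except the last
  # (sum(m_i) + j - 1 <= L  <=>  sum(m_i + 1) <= L + 1)
  recurse <- function(prefix, max_part, budget) {
    push(prefix)
    if (budget < 2L) return(invisible())
    for (m in seq_len(min(max_part, budget - 1L))) {
      recurse(c(prefix, m), m, budget - m - 1L)
    }
  }
  recurse(integer(0), max_part = L, budget = L + 1L)
  out[seq_len(n_out)]
}

# Exact placement count of an ordered-agnostic run multiset in L positions.
.omega <- function(runs, L) {
  j <- length(runs)
  if (j == 0L) return(1)
  M <- sum(runs)
  perms <- factorial(j) / prod(factorial(tabulate(runs, nbins = max(runs))))
  perms * choose(L - M + 1, j)
}

.comp_key <- function(runs) {
  if (length(runs) == 0L) return("coil")
  paste(sort(as.integer(runs), decreasing = TRUE), collapse = "+")
}

# Composition table for a chain: one row per run multiset with the
# Lifson-Roig exponents, degeneracy and spectroscopic unit counts.
# Cached per (n_res, blocked).
.composition_table <- function(chain) {
  key <- sprintf("n%d_b%d", chain$n_res, as.integer(chain$blocked))
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  L <- max(0L, chain$n_res - 2L)  # interior residues (termini fixed coil)
  sets <- .run_multisets(L)
  nr <- length(sets)
  keyv <- character(nr); n_v <- integer(nr); m_w <- integer(nr)
  omega <- numeric(nr); n_H <- integer(nr); n_seg <- integer(nr)
  a_units <- integer(nr); b_units <- integer(nr)
  for (i in seq_len(nr)) {
    runs <- sets[[i]]
    keyv[i] <- .comp_key(runs)
    n_v[i] <- sum(ifelse(runs == 1L, 1L, 2L))
    m_w[i] <- sum(pmax(runs - 2L, 0L))
    omega[i] <- .omega(runs, L)
    segs <- runs[runs >= 3L] + 1L       # segment lengths in peptide units
    n_H[i] <- sum(segs)
    n_seg[i] <- length(segs)
    a_units[i] <- sum(pmin(segs, 6L))   # singly H-bonded (end) units
    b_units[i] <- sum(pmax(segs - 6L, 0L))  # doubly H-bonded interior units
  }
  tab <- data.frame(key = keyv, n_v = n_v, m_w = m_w, omega = omega,
                    n_H = n_H, n_seg = n_seg, a_units = a_units,
                    b_units = b_units, n_coil = chain$n_pep - n_H,
                    stringsAsFactors = FALSE)
  .comp_cache[[key]] <- tab
  tab
}

.new_ensemble <- function(chain, v, w, comp, method) {
  weight <- comp$omega * v^comp$n_v * w^comp$m_w
  Q <- sum(weight)
  structure(list(chain = chain, v = v, w = w,
                 comp = cbind(comp, weight = weight, prob = weight / Q),
                 Q = Q, method = method),
            class = "helix_ensemble")
}

#' Composition-resolved helix-coil ensemble
#'
#' Builds the full Lifson-Roig ensemble of a peptide chain at nucleation
#' constant `v` and propagation constant `w`, resolved by conformer class:
#' the multiset of helical-run lengths. Runs of three or more consecutive
#' helical residues are helical segments of `run + 1` peptide units; shorter
#' runs are spectroscopic coil. Terminal residues are held in the coil state.
#' The enumeration is exact over all segment counts; degeneracies are
#' computed combinatorially, so the cost grows with the number of run
#' partitions, not with `2^n_res`.
#'
#' @param chain A [chain_spec()] object.
#' @param v,w Lifson-Roig nucleation and propagation constants (`v > 0`,
#'   `w >= 0`).
#' @return An object of class `"helix_ensemble"`: a list with the chain, the
#'   parameters, the partition function `Q` and a `comp` data frame holding,
#'   per conformer class, the run-multiset key, the `v` and `w` exponents,
#'   the degeneracy `omega`, helical-unit count `n_H`, segment count
#'   `n_seg`, singly/doubly hydrogen-bonded unit counts and the statistical
#'   weight and probability.
#' @seealso [enumerate_bruteforce()], [mean_helicity()],
#'   [segment_count_distribution()], [ensemble_signal()]
#' @examples
#' dist <- composition_weights(chain_spec(32), v = 0.048, w = 1.8)
#' mean_helicity(dist)
#' @export
composition_weights <- function(chain, v, w) {
  stopifnot(inherits(chain, "chain_spec"))
  stopifnot(is.numeric(v), length(v) == 1L, v >= 0,
            is.numeric(w), length(w) == 1L, w >= 0)
  .new_ensemble(chain, v, w, .composition_table(chain), "combinatorial")
}

#' Brute-force ensemble enumeration
#'
#' Reference implementation that enumerates every helix/coil configuration
#' of the chain interior (terminal residues fixed coil), assigns each state
#' its Lifson-Roig weight run by run, and groups states into conformer
#' classes. Exponential in chain length; intended as an oracle for
#' [composition_weights()] on short chains.
#'
#' @inheritParams composition_weights
#' @return A `"helix_ensemble"` object (see [composition_weights()]).
#' @export
enumerate_bruteforce <- function(chain, v, w) {
  stopifnot(inherits(chain, "chain_spec"))
  if (chain$n_res > 22)
    stop("brute-force enumeration is limited to n_res <= 22; ",
         "use composition_weights() for longer chains", call. = FALSE)
  L <- max(0L, chain$n_res - 2L)
  acc <- new.env(parent = emptyenv())
  for (state in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(state))[seq_len(max(L, 1L))]
    if (L == 0L) bits <- integer(0)
    r <- rle(c(0L, bits, 0L))
    runs <- r$lengths[r$values == 1L]
    key <- .comp_key(runs)
    wt <- prod(ifelse(runs == 1L, v, v^2 * w^(runs - 2L)))
    prev <- acc[[key]]
    if (is.null(prev)) {
      acc[[key]] <- list(runs = sort(runs, decreasing = TRUE),
                         omega = 1, weight = wt)
    } else {
      prev$omega <- prev$omega + 1
      prev$weight <- prev$weight + wt
      acc[[key]] <- prev
    }
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(k) {
    e <- acc[[k]]
    runs <- e$runs
    segs <- runs[runs >= 3L] + 1L
    data.frame(key = k,
               n_v = sum(ifelse(runs == 1L, 1L, 2L)),
               m_w = sum(pmax(runs - 2L, 0L)),
               omega = e$omega,
               n_H = sum(segs), n_seg = length(segs),
               a_units = sum(pmin(segs, 6L)),
               b_units = sum(pmax(segs - 6L, 0L)),
               n_coil = chain$n_pep - sum(segs),
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, rows)
  .new_ensemble(chain, v, w, comp, "bruteforce")
}

#' @export
print.helix_ensemble <- function(x, ...) {
  cat(sprintf("Lifson-Roig ensemble: %d residues (%d units), v = %g, w = %g\n",
              x$chain$n_res, x$chain$n_pep, x$v, x$w))
  cat(sprintf("  %d conformer classes, Q = %.6g\n", nrow(x$comp), x$Q))
  cat(sprintf("  mean helicity = %.4f, P(>=1 segment) = %.4f\n",
              mean_helicity(x), sum(x$comp$prob[x$comp$n_seg >= 1])))
  invisible(x)
}

#' Probability of a conformer class
#'
#' Looks up the ensemble probability `Omega v^n w^m / Q` of the conformer
#' class identified by its multiset of helical-run lengths (in residues;
#' an empty vector denotes the all-coil class).
#'
#' @param dist A `"helix_ensemble"` object.
#' @param runs Integer vector of helical-run lengths, or `numeric(0)` for
#'   the all-coil class.
#' @return The class probability.
#' @examples
#' d <- composition_weights(chain_spec(7), v = 0.07, w = 1.5)
#' conformer_class_probability(d, 3)          # single run of 3 h residues
#' conformer_class_probability(d, numeric(0)) # all coil
#' @export
conformer_class_probability <- function(dist, runs) {
  stopifnot(inherits(dist, "helix_ensemble"))
  key <- .comp_key(runs)
  i <- match(key, dist$comp$key)
  if (is.na(i))
    stop(sprintf("conformer class '%s' not present in this ensemble", key),
         call. = FALSE)
  dist$comp$prob[i]
}

#' Mean fractional helicity of an ensemble
#'
#' Probability-weighted fraction of peptide units inside helical segments,
#' `sum_i p_i n_H,i / n_pep`.
#'
#' @param dist A `"helix_ensemble"` object.
#' @return Fraction in `[0, 1]`.
#' @export
mean_helicity <- function(dist) {
  stopifnot(inherits(dist, "helix_ensemble"))
  sum(dist$comp$prob * dist$comp$n_H) / dist$chain$n_pep
}

#' Distribution of the number of helical segments
#'
#' Ensemble probabilities of conformers containing 0, 1, 2 or three-or-more
#' helical segments.
#'
#' @param dist A `"helix_ensemble"` object.
#' @return Named numeric vector `c("0", "1", "2", ">=3")` summing to 1.
#' @export
segment_count_distribution <- function(dist) {
  stopifnot(inherits(dist, "helix_ensemble"))
  ns <- dist$comp$n_seg
  p <- dist$comp$prob
  c("0"   = sum(p[ns == 0L]),
    "1"   = sum(p[ns == 1L]),
    "2"   = sum(p[ns == 2L]),
    ">=3" = sum(p[ns >= 3L]))
}
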