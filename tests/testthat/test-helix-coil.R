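test_that("propagation constant follows the Gibbs-Helmholtz relation", {
  th <- table1_thermo()
  # calibration value: dG = -0.22 kcal/mol at 0 degC gives w = 1.50
  expect_equal(round(propagation_at_T(th, 273.15), 2), 1.50)
  # zero free energy at the reference temperature gives w = 1 exactly
  th0 <- thermo_params(v = 0.05, dG0 = 0, dH0 = 0, dCp = 0)
  expect_identical(propagation_at_T(th0, 273.15), 1)
  # independently coded Gibbs-Helmholtz oracle away from T0
  for (T_K in c(283.15, 333.15, 373.15)) {
    expect_equal(propagation_at_T(th, T_K),
                 oracle_w(-0.22, -1.3, 0.006, T_K), tolerance = 1e-12)
  }
  # dCp = 0 reduces to the two-parameter van 't Hoff closed form
  th_vh <- thermo_params(v = 0.05, dG0 = -0.22, dH0 = -1.3, dCp = 0)
  T_K <- seq(263.15, 383.15, by = 10)
  dG_vh <- -1.3 - T_K * (-1.3 + 0.22) / 273.15
  expect_equal(propagation_at_T(th_vh, T_K), exp(-dG_vh / (1.987e-3 * T_K)),
               tolerance = 1e-12)
  expect_error(propagation_at_T(th, -5), "positive")
  expect_error(thermo_params(v = -0.1, dG0 = 0), "positive")
})

test_that("brute-force enumeration matches hand-derived closed forms", {
  # 4 residues: only 2 interior positions, no run of 3 -> no helical segment
  d4 <- enumerate_bruteforce(chain_spec(4), v = 0.1, w = 1.5)
  expect_equal(sum(d4$comp$prob[d4$comp$n_seg >= 1]), 0)
  # 5 residues: Q = 1 + 3v + 3v^2 + v^2 w, P(one segment) = v^2 w / Q
  v <- 0.13; w <- 0.9
  d5 <- enumerate_bruteforce(chain_spec(5), v, w)
  Q5 <- 1 + 3 * v + 3 * v^2 + v^2 * w
  expect_equal(d5$Q, Q5, tolerance = 1e-14)
  expect_equal(sum(d5$comp$prob[d5$comp$n_seg == 1]), v^2 * w / Q5,
               tolerance = 1e-14)
  # nucleation forbidden: all-coil only
  d0 <- enumerate_bruteforce(chain_spec(9), v = 0, w = 1.7)
  expect_equal(d0$Q, 1)
  expect_equal(conformer_class_probability(d0, numeric(0)), 1)
  expect_error(enumerate_bruteforce(chain_spec(23), 0.05, 1), "n_res <= 22")
})

test_that("efficient enumerator reproduces brute force composition by composition", {
  grid <- expand.grid(v = c(0.01, 0.048, 0.07, 0.1),
                      w = c(0.6, 1.0, 1.2, 1.5, 1.8))
  for (n in 2:14) {
    for (g in seq_len(nrow(grid))) {
      b <- enumerate_bruteforce(chain_spec(n), grid$v[g], grid$w[g])
      e <- composition_weights(chain_spec(n), grid$v[g], grid$w[g])
      bo <- b$comp[order(b$comp$key), ]
      eo <- e$comp[order(e$comp$key), ]
      expect_identical(bo$key, eo$key)
      expect_identical(bo$omega, eo$omega)
      expect_equal(bo$weight, eo$weight, tolerance = 1e-12)
      expect_equal(bo$prob, eo$prob, tolerance = 1e-12)
      expect_equal(b$Q, e$Q, tolerance = 1e-12)
    }
  }
})

test_that("conformer class probabilities follow Omega v^n w^m / Q", {
  d <- composition_weights(chain_spec(7), v = 0.07, w = 1.5)
  # one run of 3 helical residues has 3 interior placements in a 7-mer
  i <- match("3", d$comp$key)
  expect_identical(d$comp$omega[i], 3)
  expect_equal(conformer_class_probability(d, 3), 3 * 0.07^2 * 1.5 / d$Q)
  expect_equal(sum(d$comp$prob), 1, tolerance = 1e-12)
  # all-coil class has probability 1 when nucleation is impossible
  d0 <- composition_weights(chain_spec(12), v = 0, w = 2)
  expect_equal(conformer_class_probability(d0, numeric(0)), 1)
  expect_error(conformer_class_probability(d, c(5, 5)), "not present")
})

test_that("probabilities stay normalized up to long chains", {
  for (n in c(20, 35, 50)) {
    d <- composition_weights(chain_spec(n), v = 0.05, w = 1.3)
    expect_equal(sum(d$comp$prob), 1, tolerance = 1e-10)
    expect_true(all(d$comp$prob >= 0 & d$comp$prob <= 1))
    expect_equal(d$Q, sum(d$comp$weight), tolerance = 1e-12)
  }
})

test_that("mean helicity behaves across the propagation range", {
  ch <- chain_spec(32)
  # anchor: strongly helix-favoring conditions give ~90% helicity
  expect_equal(mean_helicity(composition_weights(ch, 0.048, 1.8)), 0.90,
               tolerance = 0.05 / 0.90)
  # w -> 0: no helix
  expect_lt(mean_helicity(composition_weights(ch, 0.048, 1e-6)), 1e-4)
  # strictly increasing in w at fixed v
  h <- vapply(seq(0.6, 1.8, by = 0.1),
              function(w) mean_helicity(composition_weights(ch, 0.048, w)), 1)
  expect_true(all(diff(h) > 0))
  # w -> infinity: the single maximal helix, (n_res - 1)/n_pep units
  for (n in c(10, 32)) {
    d <- composition_weights(chain_spec(n), 0.01, 1e6)
    expect_equal(mean_helicity(d), (n - 1) / (n + 1), tolerance = 1e-5)
  }
})

test_that("segment-count distribution is normalized and v controls splitting", {
  ch <- chain_spec(32)
  d0 <- composition_weights(ch, v = 0, w = 1.5)
  expect_equal(unname(segment_count_distribution(d0)["0"]), 1)
  for (w in c(0.8, 1.2, 1.6)) {
    p <- segment_count_distribution(composition_weights(ch, 0.07, w))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # raising v at fixed w promotes breaking single helices into double
  ratio <- vapply(seq(0.01, 0.1, by = 0.01), function(v) {
    p <- segment_count_distribution(composition_weights(ch, v, 1.2))
    unname(p["2"] / p["1"])
  }, 1)
  expect_true(all(diff(ratio) > 0))
})
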