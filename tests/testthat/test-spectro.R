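test_that("helix-length corrections evaluate to their closed forms", {
  sp <- scan_spectro() # theta_H_inf = -40000, k = 4, slopes/coil zero
  # single-bonded end-unit ellipticity theta_H1 = theta_H_inf (1 - k/6)
  expect_equal(theta_H1(sp, 0), -40000 * (1 - 4 / 6), tolerance = 1e-12)
  # vanishing end effect: theta_H1 -> theta_H_inf
  sp_k0 <- spectro_params(-40000, 0, 1e-9, 0, 0)
  expect_equal(theta_H1(sp_k0, 0), -40000, tolerance = 1e-9)
  # constant k propagates the temperature slope: d theta_H1/dT = slope (1 - k/6)
  spT <- spectro_params(-41000, 100, 3.4, 2100, -45)
  slope <- (theta_H1(spT, 1) - theta_H1(spT, 0)) / 1
  expect_equal(slope, 100 * (1 - 3.4 / 6), tolerance = 1e-9) # = 43.3
  # empirical correction
  expect_equal(helix_per_unit_empirical(33, sp, 0), -40000 * (1 - 4 / 33))
  expect_equal(helix_per_unit_empirical(4, sp, 0), -40000 * (1 - 4 / 4))
  expect_equal(helix_per_unit_empirical(1e9, sp, 0), -40000, tolerance = 1e-6)
  expect_error(helix_per_unit_empirical(0, sp, 0), ">= 1")
  expect_warning(spectro_params(-40000, 0, 6.5, 0, 0), "theta_H1")
})

test_that("dichroic per-conformer totals follow the piecewise rule", {
  sp <- scan_spectro()
  th1 <- -40000 * (1 - 4 / 6)
  # long segment: 6 single-bonded end units + interior at theta_H_inf
  expect_equal(helix_total_dichroic(10, sp, 0), 6 * th1 + 4 * -40000)
  # short segment: all units single-bonded
  expect_equal(helix_total_dichroic(4, sp, 0), 4 * th1)
  # multiple segments: end corrections applied per segment
  expect_equal(helix_total_dichroic(c(5, 9), sp, 0),
               5 * th1 + (6 * th1 + 3 * -40000))
  # dichroic and empirical agree per unit for any single segment > 6 units
  for (n in 7:33)
    expect_equal(helix_total_dichroic(n, sp, 0) / n,
                 helix_per_unit_empirical(n, sp, 0), tolerance = 1e-12)
  expect_error(helix_total_dichroic(3, sp, 0), "at least 4")
})

test_that("linear model scales the maximal-length correction", {
  sp <- scan_spectro()
  ch <- chain_spec(32) # N_pep = 33
  expect_equal(helix_total_linear(4, ch, sp, 0), 4 * -40000 * (1 - 4 / 33))
  expect_identical(helix_total_linear(0, ch, sp, 0), 0)
  expect_equal(helix_total_linear(33, ch, sp, 0), 33 * -40000 * (1 - 4 / 33))
  expect_error(helix_total_linear(34, ch, sp, 0), "n_pep")
  # all three models coincide for the full-chain helix segment
  expect_equal(helix_total_dichroic(33, sp, 0), helix_total_linear(33, ch, sp, 0),
               tolerance = 1e-12)
  expect_equal(33 * helix_per_unit_empirical(33, sp, 0),
               helix_total_linear(33, ch, sp, 0), tolerance = 1e-12)
})

test_that("coil baseline is affine in temperature", {
  sp <- table1_spectro()
  expect_equal(coil_baseline(sp, 0), 2100)
  expect_equal(coil_baseline(sp, 50), 2100 - 45 * 50)
  sp_flat <- spectro_params(-40000, 0, 4, 2100, 0)
  expect_equal(coil_baseline(sp_flat, c(0, 30, 90)), rep(2100, 3))
})

test_that("ensemble signal averages conformer contributions correctly", {
  sp <- table1_spectro()
  ch <- chain_spec(20)
  # all-coil ensemble returns the coil baseline at any temperature
  d0 <- composition_weights(ch, v = 0, w = 1.5)
  for (T in c(0, 25, 80))
    expect_equal(ensemble_signal(d0, sp, T, "dichroic"),
                 coil_baseline(sp, T), tolerance = 1e-12)
  # ensemble dominated by the maximal helix: per-unit signal approaches the
  # single-conformer total for all three models (within the residual end
  # effect of the two coil-fixed termini)
  d_inf <- composition_weights(ch, v = 0.01, w = 1e6)
  n_max <- ch$n_res - 1
  ref <- (helix_total_dichroic(n_max, sp, 25) +
            2 * coil_baseline(sp, 25)) / ch$n_pep
  expect_equal(ensemble_signal(d_inf, sp, 25, "dichroic"), ref,
               tolerance = 1e-5)
  # the three models agree within the residual end effect of the two
  # coil-fixed termini (k (1/(n_res-1) - 1/n_pep) ~ 2% for a 20-mer)
  agree <- vapply(c("dichroic", "empirical", "linear"),
                  function(m) ensemble_signal(d_inf, sp, 25, m), 1)
  expect_lt(diff(range(agree)) / abs(mean(agree)), 0.025)
  # unit-count completeness: helix + coil units account for every unit
  cm <- composition_weights(ch, 0.07, 1.2)$comp
  expect_true(all(cm$n_H + cm$n_coil == ch$n_pep))
  expect_error(ensemble_signal(d0, sp, 0, "cubic"))
})

test_that("linear model overestimates signal magnitude on mixed ensembles", {
  sp <- scan_spectro()
  ch <- chain_spec(32)
  ws <- seq(0.6, 1.8, by = 0.05)
  lin <- dic <- numeric(length(ws))
  for (i in seq_along(ws)) {
    d <- composition_weights(ch, 0.048, ws[i])
    lin[i] <- ensemble_signal(d, sp, 0, "linear")
    dic[i] <- ensemble_signal(d, sp, 0, "dichroic")
  }
  expect_true(all(abs(lin) >= abs(dic)))
  # the absolute difference peaks at intermediate helicity, not the ends
  i_pk <- which.max(abs(lin - dic))
  expect_gt(i_pk, 1)
  expect_lt(i_pk, length(ws))
})

test_that("raw signals convert to mean molar ellipticity per unit", {
  ch <- chain_spec(32) # blocked: N_pep = 33 in the denominator
  expect_equal(raw_to_molar(-20, 0.1, 1e-4, ch), -20 / (10 * 0.1 * 1e-4 * 33))
  expect_identical(raw_to_molar(0, 0.1, 1e-4, ch), 0)
  expect_equal(raw_to_molar(-20, 0.1, 1e-4, 33), raw_to_molar(-20, 0.1, 1e-4, ch))
  expect_error(raw_to_molar(-20, 0, 1e-4, ch), "path")
  expect_error(raw_to_molar(-20, 0.1, -1, ch), "concentration")
})
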