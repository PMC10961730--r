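test_that("melt simulation is exact at zero noise and seed-deterministic", {
  cfg0 <- sim_config(sigma_222 = 0, sigma_slope = 0, seed = 5,
                     chains = list(chain_spec(7), chain_spec(17)),
                     T_grid = seq(0, 90, by = 10))
  suite <- simulate_melt_suite(cfg0)
  expect_length(suite, 2L)
  for (i in 1:2) {
    clean <- predict_melt(cfg0$spectro, cfg0$thermo, cfg0$chains[[i]],
                          cfg0$T_grid)
    expect_identical(suite[[i]]$theta_222, clean$theta_222)
  }
  cfg <- sim_config(seed = 9, chains = list(chain_spec(7)),
                    T_grid = seq(0, 90, by = 10))
  expect_identical(simulate_melt_suite(cfg), simulate_melt_suite(cfg))
  cfg2 <- sim_config(seed = 10, chains = list(chain_spec(7)),
                     T_grid = seq(0, 90, by = 10))
  expect_false(identical(simulate_melt_suite(cfg)[[1]]$theta_222,
                         simulate_melt_suite(cfg2)[[1]]$theta_222))
})

test_that("noise averages out at the law-of-large-numbers rate", {
  sigma <- 300
  clean <- predict_melt(spectro_params(), table1_thermo(), chain_spec(7),
                        c(0, 50))$theta_222[1]
  reps <- vapply(seq_len(1000), function(s) {
    cfg <- sim_config(seed = s, sigma_222 = sigma,
                      chains = list(chain_spec(7)), T_grid = c(0, 50))
    simulate_melt_suite(cfg)[[1]]$theta_222[1]
  }, 1)
  expect_lt(abs(mean(reps) - clean), 3 * sigma / sqrt(1000))
})

test_that("fully-helical series is affine in 1/N with the right asymptote", {
  sp <- table1_spectro()
  ref <- simulate_fully_helical_series(sp, n_pep_list = c(7, 12, 33, 1000), T = 0)
  expect_equal(ref$value[3], -41000 * (1 - 3.4 / 33))
  expect_equal(ref$value[4], -41000, tolerance = 1e-2)
  # exactly affine in x = 1/N: second differences vanish on a uniform x grid
  x <- 1 / c(10, 20, 40)
  x <- seq(min(x), max(x), length.out = 5)
  v <- simulate_fully_helical_series(sp, n_pep_list = 1 / x, T = 0)$value
  expect_equal(diff(v, differences = 2), rep(0, 3), tolerance = 1e-9)
  expect_error(simulate_fully_helical_series(sp, n_pep_list = c(5, 10)))
})

test_that("pre-transition slopes follow the constant-k derivative", {
  sp <- table1_spectro()
  slp <- simulate_pretransition_slopes(sp, n_pep_list = c(8, 20, 50, 1e6))
  expect_equal(slp$value, 100 * (1 - 3.4 / c(8, 20, 50, 1e6)))
  expect_equal(slp$value[4], 100, tolerance = 1e-4)
  sp_k0 <- spectro_params(-41000, 100, 1e-9, 2100, -45)
  slp0 <- simulate_pretransition_slopes(sp_k0, n_pep_list = c(8, 30))
  expect_equal(slp0$value, c(100, 100), tolerance = 1e-6)
})

test_that("melt CSV round trip preserves values and metadata exactly", {
  cfg <- sim_config(seed = 21, chains = list(chain_spec(17)),
                    T_grid = seq(0, 95, by = 5))
  m <- simulate_melt_suite(cfg)[[1]]
  m$path_cm <- 0.1
  m$conc_M <- 1e-4
  path <- withr::local_tempfile(fileext = ".csv")
  write_melt_csv(m, path)
  m2 <- read_melt_csv(path)
  expect_identical(m2$theta_222, m$theta_222)
  expect_identical(m2$temperature_C, m$temperature_C)
  expect_identical(m2$chain, m$chain)
  expect_identical(m2$sigma_222, m$sigma_222)
  expect_identical(m2$label, m$label)
  expect_equal(m2$path_cm, 0.1)
  expect_equal(m2$conc_M, 1e-4)
})

test_that("reference CSV round trip preserves both series types", {
  sp <- table1_spectro()
  path <- withr::local_tempfile(fileext = ".csv")
  hel <- simulate_fully_helical_series(sp, 7:20, T = 0)
  write_reference_csv(hel, path)
  hel2 <- read_reference_csv(path)
  expect_identical(hel2$value, hel$value)
  expect_identical(hel2$n_pep, hel$n_pep)
  slp <- simulate_pretransition_slopes(sp, 7:20)
  write_reference_csv(slp, path)
  expect_s3_class(read_reference_csv(path), "slope_reference")
})

test_that("malformed melt CSVs are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # missing metadata header
  writeLines(c("temperature_C,theta_222", "0,100", "5,90"), path)
  expect_error(read_melt_csv(path), "metadata")
  # decimal commas
  writeLines(c("# n_res=7", "# blocked=true", "temperature_C,theta_222",
               "0,1894,5", "5,1800"), path)
  expect_error(read_melt_csv(path), "line 4")
  writeLines(c("# n_res=7", "# blocked=true", "temperature_C,theta_222",
               "0,abc"), path)
  expect_error(read_melt_csv(path), "decimal commas")
})
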