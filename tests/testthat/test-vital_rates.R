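test_that("Weibull survivorship matches its closed form and is proper", {
  wp <- weibull_params(log(1), 0, log(1), 0)  # b = k = 1
  expect_identical(weibull_survivorship(wp, 1, 0), 1)
  expect_equal(weibull_survivorship(wp, 1, 1), exp(-1))
  wp2 <- weibull_params(log(10), 0, log(2), 0)  # b = 10, k = 2
  expect_equal(weibull_survivorship(wp2, 1, 10), exp(-1))
  # proper survival function: S(0) = 1, nonincreasing, -> 0
  S <- weibull_survivorship(wp2, 1, 0:200)
  expect_true(all(diff(S) <= 0))
  expect_lt(S[201], 1e-12)
  expect_error(weibull_params(NaN, 0, 0, 0), "finite")
})

test_that("daily survival probabilities follow the hazard shape", {
  # exponential limit k = 1: memoryless, constant p across ages
  p_exp <- survival_probabilities(weibull_params(log(5), 0, log(1), 0),
                                  s = 3, omega = 10)
  expect_equal(unname(diff(p_exp[1, 1:9])), rep(0, 8))
  # rising hazard k > 1: p nonincreasing in age
  p_ris <- survival_probabilities(weibull_params(log(10), 0, log(2), 0),
                                  s = 2, omega = 12)
  expect_true(all(diff(p_ris[1, 1:11]) <= 0))
  expect_equal(p_ris[1, 1], exp(-0.01))
  # final age class is absorbing and all entries are probabilities
  expect_true(all(p_ris[, 12] == 0))
  expect_true(all(p_ris >= 0 & p_ris <= 1))
})

test_that("fertility schedule factorises as natural fertility x control", {
  base <- c(-2, 1.5, -0.15)
  # no maternal-age control: same schedule for every class
  ct0 <- coale_trussell_params(base, control_intercept = 0,
                               control_slope = 0)
  f0 <- fertility_schedule(ct0, s = 4, omega = 12)
  for (i in 2:4) expect_equal(f0[i, ], f0[1, ], ignore_attr = TRUE)
  expect_equal(unname(f0[1, 5]), natural_fertility(ct0, 5))
  # before the threshold age all classes coincide; after it the class
  # with the larger control level is strictly lower wherever n(j) > 0
  ct <- coale_trussell_params(base, control_threshold_age = 4,
                              control_intercept = 0.1, control_slope = 0.2)
  f <- fertility_schedule(ct, s = 6, omega = 12)
  for (j in 1:4) expect_equal(diff(f[, j]), rep(0, 5), ignore_attr = TRUE)
  for (j in 5:12) expect_true(all(diff(f[, j]) < 0))
  expect_true(all(f >= 0))
})

test_that("packaged default rates show the maternal-effect patterns", {
  v <- default_vital_rates()
  # fertility rises sharply between ages 2 and 4, identically across
  # maternal ages, and schedules diverge only after age 4
  expect_true(all(v$f[, 1] == 0))
  for (j in 1:4) expect_equal(diff(v$f[, j]), rep(0, 15),
                              ignore_attr = TRUE)
  expect_true(all(v$f[, 4] > v$f[, 2]))
  expect_true(all(v$f[, 3] > v$f[, 2]))
  for (j in 5:16) expect_true(all(diff(v$f[, j]) <= 0))
  # older maternal age declines earlier and faster
  expect_lt(v$f[9, 8], v$f[3, 8])
  # survival decreases with maternal age at young ages (throughout the
  # observed maternal-age range and beyond), crossing over only at the
  # extrapolated oldest classes
  for (j in 1:6) expect_true(all(diff(v$p[1:12, j]) <= 0))
  expect_gt(v$p[16, 15], v$p[1, 15])
})

test_that("parameter sets round-trip through flat YAML files", {
  truth <- default_truth()
  wf <- withr::local_tempfile(fileext = ".yaml")
  cf <- withr::local_tempfile(fileext = ".yaml")
  write_params(truth$weibull, wf)
  write_params(truth$fertility, cf)
  expect_equal(read_params(wf), truth$weibull)
  expect_equal(read_params(cf), truth$fertility)
})
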