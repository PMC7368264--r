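# A moderately large simulated data set shared across the fitting tests.
truth <- default_truth()
vital_true <- default_vital_rates()
lt_big <- simulate_life_table(
  vital_true, cohort_design(n_per_cohort = 800, censor_prob = 0.01,
                            seed = 2024))

test_that("single-cohort Weibull fit matches a brute-force grid search", {
  lt1 <- simulate_life_table(
    vital_true, cohort_design(maternal_ages = 3, n_per_cohort = 150,
                              censor_prob = 0, seed = 12))
  fit <- fit_weibull(lt1, fix_slopes = TRUE)
  # independent oracle: two-stage exhaustive grid over
  # (log scale, log shape)
  summ <- momage:::summarize_individuals(lt1)
  ll <- function(a, c) momage:::weibull_loglik(c(a, 0, c, 0), summ)
  best <- c(NA, NA, -Inf)
  grid_search <- function(as, cs, best) {
    for (a in as) for (cc in cs)
      if (ll(a, cc) > best[3]) best <- c(a, cc, ll(a, cc))
    best
  }
  best <- grid_search(seq(2.0, 3.4, by = 0.02),
                      seq(0.6, 2.2, by = 0.02), best)
  best <- grid_search(seq(best[1] - 0.03, best[1] + 0.03, by = 5e-4),
                      seq(best[2] - 0.03, best[2] + 0.03, by = 5e-4),
                      best)
  expect_lt(abs(fit$params$log_scale_intercept - best[1]), 1e-3)
  expect_lt(abs(fit$params$log_shape_intercept - best[2]), 1e-3)
  expect_gte(fit$loglik, best[3] - 1e-6)
})

test_that("Weibull estimates converge on the truth as cohorts grow", {
  tw <- unlist(truth$weibull)
  mae <- function(n, seed) {
    lt <- simulate_life_table(
      vital_true, cohort_design(n_per_cohort = n, censor_prob = 0.01,
                                seed = seed))
    mean(abs(unlist(fit_weibull(lt)$params) - tw) / abs(tw))
  }
  expect_lt(mae(2000, 31), mae(200, 31))
})

test_that("the optimum is never below the initial guess", {
  fw <- fit_weibull(lt_big)
  expect_gte(fw$loglik, fw$loglik_init)
  fc <- fit_coale_trussell(lt_big)
  expect_gte(fc$loglik, fc$loglik_init)
})

test_that("fertility fit agrees with an independent Poisson GLM", {
  fc <- fit_coale_trussell(lt_big)
  obs <- lt_big[lt_big$alive == 1 & lt_big$censored == 0 &
                  lt_big$day >= 3, ]
  obs$ramp <- pmax(obs$day - 4, 0)
  gl <- stats::glm(offspring ~ day + I(day^2) + ramp + ramp:maternal_age,
                   family = stats::poisson(), data = obs)
  cf <- stats::coef(gl)
  expect_equal(fc$params$natural_fertility_coeffs[2], unname(cf["day"]),
               tolerance = 1e-3)
  expect_equal(fc$params$control_intercept, -unname(cf["ramp"]),
               tolerance = 1e-3)
  expect_equal(fc$params$control_slope,
               -unname(cf["ramp:maternal_age"]), tolerance = 1e-3)
  expect_equal(fc$loglik,
               as.numeric(stats::logLik(gl)) +
                 sum(lgamma(obs$offspring + 1)),
               tolerance = 1e-6)
})

test_that("a data set with no maternal-age effect recovers a null slope", {
  ct0 <- coale_trussell_params(truth$fertility$natural_fertility_coeffs,
                               control_threshold_age = 4,
                               deviation_slope = 1,
                               control_intercept = 0.3, control_slope = 0,
                               min_reproductive_age = 3)
  v0 <- evaluate_vital_rates(truth$weibull, ct0)
  lt0 <- simulate_life_table(
    v0, cohort_design(n_per_cohort = 500, censor_prob = 0.01, seed = 77))
  fc <- fit_coale_trussell(lt0)
  expect_lt(abs(fc$params$control_slope),
            2 * fc$se["control_slope"])
})

test_that("degenerate inputs raise informative fitting errors", {
  expect_error(fit_weibull(lt_big[0, ]), "non-identifiable")
  # all individuals lost on their first day carry no survival information
  all_censored <- data.frame(individual_id = sprintf("c%02d", 1:10),
                             maternal_age = 3, day = 1, alive = 1,
                             censored = 1, offspring = 0)
  expect_error(fit_weibull(all_censored, fix_slopes = TRUE),
               "non-identifiable")
  one_class <- lt_big[lt_big$maternal_age == 3, ]
  expect_error(fit_weibull(one_class), "fix_slopes")
  zero_counts <- data.frame(individual_id = "a", maternal_age = 3,
                            day = 1:5, alive = 1, censored = 0,
                            offspring = 0)
  expect_error(fit_coale_trussell(zero_counts), "degenerate")
})

test_that("empirical rates count survivors and offspring directly", {
  toy <- data.frame(
    individual_id = rep(c("a", "b", "c", "d"), each = 1),
    maternal_age = 3, day = 1,
    alive = c(1, 1, 1, 0), censored = 0,
    offspring = c(2, 0, 1, 0))
  er <- empirical_rates(toy, s = 3, omega = 2)
  expect_equal(er$p[3, 1], 0.75)
  expect_equal(er$f[3, 1], 1)
  expect_identical(er$n_risk[3, 1], 4)
  expect_true(is.na(er$p[1, 1]))
  all_live <- data.frame(individual_id = as.character(1:10),
                         maternal_age = 1, day = 1, alive = 1,
                         censored = 0, offspring = 0)
  expect_equal(empirical_rates(all_live, s = 1, omega = 1)$p[1, 1], 1)
})

test_that("empirical rates cover the generating rates at large n", {
  lt <- simulate_life_table(
    vital_true, cohort_design(n_per_cohort = 1250, censor_prob = 0.01,
                              seed = 88))
  er <- empirical_rates(lt, s = 16, omega = 16)
  hits <- total <- 0
  for (i in c(3, 5, 7, 9)) for (j in 1:15) {
    n <- er$n_risk[i, j]
    if (!is.na(n) && n >= 20) {
      p0 <- vital_true$p[i, j]
      se <- sqrt(p0 * (1 - p0) / n)
      total <- total + 1
      if (abs(er$p[i, j] - p0) <= 3 * se + 1e-12) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("fitted rates stay close to the empirical rates", {
  fw <- fit_weibull(lt_big)
  fc <- fit_coale_trussell(lt_big)
  vf <- evaluate_vital_rates(fw$params, fc$params)
  er <- empirical_rates(lt_big, s = 16, omega = 16)
  hits <- total <- 0
  for (i in c(3, 5, 7, 9)) for (j in 1:15) {
    if (!is.na(er$n_risk[i, j]) && er$n_risk[i, j] >= 20) {
      se_p <- sqrt(max(er$p[i, j] * (1 - er$p[i, j]), 0.25 / er$n_risk[i, j])
                   / er$n_risk[i, j])
      total <- total + 1
      if (abs(vf$p[i, j] - er$p[i, j]) <= 3 * se_p) hits <- hits + 1
    }
    if (!is.na(er$n_alive[i, j]) && er$n_alive[i, j] >= 20) {
      se_f <- sqrt((er$f[i, j] + 0.1) / er$n_alive[i, j])
      total <- total + 1
      if (abs(vf$f[i, j] - er$f[i, j]) <= 3 * se_f) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("fit reports round-trip through the config format", {
  fw <- fit_weibull(lt_big)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fit_report(fw, path)
  expect_equal(read_params(path), fw$params)
  expect_true(file.exists(paste0(path, ".log")))
  log_lines <- readLines(paste0(path, ".log"))
  expect_match(log_lines[1], "log-likelihood")
})
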