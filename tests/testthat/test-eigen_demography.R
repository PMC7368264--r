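test_that("2-state eigenstructure matches the closed form", {
  # A = [[0, 2], [0.5, 0]]: lambda = sqrt(p f) = 1, w = (2/3, 1/3)
  m <- build_block_model(two_age_vital(p = 0.5, f1 = 0, f2 = 2))
  e <- eigen_analysis(m)
  expect_equal(e$lam, 1, tolerance = 1e-14)
  expect_equal(e$w, c(2 / 3, 1 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(e$residual_w, 1e-12)
  expect_lt(e$residual_v, 1e-12)
})

test_that("dense eigen matches the power-iteration oracle at 1e-10", {
  for (seed in c(11, 23)) {
    m <- build_block_model(perturbed_vital(seed))
    e <- eigen_analysis(m)
    w_oracle <- power_iteration_w(m$A, steps = 500)
    expect_lt(max(abs(e$w - w_oracle)), 1e-10)
  }
})

test_that("net reproductive rate matches the Leslie closed form", {
  # [[1, 2], [0.5, 0]]: R0 = f1 + p * f2 = 2
  m <- build_block_model(two_age_vital(p = 0.5, f1 = 1, f2 = 2))
  expect_equal(net_reproductive_rate(m), 2, tolerance = 1e-13)
  m0 <- build_block_model(vital_rates(matrix(c(0.5, 0), 1),
                                      matrix(0, 1, 2)))
  expect_identical(net_reproductive_rate(m0), 0)
})

test_that("R0 equals mean lifetime offspring of a simulated birth cohort", {
  v <- default_vital_rates()
  m <- build_block_model(v)
  r0 <- net_reproductive_rate(m)
  # stationary generation composition: Perron vector of the
  # newborn-to-newborn block of the next-generation matrix
  G <- m$F %*% solve(diag(256) - m$U)
  M <- G[1:16, 1:16]
  eg <- eigen(M)
  u <- abs(Re(eg$vectors[, which.max(Mod(eg$values))]))
  u <- u / sum(u)
  set.seed(404)
  classes <- table(factor(sample(1:16, 20000, TRUE, prob = u),
                          levels = 1:16))
  per_ind <- unlist(lapply(which(classes > 0), function(i) {
    d <- cohort_design(maternal_ages = i, n_per_cohort = classes[i],
                       censor_prob = 0, seed = 5000 + i)
    lt <- simulate_life_table(v, d)
    tapply(lt$offspring, lt$individual_id, sum)
  }))
  se <- stats::sd(per_ind) / sqrt(length(per_ind))
  expect_lt(abs(mean(per_ind) - r0), 3 * se)
})

test_that("structure summaries sum the stable-structure corner", {
  m <- build_block_model(two_age_vital(p = 0.5, f1 = 0, f2 = 2))
  e <- eigen_analysis(m)
  expect_equal(structure_summary(e, 1, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(structure_summary(e, 2, 1), 1)
  expect_identical(structure_summary(e, 0, 1), 0)
  expect_error(structure_summary(e, 3, 1), "out of range")
  e16 <- eigen_analysis(build_block_model(default_vital_rates()))
  expect_equal(structure_summary(e16, 16, 16), 1, tolerance = 1e-12)
  frac <- structure_summary(e16, 3, 5)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("increasing any matrix entry never decreases lambda", {
  v <- perturbed_vital(31)
  m <- build_block_model(v)
  lam0 <- dominant_eigenvalue(m)
  set.seed(31)
  for (rep in 1:5) {
    i <- sample(16, 1); j <- sample(15, 1)
    v2 <- vital_rates(v$p, v$f)
    v2$f[i, j] <- v2$f[i, j] + 0.5
    lam_f <- dominant_eigenvalue(build_block_model(vital_rates(v2$p, v2$f)))
    expect_gte(lam_f, lam0)
  }
})

test_that("projection from any start converges to the stable structure", {
  m <- build_block_model(default_vital_rates())
  e <- eigen_analysis(m)
  set.seed(99)
  n0 <- runif(256)
  traj <- project(m, n0, 500)
  n_end <- traj[, 501] / sum(traj[, 501])
  tv <- 0.5 * sum(abs(n_end - e$w))
  expect_lt(tv, 1e-8)
})

test_that("R0 = 1 exactly when lambda = 1 on stationary scenarios", {
  sc <- scenario_set(default_vital_rates())
  for (nm in c("B", "C")) {
    expect_equal(net_reproductive_rate(sc$models[[nm]]), 1,
                 tolerance = 1e-8)
    expect_equal(dominant_eigenvalue(sc$models[[nm]]), 1,
                 tolerance = 1e-8)
  }
})

test_that("the zero matrix is flagged degenerate", {
  e <- eigen_analysis(matrix(0, 3, 3), s = 1, omega = 3)
  expect_identical(e$lam, 0)
  expect_true(e$degenerate)
  expect_true(all(is.na(e$w)))
  expect_error(structure_summary(e, 1, 1), "undefined")
})
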