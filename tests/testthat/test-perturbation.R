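test_that("2-state selection gradients match the closed form", {
  # A = [[0, f], [p, 0]] with p = 0.5, f = 2: lambda = sqrt(p f),
  # d lambda / d p = f / (2 sqrt(p f)), d lambda / d f = p / (2 sqrt(p f))
  g <- selection_gradients(build_block_model(
    two_age_vital(p = 0.5, f1 = 0, f2 = 2)))
  expect_equal(g$d_lam_d_p[1, 1], 1.0, tolerance = 1e-12)
  expect_equal(g$d_lam_d_f[1, 2], 0.25, tolerance = 1e-12)
  # survival out of the final age class is structurally absent
  expect_identical(g$d_lam_d_p[1, 2], 0)
})

test_that("gradients agree with central finite differences", {
  v <- perturbed_vital(47)
  g <- selection_gradients(build_block_model(v))
  gmax <- max(g$d_lam_d_p, g$d_lam_d_f)
  set.seed(47)
  cases <- data.frame(which = rep(c("p", "f"), each = 20),
                      i = sample(16, 40, TRUE),
                      j = c(sample(15, 20, TRUE), sample(16, 20, TRUE)))
  for (r in seq_len(nrow(cases))) {
    ana <- if (cases$which[r] == "p") g$d_lam_d_p[cases$i[r], cases$j[r]]
    else g$d_lam_d_f[cases$i[r], cases$j[r]]
    fd <- fd_gradient(v, cases$which[r], cases$i[r], cases$j[r])
    # relative error, guarded three orders below the surface peak where
    # the finite-difference oracle runs out of resolution
    expect_lt(abs(ana - fd) / max(abs(fd), 1e-3 * gmax), 1e-5)
  }
})

test_that("scaling the model leaves normalised gradient ratios unchanged", {
  v <- perturbed_vital(53)
  c0 <- 0.5
  v_scaled <- vital_rates(cbind(c0 * v$p[, -16], 0), c0 * v$f)
  m <- build_block_model(v)
  ms <- build_block_model(v_scaled)
  expect_equal(dominant_eigenvalue(ms), c0 * dominant_eigenvalue(m),
               tolerance = 1e-12)
  g <- selection_gradients(m)
  gs <- selection_gradients(ms)
  # normalise each surface by its own peak: ratios are scale-free
  expect_equal(gs$d_lam_d_f / max(gs$d_lam_d_f),
               g$d_lam_d_f / max(g$d_lam_d_f), tolerance = 1e-8)
})

test_that("profile checks report the qualitative gradient geometry", {
  g <- selection_gradients(build_block_model(default_vital_rates()))
  pc <- gradient_profile_checks(g)
  expect_true(all(pc$survival$nonincreasing_in_age))
  expect_true(all(pc$fertility$nonincreasing_in_age))
  expect_true(pc$survival$profile_unimodal)
  expect_true(pc$fertility$profile_unimodal)
  # the peak sits at the youngest reachable maternal age class
  expect_identical(unname(pc$fertility$peak["maternal_age"]), 3L)
  expect_gt(pc$fertility$orders_of_magnitude_drop, 1)
})

test_that("LTRE of a model against itself is identically zero", {
  m <- build_block_model(default_vital_rates())
  l <- ltre(m, m)
  expect_true(all(l$c_p == 0) && all(l$c_f == 0))
  expect_identical(l$delta_lam, 0)
  expect_identical(l$approx_delta_lam, 0)
})

test_that("LTRE recovers a small single-entry perturbation", {
  v <- perturbed_vital(61)
  v2 <- vital_rates(v$p, v$f)
  v2$f[4, 5] <- v2$f[4, 5] + 1e-4
  m_ref <- build_block_model(v)
  m_a <- build_block_model(vital_rates(v2$p, v2$f))
  l <- ltre(m_a, m_ref)
  expect_lt(abs(l$approx_delta_lam - l$delta_lam) / abs(l$delta_lam),
            0.01)
  # contribution identity holds exactly
  expect_identical(sum(l$c_p) + sum(l$c_f), l$approx_delta_lam)
})

test_that("LTRE closes within 10% on removal-variant comparisons", {
  sc <- scenario_set(default_vital_rates())
  for (pair in list(c("A", "A_r"), c("B", "B_r"), c("C", "C_r"))) {
    l <- ltre(sc$models[[pair[1]]], sc$models[[pair[2]]])
    expect_lt(abs(l$approx_delta_lam - l$delta_lam) / abs(l$delta_lam),
              0.1)
    expect_lt(l$delta_lam, 0)  # senescent model is less fit
  }
})

test_that("tidy export lays surfaces out in long format", {
  g <- selection_gradients(build_block_model(tiny_vital()))
  td <- tidy_surface(g)
  expect_identical(nrow(td), 8L)
  expect_setequal(unique(td$quantity), c("d_lam_d_p", "d_lam_d_f"))
  row <- td[td$quantity == "d_lam_d_p" & td$maternal_age == 1 &
              td$age == 1, ]
  expect_equal(row$value, g$d_lam_d_p[1, 1])
})
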