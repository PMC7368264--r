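# Shared fixtures and independent oracles used across the suite.

# 2 x 2-class toy vital rates whose block matrix is known by hand.
tiny_vital <- function() {
  vital_rates(p = rbind(c(0.5, 0), c(0.4, 0)),
              f = rbind(c(2, 1), c(1.5, 0.5)))
}

# Single-stage two-age vital rates giving the plain 2 x 2 matrix
# [[f1, f2], [p, 0]] used for the closed-form micro-cases.
two_age_vital <- function(p, f1, f2) {
  vital_rates(p = matrix(c(p, 0), 1), f = matrix(c(f1, f2), 1))
}

# Seeded multiplicative perturbation of the packaged default vital rates:
# a family of valid 16 x 16 maternal-effect models for property tests.
perturbed_vital <- function(seed) {
  v <- default_vital_rates()
  set.seed(seed)
  pj <- v$p[, -v$omega, drop = FALSE] *
    matrix(runif(v$s * (v$omega - 1), 0.75, 1.0), v$s)
  f <- v$f * matrix(runif(v$s * v$omega, 0.7, 1.3), v$s)
  vital_rates(cbind(pj, 0), f)
}

# Independent power-iteration oracle for the stable structure: repeated
# multiplication from a fixed strictly positive start, sum-normalised.
power_iteration_w <- function(A, steps = 500) {
  x <- rep(1, nrow(A)) / nrow(A)
  for (i in seq_len(steps)) {
    x <- as.numeric(A %*% x)
    x <- x / sum(x)
  }
  x
}

# Central finite-difference sensitivity of lambda to one vital rate,
# applied to the assembled matrix entry where that rate lives (the matrix
# eigenvalue is defined for small negative excursions even where the rate
# itself sits at 0).
fd_gradient <- function(vital, which = c("p", "f"), i, j, h = 1e-5) {
  which <- match.arg(which)
  A <- build_block_model(vital)$A
  s <- vital$s
  pos <- if (which == "p") c(block_index(i, j + 1L, s), block_index(i, j, s))
  else c(min(j, s), block_index(i, j, s))
  bump <- function(d) {
    A2 <- A
    A2[pos[1], pos[2]] <- A2[pos[1], pos[2]] + d
    vals <- eigen(A2, only.values = TRUE)$values
    max(Re(vals[abs(Im(vals)) < 1e-8]))
  }
  (bump(h) - bump(-h)) / (2 * h)
}
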