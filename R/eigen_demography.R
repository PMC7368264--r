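# Asymptotic analysis of a block projection model: growth rate, stable
# structure, reproductive values, net reproductive rate.

# Index of the Perron root among computed eigenvalues: maximum modulus,
# ties broken by the largest real part (an imprimitive nonnegative matrix
# has several eigenvalues on the spectral circle, exactly one of them the
# real nonnegative Perron root).
perron_index <- function(values) {
  mods <- Mod(values)
  cand <- which(mods >= max(mods) * (1 - 1e-12))
  cand[which.max(Re(values[cand]))]
}

#' Dominant eigen-analysis of a projection model
#'
#' Computes the dominant eigenvalue `lam` (the intrinsic growth rate and the
#' fitness measure used throughout), the stable age-by-maternal-age
#' distribution `w` (right eigenvector, nonnegative, summing to 1) and the
#' reproductive values `v` (left eigenvector, nonnegative, scaled so that
#' `sum(v * w) = 1`). Uses a full dense decomposition and selects the
#' eigenvalue of maximum modulus; for the nonnegative matrices arising here
#' that eigenvalue is real (Perron-Frobenius), and a genuinely complex
#' dominant pair is reported as an error rather than silently truncated.
#'
#' @param model a `block_model`, or a plain nonnegative square matrix.
#' @param s,omega class counts, needed only when `model` is a plain matrix
#'   and [structure_summary()] will be used.
#' @return An object of class `eigen_analysis` with fields `lam`, `log_lam`,
#'   `w`, `v`, `s`, `omega`, `residual_w`, `residual_v`, and `degenerate`
#'   (`TRUE` for the zero matrix, where `w` is undefined).
#' @export
eigen_analysis <- function(model, s = NULL, omega = NULL) {
  if (inherits(model, "block_model")) {
    A <- model$A; s <- model$s; omega <- model$omega
  } else {
    A <- as.matrix(model)
    stopifnot(nrow(A) == ncol(A))
  }
  if (any(A < 0)) stop("A must be nonnegative", call. = FALSE)
  n <- nrow(A)
  if (all(A == 0)) {
    return(structure(list(lam = 0, log_lam = -Inf,
                          w = rep(NA_real_, n), v = rep(NA_real_, n),
                          s = s, omega = omega,
                          residual_w = NA_real_, residual_v = NA_real_,
                          degenerate = TRUE),
                     class = "eigen_analysis"))
  }
  # The block models here are reducible whenever a maternal age class is
  # unreachable (e.g. no reproduction at ages 1-2): the dominant
  # eigenvector then has exact zeros and vanishingly small entries that a
  # dense solver resolves only to an absolute noise floor, occasionally
  # with the wrong sign. The LAPACK vector (accurate in direction) is
  # therefore refined by power iteration, which keeps every entry exactly
  # nonnegative, drains unreachable states to exact zeros, and computes
  # tiny entries as sums of nonnegative products, i.e. with *relative*
  # accuracy.
  refine_perron <- function(M, lam, vec) {
    vec <- Re(vec) * sign(sum(Re(vec)))
    mx <- max(abs(vec))
    if (any(vec < -1e-3 * mx))
      stop("dominant eigenvector has mixed signs; matrix is not ",
           "Perron-like at working precision", call. = FALSE)
    x <- pmax(vec, 0)
    x <- x / sum(x)
    for (it in seq_len(2000L)) {
      x1 <- as.numeric(M %*% x)
      sx <- sum(x1)
      if (sx == 0) break  # dominant eigenvalue 0 on this start
      x1 <- x1 / sx
      delta <- max(abs(x1 - x))
      x <- x1
      if (delta < 1e-16) break
    }
    x
  }
  er <- eigen(A)
  k <- perron_index(er$values)
  lam_c <- er$values[k]
  if (abs(Im(lam_c)) > 1e-10 * max(1, Mod(lam_c)))
    stop("dominant eigenvalue is complex (imprimitive matrix); ",
         "refusing to truncate", call. = FALSE)
  lam <- Re(lam_c)
  w <- refine_perron(A, lam, er$vectors[, k])
  el <- eigen(t(A))
  kl <- perron_index(el$values)
  if (abs(Re(el$values[kl]) - lam) > 1e-8 * max(1, lam))
    stop("left/right dominant eigenvalues disagree", call. = FALSE)
  v <- refine_perron(t(A), lam, el$vectors[, kl])
  v <- v / sum(v * w)
  structure(list(lam = lam, log_lam = log(lam), w = w, v = v,
                 s = s, omega = omega,
                 residual_w = max(abs(A %*% w - lam * w)),
                 residual_v = max(abs(crossprod(A, v) - lam * v)),
                 degenerate = FALSE),
            class = "eigen_analysis")
}

#' @export
print.eigen_analysis <- function(x, ...) {
  cat(sprintf("eigen_analysis: lambda = %.6f (log lambda = %.6f)\n",
              x$lam, x$log_lam))
  if (!x$degenerate)
    cat(sprintf("  residuals: |Aw - lw| %.2e, |A'v - lv| %.2e\n",
                x$residual_w, x$residual_v))
  invisible(x)
}

#' Dominant eigenvalue shortcut
#' @inheritParams eigen_analysis
#' @return the dominant eigenvalue (real part, after the same checks as
#'   [eigen_analysis()] but without computing eigenvectors).
#' @export
dominant_eigenvalue <- function(model) {
  A <- if (inherits(model, "block_model")) model$A else as.matrix(model)
  if (all(A == 0)) return(0)
  vals <- eigen(A, only.values = TRUE)$values
  lam_c <- vals[perron_index(vals)]
  if (abs(Im(lam_c)) > 1e-10 * max(1, Mod(lam_c)))
    stop("dominant eigenvalue is complex", call. = FALSE)
  Re(lam_c)
}

#' Net reproductive rate R0
#'
#' Expected lifetime daughters per newborn: the dominant eigenvalue of the
#' next-generation matrix `F (I - U)^{-1}`. The inverse exists because `U`
#' is nilpotent (no individual survives past the last age class), so
#' `(I - U)^{-1} = I + U + U^2 + ...` is the fundamental matrix of expected
#' state occupancy. `R0 = 1` exactly when `lam = 1`.
#'
#' @param model a `block_model`.
#' @return nonnegative scalar `R0`.
#' @export
net_reproductive_rate <- function(model) {
  n <- nrow(model$A)
  N <- solve(diag(n) - model$U)       # fundamental matrix
  G <- model$F %*% N
  if (all(G == 0)) return(0)
  vals <- eigen(G, only.values = TRUE)$values
  r0 <- vals[perron_index(vals)]
  if (abs(Im(r0)) > 1e-8 * max(1, Mod(r0)))
    stop("next-generation matrix has complex dominant eigenvalue",
         call. = FALSE)
  Re(r0)
}

#' Fraction of the stable population in a young age x maternal-age corner
#'
#' Sums the stable-structure entries with age `<= max_age` and maternal age
#' `<= max_maternal_age` (both bounds inclusive; a bound of 0 gives an
#' empty set and a fraction of 0).
#'
#' @param e an `eigen_analysis` carrying `s` and `omega`.
#' @param max_age,max_maternal_age inclusive upper bounds (days).
#' @return a fraction in `[0, 1]`.
#' @export
structure_summary <- function(e, max_age, max_maternal_age) {
  if (is.null(e$s) || is.null(e$omega))
    stop("eigen_analysis lacks s/omega; supply them to eigen_analysis()",
         call. = FALSE)
  if (e$degenerate) stop("stable structure undefined for the zero matrix",
                         call. = FALSE)
  if (max_age < 0 || max_age > e$omega ||
      max_maternal_age < 0 || max_maternal_age > e$s)
    stop("bounds out of range", call. = FALSE)
  if (max_age == 0 || max_maternal_age == 0) return(0)
  idx <- as.vector(outer(seq_len(max_maternal_age), seq_len(max_age),
                         block_index, s = e$s))
  sum(e$w[idx])
}
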