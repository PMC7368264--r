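# Assembly of the age-by-maternal-age block projection matrices.
#
# The population vector stacks maternal ages within age classes:
# state (i, j) = (maternal age i, age j) sits at flat position (j-1)*s + i.
# U holds survival transitions (i, j) -> (i, j+1); F places the daughters of
# an age-j mother into age class 1 with maternal age class j.

#' Flat index of state (maternal age, age)
#'
#' Ages and maternal ages are 1-based integer days; maternal ages are
#' grouped within age classes, so state `(i, j)` maps to `(j - 1) * s + i`.
#'
#' @param maternal_age,age integer class indices (vectorised).
#' @param s number of maternal age classes.
#' @export
block_index <- function(maternal_age, age, s) (age - 1L) * s + maternal_age

#' Assemble the block projection model from vital rates
#'
#' Builds the survival matrix `U` (nonzero only on the block subdiagonal:
#' entry `(idx(i, j+1), idx(i, j)) = p[i, j]`, `j < omega`), the fertility
#' matrix `F` (nonzero only in block row 1: entry
#' `(min(j, s), idx(i, j)) = f[i, j]`, i.e. offspring of an age-`j` mother
#' enter age class 1 with maternal age class `j`; when fewer maternal age
#' classes than age classes are modelled, mothers older than `s` fall in
#' the last maternal age class, and `s = 1` recovers an ordinary Leslie
#' matrix), and their sum `A = U + F`, the one-day projection matrix.
#'
#' @param vital a [vital_rates()] object.
#' @return An object of class `block_model` with fields `s`, `omega`,
#'   `U`, `F`, `A` (dense `s*omega` square matrices) and `vital`.
#' @export
build_block_model <- function(vital) {
  if (!inherits(vital, "vital_rates"))
    stop("vital must be a vital_rates object", call. = FALSE)
  s <- vital$s; omega <- vital$omega; n <- s * omega
  Um <- matrix(0, n, n)
  Fm <- matrix(0, n, n)
  for (j in seq_len(omega)) {
    for (i in seq_len(s)) {
      if (j < omega) Um[block_index(i, j + 1L, s), block_index(i, j, s)] <-
          vital$p[i, j]
      Fm[min(j, s), block_index(i, j, s)] <- vital$f[i, j]
    }
  }
  labels <- as.vector(outer(1:s, 1:omega,
                            function(i, j) sprintf("m%02d.a%02d", i, j)))
  dimnames(Um) <- dimnames(Fm) <- list(labels, labels)
  structure(list(s = s, omega = omega, U = Um, F = Fm, A = Um + Fm,
                 vital = vital),
            class = "block_model")
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf(
    "block_model: %d x %d (s = %d maternal ages x omega = %d ages)\n",
    nrow(x$A), ncol(x$A), x$s, x$omega))
  cat(sprintf("  nonzeros: U %d, F %d\n", sum(x$U != 0), sum(x$F != 0)))
  invisible(x)
}

#' Recover the vital-rate table from a block model
#'
#' Inverse of [build_block_model()]: reads `p[i, j]` off the block
#' subdiagonal of `U` and `f[i, j]` off block row 1 of `F`.
#'
#' @param model a `block_model`.
#' @return a [vital_rates()] object.
#' @export
vital_from_model <- function(model) {
  s <- model$s; omega <- model$omega
  p <- matrix(0, s, omega)
  f <- matrix(0, s, omega)
  for (j in seq_len(omega)) {
    for (i in seq_len(s)) {
      if (j < omega) p[i, j] <- model$U[block_index(i, j + 1L, s),
                                        block_index(i, j, s)]
      f[i, j] <- model$F[min(j, s), block_index(i, j, s)]
    }
  }
  vital_rates(p, f)
}

#' Project a population vector forward in daily steps
#'
#' Iterates `n(t + 1) = A n(t)`.
#'
#' @param model a `block_model`.
#' @param n0 nonnegative start vector of length `s * omega`.
#' @param t number of daily steps.
#' @return a `(s * omega) x (t + 1)` matrix whose columns are
#'   `n(0), ..., n(t)`.
#' @export
project <- function(model, n0, t) {
  n0 <- as.numeric(n0)
  if (length(n0) != model$s * model$omega)
    stop("n0 must have length s * omega", call. = FALSE)
  if (any(n0 < 0) || any(!is.finite(n0)))
    stop("n0 must be nonnegative and finite", call. = FALSE)
  stopifnot(t >= 0)
  out <- matrix(0, length(n0), t + 1L)
  out[, 1L] <- n0
  for (k in seq_len(t)) out[, k + 1L] <- model$A %*% out[, k]
  rownames(out) <- rownames(model$A)
  out
}

# Structural validation used by the matrix readers: nonzeros are allowed
# only where the block layout puts a vital rate.
validate_block_structure <- function(Um, Fm, s, omega) {
  n <- s * omega
  stopifnot(all(dim(Um) == n), all(dim(Fm) == n))
  allowed_U <- matrix(FALSE, n, n)
  allowed_F <- matrix(FALSE, n, n)
  for (j in seq_len(omega)) {
    for (i in seq_len(s)) {
      if (j < omega)
        allowed_U[block_index(i, j + 1L, s), block_index(i, j, s)] <- TRUE
      allowed_F[min(j, s), block_index(i, j, s)] <- TRUE
    }
  }
  bad_U <- which(Um != 0 & !allowed_U, arr.ind = TRUE)
  bad_F <- which(Fm != 0 & !allowed_F, arr.ind = TRUE)
  if (nrow(bad_U) + nrow(bad_F) > 0) {
    fmt <- function(m, w) if (nrow(w) == 0) "" else
      paste0(m, ": ", paste(sprintf("(%d,%d)", w[, 1], w[, 2]),
                            collapse = " "))
    stop("structural violation: nonzeros outside permitted block positions. ",
         fmt("U", bad_U), " ", fmt("F", bad_F), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a block model directly from U and F matrices
#'
#' Validates the block structure (rejecting nonzeros outside the permitted
#' positions) and recovers the vital rates.
#'
#' @param U,F dense square matrices of dimension `s * omega`.
#' @param s,omega numbers of maternal age and age classes.
#' @return a `block_model`.
#' @export
block_model_from_matrices <- function(U, F, s, omega) {
  U <- as.matrix(U); F <- as.matrix(F)
  validate_block_structure(U, F, s, omega)
  skeleton <- structure(list(s = s, omega = omega, U = U, F = F),
                        class = "block_model")
  build_block_model(vital_from_model(skeleton))
}
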