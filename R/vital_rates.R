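# Parametric vital rates: Weibull survivorship and a Coale-Trussell style
# fertility model, both with maternal-age-dependent parameters, evaluated
# into an s x omega table of daily rates.

#' Weibull survivorship parameters with log-linear maternal-age dependence
#'
#' The survivorship of an individual whose mother was `i` days old at its
#' birth is modelled as \eqn{S_i(t) = \exp(-(t/b_i)^{k_i})} with scale
#' \eqn{b_i = \exp(a_0 + a_1 i)} and shape \eqn{k_i = \exp(c_0 + c_1 i)}.
#' The exponential link keeps both parameters positive for every maternal
#' age; a negative scale slope shortens life with maternal age, and a
#' negative shape slope flattens the hazard, which is what lets survival of
#' very old individuals *increase* with maternal age even while young-age
#' survival decreases.
#'
#' @param log_scale_intercept,log_scale_slope coefficients of
#'   \eqn{\log b_i = a_0 + a_1 i}.
#' @param log_shape_intercept,log_shape_slope coefficients of
#'   \eqn{\log k_i = c_0 + c_1 i}.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(log_scale_intercept, log_scale_slope = 0,
                           log_shape_intercept = 0, log_shape_slope = 0) {
  vals <- c(log_scale_intercept, log_scale_slope,
            log_shape_intercept, log_shape_slope)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("Weibull coefficients must be four finite numbers", call. = FALSE)
  structure(list(log_scale_intercept = unname(log_scale_intercept),
                 log_scale_slope = unname(log_scale_slope),
                 log_shape_intercept = unname(log_shape_intercept),
                 log_shape_slope = unname(log_shape_slope)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat("Weibull survivorship, maternal-age-dependent:\n")
  cat(sprintf("  log scale: %.4f %+.4f * maternal_age\n",
              x$log_scale_intercept, x$log_scale_slope))
  cat(sprintf("  log shape: %.4f %+.4f * maternal_age\n",
              x$log_shape_intercept, x$log_shape_slope))
  invisible(x)
}

#' Weibull scale and shape for a maternal age class
#' @param params a [weibull_params()] object.
#' @param maternal_age integer maternal age class (days).
#' @return positive scale (days) or shape.
#' @export
weibull_scale <- function(params, maternal_age)
  exp(params$log_scale_intercept + params$log_scale_slope * maternal_age)

#' @rdname weibull_scale
#' @export
weibull_shape <- function(params, maternal_age)
  exp(params$log_shape_intercept + params$log_shape_slope * maternal_age)

#' Weibull survivorship S_i(t)
#'
#' Probability that an individual of maternal age class `maternal_age`
#' survives from birth to age `age` (days). Vectorised over `age`.
#'
#' @inheritParams weibull_scale
#' @param age nonnegative age in days (may be a vector).
#' @return survival probabilities in `[0, 1]`; `S(0) = 1` always.
#' @export
weibull_survivorship <- function(params, maternal_age, age) {
  if (!inherits(params, "weibull_params"))
    params <- do.call(weibull_params, as.list(params))
  stopifnot(length(maternal_age) == 1L, maternal_age >= 1, all(age >= 0))
  b <- weibull_scale(params, maternal_age)
  k <- weibull_shape(params, maternal_age)
  if (!is.finite(b) || !is.finite(k) || b <= 0 || k <= 0)
    stop("invalid Weibull parameters (non-finite or non-positive scale/shape)",
         call. = FALSE)
  exp(-(age / b)^k)
}

#' Daily survival probabilities from a Weibull survivorship
#'
#' Discretises the continuous survivorship into the cohort life-table
#' convention used by the projection model: `p[i, j] = S_i(j) / S_i(j - 1)`,
#' the probability of surviving the day-`j` interval given survival to its
#' start. The final age class is absorbing: `p[i, omega] = 0`.
#'
#' @inheritParams weibull_survivorship
#' @param s number of maternal age classes.
#' @param omega number of age classes.
#' @return an `s x omega` matrix of probabilities in `[0, 1]`.
#' @export
survival_probabilities <- function(params, s, omega) {
  stopifnot(s >= 1, omega >= 1)
  p <- matrix(0, s, omega,
              dimnames = list(maternal_age = 1:s, age = 1:omega))
  for (i in 1:s) {
    S <- weibull_survivorship(params, i, 0:omega)
    if (omega > 1) {
      pi <- S[2:omega] / S[1:(omega - 1)]
      pi[!is.finite(pi)] <- 0  # dead stratum: S already underflowed to 0
      p[i, 1:(omega - 1)] <- pmin(pmax(pi, 0), 1)
    }
  }
  p
}

#' Coale-Trussell style fertility parameters with maternal-age control
#'
#' Fertility is the product of a "natural fertility" schedule depending only
#' on age and a controlled reduction acting after a threshold age:
#' \deqn{f_{ij} = n(j) \exp(m_i \nu(j)),}
#' where \eqn{n(j) = \exp(\beta_0 + \beta_1 j + \beta_2 j^2)} for ages at or
#' above `min_reproductive_age` (0 below it), the deviation schedule is a
#' ramp \eqn{\nu(j) = -\texttt{deviation\_slope}\,(j - j^*)} for
#' \eqn{j > j^*} and 0 otherwise, and the control level
#' \eqn{m_i = c_0 + c_1 i} grows with maternal age. With \eqn{m_i \ge 0}
#' and \eqn{\nu \le 0} the factor only ever reduces natural fertility, so
#' schedules for all maternal ages coincide up to the threshold age and
#' diverge beyond it, declining earlier and faster for older maternal ages.
#'
#' @param natural_fertility_coeffs numeric length-3 vector
#'   \eqn{(\beta_0, \beta_1, \beta_2)} of the log-quadratic natural
#'   fertility curve.
#' @param control_threshold_age age \eqn{j^*} (days) after which the control
#'   factor acts.
#' @param deviation_slope nonnegative rate at which \eqn{\nu} declines past
#'   the threshold. Held fixed (not estimated) by [fit_coale_trussell()]
#'   because only the product \eqn{m_i \nu(j)} is identifiable.
#' @param control_intercept,control_slope coefficients of
#'   \eqn{m_i = c_0 + c_1 i}.
#' @param min_reproductive_age age (days) below which fertility is exactly 0.
#' @return An object of class `coale_trussell_params`.
#' @export
coale_trussell_params <- function(natural_fertility_coeffs,
                                  control_threshold_age = 4,
                                  deviation_slope = 1,
                                  control_intercept = 0,
                                  control_slope = 0,
                                  min_reproductive_age = 3) {
  nf <- as.numeric(natural_fertility_coeffs)
  if (length(nf) != 3L || !all(is.finite(nf)))
    stop("natural_fertility_coeffs must be 3 finite numbers", call. = FALSE)
  if (!all(is.finite(c(control_threshold_age, deviation_slope,
                       control_intercept, control_slope,
                       min_reproductive_age))))
    stop("fertility parameters must be finite", call. = FALSE)
  if (deviation_slope < 0)
    stop("deviation_slope must be nonnegative (nu <= 0 convention)",
         call. = FALSE)
  structure(list(natural_fertility_coeffs = unname(nf),
                 control_threshold_age = unname(control_threshold_age),
                 deviation_slope = unname(deviation_slope),
                 control_intercept = unname(control_intercept),
                 control_slope = unname(control_slope),
                 min_reproductive_age = unname(min_reproductive_age)),
            class = "coale_trussell_params")
}

#' @export
print.coale_trussell_params <- function(x, ...) {
  b <- x$natural_fertility_coeffs
  cat("Coale-Trussell fertility, maternal-age control:\n")
  cat(sprintf("  log n(j) = %.4f %+.4f j %+.4f j^2  (0 below age %g)\n",
              b[1], b[2], b[3], x$min_reproductive_age))
  cat(sprintf("  nu(j) = -%g * (j - %g)+ ;  m_i = %.4f %+.4f i\n",
              x$deviation_slope, x$control_threshold_age,
              x$control_intercept, x$control_slope))
  invisible(x)
}

#' Natural (age-only) fertility curve n(j)
#' @param params a [coale_trussell_params()] object.
#' @param age age in days (vectorised).
#' @export
natural_fertility <- function(params, age) {
  b <- params$natural_fertility_coeffs
  out <- exp(b[1] + b[2] * age + b[3] * age^2)
  out[age < params$min_reproductive_age] <- 0
  out
}

#' Deviation schedule nu(j) (nonpositive ramp past the threshold age)
#' @inheritParams natural_fertility
#' @export
deviation_schedule <- function(params, age)
  -params$deviation_slope * pmax(age - params$control_threshold_age, 0)

#' Maternal-age control level m_i
#' @inheritParams natural_fertility
#' @param maternal_age maternal age class (vectorised).
#' @export
control_level <- function(params, maternal_age)
  params$control_intercept + params$control_slope * maternal_age

#' Daily fertility schedule f[i, j]
#'
#' @inheritParams natural_fertility
#' @param s number of maternal age classes.
#' @param omega number of age classes.
#' @return an `s x omega` matrix of expected daughters per day.
#' @export
fertility_schedule <- function(params, s, omega) {
  stopifnot(s >= 1, omega >= 1)
  m <- control_level(params, 1:s)
  if (any(m < 0))
    warning("control level m_i < 0 for some maternal ages; ",
            "the reduction factor exceeds 1 there")
  nj <- natural_fertility(params, 1:omega)
  nu <- deviation_schedule(params, 1:omega)
  f <- outer(m, nu, function(mi, nuj) exp(mi * nuj)) *
    matrix(nj, s, omega, byrow = TRUE)
  dimnames(f) <- list(maternal_age = 1:s, age = 1:omega)
  f
}

#' Vital-rate table over age and maternal age
#'
#' Container for the daily survival probabilities `p[i, j]` and fertilities
#' `f[i, j]`, maternal age `i` in rows, age `j` in columns, ages being
#' integer days `1..omega`.
#'
#' @param p `s x omega` matrix of survival probabilities; column `omega`
#'   must be 0 (no age class beyond `omega`).
#' @param f `s x omega` matrix of nonnegative daily fertilities.
#' @return An object of class `vital_rates` with fields `s`, `omega`, `p`, `f`.
#' @export
vital_rates <- function(p, f) {
  p <- as.matrix(p); f <- as.matrix(f)
  if (!identical(dim(p), dim(f)))
    stop("p and f must have identical dimensions", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p entries must be probabilities in [0, 1]", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("f entries must be nonnegative", call. = FALSE)
  s <- nrow(p); omega <- ncol(p)
  if (any(p[, omega] != 0))
    stop("p[, omega] must be 0: there is no age class beyond omega",
         call. = FALSE)
  dimnames(p) <- dimnames(f) <- list(maternal_age = 1:s, age = 1:omega)
  structure(list(s = s, omega = omega, p = p, f = f), class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("vital_rates: %d maternal age classes x %d age classes\n",
              x$s, x$omega))
  cat(sprintf("  p in [%.3f, %.3f] (col omega = 0), f in [%.3f, %.3f]\n",
              min(x$p[, -x$omega]), max(x$p), min(x$f), max(x$f)))
  invisible(x)
}

#' Evaluate parametric models into a vital-rate table
#'
#' @param weibull a [weibull_params()] object.
#' @param fertility a [coale_trussell_params()] object.
#' @param s,omega numbers of maternal age and age classes (days).
#' @return a [vital_rates()] object.
#' @export
evaluate_vital_rates <- function(weibull, fertility, s = 16, omega = 16) {
  vital_rates(survival_probabilities(weibull, s, omega),
              fertility_schedule(fertility, s, omega))
}

#' Read/write parameter sets as flat YAML key-value files
#'
#' Serialises [weibull_params()] or [coale_trussell_params()] objects with
#' keys exactly matching the field names, so that a fit written by one run
#' can be re-read and re-evaluated by another.
#'
#' @param params a parameter object.
#' @param path file path.
#' @return `read_params()` returns the parameter object; the class is
#'   inferred from the keys present.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 17L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  if ("log_scale_intercept" %in% names(x)) do.call(weibull_params, x)
  else if ("natural_fertility_coeffs" %in% names(x))
    do.call(coale_trussell_params, x)
  else stop("unrecognised parameter file: ", path, call. = FALSE)
}
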