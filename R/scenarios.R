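# Scenario construction: stationary variants of a fitted model and
# counterfactual removal of maternal effect senescence.

#' Fertility-normalised stationary model
#'
#' Divides every fertility entry by the net reproductive rate R0 (for the
#' default `target_lambda = 1`), leaving survival untouched. The rescaled
#' model has R0 = 1 and therefore an intrinsic growth rate of exactly 1: a
#' stationary population whose survival schedule and shape and timing of
#' reproduction are unchanged, emulating resource limitation in nature.
#' For other targets the divisor is found by root search.
#'
#' @param model a `block_model` with `R0 > 0`.
#' @param target_lambda desired growth rate (default 1, stationarity).
#' @return list with the rescaled `model` and the `R0` (or general divisor)
#'   used.
#' @export
normalize_fertility <- function(model, target_lambda = 1) {
  r0 <- net_reproductive_rate(model)
  if (r0 <= 0) stop("R0 is zero; cannot normalise fertility", call. = FALSE)
  divisor <- if (target_lambda == 1) r0 else {
    f <- function(d) dominant_eigenvalue(model$U + model$F / d) - target_lambda
    stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-14)$root
  }
  vital <- model$vital
  out <- build_block_model(vital_rates(vital$p, vital$f / divisor))
  list(model = out, R0 = r0, divisor = divisor)
}

#' Survival-multiplied stationary model
#'
#' Imposes extra mortality by multiplying every survival probability by a
#' constant `c` chosen so that the growth rate of `c U + F` equals
#' `target_lambda` (default 1). Multiplying survival by `c` adds the
#' constant `-log(c)` to each day's integrated hazard, so this is the
#' "additive mortality hazard" construction. `c` is found by bracketed
#' root search on the strictly increasing map `c -> lam(c U + F)` and
#' polished until `|lam - target| <= tol`.
#'
#' @param model a `block_model` with `lam(F) < target_lambda < lam(A)`.
#' @param target_lambda desired growth rate (default 1).
#' @param tol tolerance on `lam - target_lambda`.
#' @return list with the modified `model` and the `multiplier` `c`.
#' @export
impose_hazard <- function(model, target_lambda = 1, tol = 1e-10) {
  lamA <- dominant_eigenvalue(model)
  lamF <- dominant_eigenvalue(model$F)
  if (lamA < target_lambda)
    stop("already subcritical: lam(A) < target", call. = FALSE)
  if (lamF >= target_lambda)
    stop("no feasible multiplier: lam(F) >= target", call. = FALSE)
  f <- function(c) dominant_eigenvalue(c * model$U + model$F) - target_lambda
  r <- stats::uniroot(f, lower = 1e-6, upper = 1,
                      tol = .Machine$double.eps^0.9, extendInt = "no")
  cc <- r$root
  # secant polish: uniroot's c-tolerance does not directly bound lam - target
  fc <- f(cc)
  c2 <- cc * (1 + 1e-9); f2 <- f(c2)
  it <- 0
  while (abs(fc) > tol && it < 50) {
    step <- fc * (c2 - cc) / (f2 - fc)
    c2 <- cc; f2 <- fc
    cc <- min(max(cc - step, 1e-12), 1)
    fc <- f(cc)
    it <- it + 1
  }
  vital <- model$vital
  out <- build_block_model(vital_rates(cbind(cc * vital$p[, -model$omega,
                                                          drop = FALSE], 0),
                                       vital$f))
  list(model = out, multiplier = cc)
}

#' Remove maternal effect senescence from a vital-rate table
#'
#' Counterfactual in which every individual, regardless of maternal age,
#' receives the survival and fertility schedules of the reference maternal
#' age class (default 3 d, the class with the highest fertility and
#' survival in the fitted rotifer model).
#'
#' @param vital a [vital_rates()] object.
#' @param reference_maternal_age row whose schedules are copied to all
#'   maternal age classes.
#' @return a [vital_rates()] object with identical rows.
#' @export
remove_maternal_effects <- function(vital, reference_maternal_age = 3) {
  i <- reference_maternal_age
  if (i < 1 || i > vital$s)
    stop("reference maternal age out of range 1..s", call. = FALSE)
  p <- matrix(vital$p[i, ], vital$s, vital$omega, byrow = TRUE)
  f <- matrix(vital$f[i, ], vital$s, vital$omega, byrow = TRUE)
  vital_rates(p, f)
}

#' Construct the six scenario life histories
#'
#' From a fitted vital-rate table, builds: `A` (the fitted high-growth
#' model), `B` (fertility divided by R0: stationary, low fertility), `C`
#' (survival multiplied by a root-found constant: stationary, low
#' survival), and removal counterparts `A_r`, `B_r`, `C_r` in which all
#' maternal age classes receive the reference class's schedules of the
#' corresponding matrix.
#'
#' @param vital a [vital_rates()] object.
#' @param reference_maternal_age reference class for the removal variants.
#' @param target_lambda growth rate imposed on `B` and `C`.
#' @return An object of class `scenario_set`: `models` (named list of six
#'   `block_model`s), `lambdas`, and `provenance` (R0 used for B, hazard
#'   multiplier used for C, reference maternal age).
#' @export
scenario_set <- function(vital, reference_maternal_age = 3,
                         target_lambda = 1) {
  A <- build_block_model(vital)
  B <- normalize_fertility(A, target_lambda)
  C <- impose_hazard(A, target_lambda)
  rm_build <- function(m)
    build_block_model(remove_maternal_effects(m$vital,
                                              reference_maternal_age))
  models <- list(A = A, B = B$model, C = C$model,
                 A_r = rm_build(A), B_r = rm_build(B$model),
                 C_r = rm_build(C$model))
  structure(list(models = models,
                 lambdas = vapply(models, dominant_eigenvalue, numeric(1)),
                 provenance = list(R0 = B$R0, multiplier = C$multiplier,
                                   reference_maternal_age =
                                     reference_maternal_age,
                                   target_lambda = target_lambda)),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("scenario_set (six life histories):\n")
  l <- x$lambdas
  cat(sprintf(
    "  lambda(A) = %.4f  lambda(A_r) = %.4f\n  lambda(B) = %.4f  lambda(B_r) = %.4f\n  lambda(C) = %.4f  lambda(C_r) = %.4f\n",
    l["A"], l["A_r"], l["B"], l["B_r"], l["C"], l["C_r"]))
  cat(sprintf("  R0(A) = %.4f, hazard multiplier = %.4f, reference maternal age = %d\n",
              x$provenance$R0, x$provenance$multiplier,
              x$provenance$reference_maternal_age))
  invisible(x)
}
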