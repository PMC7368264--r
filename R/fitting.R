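# Maximum-likelihood fitting of the parametric vital-rate models to
# individual daily life tables with right censoring.
#
# Both fitters use multi-start local optimisation (Nelder-Mead followed by
# BFGS polish) from moment-based initial guesses perturbed by a fixed,
# deterministic offset design, so fits are reproducible without touching
# the global RNG.

# Per-individual summary: maternal age, last observed day, and how the
# series ended (death / lost during the day / alive at the end of follow-up).
summarize_individuals <- function(data) {
  stopifnot(all(c("individual_id", "maternal_age", "day", "alive",
                  "censored", "offspring") %in% names(data)))
  sp <- split(data, data$individual_id)
  do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$day), ]
    if (!all(d$day == seq_len(nrow(d))))
      stop("non-consecutive days for individual ", d$individual_id[1],
           call. = FALSE)
    last <- d[nrow(d), ]
    status <- if (last$alive == 0) "death"
    else if (last$censored == 1) "lost"
    else "end"
    data.frame(individual_id = last$individual_id,
               maternal_age = last$maternal_age,
               last_day = last$day, status = status,
               stringsAsFactors = FALSE)
  }))
}

# Interval-censored Weibull log-likelihood of the per-individual summary.
# Death during day t contributes log(S(t-1) - S(t)); an individual lost
# during day t was last known alive at the previous check and contributes
# log S(t-1); one alive on the final observation day t carries no survival
# information about that day (the last check has no survival draw) and is
# right-censored at the previous check, contributing log S(t-1).
weibull_loglik <- function(theta, summ) {
  b <- exp(theta[1] + theta[2] * summ$maternal_age)
  k <- exp(theta[3] + theta[4] * summ$maternal_age)
  if (any(!is.finite(b)) || any(!is.finite(k))) return(-Inf)
  S <- function(t) exp(-(t / b)^k)
  t <- summ$last_day
  ll <- numeric(nrow(summ))
  death <- summ$status == "death"
  lost <- summ$status == "lost"
  endf <- summ$status == "end"
  if (any(death)) {
    d <- (S(t - 1) - S(t))[death]
    ll[death] <- log(pmax(d, 1e-300))
  }
  if (any(lost)) ll[lost] <- -(((t - 1) / b)^k)[lost]
  if (any(endf)) ll[endf] <- -(((t - 1) / b)^k)[endf]
  sum(ll)
}

# Deterministic multi-start optimisation: Nelder-Mead then BFGS from each
# start, best result kept. `offsets` has one start per row.
multi_start_optim <- function(init, negll, offsets, reltol = 1e-10) {
  best <- NULL
  for (r in seq_len(nrow(offsets))) {
    start <- init + offsets[r, seq_along(init)]
    o1 <- try(stats::optim(start, negll, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = reltol)),
              silent = TRUE)
    if (inherits(o1, "try-error")) next
    o2 <- try(stats::optim(o1$par, negll, method = "BFGS",
                           control = list(maxit = 500, reltol = reltol)),
              silent = TRUE)
    o <- if (inherits(o2, "try-error") || o2$value > o1$value) o1 else o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimizer failed from every start", call. = FALSE)
  best
}

start_offsets <- function(npar) {
  base <- rbind(0,
                c(0.1, 0.02, -0.1, -0.02),
                c(-0.1, -0.02, 0.1, 0.02),
                c(0.2, -0.04, 0.2, 0.04),
                c(-0.2, 0.04, -0.2, -0.04))
  base[, seq_len(npar), drop = FALSE]
}

#' Fit the maternal-age-dependent Weibull survival model
#'
#' Maximum-likelihood fit of [weibull_params()] to a daily life table.
#' Deaths are interval-censored to the day (the 24-h observation cycle
#' locates a death only between two checks); individuals lost during a day
#' are right-censored at the previous check, as are individuals still
#' alive on the final observation day. Optimisation is
#' multi-start (5 deterministic starts around a moment-based initial
#' guess), and the reported optimum is guaranteed to be at least as good
#' as the initial guess.
#'
#' @param data a life-table data.frame (see [simulate_life_table()] /
#'   [read_life_table()]).
#' @param fix_slopes if `TRUE`, the maternal-age slopes are fixed at 0
#'   (required when the data hold a single maternal age class).
#' @return An object of class `weibull_fit`: `params`
#'   ([weibull_params()]), `loglik`, `loglik_init`, `se` (delta-method
#'   standard errors from the numerically inverted Hessian), `convergence`,
#'   `n_individuals`, `n_deaths`.
#' @export
fit_weibull <- function(data, fix_slopes = FALSE) {
  if (is.null(data) || nrow(data) == 0)
    stop("non-identifiable: empty life table", call. = FALSE)
  summ <- summarize_individuals(data)
  info <- summ$status == "death" | summ$last_day > 1
  if (sum(summ$status == "death") < 1 || !any(info))
    stop("non-identifiable: no observed deaths ",
         "(all individuals censored on entry?)", call. = FALSE)
  classes <- sort(unique(summ$maternal_age))
  if (length(classes) < 2 && !fix_slopes)
    stop("need >= 2 maternal age classes to estimate slopes; ",
         "use fix_slopes = TRUE for a single cohort", call. = FALSE)

  # moment-based initial guess: per-cohort mean observed lifetime gives the
  # scale line; the coefficient of variation gives a rough Weibull shape
  # via k ~ cv^-1.086 (standard approximation).
  mt <- tapply(summ$last_day, summ$maternal_age, mean)
  st <- tapply(summ$last_day, summ$maternal_age, stats::sd)
  cv <- pmin(pmax(st / mt, 0.05, na.rm = TRUE), 2)
  kk <- pmin(pmax(cv^(-1.086), 0.2), 10)
  xi <- as.numeric(names(mt))
  if (length(xi) >= 2 && !fix_slopes) {
    cs <- stats::coef(stats::lm(log(as.numeric(mt)) ~ xi))
    ck <- stats::coef(stats::lm(log(as.numeric(kk)) ~ xi))
    init <- c(cs[1], cs[2], ck[1], ck[2])
  } else {
    init <- c(log(mean(summ$last_day)), 0, log(mean(kk)), 0)
  }
  init[!is.finite(init)] <- 0

  expand <- function(theta) if (fix_slopes)
    c(theta[1], 0, theta[2], 0) else theta
  negll <- function(theta) -weibull_loglik(expand(theta), summ)
  init_red <- if (fix_slopes) init[c(1, 3)] else init
  best <- multi_start_optim(init_red, negll, start_offsets(length(init_red)))
  if (best$value > -weibull_loglik(expand(init_red), summ) + 1e-6)
    stop("optimizer non-convergence: optimum below initial guess; ",
         "final value ", -best$value, call. = FALSE)
  H <- try(stats::optimHess(best$par, negll), silent = TRUE)
  se <- rep(NA_real_, length(best$par))
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(diag(Vi) > 0))
      se <- sqrt(diag(Vi))
  }
  theta <- expand(best$par)
  se_full <- if (fix_slopes) c(se[1], NA, se[2], NA) else se
  names(se_full) <- c("log_scale_intercept", "log_scale_slope",
                      "log_shape_intercept", "log_shape_slope")
  structure(list(params = weibull_params(theta[1], theta[2], theta[3],
                                         theta[4]),
                 loglik = -best$value,
                 loglik_init = weibull_loglik(expand(init_red), summ),
                 se = se_full,
                 convergence = best$convergence,
                 n_individuals = nrow(summ),
                 n_deaths = sum(summ$status == "death")),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("weibull_fit: log-likelihood %.3f (%d individuals, %d deaths)\n",
              x$loglik, x$n_individuals, x$n_deaths))
  print(x$params)
  invisible(x)
}

# Poisson log-likelihood of daily offspring counts under the
# Coale-Trussell mean schedule; theta = (b0, b1, b2, c0, c1) with the
# deviation ramp and threshold held fixed. Works on the sufficient
# statistics per (maternal age, day) cell: total count and number of
# observed days (the per-row log(y!) constant is dropped).
ct_loglik <- function(theta, cells) {
  logmu <- theta[1] + theta[2] * cells$day + theta[3] * cells$day^2 -
    (theta[4] + theta[5] * cells$maternal_age) * cells$ramp
  if (any(!is.finite(logmu))) return(-Inf)
  sum(cells$total * logmu - cells$n * exp(logmu))
}

#' Fit the maternal-age-controlled Coale-Trussell fertility model
#'
#' Daily offspring counts on alive, uncensored days are modelled as
#' Poisson with mean `f[i, j] = n(j) exp(m_i nu(j))`. Days before the
#' minimum reproductive age are structurally zero and excluded from the
#' likelihood. Because only the product `m_i nu(j)` is identifiable, the
#' deviation ramp (`deviation_slope`, `control_threshold_age`) is held
#' fixed, as the deviation schedule is in the classical formulation of the
#' model, and the natural-fertility coefficients and control level
#' `m_i = c0 + c1 i` are estimated.
#'
#' @param data a life-table data.frame.
#' @param control_threshold_age,deviation_slope,min_reproductive_age fixed
#'   schedule constants (defaults matching [default_truth()]).
#' @return An object of class `coale_trussell_fit`: `params`
#'   ([coale_trussell_params()]), `loglik`, `loglik_init`, `se` (for the
#'   five estimated coefficients), `convergence`, `n_days`.
#' @export
fit_coale_trussell <- function(data, control_threshold_age = 4,
                               deviation_slope = 1,
                               min_reproductive_age = 3) {
  if (is.null(data) || nrow(data) == 0)
    stop("degenerate fit: empty life table", call. = FALSE)
  obs <- data[data$alive == 1 & data$censored == 0 &
                data$day >= min_reproductive_age, ]
  if (nrow(obs) == 0 || all(obs$offspring == 0))
    stop("degenerate fit: no positive offspring counts", call. = FALSE)
  if (any(data$offspring[data$day < min_reproductive_age] > 0))
    warning("positive counts below min_reproductive_age are excluded ",
            "from the likelihood")

  # sufficient statistics per (maternal age, day) cell
  agg <- stats::aggregate(offspring ~ maternal_age + day, obs,
                          function(x) c(sum(x), length(x)))
  cells <- data.frame(maternal_age = agg$maternal_age, day = agg$day,
                      total = agg$offspring[, 1], n = agg$offspring[, 2])
  cells$ramp <- deviation_slope *
    pmax(cells$day - control_threshold_age, 0)

  # moment init: quadratic in age on log of daily mean counts, no control
  dm <- stats::aggregate(offspring ~ day, obs, mean)
  cf <- stats::coef(stats::lm(log(offspring + 0.05) ~ day + I(day^2),
                              dm))
  init <- c(cf[1], cf[2], cf[3], 0, 0.01)
  init[!is.finite(init)] <- 0
  negll <- function(theta) -ct_loglik(theta, cells)
  offsets <- rbind(0,
                   c(0.1, -0.02, 0.002, 0.05, 0.01),
                   c(-0.1, 0.02, -0.002, -0.05, 0.02),
                   c(0.2, 0.05, -0.005, 0.1, -0.01),
                   c(-0.2, -0.05, 0.005, 0.2, 0.03))
  best <- multi_start_optim(init, negll, offsets)
  H <- try(stats::optimHess(best$par, negll), silent = TRUE)
  se <- rep(NA_real_, 5)
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(diag(Vi) > 0)) se <- sqrt(diag(Vi))
  }
  names(se) <- c("b0", "b1", "b2", "control_intercept", "control_slope")
  th <- best$par
  structure(list(params = coale_trussell_params(
    natural_fertility_coeffs = th[1:3],
    control_threshold_age = control_threshold_age,
    deviation_slope = deviation_slope,
    control_intercept = th[4], control_slope = th[5],
    min_reproductive_age = min_reproductive_age),
    loglik = -best$value,
    loglik_init = -negll(init),
    se = se,
    convergence = best$convergence,
    n_days = nrow(obs)),
    class = "coale_trussell_fit")
}

#' @export
print.coale_trussell_fit <- function(x, ...) {
  cat(sprintf("coale_trussell_fit: log-likelihood %.3f (%d alive-days)\n",
              x$loglik, x$n_days))
  print(x$params)
  invisible(x)
}

#' Nonparametric empirical vital rates from a life table
#'
#' Cohort life-table estimates: `p_hat[i, j]` is the fraction of cohort-`i`
#' individuals entering day `j` (excluding those censored during day `j`)
#' that survive it, and `f_hat[i, j]` is the mean offspring count on day
#' `j` among alive, uncensored cohort-`i` individuals. Cells with no
#' at-risk individuals are `NA`.
#'
#' @param data a life-table data.frame.
#' @param s,omega table dimensions; default to the largest maternal age
#'   and day present.
#' @return An object of class `empirical_rates` with matrices `p`, `f`,
#'   `n_risk` (survival denominators) and `n_alive` (fertility
#'   denominators).
#' @export
empirical_rates <- function(data, s = max(data$maternal_age),
                            omega = max(data$day)) {
  stopifnot(nrow(data) > 0)
  p <- matrix(NA_real_, s, omega,
              dimnames = list(maternal_age = 1:s, age = 1:omega))
  f <- n_risk <- n_alive <- p
  for (i in sort(unique(data$maternal_age))) {
    d <- data[data$maternal_age == i, ]
    for (j in sort(unique(d$day))) {
      dj <- d[d$day == j, ]
      surv <- sum(dj$alive == 1 & dj$censored == 0)
      died <- sum(dj$alive == 0)
      if (surv + died > 0) {
        p[i, j] <- surv / (surv + died)
        n_risk[i, j] <- surv + died
      }
      if (surv > 0) {
        f[i, j] <- mean(dj$offspring[dj$alive == 1 & dj$censored == 0])
        n_alive[i, j] <- surv
      }
    }
  }
  structure(list(p = p, f = f, n_risk = n_risk, n_alive = n_alive,
                 s = s, omega = omega),
            class = "empirical_rates")
}

#' Write a plain-text fit report
#'
#' Writes the fitted parameters as a flat YAML key-value file and a
#' companion `.log` text file recording the likelihood, convergence
#' status, and standard errors.
#'
#' @param fit a `weibull_fit` or `coale_trussell_fit`.
#' @param path output path for the parameter file (`.log` is appended for
#'   the log file).
#' @export
write_fit_report <- function(fit, path) {
  write_params(fit$params, path)
  lines <- c(sprintf("log-likelihood: %.10g", fit$loglik),
             sprintf("log-likelihood at initial guess: %.10g",
                     fit$loglik_init),
             sprintf("convergence code: %d", fit$convergence),
             sprintf("standard errors: %s",
                     paste(sprintf("%s=%.6g", names(fit$se), fit$se),
                           collapse = ", ")))
  writeLines(lines, paste0(path, ".log"))
  invisible(path)
}
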