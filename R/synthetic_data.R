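# Individual-based generator of daily life tables, emulating the cohort
# design of the rotifer maternal-age experiments: an F0 cohort plus F1
# cohorts collected at fixed maternal ages, observed every 24 h with right
# censoring of lost individuals.

#' Cohort design of a life-table experiment
#'
#' Defaults emulate the experimental design the analysis was built for:
#' F1 cohorts collected at maternal ages 3, 5, 7 and 9 d with 72
#' individuals each (the F0 cohort size, 187, is recorded for provenance;
#' F0 individuals have no defined maternal age class and are not
#' simulated), daily observation to a maximum age of 16 d, and a small
#' daily probability of accidental loss (right censoring).
#'
#' @param maternal_ages maternal age classes of the cohorts.
#' @param n_per_cohort individuals per cohort.
#' @param n_f0 size of the founding cohort (provenance only).
#' @param max_day last observed day; individuals alive at its end are
#'   administratively censored.
#' @param censor_prob daily probability that an individual is lost.
#' @param seed master seed; each individual gets its own stream derived
#'   from it, so results are invariant to cohort ordering.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(maternal_ages = c(3, 5, 7, 9), n_per_cohort = 72,
                          n_f0 = 187, max_day = 16, censor_prob = 0.01,
                          seed = 1) {
  stopifnot(all(maternal_ages >= 1), n_per_cohort >= 1, max_day >= 1,
            censor_prob >= 0, censor_prob < 1)
  structure(list(maternal_ages = as.integer(maternal_ages),
                 n_per_cohort = as.integer(n_per_cohort),
                 n_f0 = as.integer(n_f0), max_day = as.integer(max_day),
                 censor_prob = censor_prob, seed = as.integer(seed)),
            class = "cohort_design")
}

# Deterministic per-individual seed below 2^31, a function only of the
# master seed, the cohort's maternal age, and the within-cohort index.
individual_seed <- function(seed, maternal_age, index) {
  as.integer((as.double(seed) * 2654435761 + maternal_age * 40503 * 65537 +
                index * 9176) %% 2147483647)
}

#' Simulate a daily life table from vital rates
#'
#' For each individual of cohort maternal age `i`, day by day (the day-`j`
#' row is the daily check at age `j`, covering the age interval
#' `(j-1, j]`): with probability `censor_prob` the individual is lost
#' before any other event of the day (terminal row, `censored = 1`, last
#' known alive at the previous check); otherwise it produces a
#' Poisson(`f[i, j]`) count of daughters during the day -- matching the
#' projection matrix's accounting, in which a day's reproduction does not
#' require surviving that day, so the mean lifetime offspring of a cohort
#' equals the model's net reproductive rate exactly -- and then survives
#' the day with probability `p[i, j]` (death gives a terminal row with
#' `alive = 0`, offspring still recorded: neonates in the well are counted
#' at the check even if the mother died). The final observation day
#' carries no survival draw (for the terminal age class the projection
#' model defines none), so an individual present on day `max_day` ends
#' with an alive row there and is right-censored at the previous check
#' when fitted. Identical seed and design give byte-identical output.
#'
#' @param vital a [vital_rates()] object; cohort maternal ages must lie in
#'   `1..s` and `max_day` must not exceed `omega`.
#' @param design a [cohort_design()].
#' @return a `life_table` data.frame with columns `individual_id`,
#'   `maternal_age`, `day`, `alive`, `censored`, `offspring`, one row per
#'   individual-day.
#' @export
simulate_life_table <- function(vital, design) {
  stopifnot(inherits(vital, "vital_rates"), inherits(design, "cohort_design"))
  if (any(design$maternal_ages > vital$s))
    stop("cohort maternal age exceeds s", call. = FALSE)
  if (design$max_day > vital$omega)
    stop("max_day exceeds omega", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  nmax <- length(design$maternal_ages) * design$n_per_cohort * design$max_day
  id <- character(nmax); ma <- integer(nmax); day <- integer(nmax)
  alive <- integer(nmax); cens <- integer(nmax); off <- integer(nmax)
  r <- 0L
  for (i in design$maternal_ages) {
    for (k in seq_len(design$n_per_cohort)) {
      set.seed(individual_seed(design$seed, i, k))
      ind <- sprintf("m%02d_%05d", i, k)
      for (j in seq_len(design$max_day)) {
        r <- r + 1L
        id[r] <- ind; ma[r] <- i; day[r] <- j
        if (design$censor_prob > 0 && stats::runif(1) < design$censor_prob) {
          alive[r] <- 1L; cens[r] <- 1L; off[r] <- 0L
          break
        }
        off[r] <- stats::rpois(1, vital$f[i, j])
        cens[r] <- 0L
        if (j < design$max_day && stats::runif(1) > vital$p[i, j]) {
          alive[r] <- 0L
          break
        }
        alive[r] <- 1L
      }
    }
  }
  keep <- seq_len(r)
  structure(data.frame(individual_id = id[keep], maternal_age = ma[keep],
                       day = day[keep], alive = alive[keep],
                       censored = cens[keep], offspring = off[keep],
                       stringsAsFactors = FALSE),
            class = c("life_table", "data.frame"))
}

#' Packaged default generating parameters
#'
#' A qualitative stand-in parameter set (not fitted to any real data set)
#' whose vital rates reproduce the patterns the analysis was designed
#' around: no reproduction before age 3 d, fertility rising sharply
#' between ages 2 and 4 d to a peak near 4-5 d, schedules for different
#' maternal ages coinciding up to age 4 d and diverging after it, with
#' earlier and faster decline at older maternal ages; survival decreasing
#' with maternal age for young individuals but crossing over at the oldest
#' ages; and a high-growth assembled model with a growth rate between 1.5
#' and 2.5 per day. Because reproduction starts at age 3 d, maternal age
#' classes 1-2 are unreachable and class 3 is the youngest -- and
#' therefore best -- class actually present, matching the role of the
#' maternal-age-3 reference schedules in the removal scenarios.
#'
#' @return a list with components `weibull` ([weibull_params()]) and
#'   `fertility` ([coale_trussell_params()]).
#' @export
default_truth <- function() {
  list(weibull = weibull_params(log_scale_intercept = 3.0,
                                log_scale_slope = -0.10,
                                log_shape_intercept = 1.5,
                                log_shape_slope = -0.12),
       fertility = coale_trussell_params(
         natural_fertility_coeffs = c(-2.141, 1.62, -0.18),
         control_threshold_age = 4,
         deviation_slope = 1,
         control_intercept = 0.02,
         control_slope = 0.10,
         min_reproductive_age = 3))
}

#' Vital rates of the packaged default model
#' @param s,omega class counts (defaults 16 x 16).
#' @return a [vital_rates()] object.
#' @export
default_vital_rates <- function(s = 16, omega = 16) {
  truth <- default_truth()
  evaluate_vital_rates(truth$weibull, truth$fertility, s, omega)
}
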