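# Selection gradients (eigenvalue sensitivities) and LTRE decomposition.

#' Selection gradients on every vital rate
#'
#' The selection gradient on a trait affecting one matrix entry is the
#' partial derivative of the growth rate with respect to that entry,
#' `d lam / d a[r, c] = v[r] w[c] / (v' w)`. Each survival probability
#' `p[i, j]` appears once in `U` (at row `idx(i, j+1)`, column `idx(i, j)`)
#' and each fertility `f[i, j]` once in `F` (at row `min(j, s)`, column
#' `idx(i, j)`), so the gradient surfaces are those sensitivities laid out
#' over maternal age x age. Survival at the final age class is structurally
#' absent and its gradient is 0.
#'
#' @param model a `block_model`.
#' @return An object of class `gradient_surface` with `s x omega` matrices
#'   `d_lam_d_p` and `d_lam_d_f`, plus the underlying `eigen` analysis.
#' @export
selection_gradients <- function(model) {
  e <- eigen_analysis(model)
  s <- model$s; omega <- model$omega
  vw <- sum(e$v * e$w)  # 1 by normalisation, kept explicit
  dp <- matrix(0, s, omega, dimnames = dimnames(model$vital$p))
  df <- matrix(0, s, omega, dimnames = dimnames(model$vital$f))
  for (j in seq_len(omega)) {
    cols <- block_index(seq_len(s), j, s)
    if (j < omega)
      dp[, j] <- e$v[block_index(seq_len(s), j + 1L, s)] * e$w[cols] / vw
    df[, j] <- e$v[min(j, s)] * e$w[cols] / vw
  }
  structure(list(d_lam_d_p = dp, d_lam_d_f = df, eigen = e,
                 s = s, omega = omega, vital = model$vital),
            class = "gradient_surface")
}

#' @export
print.gradient_surface <- function(x, ...) {
  cat(sprintf("gradient_surface (%d x %d): max d lam/d p = %.4g, ",
              x$s, x$omega, max(x$d_lam_d_p)))
  cat(sprintf("max d lam/d f = %.4g\n", max(x$d_lam_d_f)))
  invisible(x)
}

#' Qualitative profile checks on a gradient surface
#'
#' Reports, for each maternal age class, whether the gradients are
#' nonincreasing in age over the reproductive ages; the location of the
#' overall peak; the orders-of-magnitude drop from the peak to the final
#' class; and the maternal-age profile (gradients summed over age), with a
#' check of whether that profile is unimodal -- rising at first, then
#' declining -- the concave shape that lets maternal effect senescence
#' evolve.
#'
#' The age-monotonicity check starts at `from_age`, by default the first
#' age with positive fertility. Before reproduction begins the survival
#' gradient is essentially flat: the ratio of successive gradients there
#' is `p[i, j] / p[i, j + 1]`, so a rising hazard produces a
#' sub-percent *increase* across pre-reproductive ages. The biologically
#' meaningful decline -- orders of magnitude across the reproductive span
#' -- is what is checked.
#'
#' @param g a `gradient_surface`.
#' @param from_age first age included in the monotonicity check; defaults
#'   to the first reproductive age of the model the surface came from.
#' @param rel_tol slack in the comparisons, relative to the largest entry
#'   of each surface (absorbs eigensolver noise at vanishingly rare
#'   states).
#' @return a list report with components `survival` and `fertility`.
#' @export
gradient_profile_checks <- function(g, from_age = NULL, rel_tol = 1e-9) {
  if (is.null(from_age)) {
    from_age <- if (!is.null(g$vital)) {
      reproductive <- which(colSums(g$vital$f) > 0)
      if (length(reproductive)) min(reproductive) else 1L
    } else 1L
  }
  check_one <- function(mat, skip_last_age = FALSE) {
    use <- if (skip_last_age) mat[, -ncol(mat), drop = FALSE] else mat
    tol <- rel_tol * max(use)
    use[use < tol] <- 0
    ages <- from_age:ncol(use)
    noninc <- apply(use[, ages, drop = FALSE], 1,
                    function(r) all(diff(r) <= tol))
    peak <- which(use == max(use), arr.ind = TRUE)
    profile <- rowSums(use)
    d <- diff(profile)
    pk <- which.max(profile)
    unimodal <- all(d[seq_len(pk - 1)] >= -tol) &&
      (pk > length(d) || all(d[pk:length(d)] <= tol))
    # drop from the peak to the last maternal age class that still has
    # gradients above the noise floor (later classes are effectively 0,
    # i.e. an unbounded drop)
    nonzero_rows <- which(rowSums(use) > 0)
    drop_oom <- if (length(nonzero_rows)) {
      final <- use[max(nonzero_rows), ]
      log10(max(use) / min(final[final > 0]))
    } else NA_real_
    list(nonincreasing_in_age = noninc,
         peak = c(maternal_age = peak[1, 1], age = peak[1, 2]),
         maternal_age_profile = profile,
         profile_unimodal = unimodal,
         orders_of_magnitude_drop = drop_oom)
  }
  list(survival = check_one(g$d_lam_d_p, skip_last_age = TRUE),
       fertility = check_one(g$d_lam_d_f))
}

#' Life table response experiment decomposition of a fitness difference
#'
#' Decomposes `delta_lam = lam(a) - lam(ref)` into per-rate contributions
#' `c_p[i, j] = (p_a[i, j] - p_ref[i, j]) * d lam / d p[i, j]` (and likewise
#' `c_f`), with the sensitivities evaluated at the midpoint model (the two
#' vital-rate tables averaged, then reassembled). Contributions are also
#' summed over age within each maternal age class, the view used to ask
#' which maternal ages, and which of survival vs fertility, carry the
#' fitness cost of maternal effect senescence. LTRE is a first-order
#' approximation; the closure error `|approx_delta_lam - delta_lam|` is
#' reported, with a warning above `closure_warn` relative discrepancy.
#'
#' @param model_a,model_ref `block_model`s of identical dimensions.
#' @param closure_warn relative closure discrepancy above which to warn.
#' @return An object of class `ltre_decomposition` with fields `c_p`, `c_f`,
#'   `by_maternal_age_p`, `by_maternal_age_f`, `delta_lam`,
#'   `approx_delta_lam`.
#' @export
ltre <- function(model_a, model_ref, closure_warn = 0.1) {
  if (model_a$s != model_ref$s || model_a$omega != model_ref$omega)
    stop("models must have identical s and omega", call. = FALSE)
  va <- model_a$vital; vr <- model_ref$vital
  mid <- vital_rates((va$p + vr$p) / 2, (va$f + vr$f) / 2)
  g <- selection_gradients(build_block_model(mid))
  c_p <- (va$p - vr$p) * g$d_lam_d_p
  c_f <- (va$f - vr$f) * g$d_lam_d_f
  delta_lam <- dominant_eigenvalue(model_a) - dominant_eigenvalue(model_ref)
  approx <- sum(c_p) + sum(c_f)
  if (abs(delta_lam) > 0 &&
      abs(approx - delta_lam) > closure_warn * abs(delta_lam))
    warning(sprintf(
      "LTRE closure discrepancy %.1f%% (first-order approximation)",
      100 * abs(approx - delta_lam) / abs(delta_lam)))
  structure(list(c_p = c_p, c_f = c_f,
                 by_maternal_age_p = rowSums(c_p),
                 by_maternal_age_f = rowSums(c_f),
                 delta_lam = delta_lam, approx_delta_lam = approx),
            class = "ltre_decomposition")
}

#' @export
print.ltre_decomposition <- function(x, ...) {
  cat(sprintf("LTRE: delta lambda = %.6f, sum of contributions = %.6f\n",
              x$delta_lam, x$approx_delta_lam))
  cat(sprintf("  survival total %.6f, fertility total %.6f\n",
              sum(x$c_p), sum(x$c_f)))
  invisible(x)
}

#' Tidy long-format table of a gradient surface or LTRE decomposition
#'
#' @param x a `gradient_surface` or `ltre_decomposition`.
#' @param log10_sentinel value substituted for `log10(0)` in the log-scaled
#'   column (figures of these surfaces are conventionally log-scaled and a
#'   sentinel keeps zero entries plottable).
#' @return a data.frame with columns `maternal_age`, `age`, `quantity`,
#'   `value`, `log10_value`.
#' @export
tidy_surface <- function(x, log10_sentinel = -Inf) {
  pick <- if (inherits(x, "gradient_surface"))
    list(d_lam_d_p = x$d_lam_d_p, d_lam_d_f = x$d_lam_d_f)
  else if (inherits(x, "ltre_decomposition"))
    list(c_p = x$c_p, c_f = x$c_f)
  else stop("unsupported object", call. = FALSE)
  out <- do.call(rbind, lapply(names(pick), function(nm) {
    m <- pick[[nm]]
    data.frame(maternal_age = as.integer(rep(seq_len(nrow(m)), ncol(m))),
               age = as.integer(rep(seq_len(ncol(m)), each = nrow(m))),
               quantity = nm,
               value = as.vector(m))
  }))
  out$log10_value <- ifelse(out$value > 0, log10(abs(out$value)),
                            ifelse(out$value == 0, log10_sentinel,
                                   log10(abs(out$value))))
  out
}
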