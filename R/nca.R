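#' Maximum observed concentration
#'
#' @param profile Data frame with columns `time_min` and `conc` holding the
#'   retained (quantifiable) samples of one patient in one matrix.
#' @return One-row tibble with `cmax` (ug/mL) and `tmax` (min, the earliest
#'   time attaining the maximum).
#' @examples
#' cmax(data.frame(time_min = c(0, 5, 10), conc = c(0, 100, 100)))
#' @export
cmax <- function(profile) {
  profile <- profile[is.finite(profile$conc), , drop = FALSE]
  if (nrow(profile) == 0L) abort("Empty profile: Cmax is not evaluable.")
  i <- which(profile$conc == max(profile$conc))
  i <- i[which.min(profile$time_min[i])]
  tibble::tibble(cmax = profile$conc[i], tmax = profile$time_min[i])
}

r2_stats <- function(x, y) {
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  n <- length(x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

lambda_z_not_evaluable <- function(reason, profile = NULL) {
  structure(
    list(lambda_z = NA_real_, intercept_log = NA_real_, n_points = NA_integer_,
         t_first = NA_real_, t_last = NA_real_, r2 = NA_real_,
         r2_adjusted = NA_real_, evaluable = FALSE, reason = reason,
         profile = profile),
    class = "lambda_z_fit"
  )
}

#' Terminal-slope (lambda-z) regression
#'
#' Fits ordinary least squares of ln(concentration) on time over a terminal
#' window and reports the elimination rate constant lambda-z = -slope.
#' Candidate windows are the contiguous sets of at least `min_points`
#' samples that end at the last quantifiable point and start strictly after
#' Tmax: the Cmax sample itself is kept out of the fit so that the
#' absorption peak cannot contaminate the terminal slope. A profile that
#' declines from its very first sample has no absorption peak, and there
#' the first (maximal) sample is eligible. Two selection rules are
#' offered:
#'
#' * `"maximal"` (default): the largest candidate window with a declining
#'   slope. When the terminal phase is a single exponential — the case for
#'   a drained perfusate and for post-distribution plasma — this uses all
#'   the information and, because the log-scale residual variance of a
#'   proportional-error assay is constant, the slope estimate is unbiased.
#' * `"best_adj_r2"`: the window maximising the adjusted R-squared, ties
#'   (within 1e-4) broken toward more points — the convention of common
#'   NCA software, useful when an early distribution phase must be kept
#'   out of the window. Under proportional assay noise this adaptive rule
#'   prefers windows in which noise happens to steepen the apparent
#'   decline, so it systematically shortens estimated half-lives of
#'   mono-exponential data; hence it is not the default.
#'
#' Candidate windows whose slope is not negative (no declining terminal
#' phase) are rejected; if every candidate is rejected the half-life is
#' reported as missing, never fabricated.
#'
#' @inheritParams cmax
#' @param min_points Minimum number of points in a window (default 3).
#' @param selection Window selection rule, see above.
#' @return An object of class `lambda_z_fit` with elements `lambda_z`
#'   (1/min), `intercept_log` (ln ug/mL at time 0), `n_points`, `t_first`,
#'   `t_last` (the window, min), `r2`, `r2_adjusted`, `evaluable` and
#'   `reason`. Supports [tidy()], [glance()] and [autoplot()].
#' @seealso [half_life()]
#' @export
fit_lambda_z <- function(profile, min_points = 3L,
                         selection = c("maximal", "best_adj_r2")) {
  selection <- match.arg(selection)
  profile <- dplyr::arrange(
    profile[is.finite(profile$conc), c("time_min", "conc")], .data$time_min
  )
  if (nrow(profile) == 0L) return(lambda_z_not_evaluable("empty profile"))
  tmax <- cmax(profile)$tmax
  # the Cmax sample is excluded to keep the absorption peak out of the
  # terminal fit; a profile with no rising limb has no peak to exclude
  term <- if (tmax > profile$time_min[1L]) {
    profile[profile$time_min > tmax, , drop = FALSE]
  } else {
    profile
  }
  n <- nrow(term)
  if (n < min_points) {
    return(lambda_z_not_evaluable(
      paste0("only ", n, " points after Tmax (need >= ", min_points, ")"), profile))
  }
  if (any(term$conc <= 0)) {
    return(lambda_z_not_evaluable("non-positive concentration in terminal phase", profile))
  }
  best <- NULL
  # largest window first: "maximal" takes the first declining window,
  # "best_adj_r2" keeps it unless a smaller window clearly fits better,
  # so equal fits resolve toward more points
  for (k in rev(seq(min_points, n))) {
    idx <- seq(n - k + 1L, n)
    st <- r2_stats(term$time_min[idx], log(term$conc[idx]))
    if (!is.finite(st$slope) || st$slope >= 0) next
    if (is.null(best) || st$r2_adj > best$r2_adj + 1e-4) {
      best <- c(st, list(idx = idx))
    }
    if (selection == "maximal" && !is.null(best)) break
  }
  if (is.null(best)) {
    return(lambda_z_not_evaluable("no candidate window with a declining slope", profile))
  }
  structure(
    list(lambda_z = -best$slope, intercept_log = best$intercept,
         n_points = length(best$idx),
         t_first = term$time_min[best$idx[1L]],
         t_last = term$time_min[tail(best$idx, 1L)],
         r2 = best$r2, r2_adjusted = best$r2_adj,
         evaluable = TRUE, reason = NA_character_, profile = profile),
    class = "lambda_z_fit"
  )
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  if (!x$evaluable) {
    cat("<lambda_z_fit> not evaluable:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<lambda_z_fit> lambda-z %.5g /min (T1/2 %.4g min), %d points [%g, %g] min, adj R2 %.4f\n",
      x$lambda_z, half_life(x), x$n_points, x$t_first, x$t_last, x$r2_adjusted))
  }
  invisible(x)
}

#' Terminal half-life from a lambda-z fit
#'
#' @param fit A `lambda_z_fit` object, or directly a positive rate constant
#'   in 1/min.
#' @return Half-life ln(2)/lambda-z in minutes; `NA` for a non-evaluable fit.
#' @examples
#' half_life(log(2) / 104) # 104
#' @export
half_life <- function(fit) {
  lz <- if (inherits(fit, "lambda_z_fit")) fit$lambda_z else fit
  if (is.na(lz)) return(NA_real_)
  if (lz <= 0) abort("lambda-z must be positive.")
  log(2) / lz
}

interp_conc <- function(t, t1, t2, c1, c2, method) {
  if (method == "linear_up_log_down" && c2 < c1 && c1 > 0 && c2 > 0) {
    exp(log(c1) + (log(c2) - log(c1)) * (t - t1) / (t2 - t1))
  } else {
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
  }
}

segment_auc <- function(dt, c1, c2, method) {
  if (method == "linear_up_log_down" && c2 < c1 && c1 > 0 && c2 > 0) {
    dt * (c1 - c2) / log(c1 / c2)
  } else {
    dt * (c1 + c2) / 2
  }
}

#' Windowed trapezoidal area under the concentration-time curve
#'
#' Piecewise trapezoidal integral of a profile over `[t_start, t_end]`. When
#' a bound falls between two samples, the concentration at the bound is
#' interpolated consistently with the chosen method (linear everywhere, or
#' log-linear on declining segments for `"linear_up_log_down"`). The
#' integral is additive over adjacent windows. No extrapolation beyond the
#' sampled range is performed: bounds outside it are an error.
#'
#' @inheritParams cmax
#' @param t_start,t_end Window bounds in minutes, `t_start < t_end`, both
#'   within the sampled time range.
#' @param method `"linear"` (default) or `"linear_up_log_down"`.
#' @return AUC in min.ug/mL.
#' @examples
#' auc_trapezoid(data.frame(time_min = c(0, 90), conc = c(0, 29)), 0, 90) # 1305
#' @export
auc_trapezoid <- function(profile, t_start, t_end,
                          method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= t_end) {
    abort("Need finite bounds with t_start < t_end.")
  }
  profile <- dplyr::arrange(
    profile[is.finite(profile$conc), c("time_min", "conc")], .data$time_min
  )
  tt <- profile$time_min
  cc <- profile$conc
  if (length(tt) < 2L) abort("Need at least two quantifiable points to integrate.")
  if (t_start < tt[1L] || t_end > tail(tt, 1L)) {
    abort(sprintf(
      "Window [%g, %g] exceeds the sampled range [%g, %g]; no extrapolation is performed.",
      t_start, t_end, tt[1L], tail(tt, 1L)))
  }
  bound_conc <- function(t) {
    hit <- which(tt == t)
    if (length(hit)) return(cc[hit[1L]])
    j <- findInterval(t, tt)
    interp_conc(t, tt[j], tt[j + 1L], cc[j], cc[j + 1L], method)
  }
  inside <- tt > t_start & tt < t_end
  knots_t <- c(t_start, tt[inside], t_end)
  knots_c <- c(bound_conc(t_start), cc[inside], bound_conc(t_end))
  sum(vapply(seq_len(length(knots_t) - 1L), function(i) {
    segment_auc(knots_t[i + 1L] - knots_t[i], knots_c[i], knots_c[i + 1L], method)
  }, numeric(1)))
}

#' Intraperitoneal-to-plasma exposure ratio
#'
#' The ratio of the perfusate AUC to the plasma AUC over the perfusion
#' window quantifies the local-exposure advantage of intraperitoneal
#' delivery. Full precision is retained; round only for presentation.
#'
#' @param auc90_pf,auc90_pl Perfusate and plasma AUC over the perfusion
#'   period, min.ug/mL. `auc90_pl` must be positive.
#' @return The unitless ratio, vectorised.
#' @examples
#' auc_ratio(25865, 1572) # 16.45...
#' @export
auc_ratio <- function(auc90_pf, auc90_pl) {
  if (any(!is.finite(auc90_pl) | auc90_pl <= 0)) {
    abort("`auc90_pl` must be positive.")
  }
  auc90_pf / auc90_pl
}

fit_or_na <- function(profile, min_points = 3L, selection = "maximal") {
  if (nrow(profile) == 0L) lambda_z_not_evaluable("empty profile") else
    fit_lambda_z(profile, min_points, selection)
}

safe_auc <- function(profile, t_start, t_end, method) {
  if (nrow(profile) < 2L) return(NA_real_)
  rng <- range(profile$time_min)
  if (t_start < rng[1L] || t_end > rng[2L]) return(NA_real_)
  auc_trapezoid(profile, t_start, t_end, method)
}

#' Per-patient noncompartmental analysis of a dual-matrix cohort
#'
#' Orchestrates the full noncompartmental analysis for every patient: Cmax
#' and Tmax per matrix, terminal half-life per matrix via [fit_lambda_z()],
#' trapezoidal AUC over the perfusion window `[0, perfusion_end]` for both
#' matrices, plasma AUC over the whole sampling period (0 to the last
#' quantifiable plasma time) and the intraperitoneal-to-plasma AUC ratio.
#' BLQ-flagged samples are excluded first via [apply_llq_policy()].
#' Perfusate lambda-z uses only intra-perfusion samples (the perfusate
#' ceases to exist at drain); plasma lambda-z uses all post-Tmax samples.
#'
#' A parameter that cannot be computed for a patient (too few points, no
#' declining terminal phase, window not covered) is reported as `NA` for
#' that patient without aborting the cohort run; the reasons are collected
#' in attribute `"notes"`.
#'
#' @param conc A validated concentration tibble (with `blq` flags), e.g.
#'   from [read_concentration_table()] or [simulate_cohort()].
#' @param patients Optional patient tibble; if supplied, `peritonectomy`,
#'   `crs_timing`, `bsa` and `dose` are joined onto the result.
#' @param policy An [llq_policy()].
#' @param auc_method Trapezoidal variant, see [auc_trapezoid()].
#' @param lambda_selection Terminal-window selection rule, see
#'   [fit_lambda_z()].
#' @param perfusion_end End of perfusion in minutes (default 90); defines
#'   the AUC window and the perfusate sample range.
#' @return A tibble with one row per patient: `cmax_pf`, `tmax_pf`,
#'   `cmax_pl`, `tmax_pl` (ug/mL, min), `t_half_pf`, `t_half_pl` (min),
#'   `auc90_pf`, `auc90_pl`, `auc_total_pl` (min.ug/mL), `auc_ratio`, and
#'   lambda-z diagnostics (`lambda_z_*`, `n_lambda_*`, `r2_adj_*`).
#' @export
run_nca <- function(conc, patients = NULL, policy = llq_policy(),
                    auc_method = c("linear", "linear_up_log_down"),
                    lambda_selection = c("maximal", "best_adj_r2"),
                    perfusion_end = 90) {
  auc_method <- match.arg(auc_method)
  lambda_selection <- match.arg(lambda_selection)
  if (is.null(conc[["blq"]])) conc <- as_concentration_table(conc, policy)
  kept <- apply_llq_policy(conc, policy)
  notes <- list()

  one_patient <- function(df, id) {
    pf <- df[df$matrix == "perfusate" & df$time_min <= perfusion_end, , drop = FALSE]
    pl <- df[df$matrix == "plasma", , drop = FALSE]
    cm_pf <- if (nrow(pf)) cmax(pf) else tibble::tibble(cmax = NA_real_, tmax = NA_real_)
    cm_pl <- if (nrow(pl)) cmax(pl) else tibble::tibble(cmax = NA_real_, tmax = NA_real_)
    fit_pf <- fit_or_na(pf, selection = lambda_selection)
    fit_pl <- fit_or_na(pl, selection = lambda_selection)
    for (m in c("perfusate", "plasma")) {
      f <- if (m == "perfusate") fit_pf else fit_pl
      if (!f$evaluable) {
        notes[[length(notes) + 1L]] <<- sprintf(
          "patient %s, %s: half-life not evaluable (%s)", id, m, f$reason)
      }
    }
    # plasma is predose-zero at t = 0 (the sample is below LLQ by design), so
    # the rising limb is anchored at a zero origin for integration only
    pl_auc <- pl
    if (nrow(pl_auc) && min(pl_auc$time_min) > 0) {
      pl_auc <- dplyr::bind_rows(
        dplyr::mutate(pl_auc[1L, ], time_min = 0, conc = 0), pl_auc)
    }
    auc90_pf <- safe_auc(pf, 0, perfusion_end, auc_method)
    auc90_pl <- safe_auc(pl_auc, 0, perfusion_end, auc_method)
    auc_tot <- if (nrow(pl_auc) >= 2L) {
      safe_auc(pl_auc, 0, max(pl_auc$time_min), auc_method)
    } else NA_real_
    tibble::tibble(
      cmax_pf = cm_pf$cmax, tmax_pf = cm_pf$tmax,
      cmax_pl = cm_pl$cmax, tmax_pl = cm_pl$tmax,
      t_half_pf = half_life(fit_pf), t_half_pl = half_life(fit_pl),
      auc90_pf = auc90_pf, auc90_pl = auc90_pl, auc_total_pl = auc_tot,
      auc_ratio = if (is.finite(auc90_pf) && is.finite(auc90_pl) && auc90_pl > 0) {
        auc90_pf / auc90_pl
      } else NA_real_,
      lambda_z_pf = fit_pf$lambda_z, n_lambda_pf = fit_pf$n_points,
      r2_adj_pf = fit_pf$r2_adjusted,
      lambda_z_pl = fit_pl$lambda_z, n_lambda_pl = fit_pl$n_points,
      r2_adj_pl = fit_pl$r2_adjusted
    )
  }

  out <- kept |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ one_patient(.x, .y$patient_id)) |>
    dplyr::ungroup()
  if (!is.null(patients)) {
    keep_cols <- intersect(
      c("patient_id", "bsa", "dose", "pci", "peritonectomy", "crs_timing"),
      names(patients))
    out <- dplyr::left_join(out, patients[keep_cols], by = "patient_id")
  }
  attr(out, "notes") <- unlist(notes) %||% character(0)
  attr(out, "llq_removed") <- attr(kept, "removed")
  out
}
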