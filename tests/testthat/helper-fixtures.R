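# Small in-code fixtures shared across the suite.

# a clean two-matrix profile for one patient on the standard schedules
make_patient_conc <- function(id = "P1", ka = log(2) / 104, ke = log(2) / 160,
                              dose = 1456, v_pf = 4.2, v_c = 15) {
  prof <- analytic_profiles(ka, ke, dose, v_pf, v_c, drain_time = 90)
  dplyr::bind_rows(
    tibble::tibble(patient_id = id, matrix = "perfusate",
                   time_min = perfusate_schedule(),
                   conc = prof$conc_pf(perfusate_schedule())),
    tibble::tibble(patient_id = id, matrix = "plasma",
                   time_min = plasma_schedule(),
                   conc = prof$conc_pl(plasma_schedule()))
  )
}

# random noisy declining profile for window-selection property tests
random_terminal_profile <- function(n_points = 8, thalf = 100, cv = 0.15) {
  times <- sort(sample(seq(5, 200, by = 5), n_points))
  conc <- 100 * exp(-log(2) / thalf * times) *
    rlnorm(n_points, 0, sqrt(log(1 + cv^2)))
  tibble::tibble(time_min = times, conc = conc)
}

# independent brute-force oracle for best-adjusted-R2 window selection:
# enumerate every contiguous terminal window of >= 3 points starting after
# the peak (peak kept for monotone profiles), pick max adjusted R2, ties
# (within 1e-4) broken toward more points
brute_force_lambda_window <- function(profile, min_points = 3) {
  profile <- profile[order(profile$time_min), ]
  imax <- which.max(profile$conc)[1]
  term <- if (profile$time_min[imax] > profile$time_min[1]) {
    profile[profile$time_min > profile$time_min[imax], ]
  } else {
    profile
  }
  n <- nrow(term)
  cand <- list()
  for (k in seq(min_points, n)) {
    idx <- seq(n - k + 1, n)
    f <- stats::lm(log(conc) ~ time_min, data = term[idx, ])
    slope <- stats::coef(f)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    cand[[length(cand) + 1]] <- list(
      k = k, slope = slope, r2_adj = summary(f)$adj.r.squared,
      t_first = term$time_min[idx[1]]
    )
  }
  if (!length(cand)) return(NULL)
  r2 <- vapply(cand, `[[`, numeric(1), "r2_adj")
  top <- which(r2 >= max(r2) - 1e-4)
  cand[[top[which.max(vapply(cand[top], `[[`, numeric(1), "k"))]]]
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
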