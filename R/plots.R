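#' Mean concentration-time curves by matrix
#'
#' Cohort mean concentration with standard-error bars in perfusate and
#' plasma, the standard display of dual-matrix HIPEC kinetics. Restrict to
#' `t_max = 90` to show only the perfusion phase, or pass `Inf` to include
#' the post-perfusion plasma tail.
#'
#' @param conc A validated concentration tibble (BLQ rows are dropped).
#' @param t_max Right edge of the time axis in minutes (default 90).
#' @param log_y Plot concentration on a log axis.
#' @return A ggplot object.
#' @export
plot_mean_concentration <- function(conc, t_max = 90, log_y = FALSE) {
  dat <- conc |>
    dplyr::filter(!.data$blq, .data$time_min <= t_max) |>
    dplyr::group_by(.data$matrix, .data$time_min) |>
    dplyr::summarise(
      mean_conc = mean(.data$conc),
      se = sd(.data$conc) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_min, .data$mean_conc,
                                         colour = .data$matrix)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_conc - .data$se,
                   ymax = .data$mean_conc + .data$se),
      width = 0
    ) +
    ggplot2::labs(x = "Time from start of perfusion (min)",
                  y = "Carboplatin concentration (µg/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn fit_lambda_z Plot the log-concentration profile with the
#'   selected terminal window and fitted slope highlighted.
#' @param object A `lambda_z_fit`.
#' @param ... Unused.
#' @method autoplot lambda_z_fit
#' @export
autoplot.lambda_z_fit <- function(object, ...) {
  if (is.null(object$profile)) abort("Fit carries no profile data to plot.")
  dat <- object$profile
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_min, .data$conc)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (min)", y = "Concentration (µg/mL)") +
    ggplot2::theme_minimal()
  if (isTRUE(object$evaluable)) {
    win <- dat[dat$time_min >= object$t_first & dat$time_min <= object$t_last, ]
    fit_line <- tibble::tibble(
      time_min = seq(object$t_first, object$t_last, length.out = 50),
    )
    fit_line$conc <- exp(object$intercept_log - object$lambda_z * fit_line$time_min)
    p <- p +
      ggplot2::geom_point(data = win, colour = "red") +
      ggplot2::geom_line(data = fit_line, colour = "red")
  }
  p
}

#' Serial blood-count course with CTCAE grade bands
#'
#' One panel per analyte; horizontal dashed lines mark the grade
#' boundaries, and the day-0/1 surgical-attribution window is shaded.
#'
#' @param cbc A CBC tibble (one or more patients).
#' @param thresholds A [ctcae_thresholds()] object.
#' @return A ggplot object.
#' @export
plot_cbc_course <- function(cbc, thresholds = ctcae_thresholds()) {
  present <- intersect(names(thresholds), names(cbc))
  long <- tidyr::pivot_longer(cbc, dplyr::all_of(present),
                              names_to = "analyte", values_to = "value")
  bands <- purrr::map_dfr(present, function(a) {
    tibble::tibble(analyte = a, bound = thresholds[[a]]$cuts)
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                     group = .data$patient_id)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = 1.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = bands,
                        ggplot2::aes(yintercept = .data$bound),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Day relative to surgery", y = NULL) +
    ggplot2::theme_minimal()
}
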