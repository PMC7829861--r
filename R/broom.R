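#' Tidy a lambda-z fit
#'
#' @param x A `lambda_z_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the rate constant, derived half-life, window
#'   and fit diagnostics.
#' @method tidy lambda_z_fit
#' @export
tidy.lambda_z_fit <- function(x, ...) {
  tibble::tibble(
    lambda_z = x$lambda_z, half_life = half_life(x),
    intercept_log = x$intercept_log, n_points = x$n_points,
    t_first = x$t_first, t_last = x$t_last,
    r2 = x$r2, r2_adjusted = x$r2_adjusted,
    evaluable = x$evaluable, reason = x$reason
  )
}

#' @rdname tidy.lambda_z_fit
#' @method glance lambda_z_fit
#' @export
glance.lambda_z_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_adjusted = x$r2_adjusted,
                 n_points = x$n_points, evaluable = x$evaluable)
}

#' Tidy a geometric-mean group comparison
#'
#' @param x A `gm_comparison` object from [compare_groups_log_t()].
#' @param ... Unused.
#' @return One-row tibble with the ratio of geometric means, its confidence
#'   interval, the t statistic, degrees of freedom, p-value and group sizes.
#' @method tidy gm_comparison
#' @export
tidy.gm_comparison <- function(x, ...) {
  tibble::tibble(
    ratio_of_geometric_means = x$ratio_of_geometric_means,
    ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    n_a = x$n_a, n_b = x$n_b, conf_level = x$level
  )
}

#' @rdname tidy.gm_comparison
#' @method glance gm_comparison
#' @export
glance.gm_comparison <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, t_statistic = x$t_statistic, df = x$df)
}
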