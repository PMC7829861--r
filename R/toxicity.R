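toxicity_names <- c(hemoglobin = "anemia", neutrophils = "neutropenia",
                    platelets = "thrombocytopenia", leukocytes = "leukopenia")

#' CTCAE v4.0 grade boundaries for hematological toxicity
#'
#' Grade bands for the four hematological toxicities, in the units the
#' laboratory reports: hemoglobin in mmol/L, cell counts in 10^9/L. A value
#' at or above the lower limit of normal (LLN) is grade 0; below it the
#' grade increases as the value crosses successive boundaries. A value
#' exactly on a boundary belongs to the less severe grade (the bands are
#' half-open below, matching the strict inequalities of the scale). Anemia
#' has no numeric grade-4 laboratory threshold (grade 4 is defined
#' clinically), so laboratory grading of hemoglobin tops out at 3.
#'
#' Defaults: neutrophils LLN 2.0, grade boundaries 1.5 / 1.0 / 0.5;
#' leukocytes LLN 4.0, boundaries 3.0 / 2.0 / 1.0; platelets LLN 150,
#' boundaries 75 / 50 / 25; hemoglobin LLN 7.3 mmol/L, boundaries 6.2 / 4.9
#' mmol/L (the g/dL scale converted to the mmol/L units used in Danish
#' laboratories; 4.9 mmol/L is the grade-3 bound).
#'
#' @param lln Named numeric vector overriding any lower limit of normal.
#' @return Named list of per-analyte threshold definitions, class
#'   `ctcae_thresholds`.
#' @examples
#' grade_analyte("neutrophils", 0.8) # 3
#' @export
ctcae_thresholds <- function(lln = NULL) {
  th <- list(
    neutrophils = list(lln = 2.0, cuts = c(1.5, 1.0, 0.5)),
    leukocytes = list(lln = 4.0, cuts = c(3.0, 2.0, 1.0)),
    platelets = list(lln = 150, cuts = c(75, 50, 25)),
    hemoglobin = list(lln = 7.3, cuts = c(6.2, 4.9))
  )
  if (!is.null(lln)) {
    bad <- setdiff(names(lln), names(th))
    if (length(bad)) abort(paste0("Unknown analyte(s) in `lln`: ",
                                  paste(bad, collapse = ", "), "."))
    for (a in names(lln)) {
      if (lln[[a]] <= max(th[[a]]$cuts)) {
        abort(paste0("LLN for ", a, " must exceed its grade-1 boundary."))
      }
      th[[a]]$lln <- lln[[a]]
    }
  }
  structure(th, class = "ctcae_thresholds")
}

#' Grade a laboratory value on the CTCAE scale
#'
#' @param analyte One of `"hemoglobin"`, `"neutrophils"`, `"platelets"`,
#'   `"leukocytes"`.
#' @param value Laboratory value(s), `>= 0`, in the analyte's units
#'   (mmol/L for hemoglobin, 10^9/L otherwise).
#' @param thresholds A [ctcae_thresholds()] object.
#' @return Integer grade(s) 0-4 (0-3 for hemoglobin); `NA` in, `NA` out.
#' @export
grade_analyte <- function(analyte, value, thresholds = ctcae_thresholds()) {
  if (!analyte %in% names(thresholds)) {
    abort(paste0("Unknown analyte: \"", analyte, "\"."))
  }
  if (any(!is.na(value) & value < 0)) abort("Laboratory values must be >= 0.")
  bounds <- c(thresholds[[analyte]]$lln, thresholds[[analyte]]$cuts)
  vapply(value, function(v) {
    if (is.na(v)) NA_integer_ else sum(v < bounds)
  }, integer(1))
}

#' Assess hematological toxicity over a postoperative course
#'
#' Scans each patient's serial blood counts for toxicity events inside the
#' surveillance window (postoperative days 1-30 by default). For every
#' analyte the in-window nadir is located and graded; an event (grade >= 1)
#' is emitted with its nadir day and value. Anemia and thrombocytopenia
#' observed during surgery (day 0) or on postoperative day 1 are attributed
#' to the surgical procedure itself, not the chemotherapy: such events are
#' recorded with `counted = FALSE` unless the course shows a further
#' decrease — an in-window nadir after day 1 that falls below the day-1
#' value. Neutropenia and leukopenia are counted anywhere in the window.
#'
#' @param cbc A CBC tibble (see [read_cbc_table()]); may contain several
#'   patients.
#' @param thresholds A [ctcae_thresholds()] object.
#' @param window Integer vector `c(first, last)` of postoperative days
#'   scanned, default `c(1, 30)`.
#' @return Tibble of events: `patient_id`, `analyte`, `toxicity` (clinical
#'   name), `grade` (worst in-window), `day_of_nadir`, `nadir_value`,
#'   `counted`. Zero rows when every value is within normal limits.
#'   A missing preoperative baseline (day -1) triggers a warning; the
#'   assessment proceeds on in-window data.
#' @export
assess_course <- function(cbc, thresholds = ctcae_thresholds(),
                          window = c(1L, 30L)) {
  cbc <- validate_cbc_table(cbc)
  out <- cbc |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ assess_one(.x, .y$patient_id, thresholds, window)) |>
    dplyr::ungroup()
  if (!nrow(out)) {
    out <- tibble::tibble(patient_id = character(), analyte = character(),
                          toxicity = character(), grade = integer(),
                          day_of_nadir = integer(), nadir_value = double(),
                          counted = logical())
  }
  out
}

assess_one <- function(series, id, thresholds, window) {
  if (!any(series$day == -1L)) {
    warn(paste0("Patient ", id,
                ": no preoperative baseline (day -1); assessing in-window data only."))
  }
  present <- intersect(names(thresholds), names(series))
  purrr::map_dfr(present, function(a) {
    inw <- series[series$day >= window[1L] & series$day <= window[2L] &
                    !is.na(series[[a]]), c("day", a)]
    if (!nrow(inw)) return(NULL)
    v <- inw[[a]]
    nadir <- min(v)
    day_nadir <- min(inw$day[v == nadir])
    grade <- grade_analyte(a, nadir, thresholds)
    if (grade < 1L) return(NULL)
    counted <- if (a %in% c("hemoglobin", "platelets")) {
      day1 <- series[[a]][series$day == 1L]
      day1 <- day1[!is.na(day1)]
      day_nadir > 1L && (!length(day1) || nadir < day1[1L])
    } else TRUE
    tibble::tibble(
      analyte = a, toxicity = unname(toxicity_names[a]), grade = grade,
      day_of_nadir = day_nadir, nadir_value = nadir, counted = counted
    )
  })
}

#' Cohort summary of severe hematological toxicity
#'
#' Counts, per toxicity, the patients whose worst counted event reaches
#' grade 3 or higher, with the percentage of the cohort.
#'
#' @param events Event tibble from [assess_course()].
#' @param n_patients Cohort size (needed because event-free patients do not
#'   appear in `events`).
#' @param min_grade Severity threshold, default 3.
#' @return Tibble with one row per toxicity: `analyte`, `toxicity`,
#'   `n_patients_severe`, `pct` (0-100, full precision).
#' @export
summarize_toxicity <- function(events, n_patients, min_grade = 3L) {
  stopifnot(is.numeric(n_patients), n_patients >= 1)
  counts <- events |>
    dplyr::filter(.data$counted, .data$grade >= min_grade) |>
    dplyr::distinct(.data$patient_id, .data$analyte) |>
    dplyr::count(.data$analyte, name = "n_patients_severe")
  tibble::tibble(analyte = names(toxicity_names),
                 toxicity = unname(toxicity_names)) |>
    dplyr::left_join(counts, by = "analyte") |>
    dplyr::mutate(
      n_patients_severe = dplyr::coalesce(.data$n_patients_severe, 0L),
      pct = 100 * .data$n_patients_severe / n_patients
    )
}
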