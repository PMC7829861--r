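#' LLQ handling policy
#'
#' Assay samples with concentrations below the lower limit of quantification
#' (LLQ) cannot be distinguished from noise. The policy records the LLQ (in
#' ug/mL) and how flagged samples are treated; the only supported handling is
#' `"exclude"`, i.e. below-LLQ samples are dropped before any pharmacokinetic
#' computation rather than imputed.
#'
#' @param llq Lower limit of quantification in ug/mL. Must be positive.
#'   Default 0.01, the LLQ of a typical LC-MS total-platinum assay.
#' @param handling How flagged samples are treated. Only `"exclude"`.
#' @return An object of class `llq_policy`.
#' @examples
#' llq_policy()
#' llq_policy(llq = 0.05)
#' @export
llq_policy <- function(llq = 0.01, handling = c("exclude")) {
  handling <- match.arg(handling)
  if (!is.numeric(llq) || length(llq) != 1L || !is.finite(llq) || llq <= 0) {
    abort("`llq` must be a single positive number (ug/mL).")
  }
  structure(list(llq = llq, handling = handling), class = "llq_policy")
}

#' @export
print.llq_policy <- function(x, ...) {
  cat("<llq_policy> LLQ =", x$llq, "ug/mL, handling =", x$handling, "\n")
  invisible(x)
}

matrix_levels <- c("perfusate", "plasma")

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a long-format concentration table
#'
#' Reads timed drug concentration measurements for one or more patients in one
#' or both matrices (perfusate, plasma). The file must be delimiter-separated
#' (comma or tab, guessed from the header line unless `delim` is given) with
#' header columns `patient_id`, `matrix`, `time_min`, `conc`. The `conc` field
#' holds a concentration in ug/mL or the literal token `"BLQ"` for a sample
#' the assay could not quantify.
#'
#' Samples are validated (known matrix, finite non-negative time, no duplicate
#' (patient, matrix, time) keys) and flagged below the limit of quantification
#' when `conc` is the `"BLQ"` token or a numeric value below `policy$llq`.
#'
#' @param path Path to a delimited text file.
#' @param policy An [llq_policy()].
#' @param delim Field delimiter; `NULL` (default) guesses comma vs tab.
#' @return A tibble with columns `patient_id` (character), `matrix`
#'   (character, `"perfusate"` or `"plasma"`), `time_min` (double), `conc`
#'   (double, `NA` for token-BLQ rows) and `blq` (logical), sorted by
#'   (patient_id, matrix, time_min).
#' @seealso [apply_llq_policy()], [write_concentration_table()]
#' @export
read_concentration_table <- function(path, policy = llq_policy(), delim = NULL) {
  stopifnot(inherits(policy, "llq_policy"))
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  as_concentration_table(raw, policy)
}

#' Validate an in-memory concentration table
#'
#' Applies the same validation and BLQ flagging as
#' [read_concentration_table()] to a data frame already in memory (for
#' example one produced by [simulate_cohort()]).
#'
#' @param data Data frame with columns `patient_id`, `matrix`, `time_min`,
#'   `conc`; `conc` may be numeric or character with `"BLQ"` tokens. An
#'   existing logical `blq` column is honoured and extended.
#' @inheritParams read_concentration_table
#' @return See [read_concentration_table()].
#' @export
as_concentration_table <- function(data, policy = llq_policy()) {
  stopifnot(inherits(policy, "llq_policy"))
  need <- c("patient_id", "matrix", "time_min", "conc")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Concentration table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  n <- nrow(data)
  row_id <- seq_len(n)

  prior_blq <- if (is.null(data[["blq"]])) rep(FALSE, n) else as.logical(data$blq)
  conc_chr <- trimws(as.character(data$conc))
  token_blq <- (toupper(conc_chr) == "BLQ" & !is.na(conc_chr)) |
    (is.na(conc_chr) & prior_blq)
  conc_num <- suppressWarnings(as.numeric(conc_chr))
  bad_conc <- row_id[!token_blq & (is.na(conc_num) | conc_num < 0)]
  if (length(bad_conc)) {
    abort(paste0("Malformed `conc` (not a non-negative number or \"BLQ\") in row(s): ",
                 paste(head(bad_conc, 5L), collapse = ", "), "."))
  }

  time_num <- suppressWarnings(as.numeric(as.character(data$time_min)))
  bad_time <- row_id[is.na(time_num) | !is.finite(time_num) | time_num < 0]
  if (length(bad_time)) {
    abort(paste0("`time_min` must be finite and >= 0; offending row(s): ",
                 paste(head(bad_time, 5L), collapse = ", "), "."))
  }

  mat <- tolower(trimws(as.character(data$matrix)))
  bad_mat <- row_id[!mat %in% matrix_levels]
  if (length(bad_mat)) {
    abort(paste0("`matrix` must be one of ", paste(matrix_levels, collapse = "/"),
                 "; offending row(s): ", paste(head(bad_mat, 5L), collapse = ", "), "."))
  }

  out <- tibble::tibble(
    patient_id = as.character(data$patient_id),
    matrix = mat,
    time_min = time_num,
    conc = ifelse(token_blq, NA_real_, conc_num),
    blq = token_blq | (!token_blq & conc_num < policy$llq)
  )
  out$blq <- out$blq | prior_blq

  dup <- duplicated(out[c("patient_id", "matrix", "time_min")])
  if (any(dup)) {
    abort(paste0("Duplicate (patient_id, matrix, time_min) key(s) in row(s): ",
                 paste(head(row_id[dup], 5L), collapse = ", "), "."))
  }
  dplyr::arrange(out, .data$patient_id, .data$matrix, .data$time_min)
}

#' Write a concentration table
#'
#' Inverse of [read_concentration_table()]: token-BLQ samples (flagged with a
#' missing concentration) are written back as the literal `"BLQ"`; numeric
#' sub-LLQ values are written as numbers and re-flagged on reading, so a
#' write/read round trip reproduces the table field for field.
#'
#' @param data A validated concentration tibble.
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(data, path, delim = ",") {
  out <- dplyr::mutate(
    data,
    conc = ifelse(is.na(.data$conc) & .data$blq, "BLQ",
                  format(.data$conc, digits = 15, trim = TRUE, scientific = FALSE))
  )
  readr::write_delim(out[c("patient_id", "matrix", "time_min", "conc")],
                     path, delim = delim)
  invisible(path)
}

#' BSA-based carboplatin dose
#'
#' The HIPEC dose is scaled to body surface area at `dose_per_m2` mg/m2 and
#' capped: patients above `cap / dose_per_m2` m2 (2.0 m2 at the defaults)
#' receive the flat maximum. The result is rounded to the nearest mg.
#'
#' @param bsa Body surface area(s) in m2; must be positive.
#' @param dose_per_m2 Dose scaling, mg per m2 (default 800).
#' @param cap Maximum dose in mg (default 1600).
#' @return Dose(s) in mg, integer-valued.
#' @examples
#' compute_dose(1.92) # 1536
#' compute_dose(2.16) # capped at 1600
#' @export
compute_dose <- function(bsa, dose_per_m2 = 800, cap = 1600) {
  if (!is.numeric(bsa) || any(!is.finite(bsa)) || any(bsa <= 0)) {
    abort("`bsa` must be positive and finite (m2).")
  }
  pmin(round(dose_per_m2 * bsa), cap)
}

#' Drop below-LLQ samples before pharmacokinetic analysis
#'
#' Removes every BLQ-flagged sample (the exclusion policy; no imputation).
#' The number of samples removed per patient and matrix is attached as
#' attribute `"removed"`, and profiles left with fewer than three
#' quantifiable points — too few for terminal-slope estimation — are listed
#' in attribute `"non_evaluable"`. Retained concentration values are never
#' altered.
#'
#' @param data A validated concentration tibble (see
#'   [read_concentration_table()]).
#' @param policy An [llq_policy()]; present for interface symmetry, the
#'   flags in `data` already encode it.
#' @return The retained rows, with attributes `removed` and `non_evaluable`.
#'   Errors if no quantifiable sample remains at all.
#' @export
apply_llq_policy <- function(data, policy = llq_policy()) {
  stopifnot(inherits(policy, "llq_policy"))
  kept <- dplyr::filter(data, !.data$blq)
  removed <- data |>
    dplyr::filter(.data$blq) |>
    dplyr::count(.data$patient_id, .data$matrix, name = "n_removed")
  non_eval <- kept |>
    dplyr::count(.data$patient_id, .data$matrix, name = "n_quantifiable") |>
    tidyr::complete(
      tidyr::nesting(!!!dplyr::distinct(data, .data$patient_id, .data$matrix)),
      fill = list(n_quantifiable = 0L)
    ) |>
    dplyr::filter(.data$n_quantifiable < 3L)
  if (nrow(kept) == 0L) {
    abort("No quantifiable samples remain after LLQ exclusion: cohort is non-evaluable.")
  }
  attr(kept, "removed") <- removed
  attr(kept, "non_evaluable") <- non_eval
  kept
}

#' Read a patient metadata table
#'
#' Columns required: `patient_id`, `bsa` (m2), `dose` (mg), `pci` (0-39),
#' `peritonectomy` (`minor`/`major`), `crs_timing` (`upfront`/`interval`),
#' `perfusate_volume_abdomen` (L, the volume retained intra-abdominally).
#' Extra columns are kept as-is.
#'
#' @param path Path to a delimited text file (comma or tab).
#' @param delim Field delimiter; `NULL` guesses.
#' @return A validated tibble.
#' @export
read_patient_table <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_patient_table(out)
}

validate_patient_table <- function(data) {
  need <- c("patient_id", "bsa", "dose", "pci", "peritonectomy", "crs_timing")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Patient table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  data$patient_id <- as.character(data$patient_id)
  data$peritonectomy <- tolower(as.character(data$peritonectomy))
  data$crs_timing <- tolower(as.character(data$crs_timing))
  if (any(!is.finite(data$bsa) | data$bsa <= 0 | data$bsa >= 3)) {
    abort("`bsa` must lie in (0, 3) m2.")
  }
  if (any(!is.finite(data$pci) | data$pci < 0 | data$pci > 39)) {
    abort("`pci` must lie in [0, 39].")
  }
  if (any(!data$peritonectomy %in% c("minor", "major"))) {
    abort("`peritonectomy` must be \"minor\" or \"major\".")
  }
  if (any(!data$crs_timing %in% c("upfront", "interval"))) {
    abort("`crs_timing` must be \"upfront\" or \"interval\".")
  }
  if (anyDuplicated(data$patient_id)) abort("Duplicate `patient_id` in patient table.")
  tibble::as_tibble(data)
}

#' Check recorded doses against the dosing rule
#'
#' @param patients A patient tibble (see [read_patient_table()]).
#' @inheritParams compute_dose
#' @return Tibble of patients whose recorded dose differs from
#'   `compute_dose(bsa)`, with the expected dose; zero rows when all conform.
#' @export
check_dose_rule <- function(patients, dose_per_m2 = 800, cap = 1600) {
  patients |>
    dplyr::mutate(dose_expected = compute_dose(.data$bsa, dose_per_m2, cap)) |>
    dplyr::filter(.data$dose != .data$dose_expected) |>
    dplyr::select("patient_id", "bsa", "dose", "dose_expected")
}

#' Read a serial complete-blood-count table
#'
#' Long-by-day table with columns `patient_id`, `day` (integer, relative to
#' surgery: -1 is the preoperative baseline, 0 the day of surgery) and any of
#' `hemoglobin` (mmol/L), `neutrophils`, `platelets`, `leukocytes`
#' (10^9/L). Any analyte may be missing (`NA`) on any day.
#'
#' @inheritParams read_patient_table
#' @return A validated tibble sorted by (patient_id, day).
#' @export
read_cbc_table <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_cbc_table(out)
}

cbc_analytes <- c("hemoglobin", "neutrophils", "platelets", "leukocytes")

validate_cbc_table <- function(data) {
  if (!all(c("patient_id", "day") %in% names(data))) {
    abort("CBC table needs columns `patient_id` and `day`.")
  }
  present <- intersect(cbc_analytes, names(data))
  if (!length(present)) {
    abort(paste0("CBC table needs at least one analyte column among: ",
                 paste(cbc_analytes, collapse = ", "), "."))
  }
  data$patient_id <- as.character(data$patient_id)
  if (any(data$day != round(data$day))) abort("`day` must be integer-valued.")
  data$day <- as.integer(data$day)
  for (a in present) {
    v <- data[[a]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      abort(paste0("Analyte `", a, "` has negative or non-finite values."))
    }
  }
  if (anyDuplicated(data[c("patient_id", "day")])) {
    abort("Duplicate (patient_id, day) rows in CBC table.")
  }
  dplyr::arrange(tibble::as_tibble(data), .data$patient_id, .data$day)
}

#' Published 15-patient carboplatin-HIPEC validation cohort
#'
#' Per-patient surgical/HIPEC details (`reference_patients()`) and
#' noncompartmental pharmacokinetic results (`reference_nca()`) from a
#' published cohort of 15 women with advanced epithelial ovarian cancer who
#' received cytoreductive surgery and 90 min carboplatin HIPEC at
#' 800 mg/m2 (capped at 1600 mg). These tables ship with the package as
#' plain-text CSVs and serve as the fixture against which the summary
#' statistics, the group comparison and the dosing rule are validated.
#'
#' @return A tibble: one row per patient. `reference_nca()` has the
#'   per-patient Cmax (ug/mL), terminal half-lives (min), windowed AUCs
#'   (min.ug/mL) and the intraperitoneal-to-plasma AUC ratio for both the
#'   perfusate (`_pf`) and plasma (`_pl`) matrices.
#' @export
reference_patients <- function() {
  path <- system.file("extdata", "reference_patients.csv", package = "hipecpk",
                      mustWork = TRUE)
  validate_patient_table(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' @rdname reference_patients
#' @export
reference_nca <- function() {
  path <- system.file("extdata", "reference_nca.csv", package = "hipecpk",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$patient_id <- as.character(out$patient_id)
  out
}
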