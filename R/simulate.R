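#' Sampling schedules
#'
#' The perfusate is sampled from the joined outflow catheters at 0, 5, 7.5,
#' 10, 20, 30, 40, 50, 60, 70, 80 and 90 min of perfusion; blood at 0, 15,
#' 30, 45, 60, 75 and 90 min of perfusion and 8, 16, 24 and 48 h after its
#' start (480, 960, 1440, 2880 min). Serial blood counts are taken the day
#' before surgery, daily on postoperative days 1-7, and on days 14, 21
#' and 30.
#'
#' @return Numeric vector of sampling times (minutes for the concentration
#'   schedules, days relative to surgery for [cbc_schedule()]).
#' @export
perfusate_schedule <- function() c(0, 5, 7.5, 10, 20, 30, 40, 50, 60, 70, 80, 90)

#' @rdname perfusate_schedule
#' @export
plasma_schedule <- function() c(0, 15, 30, 45, 60, 75, 90, 480, 960, 1440, 2880)

#' @rdname perfusate_schedule
#' @export
cbc_schedule <- function() c(-1L, 1:7, 14L, 21L, 30L)

#' Configuration of the perfusate-to-plasma kinetic simulator
#'
#' The simulator is a two-compartment model: the drug is instilled as a
#' single dose into the peritoneal perfusate, transfers to plasma by
#' first-order absorption (`ka`) and is eliminated from plasma by
#' first-order elimination (`ke`); at `drain_time` the perfusate is removed
#' and only plasma elimination continues. Defaults are calibrated so that a
#' default cohort's noncompartmental geometric means land near the observed
#' clinical values: `ka = ln2/104` (perfusate half-life 104 min),
#' `ke = ln2/160` (plasma terminal half-life 160 min), effective perfusate
#' volume 4.2 L (smaller than the 5 L carrier because the drug concentrates
#' as the saline carrier is absorbed faster), central plasma volume 15 L.
#'
#' @param ka Perfusate-to-plasma first-order transfer constant, 1/min.
#' @param ke Plasma first-order elimination constant, 1/min.
#' @param v_pf Effective perfusate distribution volume, L.
#' @param v_c Central plasma distribution volume, L.
#' @param drain_time End of perfusion (perfusate removal), min.
#' @param dose_per_m2,dose_cap Dosing rule, mg/m2 and mg (see
#'   [compute_dose()]).
#' @param bsa_mean,bsa_sd,bsa_range Truncated-normal body-surface-area
#'   distribution (m2) the cohort is drawn from.
#' @param iiv_cv Lognormal interindividual coefficient of variation applied
#'   to `ka`, `ke`, `v_pf` and `v_c` (default 0.20).
#' @param assay_cv Proportional lognormal assay error (default 0.08; the
#'   assay's coefficient of variation is below 10%).
#' @param llq Lower limit of quantification, ug/mL; simulated observations
#'   below it are emitted as BLQ.
#' @param perfusate_times,plasma_times Sampling grids in minutes.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(ka = log(2) / 104, ke = log(2) / 160,
                              v_pf = 4.2, v_c = 15, drain_time = 90,
                              dose_per_m2 = 800, dose_cap = 1600,
                              bsa_mean = 1.83, bsa_sd = 0.21,
                              bsa_range = c(1.42, 2.16),
                              iiv_cv = 0.20, assay_cv = 0.08, llq = 0.01,
                              perfusate_times = perfusate_schedule(),
                              plasma_times = plasma_schedule()) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  for (f in c("ka", "ke", "v_pf", "v_c", "drain_time", "dose_per_m2",
              "dose_cap", "bsa_mean", "bsa_sd", "llq")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      abort(paste0("`", f, "` must be a single positive number."))
    }
  }
  if (cfg$iiv_cv < 0 || cfg$assay_cv < 0) abort("CVs must be >= 0.")
  if (cfg$drain_time > max(cfg$perfusate_times)) {
    abort("`drain_time` must lie within the perfusate sampling schedule.")
  }
  if (diff(cfg$bsa_range) <= 0) abort("`bsa_range` must be increasing.")
  cfg
}

#' Closed-form concentration profiles of the two-compartment model
#'
#' For dose D instilled in the perfusate at t = 0, the amounts are
#' `A_pf(t) = D exp(-ka t)` up to the drain and 0 after, and
#' `A_pl(t) = D ka/(ka - ke) (exp(-ke t) - exp(-ka t))` up to the drain,
#' followed by pure elimination `A_pl(drain) exp(-ke (t - drain))`. When
#' `ka = ke` the limiting form `D ka t exp(-ka t)` is used. Concentrations
#' are amounts divided by the respective distribution volumes (mg/L, i.e.
#' ug/mL). The cumulative eliminated amount completes the mass balance:
#' for t up to the drain, `A_pf + A_pl + eliminated = D` identically.
#'
#' @inheritParams simulation_config
#' @param dose Dose in mg.
#' @return List of vectorised functions of time (min): `amount_pf`,
#'   `amount_pl`, `eliminated` (mg) and `conc_pf`, `conc_pl` (ug/mL).
#' @export
analytic_profiles <- function(ka, ke, dose, v_pf, v_c, drain_time = 90) {
  stopifnot(ka > 0, ke > 0, dose > 0, v_pf > 0, v_c > 0, drain_time > 0)
  amount_pl_perf <- if (ka == ke) {
    function(t) dose * ka * t * exp(-ka * t)
  } else {
    function(t) dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
  eliminated_perf <- if (ka == ke) {
    function(t) dose * (1 - exp(-ka * t) * (1 + ka * t))
  } else {
    function(t) {
      dose * ka / (ka - ke) *
        ((1 - exp(-ke * t)) / ke - (1 - exp(-ka * t)) / ka) * ke
    }
  }
  a_drain <- amount_pl_perf(drain_time)
  e_drain <- eliminated_perf(drain_time)
  amount_pf <- function(t) ifelse(t <= drain_time, dose * exp(-ka * t), 0)
  amount_pl <- function(t) {
    ifelse(t <= drain_time, amount_pl_perf(t),
           a_drain * exp(-ke * (t - drain_time)))
  }
  eliminated <- function(t) {
    ifelse(t <= drain_time, eliminated_perf(t),
           e_drain + a_drain * (1 - exp(-ke * (t - drain_time))))
  }
  list(
    amount_pf = amount_pf, amount_pl = amount_pl, eliminated = eliminated,
    conc_pf = function(t) amount_pf(t) / v_pf,
    conc_pl = function(t) amount_pl(t) / v_c
  )
}

draw_truncnorm <- function(mean, sd, range) {
  for (i in 1:1000) {
    x <- rnorm(1L, mean, sd)
    if (x >= range[1L] && x <= range[2L]) return(x)
  }
  mean
}

lnorm_mult <- function(n, cv) {
  # median-1 lognormal multiplier with the requested coefficient of variation
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

patient_seed <- function(seed, i) (seed + 104729 * i) %% 2147483647L

#' Simulate one patient's dual-matrix concentration profiles
#'
#' Draws individual kinetic parameters lognormally around the configured
#' values (median-preserving, CV `iiv_cv`), evaluates the closed-form
#' profiles on the configured sampling schedules, applies proportional
#' lognormal assay error, and censors observations below the LLQ as BLQ.
#' Fully reproducible from `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param patient_id Identifier for the emitted samples.
#' @param seed Integer seed for this patient's stream.
#' @param bsa Body surface area; drawn from the configured distribution
#'   when `NULL`.
#' @param peritonectomy,crs_timing Group labels carried into the truth row.
#' @return List with `truth` (one-row tibble of the realised parameters)
#'   and `samples` (validated concentration tibble, both matrices).
#' @export
simulate_patient <- function(config = simulation_config(), patient_id = "1",
                             seed = 1L, bsa = NULL,
                             peritonectomy = "minor", crs_timing = "interval") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  if (is.null(bsa)) {
    bsa <- draw_truncnorm(config$bsa_mean, config$bsa_sd, config$bsa_range)
  }
  dose <- compute_dose(bsa, config$dose_per_m2, config$dose_cap)
  mult <- lnorm_mult(4L, config$iiv_cv)
  ka <- config$ka * mult[1L]
  ke <- config$ke * mult[2L]
  v_pf <- config$v_pf * mult[3L]
  v_c <- config$v_c * mult[4L]
  prof <- analytic_profiles(ka, ke, dose, v_pf, v_c, config$drain_time)

  emit <- function(times, conc_fn, matrix) {
    true_conc <- conc_fn(times)
    obs <- true_conc * lnorm_mult(length(times), config$assay_cv)
    blq <- obs < config$llq
    tibble::tibble(
      patient_id = as.character(patient_id), matrix = matrix,
      time_min = times, conc = ifelse(blq, NA_real_, obs), blq = blq
    )
  }
  samples <- dplyr::bind_rows(
    emit(config$perfusate_times, prof$conc_pf, "perfusate"),
    emit(config$plasma_times, prof$conc_pl, "plasma")
  )
  truth <- tibble::tibble(
    patient_id = as.character(patient_id), bsa = bsa, dose = dose,
    ka = ka, ke = ke, v_pf = v_pf, v_c = v_c,
    t_half_pf_true = log(2) / ka, t_half_pl_true = log(2) / ke,
    peritonectomy = peritonectomy, crs_timing = crs_timing
  )
  list(truth = truth, samples = as_concentration_table(
    samples, llq_policy(llq = config$llq)))
}

#' Simulate a HIPEC cohort
#'
#' Generates `n` patients with body surface areas from the configured
#' truncated-normal distribution, doses via the BSA rule,
#' minor/major peritonectomy labels in a 9:6 proportion (upfront/interval
#' timing 4:11) and per-patient concentration tables ready for
#' [run_nca()]. Each patient draws from a substream derived
#' deterministically from the master seed, so enlarging the cohort does not
#' reshuffle existing patients.
#'
#' @param n Number of patients (>= 2), default 15.
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @return List of tibbles: `patients` (metadata table), `concentrations`
#'   (both matrices, BLQ-flagged) and `truth` (realised individual
#'   parameters).
#' @export
simulate_cohort <- function(n = 15L, config = simulation_config(), seed = 1L) {
  stopifnot(n >= 2L)
  n_major <- round(n * 6 / 15)
  n_upfront <- round(n * 4 / 15)
  perit <- rep("minor", n)
  if (n_major > 0) perit[unique(round(seq(2, n, length.out = n_major)))] <- "major"
  timing <- rep("interval", n)
  if (n_upfront > 0) timing[unique(round(seq(1, n, length.out = n_upfront)))] <- "upfront"

  sims <- purrr::map(seq_len(n), function(i) {
    simulate_patient(config, patient_id = as.character(i),
                     seed = patient_seed(seed, i),
                     peritonectomy = perit[i], crs_timing = timing[i])
  })
  truth <- purrr::list_rbind(purrr::map(sims, "truth"))
  set.seed(patient_seed(seed, 0L))
  patients <- tibble::tibble(
    patient_id = truth$patient_id,
    bsa = truth$bsa, dose = truth$dose,
    pci = pmin(pmax(round(rlnorm(n, log(9), 0.45)), 3L), 22L),
    peritonectomy = truth$peritonectomy, crs_timing = truth$crs_timing,
    perfusate_volume_abdomen = round(stats::runif(n, 1.8, 3.9), 1)
  )
  list(patients = validate_patient_table(patients),
       concentrations = purrr::list_rbind(purrr::map(sims, "samples")),
       truth = truth)
}

grade_band_target <- function(analyte, grade, thresholds) {
  bounds <- c(thresholds[[analyte]]$lln, thresholds[[analyte]]$cuts)
  if (grade < 1L || grade > length(bounds)) {
    abort(paste0("Grade ", grade, " has no laboratory band for ", analyte, "."))
  }
  upper <- bounds[grade]
  lower <- if (grade < length(bounds)) bounds[grade + 1L] else 0
  (lower + upper) / 2
}

#' Simulate a serial complete-blood-count course
#'
#' Produces a baseline-normal CBC series on the standard surveillance
#' schedule with mild proportional noise, optionally injecting (a) a smooth
#' toxicity dip whose nadir reaches the midpoint of a requested CTCAE grade
#' band on a requested day, and (b) a surgery-related day-1 drop in
#' hemoglobin and/or platelets that recovers thereafter — the pattern the
#' day-0/1 exclusion rule of [assess_course()] must not count.
#'
#' @param patient_id Identifier.
#' @param event_spec `NULL`, or a list/data frame with fields `analyte`
#'   (measurement name or clinical toxicity name), `grade` (target CTCAE
#'   grade) and `day` (nadir day); if `day` is not on the schedule the
#'   nearest scheduled day is used with a message.
#' @param seed Integer seed.
#' @param baseline Named vector of healthy baseline values (hemoglobin
#'   mmol/L, counts 10^9/L).
#' @param surgery_dip `NULL`, or a named vector of day-1 values for
#'   `hemoglobin` and/or `platelets` (e.g. `c(platelets = 45)`).
#' @param noise_cv Proportional lognormal noise on non-nadir days.
#' @param thresholds A [ctcae_thresholds()] object defining the bands.
#' @param days Sampling days relative to surgery.
#' @return A validated CBC tibble (one row per day).
#' @export
simulate_cbc <- function(patient_id = "1", event_spec = NULL, seed = 1L,
                         baseline = c(hemoglobin = 8.2, neutrophils = 4.5,
                                      platelets = 280, leukocytes = 7.5),
                         surgery_dip = NULL, noise_cv = 0.03,
                         thresholds = ctcae_thresholds(),
                         days = cbc_schedule()) {
  set.seed(seed)
  vals <- purrr::map(names(baseline), function(a) {
    base <- baseline[[a]]
    v <- base * lnorm_mult(length(days), noise_cv)
    if (!is.null(surgery_dip) && a %in% names(surgery_dip)) {
      post <- days >= 1
      dip <- surgery_dip[[a]]
      v[post] <- base - (base - dip) * exp(-(days[post] - 1) / 2)
      v[days == 1] <- dip
    }
    v
  })
  names(vals) <- names(baseline)
  out <- tibble::as_tibble(c(list(patient_id = as.character(patient_id),
                                  day = as.integer(days)), vals))

  if (!is.null(event_spec)) {
    spec <- as.data.frame(event_spec, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(spec))) {
      a <- as.character(spec$analyte[i])
      if (a %in% toxicity_names) a <- names(toxicity_names)[toxicity_names == a]
      if (!a %in% names(out)) abort(paste0("Unknown analyte in event_spec: ", a))
      day <- spec$day[i]
      if (!day %in% days) {
        day <- days[which.min(abs(days - day))]
        inform(paste0("Nadir day ", spec$day[i],
                      " is not on the schedule; using nearest day ", day, "."))
      }
      target <- grade_band_target(a, as.integer(spec$grade[i]), thresholds)
      base <- baseline[[a]]
      depth <- 1 - target / base
      dip_days <- out$day >= 1
      shape <- depth * exp(-((out$day[dip_days] - day) / 3)^2)
      out[[a]][dip_days] <- pmin(out[[a]][dip_days],
                                 base * (1 - shape) * lnorm_mult(sum(dip_days), noise_cv / 3))
      out[[a]][out$day == day] <- target
    }
  }
  validate_cbc_table(out)
}
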