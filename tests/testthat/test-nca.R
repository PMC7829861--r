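test_that("cmax returns the maximum and the earliest time attaining it", {
  expect_equal(
    cmax(data.frame(time_min = c(0, 5, 10), conc = c(0, 100, 100))),
    tibble::tibble(cmax = 100, tmax = 5))
  expect_equal(
    cmax(data.frame(time_min = c(10, 30, 50), conc = c(7, 7, 7))),
    tibble::tibble(cmax = 7, tmax = 10))
  expect_error(cmax(data.frame(time_min = numeric(), conc = numeric())),
               "Empty profile")
})

test_that("lambda-z recovers exact exponentials to machine precision", {
  # perfusate-like: declining from t = 0 on the intraperfusion schedule
  sched <- perfusate_schedule()
  prof <- data.frame(time_min = sched, conc = 100 * exp(-log(2) / 104 * sched))
  for (sel in c("maximal", "best_adj_r2")) {
    fit <- fit_lambda_z(prof, selection = sel)
    expect_true(fit$evaluable)
    expect_equal(fit$lambda_z, log(2) / 104, tolerance = 1e-10)
    expect_equal(half_life(fit), 104, tolerance = 1e-10)
  }
  # three post-perfusion plasma points, monotone declining
  prof3 <- data.frame(time_min = c(480, 960, 1440),
                      conc = 30 * exp(-log(2) / 160 * c(480, 960, 1440)))
  expect_equal(half_life(fit_lambda_z(prof3)), 160, tolerance = 1e-10)
})

test_that("half_life inverts lambda-z and scales inversely", {
  expect_equal(half_life(log(2) / 104), 104)
  expect_equal(half_life(log(2) / 63), 63)
  lz <- log(2) / 120
  expect_equal(half_life(2 * lz), half_life(lz) / 2)
  expect_error(half_life(-0.01), "positive")
})

test_that("half-life is reported missing, never fabricated", {
  # too few eligible points after the peak
  rising <- data.frame(time_min = c(0, 15, 30, 45), conc = c(0.1, 5, 20, 31))
  fit <- fit_lambda_z(rising)
  expect_false(fit$evaluable)
  expect_true(is.na(half_life(fit)))
  # monotone rising: no declining window exists
  up <- data.frame(time_min = c(0, 10, 20, 30, 40), conc = c(1, 2, 4, 8, 16))
  expect_false(fit_lambda_z(up)$evaluable)
})

test_that("best-adjusted-R2 window selection matches exhaustive enumeration", {
  set.seed(2024)
  n_match <- 0L
  for (i in 1:120) {
    prof <- random_terminal_profile(n_points = sample(6:12, 1),
                                    thalf = runif(1, 60, 200),
                                    cv = runif(1, 0.02, 0.25))
    fit <- fit_lambda_z(prof, selection = "best_adj_r2")
    oracle <- brute_force_lambda_window(prof)
    if (is.null(oracle)) {
      expect_false(fit$evaluable)
    } else {
      expect_equal(fit$n_points, oracle$k)
      expect_equal(fit$t_first, oracle$t_first)
      expect_equal(fit$lambda_z, -oracle$slope, tolerance = 1e-12)
      n_match <- n_match + 1L
    }
  }
  expect_gte(n_match, 100L)
})

test_that("the maximal rule takes the largest declining post-peak window", {
  tt <- seq(10, 100, by = 10)
  prof <- data.frame(time_min = tt, conc = 80 * exp(-0.01 * tt))
  fit <- fit_lambda_z(prof, selection = "maximal")
  expect_equal(fit$n_points, 10L) # monotone: every point is eligible
  expect_equal(fit$t_first, 10)
  # with a rising limb, the window is every point strictly after the peak
  set.seed(7)
  prof2 <- random_terminal_profile(n_points = 10, thalf = 120, cv = 0.1)
  fit2 <- fit_lambda_z(prof2, selection = "maximal")
  tmax2 <- prof2$time_min[which.max(prof2$conc)]
  eligible <- if (tmax2 > min(prof2$time_min)) {
    sum(prof2$time_min > tmax2)
  } else {
    nrow(prof2)
  }
  expect_equal(fit2$n_points, eligible)
})

test_that("trapezoidal AUC reproduces simple geometry and closed forms", {
  const <- data.frame(time_min = c(0, 30, 60, 90), conc = 12)
  expect_equal(auc_trapezoid(const, 0, 90), 90 * 12)
  tri <- data.frame(time_min = c(0, 90), conc = c(0, 29))
  expect_equal(auc_trapezoid(tri, 0, 90), 1305)
  # fine grid against the analytic integral of an exponential
  tt <- seq(0, 90, by = 0.1)
  expo <- data.frame(time_min = tt, conc = 348 * exp(-0.00667 * tt))
  analytic <- 348 / 0.00667 * (1 - exp(-0.00667 * 90))
  expect_equal(auc_trapezoid(expo, 0, 90), analytic, tolerance = 1e-4)
  expect_equal(auc_trapezoid(expo, 0, 90, method = "linear_up_log_down"),
               analytic, tolerance = 1e-7)
})

test_that("AUC is additive over adjacent windows and interpolates bounds", {
  set.seed(31)
  for (method in c("linear", "linear_up_log_down")) {
    for (i in 1:20) {
      prof <- random_terminal_profile(n_points = 9, thalf = 90, cv = 0.3)
      cut <- runif(1, min(prof$time_min) + 1, max(prof$time_min) - 1)
      whole <- auc_trapezoid(prof, min(prof$time_min), max(prof$time_min), method)
      parts <- auc_trapezoid(prof, min(prof$time_min), cut, method) +
        auc_trapezoid(prof, cut, max(prof$time_min), method)
      expect_equal(whole, parts, tolerance = 1e-10)
    }
  }
})

test_that("a sample at or above the interpolated chord never lowers linear AUC", {
  set.seed(77)
  for (i in 1:25) {
    prof <- random_terminal_profile(n_points = 7, thalf = 110, cv = 0.2)
    t0 <- min(prof$time_min); t1 <- max(prof$time_min)
    base <- auc_trapezoid(prof, t0, t1)
    tin <- runif(1, t0 + 0.5, t1 - 0.5)
    chord <- stats::approx(prof$time_min, prof$conc, xout = tin)$y
    aug <- rbind(prof, data.frame(time_min = tin, conc = chord + rexp(1, 2)))
    expect_gte(auc_trapezoid(aug, t0, t1), base - 1e-10)
  }
})

test_that("AUC refuses bounds outside the sampled range", {
  prof <- data.frame(time_min = c(10, 50, 90), conc = c(5, 4, 3))
  expect_error(auc_trapezoid(prof, 0, 90), "extrapolation")
  expect_error(auc_trapezoid(prof, 10, 120), "extrapolation")
  expect_error(auc_trapezoid(prof, 50, 50), "t_start < t_end")
})

test_that("auc_ratio reproduces per-patient exposure ratios at report rounding", {
  expect_equal(round(auc_ratio(25865, 1572), 1), 16.5)
  expect_equal(round(auc_ratio(17671, 2384), 1), 7.4)
  expect_equal(auc_ratio(1234.5, 1234.5), 1)
  expect_error(auc_ratio(100, 0), "positive")
})

test_that("run_nca recovers the generating kinetics from a noiseless patient", {
  cfg <- simulation_config(iiv_cv = 0, assay_cv = 0)
  sim <- simulate_patient(cfg, patient_id = "X", seed = 5, bsa = 1.82)
  res <- run_nca(sim$samples)
  expect_equal(res$t_half_pf, 104, tolerance = 0.02)
  expect_equal(res$t_half_pl, 160, tolerance = 0.02)
  expect_equal(res$cmax_pf, compute_dose(1.82) / 4.2, tolerance = 1e-10)
  expect_equal(res$tmax_pl, 90)
  expect_true(res$auc_total_pl > res$auc90_pl)
})

test_that("fine-grid NCA matches the closed form within 0.1%", {
  cfg <- simulation_config(iiv_cv = 0, assay_cv = 0,
                           perfusate_times = seq(0, 90, by = 0.1),
                           plasma_times = seq(0, 1440, by = 0.5))
  sim <- simulate_patient(cfg, seed = 2, bsa = 1.82)
  res <- run_nca(sim$samples)
  dose <- compute_dose(1.82)
  prof <- analytic_profiles(cfg$ka, cfg$ke, dose, cfg$v_pf, cfg$v_c, 90)
  auc90_pf_true <- dose / cfg$v_pf / cfg$ka * (1 - exp(-cfg$ka * 90))
  auc90_pl_true <- dose * cfg$ka / (cfg$ka - cfg$ke) / cfg$v_c *
    ((1 - exp(-cfg$ke * 90)) / cfg$ke - (1 - exp(-cfg$ka * 90)) / cfg$ka)
  expect_equal(res$t_half_pf, 104, tolerance = 1e-3)
  expect_equal(res$t_half_pl, 160, tolerance = 1e-3)
  expect_equal(res$auc90_pf, auc90_pf_true, tolerance = 1e-3)
  expect_equal(res$auc90_pl, auc90_pl_true, tolerance = 1e-3)
})

test_that("the exposure ratio is dose-invariant in a noiseless cohort", {
  cfg <- simulation_config(iiv_cv = 0, assay_cv = 0)
  co <- simulate_cohort(n = 5, config = cfg, seed = 9)
  res <- run_nca(co$concentrations, co$patients)
  expect_equal(diff(range(res$auc_ratio)), 0, tolerance = 1e-9)
  expect_equal(diff(range(res$t_half_pf)), 0, tolerance = 1e-9)
})

test_that("partial evaluability: two plasma points lose T1/2 but keep Cmax", {
  conc <- as_concentration_table(tibble::tibble(
    patient_id = "P9",
    matrix = c(rep("perfusate", 12), "plasma", "plasma"),
    time_min = c(perfusate_schedule(), 60, 90),
    conc = c(300 * exp(-0.006 * perfusate_schedule()), 20, 25)
  ))
  res <- run_nca(conc)
  expect_true(is.na(res$t_half_pl))
  expect_equal(res$cmax_pl, 25)
  expect_false(is.na(res$t_half_pf))
  expect_match(paste(attr(res, "notes"), collapse = " "), "plasma")
})
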