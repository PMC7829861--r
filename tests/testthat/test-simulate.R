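test_that("closed-form profiles honour initial conditions and limits", {
  prof <- analytic_profiles(ka = log(2) / 104, ke = log(2) / 160,
                            dose = 1456, v_pf = 4.2, v_c = 15)
  expect_equal(prof$conc_pf(0), 1456 / 4.2)
  expect_equal(prof$conc_pl(0), 0)
  expect_equal(prof$eliminated(0), 0)
  # vanishing elimination: everything absorbed by the drain is still in plasma
  slow <- analytic_profiles(ka = log(2) / 104, ke = 1e-10, dose = 1456,
                            v_pf = 4.2, v_c = 15)
  expect_equal(slow$amount_pl(90), 1456 * (1 - exp(-log(2) / 104 * 90)),
               tolerance = 1e-6)
  # perfusate ceases to exist at the drain
  expect_equal(prof$amount_pf(90.1), 0)
  expect_gt(prof$amount_pl(90), prof$amount_pl(200))
})

test_that("closed forms agree with independent numerical ODE integration", {
  ka <- log(2) / 104; ke <- log(2) / 160; dose <- 1456
  rhs <- function(t, y, p) {
    list(c(-ka * y[1], ka * y[1] - ke * y[2], ke * y[2]))
  }
  times <- seq(0, 90, by = 5)
  num <- deSolve::lsoda(c(pf = dose, pl = 0, el = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  prof <- analytic_profiles(ka, ke, dose, v_pf = 4.2, v_c = 15)
  expect_equal(unname(num[, "pf"]), prof$amount_pf(times), tolerance = 1e-8)
  expect_equal(unname(num[, "pl"]), prof$amount_pl(times), tolerance = 1e-8)
  expect_equal(unname(num[, "el"]), prof$eliminated(times), tolerance = 1e-8)
})

test_that("mass is conserved to 1e-9 up to the drain, including ka == ke", {
  tgrid <- seq(0, 90, by = 0.5)
  prof <- analytic_profiles(log(2) / 104, log(2) / 160, 1456, 4.2, 15)
  total <- prof$amount_pf(tgrid) + prof$amount_pl(tgrid) + prof$eliminated(tgrid)
  expect_equal(total, rep(1456, length(tgrid)), tolerance = 1e-9)
  k <- log(2) / 120
  profeq <- analytic_profiles(k, k, 1000, 4.2, 15)
  totaleq <- profeq$amount_pf(tgrid) + profeq$amount_pl(tgrid) +
    profeq$eliminated(tgrid)
  expect_equal(totaleq, rep(1000, length(tgrid)), tolerance = 1e-9)
  # the ka == ke special case is continuous in ka
  near <- analytic_profiles(k * (1 + 1e-9), k, 1000, 4.2, 15)
  expect_equal(near$amount_pl(tgrid), profeq$amount_pl(tgrid), tolerance = 1e-6)
})

test_that("noise-free simulation reproduces the analytic profile exactly", {
  cfg <- simulation_config(iiv_cv = 0, assay_cv = 0)
  sim <- simulate_patient(cfg, seed = 3, bsa = 1.82)
  prof <- analytic_profiles(cfg$ka, cfg$ke, compute_dose(1.82),
                            cfg$v_pf, cfg$v_c, cfg$drain_time)
  pf <- sim$samples[sim$samples$matrix == "perfusate", ]
  expect_equal(pf$conc, prof$conc_pf(pf$time_min))
  pl <- sim$samples[sim$samples$matrix == "plasma" & !sim$samples$blq, ]
  expect_equal(pl$conc, prof$conc_pl(pl$time_min))
})

test_that("simulation is deterministic in (config, seed)", {
  a <- simulate_patient(seed = 17)
  b <- simulate_patient(seed = 17)
  expect_identical(a, b)
  ca <- simulate_cohort(n = 4, seed = 23)
  cb <- simulate_cohort(n = 4, seed = 23)
  expect_identical(ca, cb)
})

test_that("cohorts extend without reshuffling existing patients", {
  small <- simulate_cohort(n = 5, seed = 31)
  big <- simulate_cohort(n = 9, seed = 31)
  expect_equal(big$truth$ka[1:5], small$truth$ka)
  expect_equal(
    big$concentrations[big$concentrations$patient_id %in% as.character(1:5), ]$conc,
    small$concentrations$conc)
})

test_that("the 48 h plasma sample is censored below the LLQ", {
  sim <- simulate_patient(seed = 19)
  s48 <- sim$samples[sim$samples$matrix == "plasma" &
                       sim$samples$time_min == 2880, ]
  expect_true(s48$blq)
})

test_that("no emitted quantifiable sample lies below the LLQ", {
  for (seed in c(1, 7, 99)) {
    co <- simulate_cohort(n = 6, seed = seed)
    q <- co$concentrations[!co$concentrations$blq, ]
    expect_true(all(q$conc >= 0.01))
    expect_true(all(is.na(co$concentrations$conc[co$concentrations$blq])))
  }
})

test_that("faster absorption shortens perfusate half-life and the AUC ratio", {
  res <- purrr::map_dfr(c(0.5, 1, 2), function(f) {
    cfg <- simulation_config(ka = f * log(2) / 104, iiv_cv = 0, assay_cv = 0)
    run_nca(simulate_patient(cfg, seed = 1, bsa = 1.8)$samples)
  })
  expect_true(all(diff(res$t_half_pf) < 0))
  expect_true(all(diff(res$auc_ratio) < 0))
})

test_that("cohort tables carry the dosing rule and the 9:6 / 4:11 labels", {
  co <- simulate_cohort(n = 15, seed = 2)
  expect_equal(co$patients$dose, compute_dose(co$patients$bsa))
  expect_equal(sum(co$patients$peritonectomy == "minor"), 9L)
  expect_equal(sum(co$patients$peritonectomy == "major"), 6L)
  expect_equal(sum(co$patients$crs_timing == "upfront"), 4L)
  expect_true(all(co$patients$bsa >= 1.42 & co$patients$bsa <= 2.16))
  expect_error(simulate_cohort(n = 1), "n >= 2")
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(ka = -1), "positive")
  expect_error(simulation_config(llq = 0), "positive")
  expect_error(simulation_config(drain_time = 120), "schedule")
  expect_error(simulation_config(iiv_cv = -0.1), ">= 0")
})

test_that("an off-schedule nadir day snaps to the nearest sampling day", {
  expect_message(
    cbc <- simulate_cbc("P1", event_spec = list(analyte = "neutropenia",
                                                grade = 3, day = 11),
                        seed = 5),
    "nearest")
  ev <- assess_course(cbc)
  expect_true(ev$day_of_nadir[ev$analyte == "neutrophils"] %in% c(7L, 14L))
})
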