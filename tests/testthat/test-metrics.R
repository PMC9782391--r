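# Reporting pipeline: phases, volumes, MAC-hours, per-professional split,
# exclusions, aggregation.

phase_case <- function(n = 90, first_on = 0, last_on = 65, ps = 10, pe = 70,
                       et = 1.8, age = 40, fgf = 1, dial = 2,
                       cum = NULL, professionals = NULL,
                       case_date = as.Date(NA), case_id = "m-1") {
  t <- 0:(n - 1)
  d <- ifelse(t >= first_on & t <= last_on, dial, 0)
  m <- data.frame(t = t, fgf_total = fgf, dial_sevoflurane = d,
                  et_sevoflurane = ifelse(d > 0, et, 0))
  if (!is.null(cum)) m$cum_sevoflurane <- cum
  case_record(case_id, age, ps, pe, m, professionals = professionals,
              case_date = case_date)
}

test_that("phase segmentation follows the pseudocode boundaries", {
  ph <- compute_phases(phase_case(last_on = 65, ps = 10, pe = 70))
  expect_equal(ph$induction, c(0, 10))
  expect_equal(ph$maintenance, c(10, 65))
  expect_equal(ph$anesthetic_gas_stop, 65)

  # gas stop after procedure stop: the earlier time wins
  ph2 <- compute_phases(phase_case(n = 90, last_on = 80, ps = 10, pe = 70))
  expect_equal(ph2$maintenance, c(10, 70))

  # dial never above zero: empty phases, flagged
  ph3 <- compute_phases(phase_case(dial = 0))
  expect_true(ph3$empty)

  cs <- phase_case()
  cs$procedure_start <- NA_real_
  expect_error(compute_phases(cs), "procedure")
})

test_that("agent volume subtracts cumulative readings at window boundaries", {
  # cumulative reads 4.0 mL through the end of induction, 14.0 at the end of
  # maintenance
  n <- 90
  cum <- c(seq(0, 4, length.out = 10),         # t=0..9, induction
           seq(4.5, 14, length.out = 55),      # t=10..64, maintenance
           rep(14, 25))
  cs <- phase_case(cum = cum)
  # the fabricated cumulative trace intentionally disagrees with the
  # calculated path, which agent_volume reports with a warning
  v <- suppressWarnings(agent_volume(cs, c(10, 65), "sevoflurane"))
  expect_equal(as.numeric(v), 10.0)
  expect_equal(attr(v, "source"), "cumulative")

  # empty window and degenerate windows
  expect_equal(as.numeric(agent_volume(cs, c(20, 20), "sevoflurane")), 0)

  # decreasing cumulative series is a validation error
  bad <- cs
  bad$minutes$cum_sevoflurane[40] <- 0
  expect_error(agent_volume(bad, c(10, 65), "sevoflurane"), "decreases")
})

test_that("calculated volume path agrees with the per-minute agent formula", {
  cs <- const_case(n = 60, fgf = 1, dial = 2, pe = 60)
  v <- agent_volume(cs, c(0, 60), "sevoflurane")
  expect_equal(attr(v, "source"), "calculated")
  expect_equal(as.numeric(v), liquid_ml_consumed("sevoflurane", 1, 2, 60),
               tolerance = 1e-12)
})

test_that("MAC-hours integrate the end-tidal trace against age-adjusted MAC", {
  mac40 <- age_adjusted_mac_pct("sevoflurane", 40)
  # et held exactly at the patient's MAC for a 2-hour window: 2.0 MAC-hours
  cs <- phase_case(n = 140, last_on = 135, ps = 10, pe = 135, et = mac40)
  expect_equal(mac_hours(cs, c(10, 130), "sevoflurane"), 2.0)

  # zero end-tidal: zero MAC-hours (well-defined, distinct from missing)
  cs0 <- phase_case(et = 0)
  expect_equal(mac_hours(cs0, c(10, 65), "sevoflurane"), 0)

  # missing end-tidal records: an error, not zero
  csna <- const_case(n = 60, pe = 60)
  expect_error(mac_hours(csna, c(0, 60), "sevoflurane"), "end-tidal")

  # piecewise trace equals longhand per-minute integration
  set.seed(5)
  et_trace <- round(runif(55, 0.5, 2.5), 2)
  cs2 <- phase_case()
  cs2$minutes$et_sevoflurane[11:65] <- et_trace
  got <- mac_hours(cs2, c(10, 65), "sevoflurane")
  longhand <- sum(et_trace / mac40 / 60)   # per-minute MAC-minutes -> hours
  expect_equal(got, longhand, tolerance = 1e-12)
})

test_that("the efficiency metric assembles volume over MAC-hours", {
  mac40 <- age_adjusted_mac_pct("sevoflurane", 40)
  # 2 MAC-hours of maintenance with a cumulative volume delta of 10 mL
  n <- 140
  cum <- c(seq(0, 4, length.out = 10), seq(4.1, 14, length.out = 120),
           rep(14, 10))
  cs <- phase_case(n = n, last_on = 130, ps = 10, pe = 130, et = mac40,
                   cum = cum)
  met <- suppressWarnings(ml_per_mac_hour(cs))
  expect_equal(met$mac_hours, 2.0)
  expect_equal(met$set_agent_volume_ml, 10.0)
  expect_equal(met$ml_per_mac_hour, 5.0)

  # zero-volume case: 0 mL per MAC-hour, defined
  csz <- phase_case(et = 1.8)
  csz$minutes$cum_sevoflurane <- 0
  metz <- ml_per_mac_hour(csz)
  expect_equal(metz$ml_per_mac_hour, 0)

  # zero MAC-hours: flagged undefined, NA ratio
  cs0 <- phase_case(et = 0)
  met0 <- ml_per_mac_hour(cs0)
  expect_true(is.na(met0$ml_per_mac_hour))
  expect_match(met0$flags, "undefined_metric")

  # doubling FGF doubles volume and the ratio on the calculated path
  base <- ml_per_mac_hour(phase_case(fgf = 1), volume_source = "calculated")
  dbl <- ml_per_mac_hour(phase_case(fgf = 2), volume_source = "calculated")
  expect_equal(dbl$set_agent_volume_ml, 2 * base$set_agent_volume_ml)
  expect_equal(dbl$ml_per_mac_hour, 2 * base$ml_per_mac_hour)
})

test_that("professional metrics split maintenance and permit overlap", {
  profs <- data.frame(
    professional_id = c("att", "res-a", "res-b"),
    role = c("attending", "resident", "resident"),
    t_in = c(0, 0, 38), t_out = c(90, 38, 90))
  cs <- phase_case(n = 90, last_on = 89, ps = 10, pe = 66, et = 1.8,
                   professionals = profs)
  # maintenance [10, 66); residents split it at t=38: 28 minutes each
  pm <- per_professional_metrics(cs)
  case_met <- ml_per_mac_hour(cs)
  att <- pm[pm$professional_id == "att", ]
  ra <- pm[pm$professional_id == "res-a", ]
  rb <- pm[pm$professional_id == "res-b", ]

  # the attending covers the whole case and reproduces the case metrics
  expect_equal(att$set_agent_volume_ml, case_met$set_agent_volume_ml)
  expect_equal(att$mac_hours, case_met$mac_hours)
  expect_equal(att$ml_per_mac_hour, case_met$ml_per_mac_hour)

  # an even split under constant conditions: half the volume and MAC-hours
  # each, identical efficiency; double counting across roles is deliberate
  expect_equal(ra$set_agent_volume_ml, rb$set_agent_volume_ml)
  expect_equal(ra$set_agent_volume_ml + rb$set_agent_volume_ml,
               case_met$set_agent_volume_ml, tolerance = 1e-12)
  expect_equal(ra$mac_hours + rb$mac_hours, case_met$mac_hours,
               tolerance = 1e-12)
  expect_equal(ra$ml_per_mac_hour, case_met$ml_per_mac_hour)
  expect_equal(rb$ml_per_mac_hour, case_met$ml_per_mac_hour)

  # an interval reaching outside the recorded span is clipped with a warning
  p2 <- data.frame(professional_id = "x", role = "crna",
                   t_in = -5, t_out = 200)
  cs2 <- phase_case(professionals = p2)
  expect_warning(pm2 <- per_professional_metrics(cs2), "clipping")
  expect_equal(pm2$set_agent_volume_ml,
               ml_per_mac_hour(cs2)$set_agent_volume_ml)
})

test_that("per-professional volumes over any partition sum to the case volume", {
  set.seed(9)
  for (k in 1:10) {
    cut1 <- sample(15:40, 1); cut2 <- sample(45:60, 1)
    profs <- data.frame(professional_id = c("p1", "p2", "p3"),
                        role = "crna",
                        t_in = c(0, cut1, cut2), t_out = c(cut1, cut2, 90))
    cs <- phase_case(n = 90, last_on = 89, ps = 10, pe = 66,
                     et = runif(1, 0.8, 2.5), fgf = runif(1, 0.4, 3),
                     professionals = profs)
    pm <- per_professional_metrics(cs)
    expect_equal(sum(pm$set_agent_volume_ml),
                 ml_per_mac_hour(cs)$set_agent_volume_ml, tolerance = 1e-12)
  }
})

test_that("exclusion filters partition the cohort with per-case reasons", {
  loc <- phase_case(case_id = "loc-1")
  loc$location <- "non_or"
  multi <- phase_case(case_id = "multi-1")
  multi$minutes$dial_isoflurane <- c(rep(0, 40), 0.6, rep(0, 49))
  short <- phase_case(case_id = "short-1", first_on = 0, last_on = 13,
                      ps = 2, pe = 20)
  clean1 <- phase_case(case_id = "ok-1")
  clean2 <- phase_case(case_id = "ok-2")
  rep_ <- apply_exclusions(list(loc, multi, short, clean1, clean2))
  expect_setequal(rep_$included, c("ok-1", "ok-2"))
  expect_equal(nrow(rep_$excluded), 3L)
  expect_setequal(rep_$excluded$reason,
                  c("location", "multi_agent", "short_delivery"))
  # partition: every case is in exactly one side
  expect_setequal(c(rep_$included, rep_$excluded$case_id),
                  c("loc-1", "multi-1", "short-1", "ok-1", "ok-2"))

  # exactly 15 minutes of recorded delivery is included (strict <)
  b15 <- phase_case(case_id = "b15", first_on = 0, last_on = 14, ps = 2,
                    pe = 20)
  b14 <- phase_case(case_id = "b14", first_on = 0, last_on = 13, ps = 2,
                    pe = 20)
  rep2 <- apply_exclusions(list(b15, b14))
  expect_equal(rep2$included, "b15")
  expect_equal(rep2$excluded$reason, "short_delivery")

  empty <- apply_exclusions(list())
  expect_length(empty$included, 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("excluded cases never contribute to metrics or aggregates", {
  loc <- phase_case(case_id = "loc-1", case_date = as.Date("2021-02-10"))
  loc$location <- "labor_and_delivery"
  ok <- phase_case(case_id = "ok-1", case_date = as.Date("2021-02-12"))
  cfg <- alert_config()
  log <- run_engine_cohort(list(loc, ok), cfg)
  met <- cohort_metrics(list(loc, ok))
  expect_equal(met$case_id, "ok-1")
  agg <- aggregate_cohort(list(loc, ok), log)
  expect_equal(sum(agg$n_cases), 1L)
})

test_that("cohort aggregation is periodic, order-invariant, explicit about empty months", {
  c_jan <- phase_case(case_id = "jan", case_date = as.Date("2021-01-05"))
  c_mar <- phase_case(case_id = "mar", case_date = as.Date("2021-03-20"))
  cfg <- alert_config()
  log <- run_engine_cohort(list(c_jan, c_mar), cfg)
  agg <- aggregate_cohort(list(c_jan, c_mar), log)
  expect_setequal(agg$period, c("2021-01", "2021-02", "2021-03"))
  feb <- agg[agg$period == "2021-02", ]
  expect_equal(feb$n_cases, 0L)
  expect_true(is.na(feb$mean_ml_per_mac_hour))  # explicit null, not zero

  # single-case month: the mean is that case's value
  jan <- agg[agg$period == "2021-01", ]
  expect_equal(jan$mean_ml_per_mac_hour, ml_per_mac_hour(c_jan)$ml_per_mac_hour)

  # permutation invariance
  agg2 <- aggregate_cohort(list(c_mar, c_jan),
                           run_engine_cohort(list(c_mar, c_jan), cfg))
  ord <- order(agg$period, agg$agent)
  ord2 <- order(agg2$period, agg2$agent)
  expect_equal(agg[ord, ], agg2[ord2, ], ignore_attr = TRUE)
})

test_that("metrics survive an I/O round trip unchanged", {
  sim <- simulate_cohort(sim_params(n_cases = 8, seed = 21))
  cases <- strip_truth(sim$cases)
  d <- withr::local_tempdir()
  write_cases(cases, file.path(d, "coh"), format = "csv")
  back <- read_cases(file.path(d, "coh"), format = "csv")
  expect_equal(cohort_metrics(back), cohort_metrics(cases))
})
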