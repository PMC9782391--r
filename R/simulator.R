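# Synthetic operating-room cohort generator.
#
# Each case has the phase structure the advisory engine and the reporting
# pipeline expect: a high-flow induction segment before the procedure start,
# a maintenance segment whose FGF is drawn from a two-component mixture
# (a low-flow practice mode near 0.5 L/min and a high-flow mode near
# 2 L/min), and an emergence segment with the dial at zero and flows raised.
# End-tidal concentration relaxes exponentially toward the age-adjusted MAC
# times the target MAC multiple; cumulative liquid consumption is written
# exactly from the calculated-consumption formula, so the two volume paths
# in the metrics module agree by construction.
#
# Practitioner response is memoryless per firing episode: with probability
# `response_probability` an episode leads, after `response_latency` minutes,
# to FGF reduction below the threshold for the rest of maintenance. The
# latent draws are returned as a ground-truth table for recovery tests.

#' Simulation parameters
#'
#' Defaults describe a generic academic OR case mix: case duration
#' lognormal with median ~110 minutes, 5-15 minute inductions at ~6 L/min,
#' an even split between low-flow (~0.5 L/min) and high-flow (~2 L/min)
#' maintenance practice, mostly sevoflurane, adult-skewed ages, and a 70%
#' chance that a firing episode produces a flow reduction within 2 minutes.
#'
#' @param n_cases Number of cases.
#' @param seed RNG seed (integer); a fixed seed reproduces the cohort
#'   byte for byte.
#' @param duration_meanlog,duration_sdlog,duration_range Lognormal case
#'   duration (minutes), truncated to the range.
#' @param induction_range Integer range of induction length (minutes).
#' @param induction_fgf_mean,induction_fgf_sd Induction FGF (L/min).
#' @param maintenance_low_mean,maintenance_low_sd Low-flow mode (L/min).
#' @param maintenance_high_mean,maintenance_high_sd High-flow mode (L/min).
#' @param high_flow_weight Mixture weight of the high-flow mode.
#' @param fgf_jitter_sd Per-minute FGF measurement jitter (L/min). Zero by
#'   default: maintenance flow is a per-case draw from the mixture, held
#'   constant within each segment, so that episode counts on a fixed cohort
#'   are monotone in the engine threshold (minute-level noise around a sweep
#'   threshold would split episodes at counter resets).
#' @param agent_mix Named probabilities over the volatile agents.
#' @param age_mean,age_sd,age_range Truncated-normal patient age (years).
#' @param response_probability Probability a firing episode causes FGF
#'   reduction below the threshold.
#' @param response_latency Minutes from episode start to the reduction.
#' @param target_mac MAC multiple the end-tidal concentration is driven
#'   toward.
#' @param et_tau_minutes Exponential time constant of the end-tidal
#'   relaxation.
#' @param alert_threshold Threshold (L/min) the simulated practitioner
#'   responds relative to; kept equal to the engine config under study.
#' @param start_date,n_months Case dates are spread uniformly over this
#'   window for monthly aggregation.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_cases = 200, seed = 1,
                       duration_meanlog = log(110), duration_sdlog = 0.45,
                       duration_range = c(40, 480),
                       induction_range = c(5, 15),
                       induction_fgf_mean = 6, induction_fgf_sd = 0.5,
                       maintenance_low_mean = 0.5, maintenance_low_sd = 0.05,
                       maintenance_high_mean = 2.0, maintenance_high_sd = 0.3,
                       high_flow_weight = 0.5, fgf_jitter_sd = 0,
                       agent_mix = c(sevoflurane = 0.7, isoflurane = 0.15,
                                     desflurane = 0.15),
                       age_mean = 50, age_sd = 18, age_range = c(2, 95),
                       response_probability = 0.7, response_latency = 2,
                       target_mac = 1.0, et_tau_minutes = 3,
                       alert_threshold = 0.7,
                       start_date = as.Date("2021-01-01"), n_months = 6) {
  stopifnot(n_cases >= 0,
            response_probability >= 0, response_probability <= 1,
            high_flow_weight >= 0, high_flow_weight <= 1,
            abs(sum(agent_mix) - 1) < 1e-8,
            all(names(agent_mix) %in% volatile_agents()))
  structure(as.list(environment()), class = "sim_params")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

.case_seed <- function(seed, case_index) {
  as.integer((as.numeric(seed) * 48271 + case_index * 9973) %% 2147483629)
}

#' Simulate one operating-room case
#'
#' Deterministic given `(params, case_index)`: the per-case seed is derived
#' from the cohort seed and the index.
#'
#' @param params A `sim_params`.
#' @param case_index Positive integer index within the cohort.
#' @param constants Agent constants table.
#' @return A valid `case_record`; the latent draws are attached as the
#'   one-row data frame attribute `"truth"`.
#' @export
simulate_case <- function(params, case_index, constants = agent_constants()) {
  set.seed(.case_seed(params$seed, case_index))
  p <- params
  case_id <- sprintf("sim-%05d", case_index)

  agent <- sample(names(p$agent_mix), 1, prob = p$agent_mix)
  age <- .rtrunc_norm(1, p$age_mean, p$age_sd, p$age_range[1], p$age_range[2])
  mac <- age_adjusted_mac_pct(agent, age, constants)

  total <- round(pmin(pmax(stats::rlnorm(1, p$duration_meanlog,
                                         p$duration_sdlog),
                           p$duration_range[1]), p$duration_range[2]))
  ind <- sample(seq(p$induction_range[1], p$induction_range[2]), 1)
  emerge <- sample(3:8, 1)
  maint <- max(16, total - ind - emerge)
  ps <- ind                       # procedure start
  t_gs <- ps + maint              # anesthetic gas stop (first zero-dial minute)
  stop_gap <- sample(1:4, 1)
  pe <- t_gs + stop_gap           # procedure stop
  t_end <- pe + sample(2:5, 1)
  t <- 0:(t_end - 1)
  n <- length(t)

  high <- stats::runif(1) < p$high_flow_weight
  base_fgf <- if (high) {
    max(1.0, stats::rnorm(1, p$maintenance_high_mean, p$maintenance_high_sd))
  } else {
    min(max(0.25, stats::rnorm(1, p$maintenance_low_mean,
                               p$maintenance_low_sd)),
        p$alert_threshold - 0.02)
  }
  responded <- if (high) stats::runif(1) < p$response_probability else NA
  # in a high-flow case the flow condition is already satisfied throughout
  # induction, so the first firing episode opens at the procedure start
  response_onset <- if (isTRUE(responded)) ps + p$response_latency + 1 else NA_real_
  reduced_fgf <- min(max(0.25, stats::rnorm(1, p$maintenance_low_mean,
                                            p$maintenance_low_sd)),
                     p$alert_threshold - 0.02)

  fgf <- numeric(n)
  ind_idx <- t < ps
  maint_idx <- t >= ps & t < t_gs
  em_idx <- t >= t_gs
  fgf[ind_idx] <- .rtrunc_norm(sum(ind_idx), p$induction_fgf_mean,
                               p$induction_fgf_sd, 2, 10)
  m_fgf <- rep(base_fgf, sum(maint_idx))
  if (isTRUE(responded)) {
    tm <- t[maint_idx]
    m_fgf[tm >= response_onset] <- reduced_fgf
  }
  jit <- stats::rnorm(sum(maint_idx), 0, p$fgf_jitter_sd)
  m_fgf <- m_fgf + jit
  hi_part <- rep(base_fgf, sum(maint_idx)) > p$alert_threshold
  if (isTRUE(responded)) hi_part <- hi_part & t[maint_idx] < response_onset
  # jitter must not carry a value across the threshold
  m_fgf[hi_part] <- pmax(m_fgf[hi_part], p$alert_threshold + 0.05)
  m_fgf[!hi_part] <- pmin(m_fgf[!hi_part], p$alert_threshold - 0.02)
  fgf[maint_idx] <- m_fgf
  fgf[em_idx] <- .rtrunc_norm(sum(em_idx), 8, 1, 4, 12)

  dial <- numeric(n)
  dial[ind_idx] <- round(2.0 * mac, 2)
  dial[maint_idx] <- round(1.2 * mac, 2)
  dial[em_idx] <- 0

  target <- p$target_mac * mac
  et <- numeric(n)
  on_idx <- t < t_gs
  et[on_idx] <- target * (1 - exp(-(t[on_idx] + 1) / p$et_tau_minutes))
  et_at_gs <- target * (1 - exp(-t_gs / p$et_tau_minutes))
  et[em_idx] <- et_at_gs * exp(-(t[em_idx] - t_gs + 1) / 8)

  liq <- liquid_ml_consumed(agent, fgf, dial, 1, constants)
  cum <- cumsum(liq)

  minutes <- data.frame(t = t, fgf_total = fgf)
  minutes[[paste0("dial_", agent)]] <- dial
  minutes[[paste0("et_", agent)]] <- et
  minutes[[paste0("cum_", agent)]] <- cum
  minutes$flow_oxygen <- fgf * 0.5
  minutes$flow_air <- fgf * 0.5
  minutes$flow_nitrous_oxide <- 0

  split_case <- stats::runif(1) < 0.5
  profs <- if (split_case) {
    mid <- floor(t_end / 2)
    data.frame(professional_id = c(sprintf("att-%04d", case_index),
                                   sprintf("res-%04d-a", case_index),
                                   sprintf("res-%04d-b", case_index)),
               role = c("attending", "resident", "resident"),
               t_in = c(0, 0, mid), t_out = c(t_end, mid, t_end),
               stringsAsFactors = FALSE)
  } else {
    data.frame(professional_id = sprintf("att-%04d", case_index),
               role = "attending", t_in = 0, t_out = t_end,
               stringsAsFactors = FALSE)
  }
  case_date <- p$start_date + sample(0:(p$n_months * 30 - 1), 1)

  cs <- case_record(case_id = case_id, patient_age = age,
                    procedure_start = ps, procedure_stop = pe,
                    minutes = device_minutes(minutes), professionals = profs,
                    location = "or", case_date = case_date)
  attr(cs, "truth") <- data.frame(case_id = case_id, agent = agent,
                                  age = age, high_flow = high,
                                  base_fgf = base_fgf, responded = responded,
                                  response_onset = response_onset,
                                  procedure_start = ps, procedure_stop = pe,
                                  anesthetic_gas_stop = t_gs,
                                  n_minutes = n, split_case = split_case,
                                  stringsAsFactors = FALSE)
  cs
}

#' Simulate a cohort with ground truth
#'
#' @param params A `sim_params`.
#' @param constants Agent constants table.
#' @return List with `cases` (list of `case_record`) and `truth` (data frame
#'   of latent draws, one row per case).
#' @export
simulate_cohort <- function(params, constants = agent_constants()) {
  if (params$n_cases == 0L) {
    return(list(cases = list(),
                truth = data.frame(case_id = character(),
                                   stringsAsFactors = FALSE)))
  }
  cases <- lapply(seq_len(params$n_cases), function(i) {
    simulate_case(params, i, constants)
  })
  truth <- do.call(rbind, lapply(cases, attr, "truth"))
  rownames(truth) <- NULL
  list(cases = cases, truth = truth)
}

#' Estimate the practitioner response probability from an alert log
#'
#' A firing episode counts as "responded" when total FGF falls to or below
#' the configured threshold within `response_latency + tolerance` minutes of
#' the episode's first firing. Returns the binomial point estimate with an
#' exact (Clopper-Pearson) 95% confidence interval.
#'
#' @param cases List of `case_record`s the log was computed on.
#' @param alerts Alert log from [run_engine_cohort()].
#' @param config The `alert_config` used.
#' @param response_latency Assumed minutes from episode start to a response.
#' @param tolerance Extra minutes of slack in the response window.
#' @return List with `estimate`, `conf_int` (length 2), `n_episodes`,
#'   `n_responded`. With zero episodes the estimate is `NA` and
#'   `undefined = TRUE`.
#' @export
estimate_response_probability <- function(cases, alerts, config,
                                          response_latency = 2,
                                          tolerance = 2) {
  if (!nrow(alerts)) {
    return(list(estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                n_episodes = 0L, n_responded = 0L, undefined = TRUE))
  }
  first <- stats::aggregate(t ~ case_id + episode_id, data = alerts, FUN = min)
  by_id <- stats::setNames(cases, vapply(cases, function(cs) cs$case_id,
                                         character(1)))
  window <- response_latency + tolerance
  responded <- vapply(seq_len(nrow(first)), function(i) {
    cs <- by_id[[first$case_id[i]]]
    t0 <- first$t[i]
    m <- cs$minutes
    rows <- m$t > t0 & m$t <= t0 + window
    any(m$fgf_total[rows] <= config$threshold, na.rm = TRUE)
  }, logical(1))
  n <- length(responded); x <- sum(responded)
  ci <- stats::binom.test(x, n)$conf.int
  list(estimate = x / n, conf_int = as.numeric(ci),
       n_episodes = n, n_responded = x, undefined = FALSE)
}
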