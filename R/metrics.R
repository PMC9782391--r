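# Reporting pipeline: phase segmentation, liquid agent volume, age-adjusted
# MAC-hours and the efficiency metric mL per MAC-hour, at case and
# professional granularity, plus the cohort exclusion filters and monthly
# aggregation.
#
# All windows are half-open [start, stop) in integer minutes; a minute's
# record describes the minute beginning at its timestamp, and a cumulative
# volume reading describes consumption through the END of that minute. This
# prevents double counting at phase boundaries.

.window_hours <- function(window) max(0, window[2] - window[1]) / 60

#' Segment a case into anesthetic phases
#'
#' Induction runs from the first minute with a nonzero set (dial)
#' concentration to the procedure start; maintenance runs from procedure
#' start to the earlier of procedure stop or the anesthetic gas stop (the
#' minute of the last nonzero dial). Cases where the dial never rises above
#' zero yield empty phases, flagged for downstream exclusion.
#'
#' @param case A `case_record` with both procedure events present.
#' @return List with elements `induction` and `maintenance` (length-2 numeric
#'   vectors, half-open `[start, stop)`), `anesthetic_gas_stop`, and `empty`.
#' @export
compute_phases <- function(case) {
  if (!is.finite(case$procedure_start) || !is.finite(case$procedure_stop)) {
    stop("compute_phases: case '", case$case_id,
         "' is missing procedure start/stop events")
  }
  m <- case$minutes
  dial_mat <- as.matrix(m[, paste0("dial_", volatile_agents()), drop = FALSE])
  on <- rowSums(dial_mat > 0, na.rm = TRUE) > 0
  if (!any(on)) {
    return(list(induction = c(NA_real_, NA_real_),
                maintenance = c(NA_real_, NA_real_),
                anesthetic_gas_stop = NA_real_, empty = TRUE))
  }
  first_on <- m$t[which(on)[1]]
  gas_stop <- m$t[which(on)[length(which(on))]]
  list(induction = c(first_on, case$procedure_start),
       maintenance = c(case$procedure_start,
                       min(case$procedure_stop, gas_stop)),
       anesthetic_gas_stop = gas_stop, empty = FALSE)
}

#' Liquid agent volume consumed over a time window
#'
#' When the ventilator reports cumulative liquid consumption, the volume is
#' the difference of the cumulative readings at the window boundaries;
#' otherwise it is the per-minute sum of the calculated consumption from
#' dial concentration and total FGF ([liquid_ml_consumed()]). The source used
#' is recorded in the `"source"` attribute. When both sources exist a
#' discrepancy above 10% is reported with a warning.
#'
#' @param case A `case_record`.
#' @param window Half-open minute interval `c(start, stop)`.
#' @param agent A volatile agent name.
#' @param constants Agent constants table.
#' @param source `"auto"` (cumulative when available), `"cumulative"`, or
#'   `"calculated"`.
#' @return mL of liquid agent, with attribute `source`.
#' @export
agent_volume <- function(case, window, agent, constants = agent_constants(),
                         source = c("auto", "cumulative", "calculated")) {
  source <- match.arg(source)
  m <- case$minutes
  if (any(!is.finite(window))) {
    return(structure(0, source = "empty"))
  }
  cum <- m[[paste0("cum_", agent)]]
  have_cum <- any(!is.na(cum))
  if (have_cum) {
    obs <- which(!is.na(cum))
    if (any(diff(cum[obs]) < -1e-9)) {
      stop("agent_volume: cumulative liquid volume for ", agent,
           " decreases within case '", case$case_id, "'")
    }
  }

  cum_at_end_of_before <- function(boundary) {
    # cumulative consumption through the end of the last minute < boundary
    i <- which(!is.na(cum) & m$t < boundary)
    if (!length(i)) 0 else cum[i[length(i)]]
  }
  calc <- function() {
    rows <- which(m$t >= window[1] & m$t < window[2])
    if (!length(rows)) return(0)
    dial <- m[[paste0("dial_", agent)]][rows]
    fgf <- m$fgf_total[rows]
    ok <- !is.na(dial) & !is.na(fgf)
    sum(liquid_ml_consumed(agent, fgf[ok], dial[ok], 1, constants))
  }

  use_cum <- switch(source, cumulative = TRUE, calculated = FALSE,
                    auto = have_cum)
  if (use_cum && !have_cum) {
    stop("agent_volume: no cumulative readings for ", agent,
         " in case '", case$case_id, "'")
  }
  if (use_cum) {
    v <- cum_at_end_of_before(window[2]) - cum_at_end_of_before(window[1])
    if (source == "auto" && have_cum) {
      v_calc <- calc()
      if (v > 0 && v_calc > 0 && abs(v - v_calc) / v > 0.10) {
        warning("agent_volume: cumulative and calculated volumes differ by >10% ",
                "in case '", case$case_id, "' (", round(v, 2), " vs ",
                round(v_calc, 2), " mL)")
      }
    }
    structure(max(0, v), source = "cumulative")
  } else {
    structure(calc(), source = "calculated")
  }
}

.mean_mac_multiple <- function(case, window, agent, constants) {
  m <- case$minutes
  rows <- which(m$t >= window[1] & m$t < window[2])
  et <- m[[paste0("et_", agent)]][rows]
  obs <- et[!is.na(et)]
  if (!length(obs)) {
    stop("mac_hours: no end-tidal records for ", agent, " in window [",
         window[1], ",", window[2], ") of case '", case$case_id, "'")
  }
  mac <- age_adjusted_mac_pct(agent, case$patient_age, constants)
  list(multiple = mean(obs) / mac,
       coverage = length(obs) / max(1, window[2] - window[1]))
}

#' MAC-hours of anesthetic exposure over a window
#'
#' The mean of all recorded end-tidal concentrations in the window, divided
#' by the patient's age-adjusted MAC, times the window duration in hours.
#' (Ratio of the mean, not mean of per-minute ratios; with the age-adjusted
#' MAC constant within a case the two coincide.)
#'
#' @inheritParams agent_volume
#' @return MAC-hours (non-negative). Errors (distinct from zero) when the
#'   window holds no end-tidal records.
#' @export
mac_hours <- function(case, window, agent, constants = agent_constants()) {
  if (any(!is.finite(window)) || window[2] <= window[1]) return(0)
  mm <- .mean_mac_multiple(case, window, agent, constants)
  mm$multiple * .window_hours(window)
}

.set_agent_in_window <- function(case, window) {
  m <- case$minutes
  rows <- which(m$t >= window[1] & m$t < window[2])
  dial_mat <- as.matrix(m[rows, paste0("dial_", volatile_agents()),
                          drop = FALSE])
  used <- volatile_agents()[colSums(dial_mat > 0, na.rm = TRUE) > 0]
  used
}

.metrics_row <- function(case, window, agent, constants, scope,
                         professional_id = NA_character_,
                         role = NA_character_, volume_source = "auto") {
  vol <- agent_volume(case, window, agent, constants, source = volume_source)
  flags <- character()
  if (any(!is.finite(window)) || window[2] <= window[1]) {
    mh <- 0; mult <- NA_real_; cov <- NA_real_
  } else {
    mm <- .mean_mac_multiple(case, window, agent, constants)
    mult <- mm$multiple
    cov <- mm$coverage
    mh <- mult * .window_hours(window)
    if (cov < 0.8) flags <- c(flags, "low_et_coverage")
  }
  if (mh > 0) {
    ratio <- as.numeric(vol) / mh
  } else {
    ratio <- NA_real_
    flags <- c(flags, "undefined_metric")
  }
  data.frame(case_id = case$case_id, scope = scope,
             professional_id = professional_id, role = role, agent = agent,
             window_start = window[1], window_stop = window[2],
             case_duration_hr =
               (case$procedure_stop - case$procedure_start) / 60,
             set_agent_volume_ml = as.numeric(vol),
             volume_source = attr(vol, "source"),
             age_adjusted_mac = mult, mac_hours = mh,
             ml_per_mac_hour = ratio, et_coverage = cov,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Case-level efficiency metric: mL of liquid agent per MAC-hour
#'
#' Assembles phase windows, maintenance liquid volume, and MAC-hours into one
#' metrics row — the "gas mileage" of the anesthetic (lower is better). The
#' case must deliver a single volatile agent during maintenance; cases with
#' zero MAC-hours get an `undefined_metric` flag and `NA` ratio so they can
#' be dropped from means with a logged reason.
#'
#' @param case A `case_record`.
#' @param constants Agent constants table.
#' @param volume_source Passed to [agent_volume()].
#' @return One-row data frame of case metrics.
#' @export
ml_per_mac_hour <- function(case, constants = agent_constants(),
                            volume_source = "auto") {
  ph <- compute_phases(case)
  if (ph$empty) {
    stop("ml_per_mac_hour: case '", case$case_id,
         "' has no volatile agent delivery")
  }
  agents <- .set_agent_in_window(case, ph$maintenance)
  if (length(agents) > 1L) {
    stop("ml_per_mac_hour: case '", case$case_id,
         "' uses >1 volatile agent during maintenance (",
         paste(agents, collapse = ","), "); apply exclusions first")
  }
  if (!length(agents)) {
    # delivery confined to induction; fall back to the agent used there
    agents <- .set_agent_in_window(case, ph$induction)[1]
  }
  .metrics_row(case, ph$maintenance, agents, constants, scope = "case",
               volume_source = volume_source)
}

#' Per-professional efficiency metrics
#'
#' Each professional's metrics are computed over the intersection of their
#' signed-in interval with the maintenance phase, so the maintenance phase
#' may be split among professionals; overlapping intervals (supervision) are
#' permitted and yield deliberate double counting across roles. Intervals
#' reaching outside the recorded case are clipped with a warning.
#'
#' @inheritParams ml_per_mac_hour
#' @return Data frame, one metrics row per professional.
#' @export
per_professional_metrics <- function(case, constants = agent_constants(),
                                     volume_source = "auto") {
  ph <- compute_phases(case)
  if (ph$empty) {
    stop("per_professional_metrics: case '", case$case_id,
         "' has no volatile agent delivery")
  }
  agents <- .set_agent_in_window(case, ph$maintenance)
  if (length(agents) > 1L) {
    stop("per_professional_metrics: case '", case$case_id,
         "' uses >1 volatile agent during maintenance")
  }
  if (!length(agents)) agents <- .set_agent_in_window(case, ph$induction)[1]
  p <- case$professionals
  if (!nrow(p)) {
    return(.metrics_row(case, ph$maintenance, agents, constants,
                        scope = "professional")[0, ])
  }
  span <- range(case$minutes$t)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    t_in <- p$t_in[i]; t_out <- p$t_out[i]
    if (t_in < span[1] || t_out > span[2] + 1) {
      warning("professional interval [", t_in, ",", t_out,
              ") reaches outside case '", case$case_id, "'; clipping")
      t_in <- max(t_in, span[1]); t_out <- min(t_out, span[2] + 1)
    }
    w <- c(max(t_in, ph$maintenance[1]), min(t_out, ph$maintenance[2]))
    .metrics_row(case, w, agents, constants, scope = "professional",
                 professional_id = p$professional_id[i], role = p$role[i],
                 volume_source = volume_source)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the cohort exclusion filters for reporting
#'
#' Excludes (a) cases in non-reportable locations (pediatric induction rooms,
#' non-OR anesthesia locations, labor and delivery), (b) cases with any
#' flowsheet entry setting a nonzero dial concentration for more than one
#' volatile agent, and (c) cases with fewer than 15 recorded minutes of
#' volatile agent delivery (strictly fewer: a 15-minute case is included).
#'
#' @param cases List of `case_record`s.
#' @param excluded_locations Location labels to drop.
#' @param min_delivery_minutes Minimum recorded delivery minutes (strict `<`
#'   excludes).
#' @param multi_agent_scope Scan the whole recorded case (`"case"`, default,
#'   matching "presence of a single flow sheet entry") or maintenance only.
#' @return Object of class `exclusion_report`: list with `included` (case
#'   ids) and `excluded` (data frame `case_id`, `reason`; a case may carry
#'   several reasons). The two partition the input cohort.
#' @export
apply_exclusions <- function(cases,
                             excluded_locations = c("pediatric_induction",
                                                    "non_or",
                                                    "labor_and_delivery"),
                             min_delivery_minutes = 15,
                             multi_agent_scope = c("case", "maintenance")) {
  multi_agent_scope <- match.arg(multi_agent_scope)
  rows <- lapply(cases, function(cs) {
    reasons <- character()
    if (cs$location %in% excluded_locations) reasons <- c(reasons, "location")
    win <- if (multi_agent_scope == "case") {
      c(-Inf, Inf)
    } else {
      ph <- try(compute_phases(cs), silent = TRUE)
      if (inherits(ph, "try-error") || ph$empty) c(-Inf, Inf) else ph$maintenance
    }
    if (length(.set_agent_in_window(cs, win)) > 1L) {
      reasons <- c(reasons, "multi_agent")
    }
    dial_mat <- as.matrix(cs$minutes[, paste0("dial_", volatile_agents()),
                                     drop = FALSE])
    delivery <- sum(rowSums(dial_mat > 0, na.rm = TRUE) > 0)
    if (delivery < min_delivery_minutes) reasons <- c(reasons, "short_delivery")
    if (!length(reasons)) return(NULL)
    data.frame(case_id = cs$case_id, reason = reasons, stringsAsFactors = FALSE)
  })
  excluded <- do.call(rbind, rows)
  if (is.null(excluded)) {
    excluded <- data.frame(case_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  structure(list(included = setdiff(ids, excluded$case_id),
                 excluded = excluded),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> included=", length(x$included),
      " excluded=", length(unique(x$excluded$case_id)), "\n", sep = "")
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Case-level metrics for a whole cohort
#'
#' Applies the exclusion filters, then computes [ml_per_mac_hour()] per
#' included case (or [per_professional_metrics()] when `by =
#' "professional"`).
#'
#' @param cases List of `case_record`s.
#' @param by `"case"` or `"professional"` granularity.
#' @param constants Agent constants table.
#' @param exclusions Optional precomputed `exclusion_report`.
#' @param volume_source Passed through to [agent_volume()].
#' @return Data frame of metrics rows with the `exclusion_report` attached as
#'   attribute `"exclusions"`.
#' @export
cohort_metrics <- function(cases, by = c("case", "professional"),
                           constants = agent_constants(), exclusions = NULL,
                           volume_source = "auto") {
  by <- match.arg(by)
  if (is.null(exclusions)) exclusions <- apply_exclusions(cases)
  keep <- Filter(function(cs) cs$case_id %in% exclusions$included, cases)
  fn <- if (by == "case") ml_per_mac_hour else per_professional_metrics
  rows <- lapply(keep, fn, constants = constants,
                 volume_source = volume_source)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- .metrics_row(case_record("x", 40, 0, 1,
                                    data.frame(t = 0, fgf_total = 0,
                                               dial_sevoflurane = 0),
                                    validate = FALSE),
                        c(0, 0), "sevoflurane", constants, "case")[0, ]
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Aggregate a cohort into a periodic report table
#'
#' Per period (calendar month of the case date) and agent: number of included
#' cases, mean mL per MAC-hour (cases with an undefined metric are dropped
#' from the mean, with their ids recorded in the `"dropped"` attribute),
#' alert episodes per case and per case-hour, firings per case, total liquid
#' volume, CO2-equivalent mass, and optional cost. Months inside the cohort
#' span with no included cases appear as rows with explicit `NA`, not zero.
#'
#' @param cases List of `case_record`s.
#' @param alerts Alert log from [run_engine_cohort()].
#' @param constants Agent constants table.
#' @param exclusions Optional precomputed `exclusion_report`.
#' @param cost_per_ml Optional named numeric vector of cost per mL by agent.
#' @return Data frame, one row per (period, agent).
#' @export
aggregate_cohort <- function(cases, alerts, constants = agent_constants(),
                             exclusions = NULL, cost_per_ml = NULL) {
  metrics <- cohort_metrics(cases, by = "case", constants = constants,
                            exclusions = exclusions)
  exclusions <- attr(metrics, "exclusions")
  keep <- Filter(function(cs) cs$case_id %in% exclusions$included, cases)
  if (!nrow(metrics) || !length(keep)) {
    return(data.frame(period = character(), agent = character(),
                      n_cases = integer(), mean_ml_per_mac_hour = numeric(),
                      episodes_per_case = numeric(),
                      episodes_per_case_hour = numeric(),
                      firings_per_case = numeric(),
                      total_volume_ml = numeric(), co2e_kg = numeric(),
                      cost = numeric(), stringsAsFactors = FALSE))
  }
  dates <- as.Date(vapply(keep, function(cs) as.character(cs$case_date),
                          character(1)))
  period <- ifelse(is.na(dates), "all", format(dates, "%Y-%m"))
  ids <- vapply(keep, function(cs) cs$case_id, character(1))
  metrics$period <- period[match(metrics$case_id, ids)]
  metrics$duration_hr <- metrics$case_duration_hr

  ep_by_case <- count_episodes(alerts)
  firings_by_case <- if (nrow(alerts)) table(alerts$case_id) else table(character())

  periods <- sort(unique(metrics$period))
  if (!any(is.na(dates)) && length(periods) > 1L) {
    # fill interior months with explicit empty rows
    mons <- seq(as.Date(paste0(min(periods), "-01")),
                as.Date(paste0(max(periods), "-01")), by = "month")
    periods <- format(mons, "%Y-%m")
  }
  dropped <- metrics$case_id[grepl("undefined_metric", metrics$flags)]
  rows <- list()
  for (p in periods) {
    sub <- metrics[metrics$period == p, , drop = FALSE]
    if (!nrow(sub)) {
      rows[[length(rows) + 1L]] <-
        data.frame(period = p, agent = NA_character_, n_cases = 0L,
                   mean_ml_per_mac_hour = NA_real_,
                   episodes_per_case = NA_real_,
                   episodes_per_case_hour = NA_real_,
                   firings_per_case = NA_real_, total_volume_ml = NA_real_,
                   co2e_kg = NA_real_, cost = NA_real_,
                   stringsAsFactors = FALSE)
      next
    }
    for (ag in sort(unique(sub$agent))) {
      ss <- sub[sub$agent == ag, , drop = FALSE]
      ok <- !grepl("undefined_metric", ss$flags)
      eps <- ep_by_case[ss$case_id]
      eps[is.na(eps)] <- 0
      fir <- as.integer(firings_by_case[ss$case_id])
      fir[is.na(fir)] <- 0L
      vol <- sum(ss$set_agent_volume_ml)
      cost <- if (!is.null(cost_per_ml) && ag %in% names(cost_per_ml)) {
        vol * cost_per_ml[[ag]]
      } else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(period = p, agent = ag, n_cases = nrow(ss),
                   mean_ml_per_mac_hour =
                     if (any(ok)) mean(ss$ml_per_mac_hour[ok]) else NA_real_,
                   episodes_per_case = mean(eps),
                   episodes_per_case_hour =
                     sum(eps) / max(sum(ss$duration_hr), 1e-12),
                   firings_per_case = mean(fir),
                   total_volume_ml = vol,
                   co2e_kg = co2e_kg(ag, vol, constants),
                   cost = cost, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
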