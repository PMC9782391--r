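# Per-minute low-flow advisory engine.
#
# Seven firing rules, evaluated once per minute:
#   1  a volatile agent is the set agent (a dial reading is recorded; the set
#      agent is the volatile with the highest dial, ties broken in the fixed
#      order sevoflurane, isoflurane, desflurane)
#   2  that agent is in use (its dial concentration > 0)
#   3  total fresh gas flow has exceeded the threshold (strictly) for at
#      least the last `lookback` consecutive minutes
#   4  the procedure start event has been activated (t >= procedure_start);
#      this excludes the induction period
#   5  the procedure stop event has not been activated (t < procedure_stop);
#      this excludes emergence
#   6  the patient is older than the age cutoff (strictly)
#   7  the advisory is neither snoozed nor disabled
#
# An advisory fires at every evaluated minute on which rules 1-6 hold and
# rule 7 permits; consecutive firing-eligible minutes are grouped into one
# episode, the headline burden unit. A gap in the minute grid resets the
# consecutive-minute counter (unknown flow is not evidence of high flow) and
# closes any open episode. Nitrous oxide alone never fires (it has no dial
# entry among the volatile agents); N2O alongside a volatile agent can.

#' Advisory engine configuration
#'
#' @param threshold FGF threshold in L/min; an advisory requires total FGF
#'   strictly above this value. Default 0.7.
#' @param lookback Consecutive minutes the flow condition must hold before
#'   firing. Default 5, so abrupt reactive flow changes do not fire.
#' @param snooze_duration Minutes an explicit snooze suppresses firing.
#'   Default 10.
#' @param age_cutoff Patients aged at or below this (years) never trigger an
#'   advisory. Default 1.
#' @param mode Display semantics of emitted events: `"noninterruptive"`
#'   (visible sidebar alert), `"interruptive"` (requires acknowledgment),
#'   `"passive"` (logged but flagged non-displayed). Mode changes event
#'   metadata only, never the firing logic.
#' @param snooze_resets_counter If `TRUE`, a snooze also clears the
#'   consecutive-minute counter; by default the condition keeps being tracked
#'   during the snooze so an advisory can fire the minute it expires.
#' @return Object of class `alert_config`.
#' @export
alert_config <- function(threshold = 0.7, lookback = 5, snooze_duration = 10,
                         age_cutoff = 1,
                         mode = c("noninterruptive", "interruptive", "passive"),
                         snooze_resets_counter = FALSE) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, lookback >= 1, snooze_duration >= 0)
  structure(list(threshold = threshold, lookback = as.integer(lookback),
                 snooze_duration = snooze_duration, age_cutoff = age_cutoff,
                 mode = mode, evaluation_interval = 1L,
                 snooze_resets_counter = isTRUE(snooze_resets_counter)),
            class = "alert_config")
}

#' @export
print.alert_config <- function(x, ...) {
  cat("<alert_config> threshold=", x$threshold, " L/min, lookback=",
      x$lookback, " min, snooze=", x$snooze_duration, " min, age_cutoff=",
      x$age_cutoff, " yr, mode=", x$mode, "\n", sep = "")
  invisible(x)
}

#' Fresh advisory-engine state
#'
#' Mutable evaluation state threaded through [evaluate_minute()].
#'
#' @return Object of class `alert_state`.
#' @export
alert_state <- function() {
  structure(list(last_t = NA_real_, consecutive_above = 0L,
                 snoozed_until = NA_real_, disabled = FALSE,
                 episode_id = 0L, episode_active = FALSE,
                 last_fired = NA_real_),
            class = "alert_state")
}

# set agent at one minute: index into volatile_agents(), or NA when no dial
# reading is recorded. which.max takes the first maximum, giving the fixed
# tie order sevo > iso > des.
.set_agent_index <- function(dials) {
  if (all(is.na(dials))) return(NA_integer_)
  which.max(replace(dials, is.na(dials), -Inf))
}

#' Evaluate the advisory rules for one device minute
#'
#' Minutes must be supplied in strictly increasing time order; out-of-order
#' invocation is a contract error. Returns the updated state and the emitted
#' advisory (or `NULL`).
#'
#' @param state An `alert_state`.
#' @param minute One device-minute row (one-row data frame or list with the
#'   canonical minute fields).
#' @param case The `case_record` the minute belongs to (supplies procedure
#'   events and patient age).
#' @param config An `alert_config`.
#' @return `list(state = <alert_state>, event = <named list or NULL>)`.
#' @export
evaluate_minute <- function(state, minute, case, config) {
  t <- as.numeric(minute[["t"]])
  if (!is.na(state$last_t) && t <= state$last_t) {
    stop("evaluate_minute: minutes must be processed in increasing t (got t=",
         t, " after t=", state$last_t, ")")
  }
  dials <- vapply(paste0("dial_", volatile_agents()),
                  function(cn) as.numeric(minute[[cn]]), numeric(1))
  idx <- .set_agent_index(dials)
  r1 <- !is.na(idx)
  r2 <- r1 && !is.na(dials[idx]) && dials[idx] > 0
  fgf <- as.numeric(minute[["fgf_total"]])
  above <- r1 && r2 && !is.na(fgf) && fgf > config$threshold

  contiguous <- is.na(state$last_t) || t == state$last_t + 1
  state$consecutive_above <-
    if (above) (if (contiguous) state$consecutive_above + 1L else 1L) else 0L

  r3 <- state$consecutive_above >= config$lookback
  r4 <- is.finite(case$procedure_start) && t >= case$procedure_start
  r5 <- !is.finite(case$procedure_stop) || t < case$procedure_stop
  r6 <- is.finite(case$patient_age) && case$patient_age > config$age_cutoff
  snoozed <- !is.na(state$snoozed_until) && t < state$snoozed_until
  r7 <- !state$disabled && !snoozed

  eligible <- r1 && r2 && r3 && r4 && r5 && r6
  if (eligible) {
    if (!state$episode_active || !contiguous) {
      state$episode_id <- state$episode_id + 1L
    }
    state$episode_active <- TRUE
  } else {
    state$episode_active <- FALSE
  }

  event <- NULL
  if (eligible && r7) {
    state$last_fired <- t
    event <- list(case_id = case$case_id, t = t,
                  episode_id = state$episode_id, mode = config$mode,
                  displayed = config$mode != "passive",
                  requires_ack = config$mode == "interruptive",
                  rule1 = r1, rule2 = r2, rule3 = r3, rule4 = r4,
                  rule5 = r5, rule6 = r6, rule7 = r7)
  }
  state$last_t <- t
  list(state = state, event = event)
}

#' Snooze the advisory
#'
#' Suppresses firing until `t + snooze_duration`. Condition tracking
#' continues during the snooze (unless `snooze_resets_counter`), so if the
#' rules still hold when the snooze expires, the advisory fires at that
#' minute.
#'
#' @param state An `alert_state`.
#' @param t Minute at which the snooze is taken.
#' @param config An `alert_config`.
#' @return Updated `alert_state`.
#' @export
snooze <- function(state, t, config) {
  state$snoozed_until <- t + config$snooze_duration
  if (config$snooze_resets_counter) state$consecutive_above <- 0L
  state
}

#' Disable / re-enable the advisory engine
#'
#' A disabled engine emits no events until re-enabled (clinical circumstances
#' such as a circuit leak or a code scenario). Enabling a never-disabled
#' engine is a no-op.
#'
#' @param state An `alert_state`.
#' @return Updated `alert_state`.
#' @export
disable <- function(state) { state$disabled <- TRUE; state }

#' @rdname disable
#' @export
enable <- function(state) { state$disabled <- FALSE; state }

.empty_alert_log <- function() {
  data.frame(case_id = character(), t = numeric(), episode_id = integer(),
             mode = character(), displayed = logical(),
             requires_ack = logical(),
             rule1 = logical(), rule2 = logical(), rule3 = logical(),
             rule4 = logical(), rule5 = logical(), rule6 = logical(),
             rule7 = logical(), stringsAsFactors = FALSE)
}

.check_actions <- function(actions) {
  if (is.null(actions) || !nrow(as.data.frame(actions))) return(NULL)
  actions <- as.data.frame(actions)
  stopifnot(all(c("t", "action") %in% names(actions)))
  bad <- setdiff(actions$action, c("snooze", "disable", "enable"))
  if (length(bad)) stop("unknown engine action(s): ", paste(bad, collapse = ","))
  actions[order(actions$t), , drop = FALSE]
}

#' Run the advisory engine over a whole case
#'
#' Deterministic batch driver: equivalent to folding [evaluate_minute()] over
#' the case's minutes in time order, applying any scripted snooze / disable /
#' enable actions at the start of the minute they are scheduled for. Passive
#' mode produces annotation events flagged `displayed = FALSE` rather than
#' suppressing the log.
#'
#' @param case A `case_record` (minutes on the integer grid, sorted).
#' @param config An `alert_config`.
#' @param actions Optional data frame with columns `t`, `action`
#'   (`"snooze"`, `"disable"`, `"enable"`) of scripted clinician actions.
#' @return Data frame alert log: one row per fired minute with columns
#'   `case_id`, `t`, `episode_id`, `mode`, `displayed`, `requires_ack`, and
#'   the rule trace `rule1`..`rule7`.
#' @export
run_engine <- function(case, config, actions = NULL) {
  actions <- .check_actions(actions)
  if (is.null(actions)) .run_engine_vec(case, config)
  else .run_engine_fold(case, config, actions)
}

# Vectorized path (no scripted actions, hence no snooze/disable timeline).
.run_engine_vec <- function(case, config) {
  m <- case$minutes
  n <- nrow(m)
  if (!n) return(.empty_alert_log())
  t <- m$t
  dial_mat <- as.matrix(m[, paste0("dial_", volatile_agents()), drop = FALSE])
  any_rec <- rowSums(!is.na(dial_mat)) > 0
  max_dial <- suppressWarnings(apply(dial_mat, 1L, max, na.rm = TRUE))
  max_dial[!any_rec] <- NA_real_
  r1 <- any_rec
  r2 <- r1 & !is.na(max_dial) & max_dial > 0
  above <- r1 & r2 & !is.na(m$fgf_total) & m$fgf_total > config$threshold

  contiguous <- c(TRUE, diff(t) == 1)
  cons <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) (if (contiguous[i]) run + 1L else 1L) else 0L
    cons[i] <- run
  }

  r3 <- cons >= config$lookback
  r4 <- is.finite(case$procedure_start) & t >= case$procedure_start
  r5 <- !is.finite(case$procedure_stop) | t < case$procedure_stop
  r6 <- is.finite(case$patient_age) && case$patient_age > config$age_cutoff
  eligible <- r1 & r2 & r3 & r4 & r5 & r6

  ep_new <- eligible & (!c(FALSE, eligible[-n]) | !contiguous)
  ep_id <- cumsum(ep_new)

  fire <- which(eligible)  # rule 7 always permits: no snooze/disable actions
  if (!length(fire)) return(.empty_alert_log())
  data.frame(case_id = case$case_id, t = t[fire],
             episode_id = as.integer(ep_id[fire]), mode = config$mode,
             displayed = config$mode != "passive",
             requires_ack = config$mode == "interruptive",
             rule1 = TRUE, rule2 = TRUE, rule3 = TRUE, rule4 = TRUE,
             rule5 = TRUE, rule6 = TRUE, rule7 = TRUE,
             stringsAsFactors = FALSE)
}

# Sequential fold, used when scripted actions are present.
.run_engine_fold <- function(case, config, actions = NULL) {
  m <- case$minutes
  n <- nrow(m)
  if (!n) return(.empty_alert_log())
  state <- alert_state()
  a_i <- 1L
  n_a <- if (is.null(actions)) 0L else nrow(actions)
  events <- vector("list", n)
  n_ev <- 0L
  for (i in seq_len(n)) {
    t_i <- m$t[i]
    while (a_i <= n_a && actions$t[a_i] <= t_i) {
      state <- switch(actions$action[a_i],
                      snooze = snooze(state, actions$t[a_i], config),
                      disable = disable(state),
                      enable = enable(state))
      a_i <- a_i + 1L
    }
    res <- evaluate_minute(state, m[i, , drop = FALSE], case, config)
    state <- res$state
    if (!is.null(res$event)) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- res$event
    }
  }
  if (!n_ev) return(.empty_alert_log())
  out <- do.call(rbind, lapply(events[seq_len(n_ev)], function(e) {
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the engine over a cohort
#'
#' @param cases List of `case_record`s.
#' @param config An `alert_config`.
#' @param actions Optional named list mapping case id to a scripted-actions
#'   data frame (see [run_engine()]).
#' @return Combined alert log across cases.
#' @export
run_engine_cohort <- function(cases, config, actions = NULL) {
  logs <- lapply(cases, function(cs) {
    run_engine(cs, config, actions = actions[[cs$case_id]])
  })
  out <- do.call(rbind, logs)
  if (is.null(out) || !nrow(out)) return(.empty_alert_log())
  rownames(out) <- NULL
  out
}

#' Count firing episodes in an alert log
#'
#' Consecutive firing minutes within a case share an episode id; the episode
#' count is the headline alert-burden metric (per-minute refires are also in
#' the log for sites that count every firing).
#'
#' @param alerts Alert log from [run_engine()] / [run_engine_cohort()].
#' @return Named integer: episodes per case id (zero-length when no alerts).
#' @export
count_episodes <- function(alerts) {
  if (!nrow(alerts)) return(integer())
  tab <- tapply(alerts$episode_id, alerts$case_id,
                function(e) length(unique(e)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
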