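# Independent brute-force advisory oracle: at every minute it re-examines
# the full trailing clock window (O(n * lookback)), instead of keeping a
# running counter, and replays scripted actions. Used to cross-check
# run_engine on randomized traces.

oracle_engine <- function(case, config, actions = NULL) {
  m <- case$minutes
  ts <- m$t
  n <- nrow(m)
  if (!n) return(data.frame(t = numeric(), episode_id = integer()))
  dials <- as.matrix(m[, paste0("dial_", volatile_agents()), drop = FALSE])

  # rules 1-2 and instantaneous flow condition at row j
  hot_row <- function(j) {
    d <- dials[j, ]
    if (all(is.na(d))) return(FALSE)
    k <- which.max(replace(d, is.na(d), -Inf))
    isTRUE(d[k] > 0) && !is.na(m$fgf_total[j]) &&
      m$fgf_total[j] > config$threshold
  }

  if (!is.null(actions)) actions <- actions[order(actions$t), , drop = FALSE]
  ai <- 1L
  snoozed_until <- -Inf
  disabled <- FALSE
  eligible <- logical(n)
  out_t <- numeric(0)
  out_ep <- integer(0)
  episode <- 0L

  for (i in seq_len(n)) {
    t <- ts[i]
    while (!is.null(actions) && ai <= nrow(actions) && actions$t[ai] <= t) {
      a <- actions$action[ai]
      if (a == "snooze") snoozed_until <- actions$t[ai] + config$snooze_duration
      if (a == "disable") disabled <- TRUE
      if (a == "enable") disabled <- FALSE
      ai <- ai + 1L
    }
    window <- (t - config$lookback + 1):t
    r3 <- all(vapply(window, function(u) {
      j <- match(u, ts)
      !is.na(j) && hot_row(j)
    }, logical(1)))
    r4 <- is.finite(case$procedure_start) && t >= case$procedure_start
    r5 <- !is.finite(case$procedure_stop) || t < case$procedure_stop
    r6 <- case$patient_age > config$age_cutoff
    eligible[i] <- r3 && r4 && r5 && r6
    if (eligible[i]) {
      prev_row <- if (i > 1L && ts[i - 1L] == t - 1) eligible[i - 1L] else FALSE
      if (!prev_row) episode <- episode + 1L
      if (!disabled && !(t < snoozed_until)) {
        out_t <- c(out_t, t)
        out_ep <- c(out_ep, episode)
      }
    }
  }
  data.frame(t = out_t, episode_id = out_ep)
}

expect_log_matches_oracle <- function(case, config, actions = NULL) {
  got <- run_engine(case, config, actions)
  want <- oracle_engine(case, config, actions)
  expect_equal(got$t, want$t, info = paste("case", case$case_id))
  expect_equal(got$episode_id, want$episode_id,
               info = paste("case", case$case_id))
}
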