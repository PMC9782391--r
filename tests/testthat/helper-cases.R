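# Builders for synthetic traces used across the tests.

# A constant-conditions case: dial and FGF flat over n minutes.
const_case <- function(n = 60, fgf = 1.0, dial = 2.0, agent = "sevoflurane",
                       ps = 0, pe = n, age = 30, et = NA_real_,
                       case_id = "case-1", location = "or",
                       professionals = NULL, case_date = as.Date(NA)) {
  m <- data.frame(t = seq_len(n) - 1, fgf_total = rep(fgf, n))
  m[[paste0("dial_", agent)]] <- rep(dial, n)
  m[[paste0("et_", agent)]] <- rep(et, n)
  case_record(case_id = case_id, patient_age = age, procedure_start = ps,
              procedure_stop = pe, minutes = m,
              professionals = professionals, location = location,
              case_date = case_date)
}

# A randomized trace for property tests: 60-300 minutes, grid gaps, dial
# on/off segments, occasional missing dial readings, an FGF random walk
# crossing the threshold, and (optionally) scripted snoozes/disables.
random_case <- function(i, with_actions = TRUE) {
  set.seed(20000 + i)
  n_full <- sample(60:300, 1)
  t <- 0:(n_full - 1)
  keep <- runif(n_full) > 0.08
  keep[1] <- TRUE
  t <- t[keep]
  n <- length(t)

  fgf <- numeric(n)
  fgf[1] <- runif(1, 0.2, 2)
  for (k in 2:n) fgf[k] <- min(max(fgf[k - 1] + rnorm(1, 0, 0.18), 0), 3.5)

  seg <- cumsum(runif(n) < 0.05)
  dial_on <- (seg %% 2 == 0)
  dial <- ifelse(dial_on, round(runif(n, 0.5, 3), 2), 0)
  dial[runif(n) < 0.05] <- NA_real_
  m <- data.frame(t = t, fgf_total = fgf, dial_sevoflurane = dial)
  if (runif(1) < 0.3) {
    m$dial_isoflurane <- ifelse(runif(n) < 0.3, round(runif(n, 0, 2), 2), 0)
  }
  ps <- sample(0:20, 1)
  pe <- ps + sample(30:280, 1)
  age <- if (runif(1) < 0.1) runif(1, 0.2, 1) else runif(1, 2, 90)

  actions <- NULL
  if (with_actions && runif(1) < 0.6) {
    acts <- list()
    if (runif(1) < 0.8) {
      for (ts in sort(sample(t, sample(1:3, 1)))) {
        acts[[length(acts) + 1]] <- data.frame(t = ts, action = "snooze")
      }
    }
    if (runif(1) < 0.4) {
      td <- sort(sample(t, 2))
      acts[[length(acts) + 1]] <- data.frame(t = td[1], action = "disable")
      acts[[length(acts) + 1]] <- data.frame(t = td[2], action = "enable")
    }
    if (length(acts)) actions <- do.call(rbind, acts)
  }
  list(case = case_record(case_id = paste0("rnd-", i), patient_age = age,
                          procedure_start = ps, procedure_stop = pe,
                          minutes = m),
       actions = actions)
}

strip_truth <- function(cases) {
  lapply(cases, function(cs) { attr(cs, "truth") <- NULL; cs })
}
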