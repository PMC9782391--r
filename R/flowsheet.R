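# Data model, validation and file I/O for per-minute intraoperative device
# data ("device minutes") and case metadata.
#
# A case is an S3 list (class "case_record") with scalar metadata plus two
# data frames:
#   minutes       one row per device minute, canonical column order below
#   professionals one row per professional sign-in interval
#
# CSV dialect: two files sharing a path prefix -- <prefix>_minutes.csv (one
# row per case-minute) and <prefix>_cases.csv (one row per case-professional;
# case metadata repeated, professional columns empty when a case has none).
# JSONL dialect: one JSON object per case per line.

.minute_cols <- function() {
  c("t",
    paste0("dial_", volatile_agents()),
    "fgf_total",
    "flow_oxygen", "flow_air", "flow_nitrous_oxide",
    paste0("et_", volatile_agents()),
    paste0("cum_", volatile_agents()))
}

.gas_flow_cols <- function() c("flow_oxygen", "flow_air", "flow_nitrous_oxide")

.prof_cols <- function() c("professional_id", "role", "t_in", "t_out")

#' Build a canonical device-minutes data frame
#'
#' Fills absent optional columns with `NA` and orders columns canonically.
#' Required columns: `t`, `fgf_total`, and at least one `dial_<agent>` column.
#'
#' @param df Data frame of per-minute records.
#' @return Data frame with the canonical column set.
#' @export
device_minutes <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("t", "fgf_total")
  missing_req <- setdiff(need, names(df))
  if (length(missing_req)) {
    stop("flowsheet schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  if (!any(paste0("dial_", volatile_agents()) %in% names(df))) {
    stop("flowsheet schema error: missing required column(s): ",
         "at least one dial_<agent> column")
  }
  out <- df
  for (col in .minute_cols()) {
    if (!col %in% names(out)) out[[col]] <- rep(NA_real_, nrow(out))
    out[[col]] <- as.numeric(out[[col]])
  }
  out <- out[, .minute_cols(), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a surgical case record
#'
#' @param case_id Opaque case identifier (character scalar).
#' @param patient_age Age in years, strictly positive; fractional allowed.
#' @param procedure_start,procedure_stop Procedure timing events, in minutes
#'   on the case clock (minute 0 is the first device record).
#' @param minutes Data frame of device minutes (see [device_minutes()]).
#' @param professionals Optional data frame with columns `professional_id`,
#'   `role` (attending/crna/resident), `t_in`, `t_out`.
#' @param location Care location label; `"or"` for a standard operating room.
#'   Non-OR labels (`"pediatric_induction"`, `"non_or"`,
#'   `"labor_and_delivery"`) are excluded from reporting downstream.
#' @param case_date Optional `Date` used for monthly cohort aggregation.
#' @param validate Run invariant checks and fail on violations.
#' @return Object of class `case_record`.
#' @export
case_record <- function(case_id, patient_age, procedure_start, procedure_stop,
                        minutes, professionals = NULL, location = "or",
                        case_date = as.Date(NA), validate = TRUE) {
  if (is.null(professionals) || nrow(as.data.frame(professionals)) == 0L) {
    professionals <- data.frame(professional_id = character(),
                                role = character(),
                                t_in = numeric(), t_out = numeric(),
                                stringsAsFactors = FALSE)
  } else {
    professionals <- as.data.frame(professionals)[, .prof_cols(), drop = FALSE]
    professionals$professional_id <- as.character(professionals$professional_id)
    professionals$role <- as.character(professionals$role)
    rownames(professionals) <- NULL
  }
  x <- structure(list(case_id = as.character(case_id),
                      location = as.character(location),
                      patient_age = as.numeric(patient_age),
                      case_date = as.Date(case_date),
                      procedure_start = as.numeric(procedure_start),
                      procedure_stop = as.numeric(procedure_stop),
                      minutes = device_minutes(minutes),
                      professionals = professionals),
                 class = "case_record")
  if (validate) {
    issues <- validate_case(x)
    if (length(issues)) {
      stop("invalid case '", x$case_id, "':\n  ",
           paste(issues, collapse = "\n  "))
    }
  }
  x
}

#' @export
print.case_record <- function(x, ...) {
  cat("<case_record> ", x$case_id,
      "  location=", x$location,
      "  age=", format(x$patient_age),
      "  minutes=", nrow(x$minutes),
      "  procedure=[", x$procedure_start, ",", x$procedure_stop, ")\n",
      sep = "")
  invisible(x)
}

#' Validate a case record against the flowsheet invariants
#'
#' Checks timestamps (non-negative, strictly increasing, no duplicates),
#' non-negativity of concentrations and flows, consistency of per-gas flows
#' with total FGF, monotone cumulative liquid volumes, procedure event order
#' and professional intervals. Missing minutes are never filled in.
#'
#' @param case A `case_record`.
#' @return Character vector of issues; empty when the case is valid.
#' @export
validate_case <- function(case) {
  issues <- character()
  m <- case$minutes
  add <- function(msg) issues <<- c(issues, msg)

  if (!is.finite(case$patient_age) || case$patient_age <= 0) {
    add("patient_age must be > 0")
  }
  if (is.finite(case$procedure_start) && is.finite(case$procedure_stop) &&
      case$procedure_start >= case$procedure_stop) {
    add("procedure_start must precede procedure_stop")
  }
  if (nrow(m)) {
    if (any(m$t < 0, na.rm = TRUE)) add("t must be >= 0")
    if (anyNA(m$t)) add("t must not be missing")
    dup <- m$t[duplicated(m$t)]
    if (length(dup)) {
      add(paste0("duplicate timestamps: t=", paste(unique(dup), collapse = ",")))
    } else if (is.unsorted(m$t, strictly = TRUE)) {
      add("minutes not strictly increasing in t")
    }
    nonneg <- setdiff(.minute_cols(), "t")
    for (col in nonneg) {
      bad <- which(m[[col]] < 0)
      if (length(bad)) {
        add(paste0(col, " negative at row(s) ", paste(bad, collapse = ",")))
      }
    }
    gf <- .gas_flow_cols()
    have_all <- stats::complete.cases(m[, gf, drop = FALSE])
    if (any(have_all)) {
      s <- rowSums(m[, gf, drop = FALSE])
      bad <- which(have_all & abs(s - m$fgf_total) > 1e-6)
      if (length(bad)) {
        add(paste0("per-gas flows do not sum to fgf_total at row(s) ",
                   paste(bad, collapse = ",")))
      }
    }
    for (ag in volatile_agents()) {
      cc <- m[[paste0("cum_", ag)]]
      obs <- which(!is.na(cc))
      if (length(obs) > 1L) {
        d <- diff(cc[obs])
        if (any(d < -1e-9)) {
          rows <- obs[which(d < -1e-9) + 1L]
          add(paste0("cumulative liquid volume for ", ag,
                     " decreases at row(s) ", paste(rows, collapse = ",")))
        }
      }
    }
  }
  p <- case$professionals
  if (nrow(p)) {
    bad <- which(!(p$t_in < p$t_out))
    if (length(bad)) {
      add(paste0("professional interval t_in >= t_out at row(s) ",
                 paste(bad, collapse = ",")))
    }
  }
  issues
}

#' Validate a cohort, reporting issues per case
#'
#' @param cases List of `case_record`s.
#' @return Data frame with columns `case_id`, `issue` (zero rows when clean).
#' @export
validate_cohort <- function(cases) {
  rows <- lapply(cases, function(cs) {
    iss <- validate_case(cs)
    if (!length(iss)) return(NULL)
    data.frame(case_id = cs$case_id, issue = iss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(case_id = character(), issue = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Align a case to the one-minute evaluation grid
#'
#' The advisory rules are evaluated once per minute, so the minute grid is the
#' engine's native clock. Fractional timestamps are snapped to the floor
#' minute (with a warning); rows are sorted by time; duplicate timestamps are
#' an error. Gaps are left explicit -- no minutes are imputed, ever.
#'
#' @param case A `case_record`.
#' @return The case with `minutes$t` on an integer grid. Idempotent.
#' @export
normalize_to_minute_grid <- function(case) {
  m <- case$minutes
  if (!nrow(m)) return(case)
  t_floor <- floor(m$t)
  if (any(t_floor != m$t)) {
    warning("case '", case$case_id, "': ", sum(t_floor != m$t),
            " record(s) snapped to the floor minute")
    m$t <- t_floor
  }
  if (anyDuplicated(m$t)) {
    stop("case '", case$case_id, "': duplicate timestamps after snapping: t=",
         paste(unique(m$t[duplicated(m$t)]), collapse = ","))
  }
  if (is.unsorted(m$t)) m <- m[order(m$t), , drop = FALSE]
  rownames(m) <- NULL
  case$minutes <- m
  case
}

# ---- serialization -----------------------------------------------------------

.csv_paths <- function(path) {
  list(minutes = paste0(path, "_minutes.csv"), cases = paste0(path, "_cases.csv"))
}

# Render a double losslessly: shortest of %.15g/%.17g that round-trips to
# the identical bit pattern, so write -> read -> write is byte-stable.
.fmt_double <- function(v) {
  if (is.na(v)) return("")
  s <- sprintf("%.15g", v)
  if (as.numeric(s) == v) s else sprintf("%.17g", v)
}

# Format numeric columns as lossless strings; returns the data frame plus
# the indices of the genuinely-character columns (the only ones quoted).
.fmt_csv_frame <- function(df) {
  char_cols <- which(vapply(df, is.character, logical(1)))
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) {
      df[[cn]] <- vapply(df[[cn]], .fmt_double, character(1))
    }
  }
  list(df = df, quote = unname(char_cols))
}

#' Write a cohort of cases to disk
#'
#' Lossless serialization with a stable column order; missing optional values
#' are written as empty cells, never as zero. Writing the result of
#' [read_cases()] reproduces the files byte for byte.
#'
#' @param cases List of `case_record`s.
#' @param path For `"csv"`, a path prefix (two files,
#'   `<prefix>_minutes.csv` and `<prefix>_cases.csv`, are written); for
#'   `"jsonl"`, the output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") .write_cases_csv(cases, path) else .write_cases_jsonl(cases, path)
  invisible(path)
}

.write_cases_csv <- function(cases, path) {
  fp <- .csv_paths(path)
  min_rows <- lapply(cases, function(cs) {
    if (!nrow(cs$minutes)) return(NULL)
    cbind(data.frame(case_id = cs$case_id, stringsAsFactors = FALSE), cs$minutes)
  })
  mdf <- do.call(rbind, min_rows)
  if (is.null(mdf)) {
    mdf <- cbind(data.frame(case_id = character(), stringsAsFactors = FALSE),
                 device_minutes(data.frame(t = numeric(), fgf_total = numeric(),
                                           dial_sevoflurane = numeric())))[0, ]
  }
  fm <- .fmt_csv_frame(mdf)
  utils::write.csv(fm$df, fp$minutes, row.names = FALSE, na = "",
                   quote = fm$quote)

  meta_rows <- lapply(cases, function(cs) {
    base <- data.frame(case_id = cs$case_id, location = cs$location,
                       patient_age = cs$patient_age,
                       case_date = as.character(cs$case_date),
                       procedure_start = cs$procedure_start,
                       procedure_stop = cs$procedure_stop,
                       stringsAsFactors = FALSE)
    p <- cs$professionals
    if (!nrow(p)) {
      p <- data.frame(professional_id = NA_character_, role = NA_character_,
                      t_in = NA_real_, t_out = NA_real_, stringsAsFactors = FALSE)
    }
    cbind(base[rep(1L, nrow(p)), , drop = FALSE], p)
  })
  cdf <- do.call(rbind, meta_rows)
  if (is.null(cdf)) {
    cdf <- data.frame(case_id = character(), location = character(),
                      patient_age = numeric(), case_date = character(),
                      procedure_start = numeric(), procedure_stop = numeric(),
                      professional_id = character(), role = character(),
                      t_in = numeric(), t_out = numeric(), stringsAsFactors = FALSE)
  }
  rownames(cdf) <- NULL
  fc <- .fmt_csv_frame(cdf)
  utils::write.csv(fc$df, fp$cases, row.names = FALSE, na = "",
                   quote = fc$quote)
}

.case_to_list <- function(cs) {
  list(case_id = cs$case_id,
       location = cs$location,
       patient_age = cs$patient_age,
       case_date = if (is.na(cs$case_date)) NULL else as.character(cs$case_date),
       procedure_start = cs$procedure_start,
       procedure_stop = cs$procedure_stop,
       minutes = cs$minutes,
       professionals = cs$professionals)
}

.write_cases_jsonl <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    jsonlite::toJSON(.case_to_list(cs), dataframe = "columns", na = "null",
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
}

#' Read a cohort of cases from disk
#'
#' Parses the documented CSV or JSONL dialect, sorts minutes by time (warning
#' when rows arrive out of order), and validates every case; validation
#' failures are reported with the case id and offending rows.
#'
#' @inheritParams write_cases
#' @return List of `case_record`s.
#' @export
read_cases <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") .read_cases_csv(path) else .read_cases_jsonl(path)
}

.assemble_case <- function(case_id, location, patient_age, case_date,
                           procedure_start, procedure_stop, minutes, profs) {
  if (nrow(minutes) && is.unsorted(minutes$t)) {
    warning("case '", case_id, "': minutes out of time order; sorting")
    minutes <- minutes[order(minutes$t), , drop = FALSE]
    rownames(minutes) <- NULL
  }
  cs <- case_record(case_id = case_id, location = location,
                    patient_age = patient_age,
                    case_date = if (is.null(case_date) || is.na(case_date) ||
                                    !nzchar(case_date)) as.Date(NA)
                                else as.Date(case_date),
                    procedure_start = procedure_start,
                    procedure_stop = procedure_stop,
                    minutes = minutes, professionals = profs, validate = FALSE)
  issues <- validate_case(cs)
  if (length(issues)) {
    stop("validation error in case '", case_id, "':\n  ",
         paste(issues, collapse = "\n  "))
  }
  cs
}

.read_cases_csv <- function(path) {
  fp <- .csv_paths(path)
  for (f in unlist(fp)) {
    if (!file.exists(f)) stop("flowsheet file not found: ", f)
  }
  mdf <- utils::read.csv(fp$minutes, colClasses = c(case_id = "character"),
                         stringsAsFactors = FALSE)
  req <- c("case_id", "t", "fgf_total")
  missing_req <- setdiff(req, names(mdf))
  if (length(missing_req)) {
    stop("flowsheet schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  cdf <- utils::read.csv(fp$cases, colClasses = c(case_id = "character"),
                         stringsAsFactors = FALSE)
  if (!"case_id" %in% names(cdf)) {
    stop("flowsheet schema error: missing required column(s): case_id")
  }
  ids <- unique(cdf$case_id)
  lapply(ids, function(id) {
    meta <- cdf[cdf$case_id == id, , drop = FALSE]
    profs <- meta[!is.na(meta$professional_id) &
                    nzchar(meta$professional_id), .prof_cols(), drop = FALSE]
    m <- mdf[mdf$case_id == id, setdiff(names(mdf), "case_id"), drop = FALSE]
    .assemble_case(id, meta$location[1], meta$patient_age[1],
                   meta$case_date[1], meta$procedure_start[1],
                   meta$procedure_stop[1], device_minutes(m), profs)
  })
}

.read_cases_jsonl <- function(path) {
  if (!file.exists(path)) stop("flowsheet file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    m <- as.data.frame(obj$minutes)
    missing_req <- setdiff(c("t", "fgf_total"), names(m))
    if (length(missing_req)) {
      stop("flowsheet schema error: missing required column(s): ",
           paste(missing_req, collapse = ", "))
    }
    profs <- if (!is.null(obj$professionals) &&
                 length(obj$professionals$professional_id)) {
      as.data.frame(obj$professionals)
    } else NULL
    .assemble_case(obj$case_id, obj$location, obj$patient_age,
                   obj$case_date %||% NA_character_,
                   obj$procedure_start %||% NA_real_,
                   obj$procedure_stop %||% NA_real_,
                   device_minutes(m), profs)
  })
}
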