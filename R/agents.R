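# Agent physical/pharmacologic constants and the conversions built on them:
# vapor <-> liquid volume, age-adjusted MAC, and GWP-based CO2e accounting.

#' Volatile anesthetic agents recognized by the package
#'
#' The three halogenated agents the advisory engine and the reporting pipeline
#' operate on. Nitrous oxide, oxygen and air are carrier gases: they contribute
#' to total fresh gas flow but carry no MAC or vapor-conversion entry.
#'
#' @return Character vector of agent names.
#' @export
volatile_agents <- function() c("sevoflurane", "isoflurane", "desflurane")

#' @rdname volatile_agents
#' @export
carrier_gases <- function() c("nitrous_oxide", "oxygen", "air")

# ideal-gas molar volume at 0 degC / 1 atm, mL/mol
.MOLAR_VOLUME_0C_ML <- 22413.97
# slope of log10(MAC) per year of age (iso-MAC power relation)
.MAC_AGE_SLOPE <- -0.00269
.MAC_REFERENCE_AGE <- 40

.agents_cache <- new.env(parent = emptyenv())

#' Load the agent constants table
#'
#' Constants (molecular weight, liquid density, MAC at age 40, GWP100) are
#' shipped as an editable YAML file rather than hard-coded, so a site can
#' substitute its own inventory values. The default table is cached after the
#' first read.
#'
#' @param path Path to a YAML constants file; `NULL` uses the table shipped
#'   with the package.
#' @return An object of class `agent_constants`: a list with elements `table`
#'   (data frame with columns `agent`, `mw_g_per_mol`, `density_g_per_ml`,
#'   `mac40_pct`, `gwp100`), `reference_temperature_c`, and `provenance`.
#' @export
agent_constants <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache && !is.null(.agents_cache$default)) {
    return(.agents_cache$default)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "agent_constants.yaml", package = "fgfcds")
  }
  if (!file.exists(path)) {
    stop("agent constants file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(raw$agents, function(a) {
    data.frame(agent = a$agent,
               mw_g_per_mol = as.numeric(a$mw_g_per_mol),
               density_g_per_ml = as.numeric(a$density_g_per_ml),
               mac40_pct = as.numeric(a$mac40_pct),
               gwp100 = as.numeric(a$gwp100),
               stringsAsFactors = FALSE)
  }))
  out <- structure(list(table = tab,
                        reference_temperature_c =
                          as.numeric(raw$reference_temperature_c %||% 21),
                        provenance = raw$provenance %||% ""),
                   class = "agent_constants")
  validate_agent_constants(out)
  if (use_cache) .agents_cache$default <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_agent_constants <- function(x) {
  tab <- x$table
  num <- c("mw_g_per_mol", "density_g_per_ml", "mac40_pct", "gwp100")
  for (col in num) {
    if (any(!is.finite(tab[[col]]) | tab[[col]] <= 0)) {
      stop("agent constants: column '", col, "' must be strictly positive")
    }
  }
  if (anyDuplicated(tab$agent)) stop("agent constants: duplicated agent entries")
  invisible(x)
}

#' @export
print.agent_constants <- function(x, ...) {
  cat("Agent constants (reference temperature ",
      x$reference_temperature_c, " degC)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

.agent_row <- function(agent, constants) {
  if (length(agent) != 1L || !agent %in% constants$table$agent) {
    stop("unsupported agent '", paste(agent, collapse = ","),
         "': no constants entry (volatile agents only)")
  }
  constants$table[constants$table$agent == agent, , drop = FALSE]
}

#' Vapor volume produced per mL of liquid agent
#'
#' Ideal-gas conversion at the configured reference temperature (default
#' 21 degC, vaporizer output at room temperature): one mL of liquid of density
#' rho and molecular weight MW yields `rho / MW` moles, i.e.
#' `rho / MW * V_m(T)` mL of vapor.
#'
#' @param agent A volatile agent name.
#' @param constants Constants table, see [agent_constants()].
#' @return mL of vapor per mL of liquid (dimensionless ratio).
#' @export
vapor_volume_per_ml_liquid <- function(agent, constants = agent_constants()) {
  row <- .agent_row(agent, constants)
  t_k <- 273.15 + constants$reference_temperature_c
  v_m <- .MOLAR_VOLUME_0C_ML * t_k / 273.15
  row$density_g_per_ml / row$mw_g_per_mol * v_m
}

#' Liquid agent consumed over a delivery interval
#'
#' Calculated consumption for machines that do not report cumulative liquid
#' volume: the vapor delivered is `dial_pct/100 * fgf * duration` litres,
#' converted to mL of liquid through the vapor/liquid ratio. Linear in each
#' argument and exactly additive over any partition of the interval.
#'
#' @param agent A volatile agent name.
#' @param fgf_l_min Total fresh gas flow, L/min (non-negative).
#' @param dial_pct Set (dial) agent concentration, vol% (non-negative).
#' @param duration_min Interval length in minutes (non-negative).
#' @param constants Constants table.
#' @return mL of liquid agent. Vectorized over the numeric arguments.
#' @export
liquid_ml_consumed <- function(agent, fgf_l_min, dial_pct, duration_min,
                               constants = agent_constants()) {
  if (any(fgf_l_min < 0, na.rm = TRUE) || any(dial_pct < 0, na.rm = TRUE) ||
      any(duration_min < 0, na.rm = TRUE)) {
    stop("liquid_ml_consumed: fgf, dial and duration must be non-negative")
  }
  ratio <- vapor_volume_per_ml_liquid(agent, constants)
  (dial_pct / 100) * fgf_l_min * 1000 * duration_min / ratio
}

#' Age-adjusted MAC
#'
#' MAC declines with age; the standard iso-MAC power relation
#' `MAC(age) = MAC40 * 10^(-0.00269 * (age - 40))` is used, anchored at the
#' reference age of 40.
#'
#' @param agent A volatile agent name.
#' @param age_years Patient age in years, strictly positive; fractional ages
#'   allowed. Vectorized.
#' @param constants Constants table.
#' @return Age-adjusted MAC in vol%.
#' @export
age_adjusted_mac_pct <- function(agent, age_years,
                                 constants = agent_constants()) {
  if (any(!is.finite(age_years) | age_years <= 0)) {
    stop("age_adjusted_mac_pct: age must be > 0")
  }
  row <- .agent_row(agent, constants)
  row$mac40_pct * 10^(.MAC_AGE_SLOPE * (age_years - .MAC_REFERENCE_AGE))
}

#' Range of 100-year global warming potentials across the volatile agents
#'
#' @param constants Constants table.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
gwp_range <- function(constants = agent_constants()) {
  g <- constants$table$gwp100
  c(min = min(g), max = max(g))
}

#' CO2-equivalent mass of a consumed liquid volume
#'
#' `liquid_ml * density` grams of agent released, scaled by GWP100, reported
#' in kg CO2e.
#'
#' @param agent A volatile agent name.
#' @param liquid_ml mL of liquid agent consumed (vectorized).
#' @param constants Constants table.
#' @return kg CO2-equivalent.
#' @export
co2e_kg <- function(agent, liquid_ml, constants = agent_constants()) {
  if (any(liquid_ml < 0, na.rm = TRUE)) stop("co2e_kg: volume must be non-negative")
  row <- .agent_row(agent, constants)
  liquid_ml * row$density_g_per_ml * row$gwp100 / 1000
}
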