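# Site configuration presets: the five deployed configurations across the
# health network (alert type/display and FGF threshold per site).

.SITE_PRESETS <- list(
  ucsf   = list(mode = "noninterruptive", threshold = 0.7),
  `uc-a` = list(mode = "interruptive",    threshold = 0.7),
  `uc-b` = list(mode = "passive",         threshold = 1.0),
  `uc-c` = list(mode = "noninterruptive", threshold = 0.7),
  `uc-d` = list(mode = "noninterruptive", threshold = 1.0)
)

#' Site configuration presets
#'
#' Expands a site preset name into a full [alert_config()]: `ucsf`, `uc-c`
#' (active noninterruptive, threshold 0.7 L/min), `uc-a` (active
#' interruptive, 0.7), `uc-b` (passive, 1), `uc-d` (active noninterruptive,
#' 1). Remaining parameters take the engine defaults unless overridden.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [alert_config()].
#' @return An `alert_config`.
#' @export
site_preset <- function(name, ...) {
  if (!name %in% names(.SITE_PRESETS)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(.SITE_PRESETS), collapse = ", "))
  }
  p <- .SITE_PRESETS[[name]]
  args <- utils::modifyList(list(threshold = p$threshold, mode = p$mode),
                            list(...))
  do.call(alert_config, args)
}

#' @rdname site_preset
#' @export
preset_names <- function() names(.SITE_PRESETS)
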