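# Scenario presets mirroring the experimental design grids: twelve rig
# presets (PA/PB/PC archetypes crossed with 10/12/14/16 s on-delay timer
# settings) plus the breath-family validation anchor (6 mm^2 exhalation
# valve).

.rig_delays <- c(`1` = 10, `2` = 12, `3` = 14, `4` = 16)

#' Names of the built-in scenario presets
#'
#' @return Character vector: `PA1`-`PA4` (5/2 valve), `PB1`-`PB4` (5/3),
#'   `PC1`-`PC4` (3/2) with timer settings 10/12/14/16 s, plus `validation`
#'   (the breath-family anchor scenario).
#' @export
preset_names <- function() {
  c(
    paste0(rep(c("PA", "PB", "PC"), each = 4), rep(1:4, 3)),
    "validation"
  )
}

#' Resolve a named scenario preset
#'
#' Rig presets pair a valve archetype with an on-delay timer setting
#' (`PA3` = 5/2 valve, 14 s timer); `validation` is the default breath
#' scenario anchored at the 6 mm^2 exhalation-valve effective area, a 500 mL
#' tidal volume, 1.2 s inspiration and 1.6 s exhaust.
#'
#' @param name One of [preset_names()].
#' @param ... Overrides passed to [update_scenario()].
#' @return A `vent_scenario`.
#' @examples
#' make_preset("PA1")$timer_delay # 10
#' @export
make_preset <- function(name, ...) {
  valid <- preset_names()
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    stop(sprintf(
      "unknown preset '%s'; valid presets: %s",
      as.character(name)[1], paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  sc <- if (name == "validation") {
    vent_scenario(exhaust_area = 6, archetype = "5/2")
  } else {
    fam <- substr(name, 1, 2)
    idx <- substr(name, 3, 3)
    vent_scenario(
      family = "rig",
      archetype = c(PA = "5/2", PB = "5/3", PC = "3/2")[[fam]],
      timer_delay = .rig_delays[[idx]],
      n_cycles = 2, washout = 1
    )
  }
  if (length(list(...)) > 0) sc <- update_scenario(sc, ...) else sc
}
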