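#' Multi-phase walking schedule for a foot model
#'
#' One step of walking (heel strike to the mirrored next heel strike) as an
#' ordered sequence of instantaneous impact phases and continuous contact
#' phases. The ellipse foot yields 4 phases (impact, double stance, single
#' stance, mirrored impact); the double-circle foot yields 7 (heel-strike
#' impact, heel/forefoot double stance, forefoot-strike impact, full double
#' stance, flat single stance, forefoot single stance, mirrored impact).
#' The left foot is the newly landing foot throughout; the final impact is
#' the first one with the legs mirrored.
#'
#' @param foot_model `"ellipse"` or `"double_circle"`.
#' @return an object of class `phase_schedule` with the full `phases` list,
#'   the continuous-phase linkage table `cont`, and the `final_impact`
#'   descriptor.
#' @export
build_phase_schedule <- function(foot_model = c("ellipse", "double_circle")) {
  foot_model <- match.arg(foot_model)
  if (foot_model == "ellipse") {
    phases <- list(
      list(name = "1e*", type = "impact", label = "DSa",
           touchdown = list(foot = "left", shape = "ellipse")),
      list(name = "2e", type = "continuous", label = "DSb",
           modes = c("ellipse_roll", "ellipse_roll")),
      list(name = "3e", type = "continuous", label = "SSa",
           modes = c("ellipse_roll", "airborne")),
      list(name = "4e*", type = "impact", label = "DSa (mirrored)",
           touchdown = list(foot = "right", shape = "ellipse")))
    cont <- list(
      list(name = "2e", modes = c("ellipse_roll", "ellipse_roll"),
           entry = "impact_v0",
           touchdown = list(foot = "left", shape = "ellipse")),
      list(name = "3e", modes = c("ellipse_roll", "airborne"),
           entry = "identity", swing_foot = "right"))
    final_impact <- list(modes = c("ellipse_roll", "ellipse_roll"),
                         touchdown = list(foot = "right", shape = "ellipse"))
  } else {
    phases <- list(
      list(name = "1c*", type = "impact", label = "DSa",
           touchdown = list(foot = "left", shape = "heel")),
      list(name = "2c", type = "continuous", label = "DSb",
           modes = c("heel_roll", "forefoot_roll")),
      list(name = "3c*", type = "impact", label = "DSc",
           touchdown = list(foot = "left", shape = "forefoot")),
      list(name = "4c", type = "continuous", label = "DSd",
           modes = c("heel_roll_forefoot_touch", "forefoot_roll")),
      list(name = "5c", type = "continuous", label = "SSa",
           modes = c("heel_roll_forefoot_touch", "airborne")),
      list(name = "6c", type = "continuous", label = "SSb",
           modes = c("forefoot_roll", "airborne")),
      list(name = "7c*", type = "impact", label = "DSa (mirrored)",
           touchdown = list(foot = "right", shape = "heel")))
    cont <- list(
      list(name = "2c", modes = c("heel_roll", "forefoot_roll"),
           entry = "impact_v0",
           touchdown = list(foot = "left", shape = "heel")),
      list(name = "4c", modes = c("heel_roll_forefoot_touch", "forefoot_roll"),
           entry = "impact",
           touchdown = list(foot = "left", shape = "forefoot")),
      list(name = "5c", modes = c("heel_roll_forefoot_touch", "airborne"),
           entry = "identity", swing_foot = "right"),
      list(name = "6c", modes = c("forefoot_roll", "airborne"),
           entry = "identity", swing_foot = "right"))
    final_impact <- list(modes = c("forefoot_roll", "heel_roll"),
                         touchdown = list(foot = "right", shape = "heel"))
  }
  structure(list(foot_model = foot_model, phases = phases, cont = cont,
                 final_impact = final_impact),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("phase_schedule (%s foot): %d phases\n", x$foot_model,
              length(x$phases)))
  for (p in x$phases) {
    if (p$type == "impact")
      cat(sprintf("  %-4s impact    %s (touchdown: %s %s)\n", p$name, p$label,
                  p$touchdown$foot, p$touchdown$shape))
    else
      cat(sprintf("  %-4s continuous %s  L=%s R=%s\n", p$name, p$label,
                  p$modes[1], p$modes[2]))
  }
  invisible(x)
}

# constraint rows of a mode pair, as row descriptors (foot, kind, shape order
# follows build order in the core)
mode_rows <- function(modes) {
  out <- list()
  for (side in 1:2) {
    m <- modes[side]
    foot <- c("left", "right")[side]
    add <- switch(m,
      airborne = list(),
      ellipse_roll = list(c("contact", "ellipse"), c("rolling", "ellipse")),
      heel_roll = list(c("contact", "heel"), c("rolling", "heel")),
      forefoot_roll = list(c("contact", "forefoot"), c("rolling", "forefoot")),
      heel_roll_forefoot_touch = list(c("contact", "heel"), c("rolling", "heel"),
                                      c("contact", "forefoot")),
      forefoot_roll_heel_touch = list(c("contact", "forefoot"),
                                      c("rolling", "forefoot"),
                                      c("contact", "heel")))
    for (r in add)
      out[[length(out) + 1]] <- list(foot = foot, kind = r[1], shape = r[2])
  }
  out
}

# indices of rows of `from` not present in `to` (dropped at a mode switch),
# and rows of `to` not present in `from` (newly imposed)
mode_switch_rows <- function(from, to) {
  key <- function(rows) vapply(rows, function(r)
    paste(r$foot, r$kind, r$shape), "")
  rf <- mode_rows(from); rt <- mode_rows(to)
  kf <- key(rf); kt <- key(rt)
  list(dropped = which(!kf %in% kt), added_rows = rt[!kt %in% kf],
       added = which(!kt %in% kf))
}
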