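#' Assemble a walking model
#'
#' Bundles body parameters, a foot-ground contact geometry (shared by both
#' feet) and, optionally, the MTG actuation set into a single model object
#' used by the dynamics, simulation and optimal-control functions.
#'
#' @param body a [body_parameters()] object.
#' @param foot a `foot_params` object ([ellipse_foot()] or
#'   [double_circle_foot()]).
#' @param actuators an `actuation_set` ([default_actuators()]), or `NULL`
#'   for a torque-free passive model.
#' @param baumgarte length-2 vector of constraint-stabilization gains:
#'   position gain (1/s^2) and velocity gain (1/s). The default (100, 20) is
#'   critically damped with a 0.1 s time constant.
#' @return an object of class `gait_model`.
#' @export
gait_model <- function(body, foot, actuators = NULL, baumgarte = c(100, 20)) {
  stopifnot(inherits(body, "body_parameters"), inherits(foot, "foot_params"))
  core <- list(body = list(mass = unname(body$mass), inertia = unname(body$inertia),
                           len_thigh = body$len_thigh, len_shank = body$len_shank,
                           com = unname(body$com), g = body$g),
               foot = foot_core(foot),
               act = act_core(actuators))
  structure(list(body = body, foot = foot, actuators = actuators,
                 baumgarte = baumgarte, core = core),
            class = "gait_model")
}

#' Default walking model
#'
#' Convenience constructor: default anthropometry, a default foot geometry
#' and (optionally) the default actuator set.
#' @param foot_model `"ellipse"` or `"double_circle"`.
#' @param actuated include the MTG actuation set?
#' @inheritParams default_body_parameters
#' @return a [gait_model()].
#' @export
default_gait_model <- function(foot_model = c("ellipse", "double_circle"),
                               actuated = TRUE, total_mass = 81.7,
                               height = 1.72) {
  foot_model <- match.arg(foot_model)
  gait_model(default_body_parameters(total_mass, height),
             default_foot(foot_model),
             if (actuated) default_actuators() else NULL)
}

core_model <- function(model) {
  if (inherits(model, "gait_model")) return(model$core)
  if (inherits(model, "body_parameters"))
    return(list(body = list(mass = unname(model$mass), inertia = unname(model$inertia),
                            len_thigh = model$len_thigh, len_shank = model$len_shank,
                            com = unname(model$com), g = model$g),
                # geometry stub: body-only operations never touch the foot
                foot = list(type = 0L, r_E = c(0, 0), theta_E = 0,
                            r_x = 0.1, r_y = 0.1),
                act = NULL))
  stop("expected a gait_model or body_parameters object")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("gait_model: planar 7-segment, 9-DoF walking model\n")
  cat(sprintf("  total mass %.1f kg, foot: %s, %s\n", sum(x$body$mass),
              if (inherits(x$foot, "ellipse_foot")) "ellipse" else "double-circle",
              if (is.null(x$actuators)) "passive (no MTGs)" else "12 MTGs + damping"))
  invisible(x)
}
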