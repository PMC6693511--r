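#' Rigid foot-ground contact geometries
#'
#' Two rigid roll-over geometries are supported, both defined in the ankle
#' frame (origin at the ankle joint, x forward, z up):
#'
#' * the **ellipse foot**: a single ellipse with centre offset `r_E`,
#'   orientation `theta_E` relative to the ankle frame and semi-axes
#'   `r_x >= r_y`; it contacts the ground at the point of closest approach
#'   and rolls without slipping.
#' * the **double-circle foot**: a heel circle (centre `r_H`, radius `rad_H`)
#'   and a forefoot circle (centre `r_F`, radius `rad_F`); one circle rolls
#'   while the other may additionally touch (contact constraint only) so the
#'   foot is never over-constrained.
#'
#' Total foot length is `2 * r_x` for the ellipse and
#' `(r_F_x + rad_F) - (r_H_x - rad_H)` for the double circle.
#'
#' @param r_E,r_H,r_F 2-vectors, ankle-frame centre offsets (m).
#' @param theta_E ellipse orientation relative to the ankle frame (rad).
#' @param r_x,r_y ellipse semi-axes (m), `r_x >= r_y > 0`.
#' @param rad_H,rad_F circle radii (m).
#' @return an object of class `ellipse_foot` or `double_circle_foot`, both
#'   inheriting from `foot_params`.
#' @export
ellipse_foot <- function(r_E, theta_E, r_x, r_y) {
  if (!(r_x >= r_y && r_y > 0)) stop("ellipse requires r_x >= r_y > 0")
  structure(list(r_E = as.numeric(r_E), theta_E = as.numeric(theta_E),
                 r_x = r_x, r_y = r_y),
            class = c("ellipse_foot", "foot_params"))
}

#' @rdname ellipse_foot
#' @export
double_circle_foot <- function(r_H, rad_H, r_F, rad_F) {
  r_H <- as.numeric(r_H); r_F <- as.numeric(r_F)
  if (rad_H <= 0 || rad_F <= 0) stop("circle radii must be > 0")
  if (r_F[1] <= r_H[1]) stop("forefoot centre must be forward of the heel centre")
  structure(list(r_H = r_H, rad_H = rad_H, r_F = r_F, rad_F = rad_F),
            class = c("double_circle_foot", "foot_params"))
}

#' Total foot length implied by the contact geometry
#' @param foot a `foot_params` object.
#' @return length in metres.
#' @export
foot_length <- function(foot) UseMethod("foot_length")

#' @export
foot_length.ellipse_foot <- function(foot) 2 * foot$r_x

#' @export
foot_length.double_circle_foot <- function(foot)
  (foot$r_F[1] + foot$rad_F) - (foot$r_H[1] - foot$rad_H)

#' @export
print.ellipse_foot <- function(x, ...) {
  cat(sprintf("ellipse foot: centre (%.4f, %.4f) m, theta %.4f rad, semi-axes %.4f / %.4f m (length %.3f m)\n",
              x$r_E[1], x$r_E[2], x$theta_E, x$r_x, x$r_y, foot_length(x)))
  invisible(x)
}

#' @export
print.double_circle_foot <- function(x, ...) {
  cat(sprintf("double-circle foot: heel (%.4f, %.4f) r %.4f m; forefoot (%.4f, %.4f) r %.4f m (length %.3f m)\n",
              x$r_H[1], x$r_H[2], x$rad_H, x$r_F[1], x$r_F[2], x$rad_F,
              foot_length(x)))
  invisible(x)
}

#' Default fitted foot geometries
#'
#' Reads the foot-parameter config shipped with the package
#' (`inst/extdata/foot_default.yaml`, values in cm, converted to m on load).
#' @param model `"ellipse"` or `"double_circle"`.
#' @param path alternative config file.
#' @return a `foot_params` object.
#' @export
default_foot <- function(model = c("ellipse", "double_circle"), path = NULL) {
  model <- match.arg(model)
  path <- path %||% system.file("extdata", "foot_default.yaml",
                                package = "rigidfoot", mustWork = TRUE)
  read_foot_config(path, model)
}

#' Read / write foot parameters as a structured config file
#'
#' YAML with explicit units: values under a `cm` unit key are converted to
#' metres on input. Parameter names follow the ankle-frame convention
#' (`r_E`, `theta_E`, `r_x`, `r_y`; `r_H`, `rad_H`, `r_F`, `rad_F`).
#' @param path file path.
#' @param model which foot block to read when the file holds both.
#' @param foot a `foot_params` object to write.
#' @param units `"m"` or `"cm"` for output.
#' @export
read_foot_config <- function(path, model = c("ellipse", "double_circle")) {
  model <- match.arg(model)
  y <- yaml::read_yaml(path)
  blk <- y[[model]]
  if (is.null(blk)) stop("config has no '", model, "' block")
  u <- blk$units %||% "m"
  k <- if (identical(u, "cm")) 0.01 else if (identical(u, "m")) 1 else
    stop("unknown units '", u, "' in foot config")
  if (model == "ellipse")
    ellipse_foot(r_E = k * unlist(blk$r_E), theta_E = blk$theta_E,
                 r_x = k * blk$r_x, r_y = k * blk$r_y)
  else
    double_circle_foot(r_H = k * unlist(blk$r_H), rad_H = k * blk$rad_H,
                       r_F = k * unlist(blk$r_F), rad_F = k * blk$rad_F)
}

#' @rdname read_foot_config
#' @export
write_foot_config <- function(foot, path, units = c("m", "cm")) {
  units <- match.arg(units)
  k <- if (units == "cm") 100 else 1
  blk <- if (inherits(foot, "ellipse_foot"))
    list(ellipse = list(units = units, r_E = k * foot$r_E, theta_E = foot$theta_E,
                        r_x = k * foot$r_x, r_y = k * foot$r_y))
  else
    list(double_circle = list(units = units, r_H = k * foot$r_H, rad_H = k * foot$rad_H,
                              r_F = k * foot$r_F, rad_F = k * foot$rad_F))
  yaml::write_yaml(blk, path, precision = 15)
  invisible(path)
}

# core-list representation used by the compiled code
foot_core <- function(foot) {
  if (inherits(foot, "ellipse_foot"))
    list(type = 0L, r_E = foot$r_E, theta_E = foot$theta_E,
         r_x = foot$r_x, r_y = foot$r_y)
  else
    list(type = 1L, r_H = foot$r_H, rad_H = foot$rad_H,
         r_F = foot$r_F, rad_F = foot$rad_F)
}

#' Ankle-frame pose and twist
#'
#' @param r_A world position of the ankle-frame origin (m).
#' @param alpha_A world orientation of the ankle frame (rad, CCW positive).
#' @param v_A linear velocity (m/s).
#' @param omega_A angular velocity (rad/s).
#' @return an object of class `ankle_pose`.
#' @export
ankle_pose <- function(r_A, alpha_A, v_A = c(0, 0), omega_A = 0) {
  stopifnot_finite(c(r_A, alpha_A, v_A, omega_A), "ankle pose")
  structure(list(r_A = as.numeric(r_A), alpha_A = alpha_A,
                 v_A = as.numeric(v_A), omega_A = omega_A),
            class = "ankle_pose")
}

#' Lowest point of the ellipse boundary over the ground plane
#'
#' Solves the stationarity condition of the world height of the polar-form
#' boundary point by bisection followed by Newton polishing, and returns the
#' ellipse-frame polar angle and the world point of closest approach to the
#' plane z = 0.
#'
#' @param foot an [ellipse_foot()].
#' @param pose an [ankle_pose()].
#' @return list with `phi` (polar angle in the ellipse frame), `point`
#'   (world 2-vector) and `height` (world z of the point; equals the contact
#'   gap).
#' @export
ellipse_lowest_point <- function(foot, pose) {
  if (!inherits(foot, "ellipse_foot")) stop("ellipse_lowest_point needs an ellipse foot")
  centre <- pose$r_A + rot2v(pose$alpha_A, foot$r_E)
  psi <- pose$alpha_A + foot$theta_E
  sol <- rf_ellipse_lowest(foot$r_x, foot$r_y, psi)
  point <- centre + sol$offset
  list(phi = sol$phi, point = point, height = point[2])
}

#' Contact-mode labels
#'
#' `airborne` carries no constraints; `ellipse_roll`, `heel_roll` and
#' `forefoot_roll` carry a contact and a rolling constraint on one shape;
#' the dual-circle modes add a contact-only constraint on the second circle
#' (3 rows in total, so the foot is not over-constrained).
#' @export
contact_modes <- function() c("airborne", "ellipse_roll", "heel_roll",
                              "forefoot_roll", "heel_roll_forefoot_touch",
                              "forefoot_roll_heel_touch")

mode_code <- function(mode) {
  m <- match(mode, contact_modes())
  if (any(is.na(m))) stop("unknown contact mode: ", paste(mode[is.na(m)], collapse = ", "))
  as.integer(m - 1L)
}

#' Velocity-level contact/rolling constraint set
#'
#' Builds the active constraint rows for the given per-foot contact modes:
#' each row is a linear form `G %*% qdot` (the world velocity of the contact
#' material point projected on e_Z for contact rows, e_X for rolling rows)
#' together with its acceleration bias, the position-level gap (contact rows
#' only), the world contact point, the owning foot and the row kind.
#'
#' @param model a [gait_model()].
#' @param state a [model_state()].
#' @param modes length-2 character vector (left, right) of [contact_modes()].
#' @return an object of class `constraint_set` with elements `G`, `gamma`,
#'   `gap`, `velocity`, `kind`, `foot`, `points`.
#' @export
constraint_set <- function(model, state, modes = c("airborne", "airborne")) {
  cm <- mode_code(modes)
  cs <- rf_constraints(core_model(model), state$q, state$qdot, cm[1], cm[2])
  for (nm in c("gamma", "gap", "velocity")) cs[[nm]] <- as.numeric(cs[[nm]])
  cs$kind <- c("contact", "rolling")[cs$kind + 1L]
  cs$foot <- c("left", "right")[cs$foot + 1L]
  cs$gap[cs$kind == "rolling"] <- NA_real_
  cs$modes <- modes
  class(cs) <- "constraint_set"
  cs
}

#' @export
print.constraint_set <- function(x, ...) {
  m <- nrow(x$G)
  cat(sprintf("constraint_set: %d rows (modes L=%s, R=%s)\n", m,
              x$modes[1], x$modes[2]))
  if (m > 0)
    print(data.frame(foot = x$foot, kind = x$kind, gap = x$gap,
                     velocity = x$velocity))
  invisible(x)
}

#' Constraint rows for the ellipse foot (contact + rolling at the point of
#' closest approach)
#'
#' @inheritParams constraint_set
#' @param side `"left"` or `"right"`.
#' @return a `constraint_set` with two rows.
#' @export
ellipse_constraints <- function(model, state, side = c("left", "right")) {
  side <- match.arg(side)
  if (!inherits(model$foot, "ellipse_foot")) stop("model does not use the ellipse foot")
  modes <- c("airborne", "airborne")
  modes[match(side, c("left", "right"))] <- "ellipse_roll"
  constraint_set(model, state, modes)
}

#' Constraint rows for the double-circle foot in a given contact mode
#'
#' Heel rows are built from the heel centre offset and radius, forefoot rows
#' from the forefoot circle; in dual-contact modes the rolling constraint is
#' attached to the circle named first in the mode and the other circle
#' contributes a contact row only.
#'
#' @inheritParams ellipse_constraints
#' @param mode one of the circle-contact [contact_modes()] (or `"airborne"`,
#'   giving an empty set).
#' @export
circle_constraints <- function(model, state, mode, side = c("left", "right")) {
  side <- match.arg(side)
  if (!inherits(model$foot, "double_circle_foot"))
    stop("model does not use the double-circle foot")
  if (!mode %in% c("airborne", "heel_roll", "forefoot_roll",
                   "heel_roll_forefoot_touch", "forefoot_roll_heel_touch"))
    stop("mode '", mode, "' is not a circle-contact mode")
  modes <- c("airborne", "airborne")
  modes[match(side, c("left", "right"))] <- mode
  constraint_set(model, state, modes)
}

#' Signed ground clearance of the candidate contact shapes
#'
#' World height of the lowest point of each contact shape of one foot;
#' zero at touch, positive above ground, negative in penetration.
#'
#' @param model a [gait_model()].
#' @param state a [model_state()], or an [ankle_pose()] via `pose`.
#' @param side `"left"` or `"right"` (ignored when a pose is given).
#' @param pose optionally evaluate for a bare ankle pose instead of a whole
#'   model state.
#' @param foot foot geometry to use with `pose` (defaults to the model's).
#' @return named vector of gaps (m): `ellipse`, or `heel` and `forefoot`.
#' @export
contact_gap <- function(model = NULL, state = NULL, side = "left",
                        pose = NULL, foot = NULL) {
  if (!is.null(pose)) {
    foot <- foot %||% model$foot
    return(pose_gaps(foot, pose))
  }
  rf_foot_gaps(core_model(model), state$q, match(side, c("left", "right")) - 1L)
}

pose_gaps <- function(foot, pose) {
  if (inherits(foot, "ellipse_foot")) {
    c(ellipse = ellipse_lowest_point(foot, pose)$height)
  } else {
    ch <- pose$r_A + rot2v(pose$alpha_A, foot$r_H)
    cf <- pose$r_A + rot2v(pose$alpha_A, foot$r_F)
    c(heel = ch[2] - foot$rad_H, forefoot = cf[2] - foot$rad_F)
  }
}

#' Centre of pressure and resultant ground force from contact multipliers
#'
#' Maps the Lagrange multipliers of an active constraint set to a world
#' ground-reaction force and a centre of pressure on the ground plane. With
#' one loaded contact the CoP is that contact point; with two it is the
#' normal-force-weighted mean of the contact x positions.
#'
#' @param cs a [constraint_set()].
#' @param lambda multiplier vector paired with the rows of `cs` (N).
#' @return list with `r_P` (world 2-vector, z = 0) and `f_P` (N, 2-vector).
#' @export
cop_and_ground_force <- function(cs, lambda) {
  if (length(lambda) != nrow(cs$G)) stop("lambda does not match the constraint set")
  normal <- cs$kind == "contact"
  if (!any(normal & lambda > 0)) stop("no positive normal force: CoP undefined")
  fx <- sum(lambda[cs$kind == "rolling"])
  fz <- sum(lambda[normal])
  w <- lambda[normal]
  xs <- cs$points[normal, 1]
  xP <- sum(w * xs) / sum(w)
  list(r_P = c(xP, 0), f_P = c(fx, fz))
}
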