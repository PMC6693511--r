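#' Whole-body inertial and geometric parameters
#'
#' Container for the seven-segment planar model: a floating-base segment
#' lumping pelvis, torso, head and arms (HAT), plus left/right thigh, shank
#' and foot. The model has 9 degrees of freedom: base position (x, z), base
#' pitch, and hip, knee and ankle revolute joints on each side. All units SI.
#'
#' @param mass named numeric vector of 7 segment masses (kg), names
#'   `hat, thigh_l, shank_l, foot_l, thigh_r, shank_r, foot_r`.
#' @param inertia planar moments of inertia about each segment COM (kg m^2),
#'   same order.
#' @param len_thigh,len_shank segment lengths between joint centres (m).
#' @param com 7 x 2 matrix of COM offsets in each segment frame (m). Segment
#'   frames: HAT at the hip point, thigh at the hip, shank at the knee, foot
#'   at the ankle; with all angles zero the legs hang straight down and the
#'   feet point forward (+x).
#' @param g gravitational acceleration magnitude (m/s^2, acts in -z).
#' @return an object of class `body_parameters`.
#' @seealso [default_body_parameters()] for a regression-table default.
#' @export
body_parameters <- function(mass, inertia, len_thigh, len_shank, com, g = 9.81) {
  segs <- c("hat", "thigh_l", "shank_l", "foot_l", "thigh_r", "shank_r", "foot_r")
  mass <- unname(unlist(mass)); inertia <- unname(unlist(inertia))
  com <- as.matrix(com)
  if (length(mass) != 7L || length(inertia) != 7L || !all(dim(com) == c(7L, 2L)))
    stop("body_parameters describes exactly 7 segments")
  if (any(mass <= 0)) stop("all segment masses must be > 0")
  if (any(inertia <= 0)) stop("all segment inertias must be > 0")
  if (len_thigh <= 0 || len_shank <= 0) stop("segment lengths must be > 0")
  structure(list(mass = setNames(mass, segs), inertia = setNames(inertia, segs),
                 len_thigh = len_thigh, len_shank = len_shank,
                 com = com, g = g, segments = segs),
            class = "body_parameters")
}

#' Default anthropometry from a standard segment-parameter regression table
#'
#' Distributes total body mass and height over the seven model segments using
#' the mass-fraction / length-fraction / radius-of-gyration table shipped in
#' `inst/extdata/body_segments.yaml` (a conventional gait-analysis regression
#' table). Head, arms and torso are lumped into the floating-base HAT
#' segment; this is an explicit modelling assumption of the planar model.
#'
#' @param total_mass subject mass (kg).
#' @param height subject stature (m).
#' @param config path to an alternative segment table (YAML).
#' @return a [body_parameters()] object.
#' @export
default_body_parameters <- function(total_mass = 81.7, height = 1.72,
                                    config = NULL) {
  path <- config %||% system.file("extdata", "body_segments.yaml",
                                  package = "rigidfoot", mustWork = TRUE)
  tb <- yaml::read_yaml(path)
  fr <- tb$segments
  m_th <- total_mass * fr$thigh$mass_frac
  m_sh <- total_mass * fr$shank$mass_frac
  m_ft <- total_mass * fr$foot$mass_frac
  m_hat <- total_mass - 2 * (m_th + m_sh + m_ft)
  L_th <- height * fr$thigh$length_frac
  L_sh <- height * fr$shank$length_frac
  L_ft <- height * fr$foot$length_frac
  L_hat <- height * fr$hat$length_frac
  I_hat <- m_hat * (fr$hat$rog_frac * L_hat)^2
  I_th <- m_th * (fr$thigh$rog_frac * L_th)^2
  I_sh <- m_sh * (fr$shank$rog_frac * L_sh)^2
  I_ft <- m_ft * (fr$foot$rog_frac * L_ft)^2
  com <- rbind(c(0, fr$hat$com_frac * L_hat),
               c(0, -fr$thigh$com_frac * L_th),
               c(0, -fr$shank$com_frac * L_sh),
               c(fr$foot$com_x_frac * L_ft, -fr$foot$com_z_frac * L_ft),
               c(0, -fr$thigh$com_frac * L_th),
               c(0, -fr$shank$com_frac * L_sh),
               c(fr$foot$com_x_frac * L_ft, -fr$foot$com_z_frac * L_ft))
  body_parameters(mass = c(m_hat, m_th, m_sh, m_ft, m_th, m_sh, m_ft),
                  inertia = c(I_hat, I_th, I_sh, I_ft, I_th, I_sh, I_ft),
                  len_thigh = L_th, len_shank = L_sh, com = com, g = 9.81)
}

#' @export
print.body_parameters <- function(x, ...) {
  cat("Planar 7-segment body (9 DoF)\n")
  cat(sprintf("  total mass %.2f kg, thigh %.3f m, shank %.3f m, g = %.2f\n",
              sum(x$mass), x$len_thigh, x$len_shank, x$g))
  print(round(cbind(mass = x$mass, inertia = x$inertia,
                    com_x = x$com[, 1], com_z = x$com[, 2]), 4))
  invisible(x)
}

#' Read / write body parameters as a structured config file
#'
#' Nested key-value YAML, one block per segment, units in the keys (kg, m,
#' kg m^2).
#' @param path file path.
#' @param body a [body_parameters()] object.
#' @return `read_body_config` returns a [body_parameters()] object.
#' @export
read_body_config <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- c("hat", "thigh_l", "shank_l", "foot_l", "thigh_r", "shank_r", "foot_r")
  mass <- vapply(segs, function(s) y$segments[[s]]$mass_kg, 0)
  inertia <- vapply(segs, function(s) y$segments[[s]]$inertia_kgm2, 0)
  com <- unname(t(vapply(segs, function(s) unlist(y$segments[[s]]$com_m), c(0, 0))))
  body_parameters(mass, inertia, y$len_thigh_m, y$len_shank_m, com,
                  g = y$g_ms2 %||% 9.81)
}

#' @rdname read_body_config
#' @export
write_body_config <- function(body, path) {
  segs <- lapply(seq_along(body$segments), function(i)
    list(mass_kg = unname(body$mass[i]), inertia_kgm2 = unname(body$inertia[i]),
         com_m = as.numeric(body$com[i, ])))
  names(segs) <- body$segments
  yaml::write_yaml(list(len_thigh_m = body$len_thigh, len_shank_m = body$len_shank,
                        g_ms2 = body$g, segments = segs), path,
                   precision = 15)
  invisible(path)
}

#' Model state (generalized positions and velocities)
#'
#' @param q 9-vector: base x (m), base z (m), base pitch (rad), left hip,
#'   knee, ankle, right hip, knee, ankle (rad). The base point is the hip
#'   joint centre; angles are CCW-positive relative to the parent segment.
#' @param qdot 9-vector of generalized velocities.
#' @return an object of class `model_state`.
#' @export
model_state <- function(q, qdot = rep(0, 9)) {
  q <- as.numeric(q); qdot <- as.numeric(qdot)
  if (length(q) != 9L || length(qdot) != 9L) stop("q and qdot must have length 9")
  stopifnot_finite(q, "q"); stopifnot_finite(qdot, "qdot")
  structure(list(q = q, qdot = qdot), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat("model_state\n  q:    ", paste(signif(x$q, 4), collapse = " "), "\n")
  cat("  qdot: ", paste(signif(x$qdot, 4), collapse = " "), "\n")
  invisible(x)
}
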