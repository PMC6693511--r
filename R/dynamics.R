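#' Mass matrix of the 9-DoF model
#'
#' @param model a [gait_model()] or [body_parameters()].
#' @param q generalized positions (9-vector).
#' @return symmetric positive-definite 9 x 9 matrix.
#' @export
mass_matrix <- function(model, q) {
  stopifnot_finite(q, "q")
  rf_mass_matrix(core_model(model), q)
}

#' Coriolis, centripetal and gravitational generalized forces
#'
#' The bias vector `c(q, qdot)` of the equations of motion
#' `M(q) qddot + c(q, qdot) = tau + t(G) lambda`.
#'
#' @param model a [gait_model()] or [body_parameters()].
#' @param state a [model_state()].
#' @return 9-vector.
#' @export
bias_forces <- function(model, state) {
  as.numeric(rf_bias_forces(core_model(model), state$q, state$qdot))
}

#' Generalized forces from the MTGs and passive damping
#'
#' Zero for the three base coordinates; one net torque per leg joint.
#' @param model an actuated [gait_model()].
#' @param state a [model_state()].
#' @param a activation 12-vector.
#' @return 9-vector of generalized forces.
#' @export
generalized_forces <- function(model, state, a) {
  if (is.null(model$actuators)) stop("model has no actuation set")
  if (any(a < 0 | a > 1)) stop("activations must lie in [0, 1]")
  as.numeric(rf_joint_torques(model$core, state$q, state$qdot, a))
}

#' Constrained forward dynamics
#'
#' Solves the index-reduced contact DAE at the acceleration level: the KKT
#' system pairing `M qddot + c = tau + t(G) lambda` with the differentiated
#' contact/rolling constraints `G qddot + gamma + stabilization = 0`.
#' Baumgarte stabilization applies position and velocity feedback on contact
#' rows and velocity feedback only on rolling rows.
#'
#' @param model a [gait_model()].
#' @param state a [model_state()].
#' @param tau generalized forces (9-vector; first three entries must be 0),
#'   or `NULL` to use the model's MTGs with activations `a`.
#' @param modes per-foot contact modes, see [contact_modes()].
#' @param a activations (only used when `tau` is `NULL` and the model is
#'   actuated).
#' @param gains Baumgarte gains, defaulting to the model's.
#' @return list with `qdd` (9-vector), `lambda` (per-row constraint forces,
#'   N), and the `constraint_set` used.
#' @export
constrained_forward_dynamics <- function(model, state, tau = NULL,
                                         modes = c("airborne", "airborne"),
                                         a = NULL, gains = NULL) {
  gains <- gains %||% model$baumgarte
  if (is.null(tau)) {
    a <- a %||% rep(0, 12)
    tau <- if (is.null(model$actuators)) rep(0, 9) else
      generalized_forces(model, state, a)
  }
  if (any(tau[1:3] != 0))
    stop("the leading three entries of tau must be zero (no base actuation)")
  cm <- mode_code(modes)
  res <- rf_fd(core_model(model), state$q, state$qdot, tau, cm[1], cm[2],
               gains[1], gains[2])
  list(qdd = as.numeric(res$qdd), lambda = as.numeric(res$lambda),
       constraints = constraint_set(model, state, modes))
}

#' Plastic (maximally dissipative) impact map
#'
#' Instantaneous touchdown transition: post-impact generalized velocities
#' minimize the kinetic-energy metric subject to the new constraint set,
#' `M (qdot_post - qdot_pre) = t(G) Lambda`, `G qdot_post = 0`. Positions
#' and activations are unchanged; kinetic energy never increases.
#'
#' @param model a [gait_model()].
#' @param state the pre-impact [model_state()].
#' @param modes_new the constraint modes active immediately after touchdown.
#' @return list with `qdot_post`, `impulses` (N s per constraint row),
#'   `dKE` (J, always <= 0) and the post-impact `state`.
#' @export
plastic_impact <- function(model, state, modes_new) {
  cm <- mode_code(modes_new)
  res <- rf_impact(core_model(model), state$q, state$qdot, cm[1], cm[2])
  list(qdot_post = as.numeric(res$qd_post),
       impulses = as.numeric(res$impulses), dKE = res$dKE,
       state = model_state(state$q, as.numeric(res$qd_post)))
}

#' Total mechanical energy
#'
#' Kinetic plus gravitational potential energy (datum at z = 0).
#' @param model a [gait_model()] or [body_parameters()].
#' @param state a [model_state()].
#' @return energy (J); attributes `kinetic` and `potential` carry the parts.
#' @export
total_energy <- function(model, state) {
  e <- rf_energy(core_model(model), state$q, state$qdot)
  structure(e$total, kinetic = e$kinetic, potential = e$potential)
}

#' Mirror a 30-dimensional state between left and right legs
#'
#' Swaps the left/right hip, knee and ankle coordinates (positions and
#' velocities) and the left/right activation blocks; base states are
#' unchanged. An involution used by the gait periodicity constraints.
#'
#' @param x state vector: 18 mechanical states, or 30 with activations.
#' @return the mirrored state vector.
#' @export
mirror_map <- function(x) {
  swap9 <- c(1:3, 7:9, 4:6)
  if (length(x) == 18) return(x[c(swap9, swap9 + 9)])
  if (length(x) == 30) return(x[c(swap9, swap9 + 9, 18 + c(7:12, 1:6))])
  stop("mirror_map expects a vector of length 18 or 30")
}
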