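#' Muscle-torque-generator (MTG) parameters
#'
#' A lumped joint-level actuator resembling a rigid-tendon Hill-type muscle:
#' torque = sign * tau_o * a * fA(theta) * fV(omega), where `fA` is a C2
#' bell-shaped active torque-angle curve (1 at the optimal angle, falling to
#' 0 at `width` rad away) and `fV` a C2 torque-angular-velocity curve with
#' fV(0) = 1, reaching 0 at the maximum shortening velocity `omega_max` and
#' saturating at `ecc` (default 1.35) for fast lengthening. Both curves are
#' quintic-segment templates; the strength values shipped as defaults are
#' plainly-labelled placeholders, not fitted subject data.
#'
#' @param tau_o maximum active isometric torque (N m), > 0.
#' @param omega_max maximum shortening angular velocity (rad/s), > 0.
#' @param sign +1 or -1, the anatomical direction of the generated torque in
#'   the joint coordinate.
#' @param theta_opt optimal joint angle (rad).
#' @param width half-width of the torque-angle bell (rad).
#' @param ecc eccentric plateau of the torque-velocity curve.
#' @return object of class `mtg_params`.
#' @export
mtg_params <- function(tau_o, omega_max, sign, theta_opt = 0, width = 2,
                       ecc = 1.35) {
  if (tau_o <= 0 || omega_max <= 0) stop("tau_o and omega_max must be > 0")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(tau_o = tau_o, omega_max = omega_max, sign = sign,
                 theta_opt = theta_opt, width = width, ecc = ecc),
            class = "mtg_params")
}

#' MTG torque
#'
#' @param p an [mtg_params()] object.
#' @param a activation in `[0, 1]`.
#' @param theta joint angle (rad).
#' @param omega joint angular velocity (rad/s).
#' @return torque (N m); vectorized over `theta` / `omega`.
#' @export
mtg_torque <- function(p, a, theta, omega) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  fa <- rf_fA(theta, p$theta_opt, p$width)
  fv <- rf_fV(p$sign * omega, p$omega_max, p$ecc)
  p$sign * p$tau_o * a * fa * fv
}

#' Activation dynamics rate
#'
#' C2 first-order lag between excitation `e` and activation `a`. The default
#' reading uses the mean of the activation and deactivation time constants,
#' `adot = (e - a) / ((tau_act + tau_deact)/2)`; the `"switched"` variant
#' blends smoothly between the two time constants depending on the sign of
#' `e - a` (the conventional formulation, C2-smoothed).
#'
#' @param e excitation in `[0, 1]`.
#' @param a activation in `[0, 1]`.
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @param variant `"mean"` (default) or `"switched"`.
#' @return `da/dt` (1/s); vectorized.
#' @export
activation_rate <- function(e, a, tau_act = 0.015, tau_deact = 0.050,
                            variant = c("mean", "switched")) {
  variant <- match.arg(variant)
  if (variant == "mean") {
    (e - a) / (0.5 * (tau_act + tau_deact))
  } else {
    x <- (e - a) / 0.1 + 0.5
    s5 <- ifelse(x <= 0, 0, ifelse(x >= 1, 1, x^3 * (10 - 15 * x + 6 * x^2)))
    teff <- tau_deact + (tau_act - tau_deact) * s5
    (e - a) / teff
  }
}

#' Agonist-antagonist joint actuator with strength-scaled damping
#'
#' Pairs a flexor and an extensor MTG at one joint and derives the passive
#' damping coefficient `beta = eta * (tau_o_F + tau_o_E) /
#' (omega_max_F + omega_max_E)`, proportional to the strength and inversely
#' proportional to the maximum contraction velocity of the musculature.
#'
#' @param flexor,extensor [mtg_params()] objects with opposite signs.
#' @param eta dimensionless damping scale (default 2).
#' @return object of class `joint_actuator` with a `beta` field (N m s/rad).
#' @export
joint_actuator <- function(flexor, extensor, eta = 2) {
  if (flexor$sign == extensor$sign)
    stop("flexor and extensor must act in opposite directions")
  structure(list(flexor = flexor, extensor = extensor, eta = eta,
                 beta = joint_damping_value(flexor, extensor, eta)),
            class = "joint_actuator")
}

joint_damping_value <- function(flexor, extensor, eta) {
  den <- flexor$omega_max + extensor$omega_max
  if (den == 0) stop("zero omega_max sum in damping computation")
  eta * (flexor$tau_o + extensor$tau_o) / den
}

#' Passive joint damping coefficient
#' @param actuator a [joint_actuator()].
#' @return `beta` (N m s/rad).
#' @export
joint_damping <- function(actuator) {
  joint_damping_value(actuator$flexor, actuator$extensor, actuator$eta)
}

#' Net joint torque from an agonist-antagonist pair plus damping
#'
#' `tau = tau_flexor + tau_extensor - beta * omega`.
#'
#' @param actuator a [joint_actuator()].
#' @param a_flexor,a_extensor activations in `[0, 1]`.
#' @param theta joint angle (rad).
#' @param omega joint angular velocity (rad/s).
#' @return torque (N m).
#' @export
net_joint_torque <- function(actuator, a_flexor, a_extensor, theta, omega) {
  mtg_torque(actuator$flexor, a_flexor, theta, omega) +
    mtg_torque(actuator$extensor, a_extensor, theta, omega) -
    actuator$beta * omega
}

#' Default actuator set for the 9-DoF model
#'
#' Six joint actuators (left/right hip, knee, ankle) read from the actuator
#' config shipped with the package. Strengths are placeholders chosen so the
#' damping identity yields `beta` between 2.7 and 7.3 N m s/rad with
#' `eta = 2`; all values are overridable through the config file.
#'
#' @param path alternative actuator config (YAML).
#' @return object of class `actuation_set`: named list of six
#'   [joint_actuator()]s plus activation-dynamics settings.
#' @export
default_actuators <- function(path = NULL) {
  path <- path %||% system.file("extdata", "actuators.yaml",
                                package = "rigidfoot", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  eta <- y$eta %||% 2
  ecc <- y$ecc %||% 1.35
  mk <- function(b) mtg_params(b$tau_o, b$omega_max, b$sign, b$theta_opt,
                               b$width %||% 2, ecc)
  joints <- c("hip", "knee", "ankle")
  acts <- list()
  for (side in c("l", "r")) for (j in joints) {
    blk <- y$joints[[j]]
    acts[[paste0(j, "_", side)]] <- joint_actuator(mk(blk$flexor), mk(blk$extensor), eta)
  }
  acts <- acts[c("hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")]
  structure(list(joints = acts, eta = eta, ecc = ecc,
                 tau_act = y$tau_act %||% 0.015,
                 tau_deact = y$tau_deact %||% 0.050,
                 variant = y$variant %||% "mean"),
            class = "actuation_set")
}

#' @export
print.actuation_set <- function(x, ...) {
  cat("actuation_set: 6 agonist-antagonist MTG pairs\n")
  b <- vapply(x$joints, `[[`, 0, "beta")
  print(round(b, 3))
  cat(sprintf("  eta = %g, tau_act = %g s, tau_deact = %g s, variant = %s\n",
              x$eta, x$tau_act, x$tau_deact, x$variant))
  invisible(x)
}

# flattened representation for the compiled code (12 MTGs: flexor/extensor
# per joint, joints ordered hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r)
act_core <- function(acts) {
  if (is.null(acts)) return(NULL)
  fl <- function(fld) unlist(lapply(acts$joints, function(j)
    c(j$flexor[[fld]], j$extensor[[fld]])), use.names = FALSE)
  list(tau0 = fl("tau_o"), omax = fl("omega_max"), sgn = fl("sign"),
       opt = fl("theta_opt"), width = fl("width"), ecc = acts$ecc,
       tau_act = acts$tau_act, tau_deact = acts$tau_deact,
       beta = vapply(acts$joints, `[[`, 0, "beta"),
       variant = if (identical(acts$variant, "switched")) 1L else 0L)
}
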