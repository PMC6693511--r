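# Design of a dynamically consistent synthetic step for the ellipse-foot
# schedule.  A posture/swing PD law is sampled AT THE SHOOTING NODES and
# interpolated linearly in between -- exactly the control parameterization
# of the optimal-control transcription -- so the designed trajectory is, by
# construction, the open-loop rollout of its own piecewise-linear
# excitation profile.  Each shooting interval is iterated to
# self-consistency (the node excitation equals the feedback law evaluated
# at the node state it produces), and each phase duration is root-found so
# the phase-ending event (trailing-foot unloading, swing-foot touchdown)
# holds exactly at the final node.

# planar 2-link inverse kinematics: joint coordinates of one leg from the
# hip and ankle world positions and the foot world orientation (pitch 0)
leg_ik <- function(model, hip, ankle, alpha) {
  L1 <- model$body$len_thigh; L2 <- model$body$len_shank
  d <- ankle - hip
  cc <- min(sqrt(sum(d^2)), L1 + L2 - 1e-6)
  a_d <- atan2(d[1], -d[2])
  beta <- acos(min(1, max(-1, (L1^2 + L2^2 - cc^2) / (2 * L1 * L2))))
  gam <- acos(min(1, max(-1, (L1^2 + cc^2 - L2^2) / (2 * L1 * cc))))
  q_hip <- a_d + gam
  q_knee <- -(pi - beta)
  c(q_hip, q_knee, alpha - q_hip - q_knee)
}

#' Design a synthetic reference step for the ellipse-foot schedule
#'
#' Builds a pre-impact double-stance state (leading foot just touching,
#' trailing foot rolling, forward momentum) and node-sampled excitation
#' profiles that carry the model through one step: a trunk servo at the
#' stance hip, a stance-knee hold, a trailing-leg push-off with an
#' anticipatory swing burst, and a swing-leg flex-then-extend program. The
#' double-stance phase ends when the trailing foot's normal force reaches
#' zero and the single-stance phase when the swing foot, after clearing the
#' ground, touches down again; both durations are located by root finding
#' under the same fixed-step discretization used by the optimal-control
#' transcription, so the emitted trajectory is exactly reproducible from
#' its excitations.
#'
#' @param model an actuated ellipse-foot [gait_model()].
#' @param speed initial forward speed of the base (m/s).
#' @param nodes shooting nodes per continuous phase of the emitted
#'   reference.
#' @param fixed_steps RK4 steps per node interval.
#' @param max_durations event-search bounds for the two phases (s).
#' @return a [gait_generator_config()] ready for
#'   [generate_reference_gait()].
#' @export
design_reference_step <- function(model, speed = 1.0, nodes = c(12, 13),
                                  fixed_steps = 8,
                                  max_durations = c(0.6, 0.5)) {
  if (!inherits(model$foot, "ellipse_foot"))
    stop("the reference-step designer supports the ellipse-foot schedule")
  hip <- c(0.08, 0.90)     # near-straight stance leg: the ground force
  q <- c(hip, 0,           # passes close to the knee, so holding the leg
         leg_ik(model, hip, c(0.14, 0.06), 0.05),   # needs little torque
         leg_ik(model, hip, c(-0.18, 0.13), -0.35))
  qd0 <- c(speed, -0.25, rep(0, 7))   # descending at touchdown loads the
  x0 <- c(q, qd0, rep(0.01, 12))      # trailing foot (friction margin)
  x0 <- project_state(model, x0, c("ellipse_roll", "ellipse_roll"))
  xr <- project_state(model, c(x0[1:9], qd0, x0[19:30]),
                      c("airborne", "ellipse_roll"))
  x0[10:18] <- xr[10:18]

  ac <- act_core(model$actuators)
  q5_0 <- x0[5]

  # feedback law; `phase` is "ds" or "swing", s in [0,1] the swing progress,
  # sf in [0,1] the anticipation/lift burst, anchor the lift-off joint state
  pd_law <- function(x, t, phase, s, sf, anchor) {
    q <- x[1:9]; qd <- x[10:18]
    e <- rep(0.02, 12)
    add <- function(j, tdes) {
      fi <- 2 * j - 1; ei <- 2 * j
      pos <- if (ac$sgn[fi] > 0) fi else ei
      neg <- if (ac$sgn[fi] > 0) ei else fi
      if (tdes >= 0) e[pos] <<- e[pos] + tdes / ac$tau0[pos]
      else e[neg] <<- e[neg] - tdes / ac$tau0[neg]
    }
    add(1, 300 * q[3] + 50 * qd[3])                   # trunk servo
    # stance knee hold; the demand is clamped so the post-impact velocity
    # transient does not saturate the extensor
    add(2, max(-60, min(60, 400 * (q5_0 - q[5]) - 40 * qd[5])) + 6)
    q7a <- anchor[7]; q8a <- anchor[8]; q9a <- anchor[9]
    # swing targets approach the mirror of the pre-impact leading-leg pose
    # (hip flexed forward, knee nearly extended, slight dorsiflexion) so the
    # step ends close to a left/right-mirrored copy of how it began
    sk <- s5curve(min(1, s / 0.55))  # knee re-extends much earlier than the hip
    hip_t <- q7a + (0.30 - q7a) * s5curve(min(1, s / 0.8)) +
      0.35 * sf * (1 - s5curve(s))
    knee_t <- q8a + (-0.15 - q8a) * sk - 0.45 * sin(pi * min(1, s / 0.55)) -
      0.7 * sf * (1 - sk)
    ank_t <- q9a + (0.06 - q9a) * s5curve(min(1, s / 0.5))
    swf <- if (phase == "ds") 0.5 else 1   # softer hold while still rolling
    add(4, swf * (90 * (hip_t - q[7]) - 9 * qd[7]))
    add(5, swf * (110 * (knee_t - q[8]) - 9 * qd[8]))
    add(6, swf * (25 * (ank_t - q[9]) - 2 * qd[9]))
    # stance-ankle push grows through the step, keeping the body up long
    # enough for the swing leg to recover and land out front
    e[6] <- max(e[6], 0.03 + 0.3 * s5curve(max(0, min(1, t / 0.5))))
    # trailing push-off, tapered away as the anticipation burst proceeds so
    # the trailing foot's whole force vector vanishes at release
    if (phase == "ds") e[12] <- max(e[12], 0.3 * (1 - sf) + 0.02)
    pmin(1, pmax(0, e))
  }

  lamR <- function(x) {
    dyn <- node_dynamics(model, x, c("ellipse_roll", "ellipse_roll"))
    sum(dyn$lambda[dyn$kinds == "contact" & dyn$feet == "right"])
  }
  # total trailing-foot contact force minus a small slack: the double-stance
  # phase ends when the whole force vector (normal and tangential) is nearly
  # zero, so the release neither violates the friction cone at the boundary
  # node nor drops a still-loaded foot
  forceR <- function(x, slack = 0.25, mu = 0.8) {
    dyn <- node_dynamics(model, x, c("ellipse_roll", "ellipse_roll"))
    N <- sum(dyn$lambda[dyn$kinds == "contact" & dyn$feet == "right"])
    T <- sum(dyn$lambda[dyn$kinds == "rolling" & dyn$feet == "right"])
    min(N, mu * N - abs(T)) - slack
  }

  # node-sampled feedback pass over one phase of duration T: excitations are
  # piecewise linear between the node samples, each interval iterated so the
  # end-node excitation matches the law at the end-node state
  build_phase <- function(x1, modes, nj, T, law) {
    h <- T / (nj - 1)
    X <- matrix(0, 30, nj); X[, 1] <- x1
    E <- matrix(0, 12, nj)
    E[, 1] <- law(X[, 1], 0)
    for (k in seq_len(nj - 1)) {
      eg <- E[, k]
      for (it in 1:3) {
        out <- integrate_phase(model, X[, k], modes, h,
                               cbind(E[, k], eg), c(0, h),
                               fixed_steps = fixed_steps)
        eg <- law(out$x_end, k * h)
      }
      # final pass with the excitation that will be stored, so the emitted
      # profile replays this trajectory exactly
      out <- integrate_phase(model, X[, k], modes, h, cbind(E[, k], eg),
                             c(0, h), fixed_steps = fixed_steps)
      X[, k + 1] <- out$x_end
      E[, k + 1] <- eg
    }
    list(X = X, E = E, T = T)
  }

  # --- double stance: ends when the trailing (right) foot unloads ---
  im <- plastic_impact(model, model_state(x0[1:9], x0[10:18]),
                       c("ellipse_roll", "ellipse_roll"))
  xds <- x0; xds[10:18] <- im$qdot_post
  ds_law <- function(t_ant) function(x, t) {
    sf <- max(0, min(1, (t - t_ant) / 0.04))
    pd_law(x, t, "ds", 0, sf, x0[1:9])
  }
  ds_end <- function(t_ant) function(T) {
    ph <- build_phase(xds, c("ellipse_roll", "ellipse_roll"), nodes[1], T,
                      ds_law(t_ant))
    forceR(ph$X[, nodes[1]])
  }
  # probe without the anticipation burst, then fix the burst onset a fixed
  # lead before the unassisted unloading time (keeps the event function
  # continuous in the phase duration)
  T0 <- event_root(ds_end(Inf), 0.05, max_durations[1],
                   "trailing-foot unloading (probe)")
  t_ant <- max(0.02, T0 - 0.12)
  T1 <- event_root(ds_end(t_ant), 0.05, max_durations[1],
                   "trailing-foot unloading")
  ds <- build_phase(xds, c("ellipse_roll", "ellipse_roll"), nodes[1], T1,
                    ds_law(t_ant))

  # --- single stance: swing foot clears, then touches down ---
  xss <- ds$X[, nodes[1]]
  anchor <- xss[1:9]
  t_ant_ss <- max(0, T1 - t_ant)
  ss_law_T <- function(T) function(x, t) {
    s <- max(0, min(1, t / 0.28))
    sf <- max(0, min(1, (t + t_ant_ss) / 0.04))
    pd_law(x, T1 + t, "swing", s, sf, anchor)
  }
  ss_gap <- function(x) shape_gap(model, x[1:9], "right", "ellipse")
  cleared <- FALSE
  ss_end <- function(T) {
    ph <- build_phase(xss, c("ellipse_roll", "airborne"), nodes[2], T,
                      ss_law_T(T))
    g <- ss_gap(ph$X[, nodes[2]])
    if (g > 2e-3) cleared <<- TRUE
    if (!cleared) 1 else g   # ignore the pre-clearance zero
  }
  T2 <- event_root(ss_end, 0.01, max_durations[2], "swing-foot touchdown")
  ss <- build_phase(xss, c("ellipse_roll", "airborne"), nodes[2], T2,
                    ss_law_T(T2))

  gait_generator_config(model, x0,
                        excitations = list(ds$E, ss$E),
                        durations = pmin(1.3 * c(T1, T2) + 0.05,
                                         max_durations + 0.2),
                        nodes = nodes, fixed_steps = fixed_steps,
                        u_durations = c(T1, T2))
}

# first downward zero crossing of f over [lo, hi]: coarse scan + bisection
event_root <- function(f, lo, hi, what, nscan = 61) {
  Ts <- seq(lo, hi, length.out = nscan)
  vals <- vapply(Ts, function(T) {
    v <- tryCatch(f(T), error = function(e) NA_real_)
    if (!is.finite(v)) NA_real_ else v
  }, 0)
  bad <- which(is.na(vals))
  if (length(bad)) {
    if (bad[1] == 1L) stop("event search failed: ", what)
    Ts <- Ts[1:(bad[1] - 1L)]; vals <- vals[1:(bad[1] - 1L)]
  }
  cross <- which(vals[-1] <= 0 & vals[-length(vals)] > 0)
  if (!length(cross)) stop("no ", what, " event within [", lo, ", ", hi, "] s")
  a <- Ts[cross[1]]; b <- Ts[cross[1] + 1]
  for (it in 1:60) {
    mid <- (a + b) / 2
    v <- tryCatch(f(mid), error = function(e) -1)
    if (is.finite(v) && v > 0) a <- mid else b <- mid
    if (b - a < 1e-12) break
  }
  (a + b) / 2
}
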