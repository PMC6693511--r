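#' Synthetic stance-trial generator configuration
#'
#' Describes a single-foot stance trial that is exactly realizable by a
#' rigid rolling foot: a monotone orientation profile (toe-up at heel
#' contact, rolling forward to heel-up at toe-off; the orientation decreases
#' because forward rolling advances the CoP), a smooth C2 double-hump
#' normal-force profile, a braking-to-propulsion tangential force ramp, and
#' optional Gaussian measurement noise added to every recorded channel.
#'
#' @param foot ground-truth `foot_params`.
#' @param alpha0,alpha1 stance start / end ankle-frame orientations (rad);
#'   `alpha0 > alpha1` (default +20 deg to -40 deg).
#' @param duration stance duration (s).
#' @param n number of samples.
#' @param peak1,peak2 normal-force hump magnitudes (N).
#' @param t_frac1,t_frac2,w_frac hump centres and half-width as fractions of
#'   the stance duration (the humps vanish at the stance endpoints).
#' @param tang_frac maximum |tangential|/normal force ratio of the ramp.
#' @param dwell_frac double-circle only: fraction of the stance spent in the
#'   flat (both circles touching) phase.
#' @param sigma_pos,sigma_ang,sigma_force measurement-noise standard
#'   deviations (m, rad, N).
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @return list of class `stance_generator_config`.
#' @export
stance_generator_config <- function(foot, alpha0 = 20 * pi / 180,
                                    alpha1 = -40 * pi / 180, duration = 0.7,
                                    n = 71, peak1 = 1.10 * 81.7 * 9.81,
                                    peak2 = 1.05 * 81.7 * 9.81,
                                    t_frac1 = 0.31, t_frac2 = 0.69,
                                    w_frac = 0.31, tang_frac = 0.15,
                                    dwell_frac = 0.40, sigma_pos = 0,
                                    sigma_ang = 0, sigma_force = 0,
                                    seed = 1L) {
  stopifnot(inherits(foot, "foot_params"), alpha0 > alpha1, duration > 0,
            n >= 2, peak1 > 0, peak2 > 0, tang_frac >= 0)
  structure(as.list(environment()), class = "stance_generator_config")
}

s5curve <- function(x) {
  x <- pmin(1, pmax(0, x))
  x^3 * (10 - 15 * x + 6 * x^2)
}

#' C2 double-hump ground-force profile
#'
#' Two C2 bump functions (zero with two vanishing derivatives at their
#' support edges, which coincide with the stance endpoints) for the normal
#' force, and a braking-to-propulsion linear ramp for the tangential
#' fraction.
#'
#' @param t time(s) within the stance.
#' @param cfg a [stance_generator_config()].
#' @return matrix with columns `force_x`, `force_z`.
#' @export
double_hump_force <- function(t, cfg) {
  bump <- function(x) ifelse(abs(x) < 1, (1 - x^2)^3, 0)
  T <- cfg$duration
  fz <- cfg$peak1 * bump((t - cfg$t_frac1 * T) / (cfg$w_frac * T)) +
        cfg$peak2 * bump((t - cfg$t_frac2 * T) / (cfg$w_frac * T))
  rho <- cfg$tang_frac * (2 * t / T - 1)
  cbind(force_x = rho * fz, force_z = fz)
}

#' Generate a synthetic stance record by rolling a known foot
#'
#' Rolls the ground-truth foot forward along the ground under the
#' prescribed orientation profile; the CoP is the instantaneous contact
#' point (interpolated across the flat span for the double-circle foot while
#' both circles touch and the ankle is stationary), the ankle pose follows
#' rigidly, forces come from the configured profiles, and Gaussian noise is
#' added last. The noise-free channels are returned alongside for use as an
#' oracle.
#'
#' @param cfg a [stance_generator_config()].
#' @return list with `record` (noisy [stance_record()]), `clean` (noise-free
#'   record) and `truth` (the generating foot and per-sample orientation).
#' @export
generate_stance_record <- function(cfg) {
  foot <- cfg$foot
  tt <- seq(0, cfg$duration, length.out = cfg$n)
  s <- s5curve(tt / cfg$duration)
  if (inherits(foot, "ellipse_foot")) {
    alpha <- cfg$alpha0 + (cfg$alpha1 - cfg$alpha0) * s
    arc <- ell_arc_fun(foot)
    xi <- roll_contact_x(foot, alpha, arc)
    off <- -xi[1]                           # heel-strike contact at x = 0
    cop <- xi + off
    ank <- t(vapply(seq_along(tt), function(i)
      ankle_from_contact(foot, alpha[i], cop[i]), c(0, 0)))
  } else {
    af <- dc_flat_angle(foot)
    span <- dc_flat_span(foot)
    if (!(cfg$alpha0 > af && af > cfg$alpha1))
      stop("orientation profile must cross the flat pose (alpha_flat = ",
           signif(af, 3), ")")
    # time split: heel roll / flat dwell / forefoot roll
    f_heel <- (1 - cfg$dwell_frac) * (cfg$alpha0 - af) /
      (cfg$alpha0 - af + af - cfg$alpha1)
    f_fore <- (1 - cfg$dwell_frac) - f_heel
    t1 <- f_heel * cfg$duration
    t2 <- t1 + cfg$dwell_frac * cfg$duration
    alpha <- numeric(cfg$n); cop <- numeric(cfg$n)
    ank <- matrix(0, cfg$n, 2)
    off <- -roll_contact_x(foot, cfg$alpha0)  # heel contact starts at x = 0
    flat_ankle <- ankle_from_contact(foot, af, off, "heel")
    for (i in seq_along(tt)) {
      ti <- tt[i]
      if (ti <= t1) {
        alpha[i] <- cfg$alpha0 + (af - cfg$alpha0) * s5curve(ti / t1)
        cop[i] <- roll_contact_x(foot, alpha[i]) + off
        ank[i, ] <- ankle_from_contact(foot, alpha[i], cop[i], "heel")
      } else if (ti <= t2) {
        alpha[i] <- af
        cop[i] <- off + span * (ti - t1) / (t2 - t1)
        ank[i, ] <- flat_ankle
      } else {
        alpha[i] <- af + (cfg$alpha1 - af) * s5curve((ti - t2) / (cfg$duration - t2))
        cop[i] <- roll_contact_x(foot, alpha[i]) + off
        ank[i, ] <- ankle_from_contact(foot, alpha[i], cop[i], "forefoot")
      }
    }
  }
  ff <- double_hump_force(tt, cfg)
  clean <- stance_record(t = tt, cop_x = cop, force_x = ff[, 1],
                         force_z = ff[, 2], ankle_x = ank[, 1],
                         ankle_z = ank[, 2], ankle_angle = alpha)
  noisy <- clean
  if (cfg$sigma_pos > 0 || cfg$sigma_ang > 0 || cfg$sigma_force > 0) {
    rng <- local_rng(cfg$seed)
    on.exit(restore_rng(rng))
    n <- cfg$n
    noisy$cop_x <- clean$cop_x + rnorm(n, 0, cfg$sigma_pos)
    noisy$ankle_x <- clean$ankle_x + rnorm(n, 0, cfg$sigma_pos)
    noisy$ankle_z <- clean$ankle_z + rnorm(n, 0, cfg$sigma_pos)
    noisy$ankle_angle <- clean$ankle_angle + rnorm(n, 0, cfg$sigma_ang)
    noisy$force_x <- clean$force_x + rnorm(n, 0, cfg$sigma_force)
    noisy$force_z <- pmax(0, clean$force_z + rnorm(n, 0, cfg$sigma_force))
  }
  list(record = noisy, clean = clean,
       truth = list(foot = foot, alpha = alpha))
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
}

#' Gait-rollout generator configuration
#'
#' Open-loop forward simulation settings for producing a synthetic reference
#' gait: the model, its phase schedule, the pre-impact initial state and
#' per-phase piecewise-linear excitation profiles. Continuous phases end at
#' their physical events: a phase followed by a constraint drop ends when
#' the normal force of the rows about to be dropped reaches zero (lift-off),
#' and a phase followed by an impact ends when the touchdown shape's ground
#' clearance reaches zero. `durations` bound the event search.
#'
#' @param model an actuated [gait_model()].
#' @param x0 pre-impact state vector (30).
#' @param excitations list (one 12 x n matrix per continuous phase).
#' @param durations maximum continuous-phase durations (s).
#' @param u_durations initial guesses of the phase durations on whose node
#'   grids the excitation profiles are played (iterated to the event times
#'   so that the emitted controls are piecewise linear on each phase's own
#'   shooting grid).
#' @param nodes shooting-node count per continuous phase (for the emitted
#'   reference trajectory).
#' @param tol integrator tolerance.
#' @param fixed_steps if positive, integrate each node interval with this
#'   many fixed RK4 steps (matching the multiple-shooting discretization,
#'   so the emitted trajectory has exactly zero shooting defects).
#' @return list of class `gait_generator_config`.
#' @export
gait_generator_config <- function(model, x0, excitations, durations,
                                  nodes = c(12, 13), tol = 1e-8,
                                  fixed_steps = 0, u_durations = NULL) {
  stopifnot(inherits(model, "gait_model"), length(x0) == 30)
  structure(list(model = model, x0 = x0, excitations = excitations,
                 durations = durations, nodes = nodes, tol = tol,
                 fixed_steps = fixed_steps,
                 u_durations = u_durations %||% durations),
            class = "gait_generator_config")
}

# world gap of the touchdown shape of a foot (minimum over candidate shapes)
touchdown_gap <- function(model, q, side) {
  min(rf_foot_gaps(core_model(model), q, match(side, c("left", "right")) - 1L))
}

#' Forward-simulate a reference gait through the phase schedule
#'
#' Applies the first impact to the pre-impact state, integrates each
#' continuous phase under its open-loop excitation profile until the
#' phase-ending event fires (lift-off: the normal force of the constraint
#' rows dropped at the next phase reaches zero; touchdown: the next impact
#' shape's gap reaches zero; both located on a coarse grid and refined by
#' bisection), and applies the impacts. Emits the exact node-sampled
#' trajectory (for inverse-crime tracking tests) together with time
#' interpolants of the tracked channels.
#'
#' @param cfg a [gait_generator_config()].
#' @param schedule a [build_phase_schedule()] result matching the model's
#'   foot.
#' @return list with `trajectory` (a `gait_trajectory`), `reference` (a
#'   `reference_data` object) and the located `event_times`.
#' @export
generate_reference_gait <- function(cfg, schedule = NULL) {
  model <- cfg$model
  schedule <- schedule %||% build_phase_schedule(
    if (inherits(model$foot, "ellipse_foot")) "ellipse" else "double_circle")
  nc <- length(schedule$cont)
  stopifnot(length(cfg$durations) == nc, length(cfg$excitations) == nc)
  x <- as.numeric(cfg$x0)
  phases <- vector("list", nc)
  impacts <- list()
  t0 <- 0
  events <- numeric(nc)
  for (j in seq_len(nc)) {
    ph <- schedule$cont[[j]]
    if (ph$entry %in% c("impact_v0", "impact")) {
      st <- model_state(x[1:9], x[10:18])
      im <- plastic_impact(model, st, ph$modes)
      impacts[[length(impacts) + 1]] <-
        list(at_phase = j, impulses = im$impulses, dKE = im$dKE,
             pre = x, modes = ph$modes)
      x[10:18] <- im$qdot_post
    }
    nj <- cfg$nodes[j]
    U <- cfg$excitations[[j]]
    if (is.null(dim(U))) U <- matrix(U, 12, nj)
    if (ncol(U) != nj) U <- U[, round(seq(1, ncol(U), length.out = nj)), drop = FALSE]
    # a phase followed by a constraint drop ends at its configured duration
    # (the lift-off boundary is free: unilaterality and friction at the
    # nodes bound the released force); a phase followed by an impact ends
    # at the touchdown event (gap of the landing shape reaches zero)
    if (j < nc && schedule$cont[[j + 1]]$entry == "identity") {
      Tj <- cfg$u_durations[j]
    } else {
      td <- if (j < nc) schedule$cont[[j + 1]]$touchdown else
        schedule$final_impact$touchdown
      evf <- function(xx) shape_gap(model, xx[1:9], td$foot, td$shape)
      # locate with the controls on a fixed node clock, then iterate the
      # clock to the located duration
      Td <- cfg$u_durations[j]
      Tj <- NULL
      for (fp in 1:10) {
        tn <- seq(0, Td, length.out = nj)
        Tj <- phase_end_root(model, x, ph$modes, U, tn, cfg$durations[j],
                             evf, cfg$tol, cfg$fixed_steps,
                             clear_first = TRUE, try_first = Td)
        if (is.null(Tj))
          stop("touchdown event did not occur in phase ", ph$name,
               " within ", cfg$durations[j], " s")
        if (abs(Tj - Td) < 1e-10) break
        Td <- Tj
      }
    }
    events[j] <- Tj
    tn <- seq(0, Tj, length.out = nj)
    out <- integrate_phase(model, x, ph$modes, Tj, U, tn, record = tn,
                           tol = cfg$tol, fixed_steps = cfg$fixed_steps)
    phases[[j]] <- list(t = t0 + tn, X = out$X, U = U, duration = Tj,
                        modes = ph$modes)
    x <- out$x_end
    t0 <- t0 + Tj
  }
  # final impact (touchdown of the swing foot)
  fi <- schedule$final_impact
  st <- model_state(x[1:9], x[10:18])
  im <- plastic_impact(model, st, fi$modes)
  impacts[[length(impacts) + 1]] <-
    list(at_phase = nc + 1, impulses = im$impulses, dKE = im$dKE,
         pre = x, modes = fi$modes)
  traj <- structure(list(phases = phases, impacts = impacts,
                         schedule = schedule, pre_impact_state = cfg$x0),
                    class = "gait_trajectory")
  list(trajectory = traj, reference = reference_from_trajectory(model, traj),
       event_times = events, touchdown_time = t0)
}

# Root-find on the phase duration: the phase-ending event value (lift-off
# normal force or touchdown gap), evaluated at the END of a rollout over
# [0, T] on the phase's own control/node grid, as a function of T.  Scanning
# then bisecting in T keeps the located duration exactly consistent with the
# discretization the trajectory is emitted with (including fixed-step RK4).
phase_end_root <- function(model, x, modes, U, tn, Tmax, evf, tol,
                           fixed_steps, clear_first = FALSE, nscan = 101,
                           try_first = NULL, tol_event = 1e-7) {
  endval <- function(T) {
    out <- tryCatch(integrate_phase(model, x, modes, T, U, tn, tol = tol,
                                    record = tn[tn < T], # node-interval segments
                                    fixed_steps = fixed_steps),
                    error = function(e) NULL)
    if (is.null(out)) return(NA_real_)
    tryCatch(evf(out$x_end), error = function(e) NA_real_)
  }
  # the configured duration may already be the event-consistent root
  if (!is.null(try_first)) {
    v <- endval(try_first)
    if (is.finite(v) && abs(v) < tol_event) return(try_first)
  }
  Ts <- seq(Tmax / 400, Tmax, length.out = nscan)
  vals <- vapply(Ts, endval, 0)
  # drop everything from the first unevaluable duration on
  bad <- which(is.na(vals))
  if (length(bad)) {
    if (bad[1] == 1L) return(NULL)
    Ts <- Ts[1:(bad[1] - 1L)]; vals <- vals[1:(bad[1] - 1L)]
  }
  i0 <- 1L
  if (clear_first) {
    lifted <- which(vals > 2e-3)
    if (!length(lifted)) return(NULL)
    i0 <- lifted[1]
  }
  cross <- which(vals[-1] <= 0 & vals[-length(vals)] > 0)
  cross <- cross[cross >= i0]
  if (!length(cross)) return(NULL)
  lo <- Ts[cross[1]]; hi <- Ts[cross[1] + 1]
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (endval(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2
}

# node-sampled reference channels + spline interpolants from a trajectory
reference_from_trajectory <- function(model, traj) {
  tt <- unlist(lapply(traj$phases, `[[`, "t"))
  X <- do.call(cbind, lapply(traj$phases, `[[`, "X"))
  cop <- fx <- fz <- numeric(length(tt))
  k <- 0
  for (ph in traj$phases) {
    for (i in seq_len(ncol(ph$X))) {
      k <- k + 1
      st <- model_state(ph$X[1:9, i], ph$X[10:18, i])
      ui <- control_at(ph$U, ph$t - ph$t[1], tt[k] - ph$t[1])
      fd <- constrained_forward_dynamics(model, st, modes = ph$modes,
                                         a = ph$X[19:30, i])
      cp <- try(cop_and_ground_force(fd$constraints, fd$lambda), silent = TRUE)
      if (!inherits(cp, "try-error")) {
        cop[k] <- cp$r_P[1]; fx[k] <- cp$f_P[1]; fz[k] <- cp$f_P[2]
      } else {
        cop[k] <- NA; fx[k] <- NA; fz[k] <- NA
      }
    }
  }
  dup <- duplicated(tt)
  mkspl <- function(y) {
    ok <- !dup & !is.na(y)
    splinefun(tt[ok], y[ok], method = "natural")
  }
  ang <- lapply(3:9, function(i) mkspl(X[i, ]))
  vel <- lapply(3:9, function(i) mkspl(X[9 + i, ]))
  structure(list(t = tt, X = X, angles = ang, rates = vel,
                 cop = mkspl(cop), force_x = mkspl(fx), force_z = mkspl(fz),
                 duration = max(tt), max_force = max(fz, na.rm = TRUE),
                 durations = vapply(traj$phases, `[[`, 0, "duration")),
            class = "reference_data")
}

#' @export
print.reference_data <- function(x, ...) {
  cat(sprintf("reference_data: %.3f s, %d samples, peak normal force %.0f N\n",
              x$duration, length(x$t), x$max_force))
  invisible(x)
}
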