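#' Optimal-control configuration
#'
#' Settings for the multi-phase walking OCPs (tracking and prediction):
#' transcription sizes, solver tolerances, bounds, cost weights and the two
#' prediction equality targets (average forward speed and step length).
#'
#' @param nodes shooting nodes per continuous phase (`NULL`: 25 total for
#'   the ellipse schedule as `c(12, 13)`, 31 for the double-circle schedule
#'   as `c(7, 8, 8, 8)`).
#' @param fixed_steps RK4 steps per shooting interval (the transcription's
#'   deterministic discretization of the dynamics).
#' @param feas_tol,opt_tol feasibility / first-order-optimality tolerances.
#' @param ineq_tol slack below zero tolerated on inequality rows before they
#'   are treated as violated (0 = strict).
#' @param max_iter SQP iteration cap.
#' @param mu friction coefficient bounding |tangential| <= mu * normal.
#' @param knee_hyper permitted knee hyper-extension (rad).
#' @param bound_pad extra room added to the reference range for the state
#'   box bounds: `c(position m, angle rad, velocity m/s, rate rad/s)`.
#' @param w_theta,w_omega tracking weights on angles / angular rates
#'   (`(4/pi)^2` and a tenth of it: a pi/4 angle error scores about 1).
#' @param ankle_scale factor applied to the ankle rows of the tracking
#'   weights (kinematic foot error is expected at the ankle).
#' @param w_P CoP tracking weight (1/m^2).
#' @param w_F force tracking weight; `NULL` means `1/max(force)^2` from the
#'   reference (normalized by the peak recorded force).
#' @param reg control/activation regularization weight.
#' @param mayer_impulse impulse regularization weight of the tracking Mayer
#'   term.
#' @param w_delta impulse weight of the prediction Mayer term.
#' @param speed,step_length prediction equality targets (m/s, m).
#' @param periodicity enforce mirrored periodicity constraints?
#' @param init_activation,init_excitation initial-guess constants.
#' @param duration_bounds 2 x n_phases matrix of duration bounds (s), or
#'   `NULL` for `[0, 0.8]` everywhere.
#' @param ankle_rate_bound optional bound on |ankle rate| (rad/s; e.g. 3.96
#'   for the constrained-ankle variant), `NULL` for none.
#' @param verbose print SQP iterations?
#' @param working_set freeze variables pressed against their bounds when
#'   computing SQP steps?
#' @param soc attempt a second-order correction when the full step is
#'   rejected?
#' @param rho_cap upper bound on the merit penalty weight.
#' @return list of class `ocp_config`.
#' @export
ocp_config <- function(nodes = NULL, fixed_steps = 8, feas_tol = 1e-6,
                       opt_tol = 1e-5, ineq_tol = 0, max_iter = 150, mu = 0.8,
                       knee_hyper = 0.1, bound_pad = c(1, 1, 1, 1),
                       w_theta = (4 / pi)^2, w_omega = 0.1 * (4 / pi)^2,
                       ankle_scale = 1 / 100, w_P = 400, w_F = NULL,
                       reg = 1e-3, mayer_impulse = 1e-5, w_delta = 1e-2,
                       speed = 1.01, step_length = 0.61, periodicity = TRUE,
                       init_activation = 0.01, init_excitation = 0.025,
                       duration_bounds = NULL, ankle_rate_bound = NULL,
                       verbose = FALSE, working_set = TRUE, soc = TRUE,
                       rho_cap = Inf) {
  structure(as.list(environment()), class = "ocp_config")
}

default_nodes <- function(schedule) {
  if (schedule$foot_model == "ellipse") c(12L, 13L) else c(7L, 8L, 8L, 8L)
}

# ---------------------------------------------------------------------------
# small kinematic helpers used by boundary constraints

foot_alpha <- function(q, side) {
  if (side == "left") q[3] + q[4] + q[5] + q[6] else q[3] + q[7] + q[8] + q[9]
}

ankle_position <- function(model, q, side) {
  b <- model$body
  phi_th <- q[3] + if (side == "left") q[4] else q[7]
  phi_sh <- phi_th + if (side == "left") q[5] else q[8]
  c(q[1], q[2]) + rot2v(phi_th, c(0, -b$len_thigh)) +
    rot2v(phi_sh, c(0, -b$len_shank))
}

# world x of the current contact point of one shape of one foot
shape_contact_x <- function(model, q, side, shape) {
  ank <- ankle_position(model, q, side)
  al <- foot_alpha(q, side)
  f <- model$foot
  if (shape == "ellipse") {
    ctr <- ank + rot2v(al, f$r_E)
    sol <- rf_ellipse_lowest(f$r_x, f$r_y, al + f$theta_E)
    ctr[1] + sol$offset[1]
  } else {
    ctr <- ank + rot2v(al, if (shape == "heel") f$r_H else f$r_F)
    ctr[1]
  }
}

shape_gap <- function(model, q, side, shape) {
  g <- rf_foot_gaps(core_model(model), q, match(side, c("left", "right")) - 1L)
  if (shape == "ellipse") g[["ellipse"]] else g[[shape]]
}

# ---------------------------------------------------------------------------
# shared cost pieces

node_tracking_cost <- function(model, x, u, tabs, ref, cfg, modes, w_F) {
  q <- x[1:9]; qd <- x[10:18]; a <- x[19:30]
  wth <- rep(cfg$w_theta, 7); wom <- rep(cfg$w_omega, 7)
  # coordinates 3..9: pitch, l hip, l knee, l ankle, r hip, r knee, r ankle
  wth[c(4, 7)] <- wth[c(4, 7)] * cfg$ankle_scale
  wom[c(4, 7)] <- wom[c(4, 7)] * cfg$ankle_scale
  cost <- 0
  for (i in 1:7) {
    cost <- cost + wth[i] * (q[i + 2] - ref$angles[[i]](tabs))^2 +
      wom[i] * (qd[i + 2] - ref$rates[[i]](tabs))^2
  }
  dyn <- node_dynamics(model, x, modes)
  cost <- cost + cfg$w_P * (dyn$cop_x - ref$cop(tabs))^2 +
    w_F * ((dyn$fx - ref$force_x(tabs))^2 + (dyn$fz - ref$force_z(tabs))^2)
  cost + cfg$reg * (sum(u^2) + sum(a^2))
}

# constraint forces, CoP and resultant at one node (lambda depends on the
# state only: excitations act through the activation derivative)
node_dynamics <- function(model, x, modes) {
  cm <- mode_code(modes)
  tau <- if (is.null(model$core$act)) rep(0, 9) else
    rf_joint_torques(model$core, x[1:9], x[10:18], pmin(pmax(x[19:30], 0), 1))
  fd <- rf_fd(model$core, x[1:9], x[10:18], tau, cm[1], cm[2],
              model$baumgarte[1], model$baumgarte[2], check = FALSE)
  rows <- mode_rows(modes)
  lam <- as.numeric(fd$lambda)
  kinds <- vapply(rows, `[[`, "", "kind")
  feet <- vapply(rows, `[[`, "", "foot")
  ncon <- kinds == "contact"
  fz <- sum(lam[ncon]); fx <- sum(lam[!ncon])
  cop <- NA_real_
  if (any(ncon) && fz > 0) {
    cs <- rf_constraints(model$core, x[1:9], x[10:18], cm[1], cm[2])
    cop <- sum(lam[ncon] * cs$points[ncon, 1]) / fz
  }
  list(lambda = lam, kinds = kinds, feet = feet, fx = fx, fz = fz,
       cop_x = if (is.finite(cop)) cop else 0)
}

#' Tracking cost of a trajectory against reference data
#'
#' Node-sampled weighted least squares on the pelvis and leg angles and
#' angular rates, the CoP and the ground-force vector (ankle rows
#' down-weighted), plus control/activation regularization (Lagrange part)
#' and impulse regularization (Mayer part).
#'
#' @param traj a `gait_trajectory`.
#' @param ref a `reference_data` object.
#' @param cfg an [ocp_config()].
#' @param model the [gait_model()].
#' @return scalar cost.
#' @export
tracking_cost <- function(traj, ref, cfg, model) {
  w_F <- cfg$w_F %||% (1 / ref$max_force^2)
  cost <- 0
  for (ph in traj$phases) {
    for (k in seq_len(ncol(ph$X)))
      cost <- cost + node_tracking_cost(model, ph$X[, k], ph$U[, k], ph$t[k],
                                        ref, cfg, ph$modes, w_F)
  }
  cost + cfg$mayer_impulse *
    sum(unlist(lapply(traj$impacts, function(im) im$impulses))^2)
}

#' Prediction cost of a trajectory
#'
#' Integrated squared muscle activation (trapezoidal quadrature over the
#' shooting nodes of every continuous phase) plus the weighted sum of
#' squared foot-ground impulses.
#'
#' @inheritParams tracking_cost
#' @return scalar cost.
#' @export
prediction_cost <- function(traj, cfg) {
  lag <- 0
  for (ph in traj$phases) {
    n <- ncol(ph$X)
    h <- ph$duration / (n - 1)
    w <- c(0.5, rep(1, n - 2), 0.5) * h
    lag <- lag + sum(w * colSums(ph$X[19:30, , drop = FALSE]^2))
  }
  lag + cfg$w_delta *
    sum(unlist(lapply(traj$impacts, function(im) im$impulses))^2)
}

# ---------------------------------------------------------------------------
# transcription

make_ocp_problem <- function(model, schedule, cost = c("tracking", "prediction"),
                             cfg = ocp_config(), ref = NULL) {
  cost <- match.arg(cost)
  if (cost == "tracking" && is.null(ref))
    stop("tracking OCP needs reference data")
  nodes <- cfg$nodes %||% default_nodes(schedule)
  nc <- length(schedule$cont)
  stopifnot(length(nodes) == nc, all(nodes >= 2))
  core <- core_model(model)
  bg <- model$baumgarte
  W <- sum(model$body$mass) * model$body$g   # force scale for constraint rows
  w_F <- cfg$w_F %||% if (!is.null(ref)) 1 / ref$max_force^2 else 1e-6

  # --- variable layout ---
  idx <- 0L
  take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  iv0 <- take(30L)
  phase <- vector("list", nc)
  for (j in seq_len(nc)) {
    phase[[j]] <- list(
      X = matrix(take(30L * (nodes[j] - 1L)), 30L),   # nodes 2..n_j
      U = matrix(take(12L * nodes[j]), 12L),
      T = take(1L))
  }
  nv <- idx
  layout <- list(v0 = iv0, phase = phase, nodes = nodes)

  cm <- lapply(schedule$cont, function(p) mode_code(p$modes))
  final_cm <- mode_code(schedule$final_impact$modes)
  first_cm <- cm[[1]]

  entry_deps <- function(j) {
    if (j == 1) iv0 else phase[[j - 1]]$X[, nodes[j - 1] - 1L]
  }
  # state entering continuous phase j (after any impact)
  entry_state <- function(v, j) {
    if (j == 1) {
      x <- v[iv0]
      im <- rf_impact(core, x[1:9], x[10:18], first_cm[1], first_cm[2])
      x[10:18] <- as.numeric(im$qd_post)
      return(x)
    }
    x <- v[phase[[j - 1]]$X[, nodes[j - 1] - 1L]]
    if (schedule$cont[[j]]$entry == "impact") {
      im <- rf_impact(core, x[1:9], x[10:18], cm[[j]][1], cm[[j]][2])
      x[10:18] <- as.numeric(im$qd_post)
    }
    x
  }
  node_state <- function(v, j, k) {
    if (k == 1) entry_state(v, j) else v[phase[[j]]$X[, k - 1L]]
  }
  node_deps <- function(j, k) {
    if (k == 1) entry_deps(j) else phase[[j]]$X[, k - 1L]
  }
  node_time <- function(v, j, k) {
    t0 <- if (j > 1) sum(v[vapply(phase[1:(j - 1)], `[[`, 0L, "T")]) else 0
    t0 + (k - 1) * v[phase[[j]]$T] / (nodes[j] - 1)
  }
  tdeps <- function(j) vapply(phase[1:j], `[[`, 0L, "T")

  impulses_at <- function(v, j) { # impulses of the impact entering phase j
    if (j == 1) {
      x <- v[iv0]
      as.numeric(rf_impact(core, x[1:9], x[10:18], first_cm[1], first_cm[2])$impulses)
    } else {
      x <- v[phase[[j - 1]]$X[, nodes[j - 1] - 1L]]
      as.numeric(rf_impact(core, x[1:9], x[10:18], cm[[j]][1], cm[[j]][2])$impulses)
    }
  }
  final_impulses <- function(v) {
    x <- v[phase[[nc]]$X[, nodes[nc] - 1L]]
    as.numeric(rf_impact(core, x[1:9], x[10:18], final_cm[1], final_cm[2])$impulses)
  }

  eq <- list(); ineq <- list(); obj <- list()
  add_eq <- function(el) eq[[length(eq) + 1L]] <<- el
  add_ineq <- function(el) ineq[[length(ineq) + 1L]] <<- el
  add_obj <- function(el) obj[[length(obj) + 1L]] <<- el

  # --- entry conditions at the pre-impact state v0 ---
  rows1 <- mode_rows(schedule$cont[[1]]$modes)
  td_foot <- schedule$cont[[1]]$touchdown$foot
  n_gap <- sum(vapply(rows1, function(r) r$kind == "contact", TRUE))
  n_vel <- sum(vapply(rows1, function(r) r$foot != td_foot, TRUE))
  add_eq(list(
    name = "entry_manifold",
    fun = function(v) {
      x <- v[iv0]
      cs <- rf_constraints(core, x[1:9], x[10:18], first_cm[1], first_cm[2])
      kinds <- cs$kind   # 0 contact, 1 rolling
      feet <- c("left", "right")[cs$foot + 1L]
      c(cs$gap[kinds == 0L], cs$velocity[feet != td_foot])
    },
    deps = iv0, n = n_gap + n_vel))

  # --- shooting defects ---
  for (j in seq_len(nc)) for (k in seq_len(nodes[j] - 1L)) {
    local({
      jj <- j; kk <- k
      nj <- nodes[jj]
      Uidx <- phase[[jj]]$U
      Tidx <- phase[[jj]]$T
      nxt <- phase[[jj]]$X[, kk]
      deps <- unique(c(node_deps(jj, kk), Uidx[, kk], Uidx[, kk + 1L],
                       Tidx, nxt))
      cmj <- cm[[jj]]
      add_eq(list(
        name = sprintf("defect_p%d_i%d", jj, kk),
        fun = function(v) {
          x <- node_state(v, jj, kk)
          Tj <- v[Tidx]
          h <- Tj / (nj - 1)
          U <- cbind(v[Uidx[, kk]], v[Uidx[, kk + 1L]])
          out <- rf_rollout(core, x, cmj[1], cmj[2], c(0, h), U, h,
                            1e-8, bg[1], bg[2], NULL, 200000L,
                            as.integer(cfg$fixed_steps))
          as.numeric(out$x_end) - v[nxt]
        },
        deps = deps, n = 30L))
    })
  }

  # --- phase-switch conditions ---
  for (j in seq_len(nc)) {
    if (j == 1) next
    local({
      jj <- j
      prev <- schedule$cont[[jj - 1]]; cur <- schedule$cont[[jj]]
      ldeps <- phase[[jj - 1]]$X[, nodes[jj - 1] - 1L]
      cmp <- cm[[jj - 1]]
      if (cur$entry == "identity") {
        # rows dropped at the switch need no boundary equality: the node
        # unilaterality/friction inequalities bound the released force, and
        # the switch time is free.  Newly imposed rolling rows must already
        # be satisfied at velocity level.
        sw <- mode_switch_rows(prev$modes, cur$modes)
        if (length(sw$added)) {
          cmn <- cm[[jj]]
          add_eq(list(
            name = sprintf("newroll_p%d", jj),
            fun = function(v) {
              x <- v[ldeps]
              cs <- rf_constraints(core, x[1:9], x[10:18], cmn[1], cmn[2])
              cs$velocity[sw$added]
            },
            deps = ldeps, n = length(sw$added)))
        }
      } else if (cur$entry == "impact") {
        td <- cur$touchdown
        add_eq(list(
          name = sprintf("touchdown_p%d", jj),
          fun = function(v) {
            q <- v[ldeps][1:9]
            shape_gap(model, q, td$foot, td$shape)
          },
          deps = ldeps, n = 1L))
      }
    })
  }

  # --- final touchdown ---
  xend_idx <- phase[[nc]]$X[, nodes[nc] - 1L]
  td_fin <- schedule$final_impact$touchdown
  add_eq(list(
    name = "final_touchdown",
    fun = function(v) {
      q <- v[xend_idx][1:9]
      shape_gap(model, q, td_fin$foot, td_fin$shape)
    },
    deps = xend_idx, n = 1L))

  # --- periodicity with left/right mirroring ---
  if (isTRUE(cfg$periodicity)) {
    sel <- c(3:9, 10:18, 19:30)   # pitch + joints, all velocities, activations
    add_eq(list(
      name = "periodicity",
      fun = function(v) {
        mx <- mirror_map(v[xend_idx])
        mx[sel] - v[iv0][sel]
      },
      deps = c(xend_idx, iv0[sel]), n = length(sel)))
  }

  # --- prediction equalities: average speed and step length ---
  if (cost == "prediction") {
    Tall <- vapply(phase, `[[`, 0L, "T")
    add_eq(list(
      name = "average_speed",
      fun = function(v)
        (v[xend_idx[1]] - v[iv0[1]]) - cfg$speed * sum(v[Tall]),
      deps = c(xend_idx[1], iv0[1], Tall), n = 1L))
    td0 <- schedule$cont[[1]]$touchdown
    add_eq(list(
      name = "step_length",
      fun = function(v) {
        x0 <- shape_contact_x(model, v[iv0][1:9], td0$foot, td0$shape)
        x1 <- shape_contact_x(model, v[xend_idx][1:9], td_fin$foot, td_fin$shape)
        (x1 - x0) - cfg$step_length
      },
      deps = c(iv0[1:9], xend_idx[1:9]), n = 1L))
  }

  # --- node path inequalities ---
  for (j in seq_len(nc)) for (k in seq_len(nodes[j])) {
    local({
      jj <- j; kk <- k
      ph <- schedule$cont[[jj]]
      rows <- mode_rows(ph$modes)
      deps <- node_deps(jj, kk)
      feet_roll <- unique(vapply(rows, `[[`, "", "foot"))
      n_norm <- sum(vapply(rows, function(r) r$kind == "contact", TRUE))
      n_fric <- 2L * length(feet_roll)
      airborne <- c("left", "right")[ph$modes == "airborne"]
      n_gap <- length(airborne) *
        (if (schedule$foot_model == "ellipse") 1L else 2L)
      add_ineq(list(
        name = sprintf("path_p%d_n%d", jj, kk),
        fun = function(v) {
          x <- node_state(v, jj, kk)
          dyn <- node_dynamics(model, x, ph$modes)
          lamN <- dyn$lambda[dyn$kinds == "contact"] / W
          fr <- unlist(lapply(feet_roll, function(ft) {
            fN <- sum(dyn$lambda[dyn$kinds == "contact" & dyn$feet == ft]) / W
            fT <- sum(dyn$lambda[dyn$kinds == "rolling" & dyn$feet == ft]) / W
            c(cfg$mu * fN - fT, cfg$mu * fN + fT)
          }))
          gaps <- unlist(lapply(airborne, function(ft)
            rf_foot_gaps(core, x[1:9], match(ft, c("left", "right")) - 1L)))
          c(lamN, fr, gaps)
        },
        deps = deps, n = n_norm + n_fric + n_gap))
    })
  }

  # --- impulse inequalities (unilaterality + friction) ---
  impulse_ineq <- function(Lam, modes) {
    rows <- mode_rows(modes)
    kinds <- vapply(rows, `[[`, "", "kind")
    feet <- vapply(rows, `[[`, "", "foot")
    LN <- Lam[kinds == "contact"] / W
    fr <- unlist(lapply(unique(feet), function(ft) {
      N <- sum(Lam[kinds == "contact" & feet == ft]) / W
      T <- sum(Lam[kinds == "rolling" & feet == ft]) / W
      c(cfg$mu * N - T, cfg$mu * N + T)
    }))
    c(LN, fr)
  }
  n_imp1 <- {
    rows <- mode_rows(schedule$cont[[1]]$modes)
    sum(vapply(rows, function(r) r$kind == "contact", TRUE)) +
      2L * length(unique(vapply(rows, `[[`, "", "foot")))
  }
  add_ineq(list(
    name = "impulse_first",
    fun = function(v) impulse_ineq(impulses_at(v, 1), schedule$cont[[1]]$modes),
    deps = iv0, n = n_imp1))
  n_impF <- {
    rows <- mode_rows(schedule$final_impact$modes)
    sum(vapply(rows, function(r) r$kind == "contact", TRUE)) +
      2L * length(unique(vapply(rows, `[[`, "", "foot")))
  }
  add_ineq(list(
    name = "impulse_final",
    fun = function(v) impulse_ineq(final_impulses(v), schedule$final_impact$modes),
    deps = xend_idx, n = n_impF))

  # --- objective ---
  if (cost == "tracking") {
    for (j in seq_len(nc)) for (k in seq_len(nodes[j])) {
      local({
        jj <- j; kk <- k
        ph <- schedule$cont[[jj]]
        deps <- unique(c(node_deps(jj, kk), phase[[jj]]$U[, kk], tdeps(jj)))
        add_obj(list(
          name = sprintf("track_p%d_n%d", jj, kk),
          fun = function(v) {
            x <- node_state(v, jj, kk)
            u <- v[phase[[jj]]$U[, kk]]
            node_tracking_cost(model, x, u, node_time(v, jj, kk), ref, cfg,
                               ph$modes, w_F)
          },
          deps = deps, n = 1L))
      })
    }
    imp_w <- cfg$mayer_impulse
  } else {
    for (j in seq_len(nc)) {
      local({
        jj <- j
        nj <- nodes[jj]
        adeps <- c(entry_deps(jj)[19:30],
                   as.integer(phase[[jj]]$X[19:30, , drop = FALSE]))
        add_obj(list(
          name = sprintf("act_quad_p%d", jj),
          fun = function(v) {
            h <- v[phase[[jj]]$T] / (nj - 1)
            w <- c(0.5, rep(1, nj - 2), 0.5) * h
            s <- 0
            for (k in seq_len(nj))
              s <- s + w[k] * sum(node_state(v, jj, k)[19:30]^2)
            s
          },
          deps = unique(c(adeps, phase[[jj]]$T)), n = 1L))
      })
    }
    imp_w <- cfg$w_delta
  }
  # impulse Mayer term (all impact phases of the step)
  imp_phases <- which(vapply(schedule$cont, function(p)
    p$entry %in% c("impact_v0", "impact"), TRUE))
  for (j in imp_phases) {
    local({
      jj <- j
      add_obj(list(
        name = sprintf("impulse_sq_%d", jj),
        fun = function(v) imp_w * sum(impulses_at(v, jj)^2),
        deps = entry_deps(jj), n = 1L))
    })
  }
  add_obj(list(
    name = "impulse_sq_final",
    fun = function(v) imp_w * sum(final_impulses(v)^2),
    deps = xend_idx, n = 1L))

  structure(list(model = model, schedule = schedule, cost = cost, cfg = cfg,
                 ref = ref, layout = layout, nv = nv, eq = eq, ineq = ineq,
                 obj = obj, W = W, entry_state = entry_state,
                 impulses_at = impulses_at, final_impulses = final_impulses,
                 w_F = w_F),
            class = "ocp_problem")
}

# ---------------------------------------------------------------------------
# pack / unpack

pack_trajectory <- function(prob, traj) {
  lay <- prob$layout
  v <- numeric(prob$nv)
  v[lay$v0] <- traj$pre_impact_state
  for (j in seq_along(lay$phase)) {
    ph <- traj$phases[[j]]
    nj <- lay$nodes[j]
    if (ncol(ph$X) != nj)
      stop("guess phase ", j, " has ", ncol(ph$X), " nodes; expected ", nj)
    v[lay$phase[[j]]$X] <- ph$X[, -1]
    v[lay$phase[[j]]$U] <- ph$U
    v[lay$phase[[j]]$T] <- ph$duration
  }
  v
}

unpack_trajectory <- function(prob, v) {
  lay <- prob$layout
  sched <- prob$schedule
  phases <- vector("list", length(lay$phase))
  impacts <- list()
  t0 <- 0
  for (j in seq_along(lay$phase)) {
    nj <- lay$nodes[j]
    x1 <- prob$entry_state(v, j)
    X <- cbind(x1, matrix(v[lay$phase[[j]]$X], 30))
    dimnames(X) <- NULL
    Tj <- v[lay$phase[[j]]$T]
    ph <- sched$cont[[j]]
    if (ph$entry %in% c("impact_v0", "impact")) {
      pre <- if (j == 1) v[lay$v0] else
        v[lay$phase[[j - 1]]$X[, lay$nodes[j - 1] - 1L]]
      impacts[[length(impacts) + 1]] <-
        list(at_phase = j, impulses = prob$impulses_at(v, j),
             modes = ph$modes, pre = pre)
    }
    phases[[j]] <- list(t = t0 + seq(0, Tj, length.out = nj), X = X,
                        U = matrix(v[lay$phase[[j]]$U], 12),
                        duration = Tj, modes = ph$modes)
    t0 <- t0 + Tj
  }
  xend <- v[lay$phase[[length(lay$phase)]]$X[, lay$nodes[length(lay$nodes)] - 1L]]
  impacts[[length(impacts) + 1]] <-
    list(at_phase = length(phases) + 1, impulses = prob$final_impulses(v),
         modes = sched$final_impact$modes, pre = xend)
  structure(list(phases = phases, impacts = impacts, schedule = sched,
                 pre_impact_state = v[lay$v0]),
            class = "gait_trajectory")
}

# ---------------------------------------------------------------------------
# bounds and initial guess

make_bounds <- function(prob, guess_v) {
  cfg <- prob$cfg
  lay <- prob$layout
  nv <- prob$nv
  lb <- rep(-Inf, nv); ub <- rep(Inf, nv)
  pad <- cfg$bound_pad
  state_idx <- c(list(lay$v0), lapply(lay$phase, function(p) as.integer(p$X)))
  # data range over all state variables, per component
  allX <- cbind(matrix(guess_v[lay$v0], 30),
                do.call(cbind, lapply(lay$phase, function(p)
                  matrix(guess_v[p$X], 30))))
  lo <- apply(allX, 1, min); hi <- apply(allX, 1, max)
  padv <- c(pad[1], pad[1], rep(pad[2], 7), pad[3], pad[3], rep(pad[4], 7),
            rep(0, 12))
  lo <- lo - padv; hi <- hi + padv
  lo[19:30] <- 0; hi[19:30] <- 1
  hi[5] <- min(hi[5], cfg$knee_hyper)   # knee hyper-extension limit
  hi[8] <- min(hi[8], cfg$knee_hyper)
  if (!is.null(cfg$ankle_rate_bound)) {
    lo[c(15, 18)] <- pmax(lo[c(15, 18)], -cfg$ankle_rate_bound)
    hi[c(15, 18)] <- pmin(hi[c(15, 18)], cfg$ankle_rate_bound)
  }
  for (ix in state_idx) {
    m <- matrix(ix, 30)
    for (i in 1:30) { lb[m[i, ]] <- lo[i]; ub[m[i, ]] <- hi[i] }
  }
  db <- cfg$duration_bounds %||%
    matrix(c(0, 0.8), 2, length(lay$phase))
  for (j in seq_along(lay$phase)) {
    u <- lay$phase[[j]]$U
    lb[u] <- 0; ub[u] <- 1
    lb[lay$phase[[j]]$T] <- db[1, j]; ub[lay$phase[[j]]$T] <- db[2, j]
  }
  list(lb = lb, ub = ub)
}

#' Build an initial guess for a walking OCP
#'
#' States are linearly interpolated from the reference at the shooting-node
#' times and polished onto the phase constraint manifolds: base height (and
#' pitch, when two shapes are in contact) is adjusted by Gauss-Newton steps
#' on the contact gaps, and velocities are projected onto the velocity-level
#' constraint manifold (the plastic-impact projection). Activations are set
#' to a small constant, controls likewise, durations from the reference
#' phase durations. The result is deliberately not dynamically feasible
#' (shooting defects are nonzero): it is a starting point, not a motion.
#'
#' @param ref a `reference_data` object.
#' @param schedule a [build_phase_schedule()] result.
#' @param cfg an [ocp_config()].
#' @param model the [gait_model()].
#' @return a `gait_trajectory` guess.
#' @export
initialize_guess <- function(ref, schedule, cfg, model) {
  nodes <- cfg$nodes %||% default_nodes(schedule)
  durations <- ref$durations
  t0 <- 0
  phases <- vector("list", length(nodes))
  interp_state <- function(tt) {
    idx <- vapply(3:9, function(i) ref$angles[[i - 2]](tt), 0)
    vel <- vapply(3:9, function(i) ref$rates[[i - 2]](tt), 0)
    qx <- approx(ref$t, ref$X[1, ], tt, rule = 2, ties = "ordered")$y
    qz <- approx(ref$t, ref$X[2, ], tt, rule = 2, ties = "ordered")$y
    vx <- approx(ref$t, ref$X[10, ], tt, rule = 2, ties = "ordered")$y
    vz <- approx(ref$t, ref$X[11, ], tt, rule = 2, ties = "ordered")$y
    c(qx, qz, idx, vx, vz, vel, rep(cfg$init_activation, 12))
  }
  for (j in seq_along(nodes)) {
    ph <- schedule$cont[[j]]
    tn <- t0 + seq(0, durations[j], length.out = nodes[j])
    X <- vapply(tn, interp_state, numeric(30))
    for (k in seq_len(ncol(X)))
      X[, k] <- project_state(model, X[, k], ph$modes)
    phases[[j]] <- list(t = tn, X = X,
                        U = matrix(cfg$init_excitation, 12, nodes[j]),
                        duration = durations[j], modes = ph$modes)
    t0 <- t0 + durations[j]
  }
  v0 <- phases[[1]]$X[, 1]
  structure(list(phases = phases, impacts = list(), schedule = schedule,
                 pre_impact_state = v0),
            class = "gait_trajectory")
}

#' Project a state onto the constraint manifold of a contact-mode pair
#'
#' Gauss-Newton on the contact gaps (moving the configuration minimally in
#' the gap-Jacobian row space), then projection of the velocities onto the
#' null space of the full constraint Jacobian.
#'
#' @param model a [gait_model()].
#' @param x state vector (30).
#' @param modes per-foot contact modes.
#' @return the projected state.
#' @export
project_state <- function(model, x, modes) {
  cmv <- mode_code(modes)
  if (all(cmv == 0L)) return(x)
  core <- core_model(model)
  for (it in 1:20) {
    cs <- rf_constraints(core, x[1:9], x[10:18], cmv[1], cmv[2])
    gap <- cs$gap[cs$kind == 0L]
    if (max(abs(gap)) < 1e-12) break
    Gc <- cs$G[cs$kind == 0L, , drop = FALSE]
    dq <- -t(Gc) %*% solve(Gc %*% t(Gc), gap)
    x[1:9] <- x[1:9] + as.numeric(dq)
  }
  im <- rf_impact(core, x[1:9], x[10:18], cmv[1], cmv[2])
  x[10:18] <- as.numeric(im$qd_post)
  x
}

# ---------------------------------------------------------------------------
# residual bundle

#' Path and boundary constraint residuals of a trajectory
#'
#' Evaluates every constraint of the multi-phase OCP at a given trajectory:
#' shooting defects, entry-manifold conditions, lift-off/touchdown
#' conditions, periodicity (when configured), prediction equalities, and
#' the node inequalities (unilateral normal forces, friction cone scaled by
#' total body weight, swing-foot clearance) plus impulse conditions.
#'
#' @param traj a `gait_trajectory`.
#' @param model the [gait_model()].
#' @param cfg an [ocp_config()].
#' @param cost `"tracking"` or `"prediction"`.
#' @param ref reference data (tracking only).
#' @param schedule phase schedule (defaults to the trajectory's).
#' @return list with named `equality` and `inequality` residual vectors
#'   (inequalities are feasible when >= 0).
#' @export
path_and_boundary_constraints <- function(traj, model, cfg = ocp_config(),
                                          cost = "prediction", ref = NULL,
                                          schedule = NULL) {
  schedule <- schedule %||% traj$schedule
  cfg$nodes <- vapply(traj$phases, function(p) ncol(p$X), 0L)
  prob <- make_ocp_problem(model, schedule, cost, cfg, ref)
  v <- pack_trajectory(prob, traj)
  eqv <- lapply(prob$eq, function(el) setNames(el$fun(v),
    rep(el$name, el$n)))
  inv <- lapply(prob$ineq, function(el) setNames(el$fun(v),
    rep(el$name, el$n)))
  list(equality = unlist(eqv), inequality = unlist(inv))
}

# ---------------------------------------------------------------------------
# solve

#' Solve a walking optimal-control problem
#'
#' Direct multiple shooting over the multi-phase schedule: states at the
#' shooting nodes, piecewise-linear excitations and phase durations are the
#' decision variables; each shooting interval is integrated with a fixed
#' RK4 discretization and continuity is enforced as defect equalities.
#' Impact phases apply the plastic-impact map and expose their impulses to
#' the cost and the impulse inequalities. The resulting nonlinear program
#' is solved by a dense Gauss-Newton SQP with an l1 merit line search.
#'
#' @param model an actuated [gait_model()].
#' @param schedule a [build_phase_schedule()] matching the model's foot.
#' @param cost `"tracking"` (weighted least squares against `ref`) or
#'   `"prediction"` (muscular effort + impulses, with average-speed and
#'   step-length equality constraints).
#' @param cfg an [ocp_config()].
#' @param guess a `gait_trajectory` initial guess (node counts must match
#'   `cfg$nodes`).
#' @param ref a `reference_data` object (tracking only).
#' @return an object of class `gait_ocp`: the solution trajectory plus
#'   objective, residual report and solver diagnostics.
#' @export
solve_ocp <- function(model, schedule, cost = c("tracking", "prediction"),
                      cfg = ocp_config(), guess, ref = NULL) {
  cost <- match.arg(cost)
  cfg$nodes <- cfg$nodes %||% vapply(guess$phases, function(p) ncol(p$X), 0L)
  prob <- make_ocp_problem(model, schedule, cost, cfg, ref)
  v0 <- pack_trajectory(prob, guess)
  bnd <- make_bounds(prob, v0)
  ctrl <- sqp_control(max_iter = cfg$max_iter, feas_tol = cfg$feas_tol,
                      opt_tol = cfg$opt_tol, ineq_tol = cfg$ineq_tol,
                      verbose = cfg$verbose,
                      working_set = cfg$working_set %||% TRUE,
                      soc = cfg$soc %||% TRUE,
                      rho_cap = cfg$rho_cap %||% Inf)
  sol <- sqp_solve(prob$eq, prob$ineq, prob$obj, v0, bnd$lb, bnd$ub, ctrl)
  traj <- unpack_trajectory(prob, sol$v)
  defect_rows <- grepl("^defect", names_of_eq(prob))
  residuals <- list(
    max_defect = if (any(defect_rows)) max(abs(sol$ce[defect_rows])) else 0,
    max_equality = if (length(sol$ce)) max(abs(sol$ce)) else 0,
    min_inequality = if (length(sol$ci)) min(sol$ci) else 0,
    stationarity = sol$stationarity)
  structure(list(trajectory = traj, objective = sol$f, cost = cost,
                 status = sol$status, converged = sol$status == "converged",
                 iterations = sol$iterations, residuals = residuals,
                 trace = sol$trace, cfg = cfg, problem = prob, v = sol$v,
                 trajectory_last = unpack_trajectory(prob, sol$v_last)),
            class = "gait_ocp")
}

names_of_eq <- function(prob)
  unlist(lapply(prob$eq, function(el) rep(el$name, el$n)))

#' Average forward speed of a solved step
#' @param x a `gait_ocp` or `gait_trajectory`.
#' @return base forward displacement divided by the step duration (m/s).
#' @export
average_speed <- function(x) {
  traj <- if (inherits(x, "gait_ocp")) x$trajectory else x
  xend <- traj$phases[[length(traj$phases)]]
  dx <- xend$X[1, ncol(xend$X)] - traj$pre_impact_state[1]
  dx / sum(vapply(traj$phases, `[[`, 0, "duration"))
}

#' Step length of a solved step
#'
#' Forward distance between the touchdown contact point at the first impact
#' and the (mirrored) touchdown contact point at the final impact.
#' @param x a `gait_ocp` or `gait_trajectory`.
#' @param model the [gait_model()].
#' @return step length (m).
#' @export
step_length <- function(x, model) {
  traj <- if (inherits(x, "gait_ocp")) x$trajectory else x
  sched <- traj$schedule
  td0 <- sched$cont[[1]]$touchdown
  tdf <- sched$final_impact$touchdown
  q0 <- traj$pre_impact_state[1:9]
  xe <- traj$phases[[length(traj$phases)]]
  qe <- xe$X[1:9, ncol(xe$X)]
  shape_contact_x(model, qe, tdf$foot, tdf$shape) -
    shape_contact_x(model, q0, td0$foot, td0$shape)
}

#' @export
print.gait_ocp <- function(x, ...) {
  cat(sprintf("gait_ocp (%s, %s foot): %s after %d iterations\n", x$cost,
              x$trajectory$schedule$foot_model, x$status, x$iterations))
  cat(sprintf("  objective %.6g; max |equality| %.2e; min inequality %.2e\n",
              x$objective, x$residuals$max_equality,
              x$residuals$min_inequality))
  invisible(x)
}

#' @export
summary.gait_ocp <- function(object, ...) {
  print(object)
  du <- vapply(object$trajectory$phases, `[[`, 0, "duration")
  cat(sprintf("  durations: %s s (total %.3f)\n",
              paste(signif(du, 4), collapse = " / "), sum(du)))
  for (im in object$trajectory$impacts)
    cat(sprintf("  impact -> phase %d: impulses [%s] N s\n", im$at_phase,
                paste(signif(im$impulses, 4), collapse = ", ")))
  invisible(object)
}

#' @export
plot.gait_ocp <- function(x, ...) {
  traj <- x$trajectory
  tt <- unlist(lapply(traj$phases, `[[`, "t"))
  X <- do.call(cbind, lapply(traj$phases, `[[`, "X"))
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
  matplot(tt, t(X[4:9, ]), type = "l", lty = 1, xlab = "t (s)",
          ylab = "joint angles (rad)", main = "joints")
  legend("topright", c("hipL", "kneeL", "ankL", "hipR", "kneeR", "ankR"),
         col = 1:6, lty = 1, cex = 0.6, bty = "n")
  plot(tt, X[2, ], type = "l", xlab = "t (s)", ylab = "base height (m)",
       main = "pelvis height")
  matplot(tt, t(X[19:30, ]), type = "l", lty = 1, xlab = "t (s)",
          ylab = "activation", main = "activations")
  plot(tt, X[1, ], type = "l", xlab = "t (s)", ylab = "base x (m)",
       main = "pelvis advance")
  invisible(x)
}

#' Predict one walking step (reduced-scale study)
#'
#' Convenience driver for the prediction OCP: designs a dynamically
#' consistent synthetic step as the initial guess, then runs the prediction
#' solve in warm-restarted rounds (each restart rebuilds the quasi-Newton
#' model, which lets the solver leave points where a single run stalls).
#' The returned solution carries the best iterate found.
#'
#' @param model an actuated ellipse-foot [gait_model()].
#' @param nodes shooting nodes per continuous phase.
#' @param rounds maximum number of warm-restarted solves.
#' @param max_iter SQP iterations per round.
#' @param cfg an [ocp_config()] overriding the study defaults.
#' @param guess optionally, a `gait_trajectory` to start from (skips the
#'   designer).
#' @param verbose print solver progress?
#' @return a `gait_ocp` object (prediction).
#' @export
predict_walking <- function(model, nodes = c(8L, 9L), rounds = 3,
                            max_iter = 200, cfg = NULL, guess = NULL,
                            verbose = FALSE) {
  schedule <- build_phase_schedule("ellipse")
  if (is.null(cfg)) {
    cfg <- ocp_config(nodes = nodes, fixed_steps = 8,
                      periodicity = TRUE, bound_pad = c(1, 1, 2, 12),
                      max_iter = max_iter, verbose = verbose)
    # plain KKT steps (no bound freezing, no second-order correction) reach
    # substantially lower infeasibility on this problem family
    cfg$working_set <- FALSE
    cfg$soc <- FALSE
  }
  cfg$nodes <- nodes
  if (is.null(guess)) {
    gen <- design_reference_step(model, speed = 1.0, nodes = nodes)
    guess <- generate_reference_gait(gen, schedule)$trajectory
  }
  sol <- NULL
  cur <- guess
  last_feas <- Inf
  for (r in seq_len(rounds)) {
    s <- solve_ocp(model, schedule, "prediction", cfg, guess = cur)
    if (is.null(sol) || s$residuals$max_equality < sol$residuals$max_equality)
      sol <- s
    if (s$status == "converged") { sol <- s; break }
    feas <- s$residuals$max_equality
    if (feas >= last_feas * 0.99) break   # no further progress
    last_feas <- feas
    cur <- s$trajectory_last
  }
  sol
}
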