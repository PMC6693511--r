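#' Integrate the model through one contact phase
#'
#' Adaptive Runge-Kutta-Fehlberg 4(5) integration of the contact DAE (with
#' Baumgarte stabilization) plus the MTG activation dynamics, under a fixed
#' per-foot contact-mode pair and piecewise-linear excitation signals.
#'
#' @param model a [gait_model()].
#' @param x0 state vector: `c(q, qdot, a)` (length 30; the activation block
#'   may be omitted for a passive model, in which case zeros are appended).
#' @param modes per-foot contact modes (length-2 character).
#' @param duration phase duration (s); zero returns `x0` unchanged.
#' @param controls 12 x n matrix of excitation values at `control_times`
#'   (piecewise linear in between), or a single 12-vector held constant.
#' @param control_times node times in `[0, duration]`.
#' @param record times in `[0, duration]` at which to report the state.
#' @param tol integrator absolute and relative tolerance.
#' @param gains Baumgarte gains (defaults to the model's).
#' @param fixed_steps if positive, use classic RK4 with this many equal
#'   steps per output segment instead of the adaptive integrator (a smooth
#'   deterministic map, used by the multiple-shooting transcription).
#' @return list with `x_end`, the matrix `X` (30 x length(record)) of
#'   recorded states, `times` and `n_steps`.
#' @export
integrate_phase <- function(model, x0, modes, duration,
                            controls = matrix(0, 12, 1), control_times = 0,
                            record = NULL, tol = 1e-8, gains = NULL,
                            fixed_steps = 0) {
  gains <- gains %||% model$baumgarte
  x0 <- as.numeric(x0)
  if (length(x0) == 18) x0 <- c(x0, rep(0, 12))
  if (length(x0) != 30) stop("state must have 18 or 30 entries")
  if (is.null(dim(controls))) controls <- matrix(controls, 12, length(control_times))
  cm <- mode_code(modes)
  out <- rf_rollout(core_model(model), x0, cm[1], cm[2],
                    as.numeric(control_times), controls, duration,
                    tol, gains[1], gains[2],
                    if (is.null(record)) NULL else as.numeric(record),
                    200000L, as.integer(fixed_steps))
  list(x_end = as.numeric(out$x_end), X = out$X,
       times = record, n_steps = out$n_steps)
}

#' Simulate a passive or open-loop rollout
#'
#' Thin convenience wrapper over [integrate_phase()] for a single phase with
#' dense state output, returning a tidy record of states, energies and (when
#' constraints are active) contact forces and centre of pressure.
#'
#' @inheritParams integrate_phase
#' @param n_record number of equally spaced output samples.
#' @return an object of class `gait_simulation`: list with `times`, `X`
#'   (30 x n), `energy`, and per-sample `lambda`, `cop`, `force` (when in
#'   contact).
#' @export
simulate_phase <- function(model, x0, modes, duration, controls = matrix(0, 12, 1),
                           control_times = 0, n_record = 101, tol = 1e-8) {
  ts <- seq(0, duration, length.out = n_record)
  out <- integrate_phase(model, x0, modes, duration, controls, control_times,
                         record = ts, tol = tol)
  X <- out$X
  en <- numeric(n_record)
  lam <- vector("list", n_record)
  copx <- rep(NA_real_, n_record); fx <- fz <- rep(NA_real_, n_record)
  has_contact <- any(modes != "airborne")
  for (i in seq_len(n_record)) {
    st <- model_state(X[1:9, i], X[10:18, i])
    en[i] <- as.numeric(total_energy(model, st))
    if (has_contact) {
      ui <- control_at(controls, control_times, ts[i])
      fd <- constrained_forward_dynamics(model, st, modes = modes, a = X[19:30, i])
      lam[[i]] <- fd$lambda
      cp <- try(cop_and_ground_force(fd$constraints, fd$lambda), silent = TRUE)
      if (!inherits(cp, "try-error")) {
        copx[i] <- cp$r_P[1]; fx[i] <- cp$f_P[1]; fz[i] <- cp$f_P[2]
      }
    }
  }
  structure(list(times = ts, X = X, energy = en, lambda = lam,
                 cop_x = copx, force_x = fx, force_z = fz, modes = modes),
            class = "gait_simulation")
}

control_at <- function(controls, control_times, t) {
  if (is.null(dim(controls))) return(controls)
  if (ncol(controls) == 1) return(controls[, 1])
  apply(controls, 1, function(row) approx(control_times, row, t, rule = 2)$y)
}

#' @export
print.gait_simulation <- function(x, ...) {
  cat(sprintf("gait_simulation: %.3f s, modes L=%s R=%s, %d samples\n",
              max(x$times), x$modes[1], x$modes[2], length(x$times)))
  invisible(x)
}
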