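#' Stance-phase trial record
#'
#' Time series of centre-of-pressure position, ground-reaction force vector
#' and ankle-frame pose over one stance phase. All quantities in SI units in
#' a fixed ground frame (x forward, z up, CoP on the ground plane).
#'
#' @param t strictly increasing sample times (s).
#' @param cop_x,cop_z CoP position (m; `cop_z` defaults to zeros).
#' @param force_x,force_z ground-reaction force (N); `force_z` (the normal
#'   component) must be non-negative.
#' @param ankle_x,ankle_z world ankle position (m).
#' @param ankle_angle world ankle-frame orientation (rad).
#' @return an object of class `stance_record` (also a data frame).
#' @export
stance_record <- function(t, cop_x, force_x, force_z, ankle_x, ankle_z,
                          ankle_angle, cop_z = rep(0, length(t))) {
  n <- length(t)
  if (n < 2) stop("a stance record needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (any(force_z < 0)) {
    bad <- which(force_z < 0)[1]
    stop("negative normal force at sample ", bad, " (t = ", t[bad], ")")
  }
  d <- data.frame(t = t, cop_x = cop_x, cop_z = cop_z, force_x = force_x,
                  force_z = force_z, ankle_x = ankle_x, ankle_z = ankle_z,
                  ankle_angle = ankle_angle)
  stopifnot_finite(as.matrix(d), "stance record")
  class(d) <- c("stance_record", "data.frame")
  d
}

#' Retain the loaded part of a stance record
#'
#' Keeps exactly the samples whose normal force exceeds `fraction` times the
#' peak normal force; the retained block must be contiguous.
#'
#' @param rec a [stance_record()].
#' @param fraction threshold fraction of the peak normal force (default 5%).
#' @return the trimmed [stance_record()].
#' @export
segment_stance <- function(rec, fraction = 0.05) {
  keep <- rec$force_z > fraction * max(rec$force_z)
  if (!any(keep)) stop("no sample exceeds the force threshold")
  idx <- which(keep)
  if (!all(diff(idx) == 1L))
    stop("retained samples are not contiguous; the record has multiple loaded episodes")
  out <- rec[idx, , drop = FALSE]
  class(out) <- c("stance_record", "data.frame")
  out
}

#' Fitting configuration for the CoP-rollback procedure
#'
#' @param w_r position-error weight (1/m^2); the default scores a 1 cm ankle
#'   position error as 1.
#' @param w_alpha orientation-error weight (1/rad^2); the default scores a
#'   pi/14 rad (~12.9 deg) error as 1.
#' @param fraction force threshold fraction for [segment_stance()].
#' @param foot_len total foot length constraint (m).
#' @param tol simplex convergence tolerance (relative).
#' @param maxit maximum simplex iterations.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(w_r = (1 / 0.01)^2, w_alpha = (14 / pi)^2,
                       fraction = 0.05, foot_len = 0.305, tol = 1e-6,
                       maxit = 2000) {
  stopifnot(w_r > 0, w_alpha > 0, fraction > 0, fraction < 1, foot_len > 0)
  structure(list(w_r = w_r, w_alpha = w_alpha, fraction = fraction,
                 foot_len = foot_len, tol = tol, maxit = maxit),
            class = "fit_config")
}

#' Reconstruct the ankle trajectory by rolling a candidate foot along the
#' recorded CoP
#'
#' The foot is posed at the recorded orientation and CoP at the final sample
#' (toe-off) and rolled backwards without slipping so that its contact point
#' visits every recorded CoP sample: the surface arc length between
#' successive contact points equals the ground distance between successive
#' CoP samples. For the double-circle foot, CoP samples between the
#' flat-pose heel and forefoot contact locations leave the orientation at
#' the flat angle and the ankle stationary. The ankle pose at each sample
#' follows rigidly from the orientation and contact point.
#'
#' @param foot a `foot_params` object.
#' @param rec a (segmented) [stance_record()].
#' @return data frame with per-sample `alpha`, `ankle_x`, `ankle_z`.
#' @export
rollback_reconstruct <- function(foot, rec) {
  n <- nrow(rec)
  an <- rec$ankle_angle[n]
  ellipse <- inherits(foot, "ellipse_foot")
  arc <- if (ellipse) ell_arc_fun(foot) else NULL
  xi <- function(a) roll_contact_x(foot, a, arc)
  off <- rec$cop_x[n] - xi(an)
  alpha <- numeric(n)
  ax <- az <- numeric(n)
  if (ellipse) {
    amax <- an + 6
    for (i in n:1) {
      rel <- rec$cop_x[i] - off
      if (i == n) {
        alpha[i] <- an
      } else {
        f <- function(a) xi(a) - rel
        flo <- f(an)
        if (flo < 0) {
          # noise can place a sample's CoP slightly ahead of the toe-off
          # anchor; hold such samples at the anchor pose
          if (flo < -0.02)
            stop("CoP at sample ", i, " lies ahead of the anchored contact point")
          alpha[i] <- an
        } else if (f(amax) > 0) {
          stop("CoP displacement at sample ", i,
               " exceeds the available rolling arc of the foot")
        } else {
          alpha[i] <- uniroot(f, c(an, amax), tol = 1e-12)$root
        }
      }
      p <- ankle_from_contact(foot, alpha[i], rec$cop_x[i])
      ax[i] <- p[1]; az[i] <- p[2]
    }
  } else {
    af <- dc_flat_angle(foot)
    span <- dc_flat_span(foot)
    for (i in n:1) {
      rel <- rec$cop_x[i] - off
      if (rel >= span) {          # forefoot rolling
        alpha[i] <- af - (rel - span) / foot$rad_F
        p <- ankle_from_contact(foot, alpha[i], rec$cop_x[i], "forefoot")
      } else if (rel <= 0) {      # heel rolling
        alpha[i] <- af - rel / foot$rad_H
        p <- ankle_from_contact(foot, alpha[i], rec$cop_x[i], "heel")
      } else {                    # flat: both circles touch, ankle fixed
        alpha[i] <- af
        p <- ankle_from_contact(foot, af, off, "heel")
      }
      ax[i] <- p[1]; az[i] <- p[2]
    }
  }
  data.frame(t = rec$t, alpha = alpha, ankle_x = ax, ankle_z = az)
}

#' Force-weighted geometric fitting cost
#'
#' Sum over samples of the normal-force-normalized weight times the weighted
#' squared ankle position and orientation errors between the rollback
#' reconstruction and the record.
#'
#' @inheritParams rollback_reconstruct
#' @param cfg a [fit_config()].
#' @return scalar cost.
#' @export
fit_cost <- function(foot, rec, cfg = fit_config()) {
  rb <- rollback_reconstruct(foot, rec)
  w <- rec$force_z / max(rec$force_z)
  dr2 <- (rb$ankle_x - rec$ankle_x)^2 + (rb$ankle_z - rec$ankle_z)^2
  da2 <- (rb$alpha - rec$ankle_angle)^2
  sum(w * (cfg$w_r * dr2 + cfg$w_alpha * da2))
}

# reduced parameter vector <-> foot object, with the foot-length constraint
# eliminated by substitution
foot_to_par <- function(foot, cfg) {
  if (inherits(foot, "ellipse_foot"))
    c(cx = foot$r_E[1], cz = foot$r_E[2], theta = foot$theta_E, r_y = foot$r_y)
  else
    c(rad_H = foot$rad_H, rad_F = foot$rad_F, fx = foot$r_F[1],
      fz = foot$r_F[2], hz = foot$r_H[2])
}

par_to_foot <- function(par, type, cfg) {
  if (type == "ellipse") {
    ellipse_foot(r_E = c(par[["cx"]], par[["cz"]]), theta_E = par[["theta"]],
                 r_x = cfg$foot_len / 2, r_y = par[["r_y"]])
  } else {
    hx <- par[["fx"]] + par[["rad_F"]] + par[["rad_H"]] - cfg$foot_len
    double_circle_foot(r_H = c(hx, par[["hz"]]), rad_H = par[["rad_H"]],
                       r_F = c(par[["fx"]], par[["fz"]]), rad_F = par[["rad_F"]])
  }
}

#' Fit foot-model geometry to a stance record
#'
#' Minimizes the CoP-rollback cost ([fit_cost()]) over the reduced parameter
#' vector by a Nelder-Mead simplex search. The foot-length constraint is
#' eliminated by substitution: the ellipse fit has 4 free parameters (centre,
#' orientation, minor semi-axis; `r_x = foot_len/2`), the double-circle fit 5
#' (both radii, forefoot centre, heel-centre height; the heel-centre x
#' follows from the length identity).
#'
#' @param initial initial `foot_params` (must satisfy the invariants; its
#'   length is replaced by the constraint).
#' @param rec a [stance_record()]; segmented internally with
#'   `cfg$fraction`.
#' @param cfg a [fit_config()].
#' @return an object of class `foot_fit`.
#' @export
fit_foot <- function(initial, rec, cfg = fit_config()) {
  type <- if (inherits(initial, "ellipse_foot")) "ellipse" else "double_circle"
  seg <- segment_stance(rec, cfg$fraction)
  par0 <- foot_to_par(initial, cfg)
  obj <- function(p) {
    ft <- try(par_to_foot(p, type, cfg), silent = TRUE)
    if (inherits(ft, "try-error")) return(1e8)
    val <- try(fit_cost(ft, seg, cfg), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e8)
    val
  }
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(reltol = cfg$tol, maxit = cfg$maxit))
  # restart the simplex once from the first optimum (standard practice:
  # a fresh simplex escapes a collapsed one)
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(reltol = cfg$tol, maxit = cfg$maxit))
  if (opt2$value <= opt$value) {
    opt2$counts <- opt$counts + opt2$counts
    opt <- opt2
  }
  converged <- opt$convergence == 0L
  if (!converged)
    warning("simplex search did not converge within ", cfg$maxit,
            " iterations; returning the best point found")
  foot <- par_to_foot(opt$par, type, cfg)
  rb <- rollback_reconstruct(foot, seg)
  pos_err <- sqrt((rb$ankle_x - seg$ankle_x)^2 + (rb$ankle_z - seg$ankle_z)^2)
  ang_err <- abs(rb$alpha - seg$ankle_angle)
  structure(list(foot = foot, initial = initial, record = seg,
                 reconstruction = rb, pos_err = pos_err, ang_err = ang_err,
                 cost = opt$value, initial_cost = obj(par0),
                 converged = converged, evaluations = opt$counts[["function"]],
                 config = cfg, type = type),
            class = "foot_fit")
}

#' Summary statistics of the geometric fit errors
#'
#' Mean, (sample) standard deviation and maximum of the per-sample ankle
#' position error norm (m) and orientation error (rad).
#'
#' @param fit a [fit_foot()] result.
#' @return data frame with rows `position` and `orientation`.
#' @export
error_statistics <- function(fit) {
  data.frame(row.names = c("position", "orientation"),
             mean = c(mean(fit$pos_err), mean(fit$ang_err)),
             sd = c(sd(fit$pos_err), sd(fit$ang_err)),
             max = c(max(fit$pos_err), max(fit$ang_err)))
}

#' @export
print.foot_fit <- function(x, ...) {
  cat(sprintf("foot_fit (%s): cost %.6g after %d evaluations%s\n", x$type,
              x$cost, x$evaluations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$foot)
  invisible(x)
}

#' @export
summary.foot_fit <- function(object, ...) {
  st <- error_statistics(object)
  cat(sprintf("CoP-rollback fit of the %s foot (%d samples)\n", object$type,
              nrow(object$record)))
  print(object$foot)
  cat(sprintf("cost: %.6g (initial %.6g)%s\n", object$cost,
              object$initial_cost,
              if (object$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("ankle position error: %.2f +/- %.2f mm (max %.2f mm)\n",
              1000 * st["position", "mean"], 1000 * st["position", "sd"],
              1000 * st["position", "max"]))
  cat(sprintf("ankle orientation error: %.2f +/- %.2f deg (max %.2f deg)\n",
              180 / pi * st["orientation", "mean"],
              180 / pi * st["orientation", "sd"],
              180 / pi * st["orientation", "max"]))
  invisible(st)
}

#' @export
coef.foot_fit <- function(object, ...) {
  f <- object$foot
  if (object$type == "ellipse")
    c(r_E_x = f$r_E[1], r_E_z = f$r_E[2], theta_E = f$theta_E,
      r_x = f$r_x, r_y = f$r_y)
  else
    c(r_H_x = f$r_H[1], r_H_z = f$r_H[2], rad_H = f$rad_H,
      r_F_x = f$r_F[1], r_F_z = f$r_F[2], rad_F = f$rad_F)
}

#' @export
fitted.foot_fit <- function(object, ...) object$reconstruction

#' @export
residuals.foot_fit <- function(object, ...) {
  data.frame(t = object$record$t, position = object$pos_err,
             orientation = object$ang_err)
}

#' @export
predict.foot_fit <- function(object, newdata = NULL, ...) {
  rec <- newdata %||% object$record
  rollback_reconstruct(object$foot, rec)
}

#' @export
plot.foot_fit <- function(x, ...) {
  rec <- x$record; rb <- x$reconstruction
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
  plot(rec$ankle_x, rec$ankle_z, type = "l", xlab = "x (m)", ylab = "z (m)",
       main = "ankle trajectory", asp = 1, ...)
  lines(rb$ankle_x, rb$ankle_z, col = 2, lty = 2)
  legend("topleft", c("record", "fit"), col = c(1, 2), lty = c(1, 2), bty = "n")
  plot(rec$t, rec$ankle_angle * 180 / pi, type = "l", xlab = "t (s)",
       ylab = "orientation (deg)", main = "ankle orientation")
  lines(rb$t, rb$alpha * 180 / pi, col = 2, lty = 2)
  invisible(x)
}
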