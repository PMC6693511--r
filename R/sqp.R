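# Dense equality-SQP solver used by the multiple-shooting transcription.
#
# The problem is described by three lists of "elements", each a closure
#   list(fun = function(v) numeric, deps = <variable indices>, n = <length>)
# so that constraint Jacobians and objective gradients can be built by
# finite differences touching only the variables an element depends on
# (shooting intervals are local, which keeps the Jacobian cost linear in
# the number of nodes).  Inequalities are kept strictly feasible at the
# solution; violated rows enter the step computation as linearized
# equalities and the merit function penalizes their violation.

sqp_control <- function(max_iter = 150, feas_tol = 1e-6, opt_tol = 1e-5,
                        ineq_tol = 0, fd_eps = 1e-6, verbose = FALSE,
                        levenberg0 = 1e-3, working_set = TRUE, soc = TRUE,
                        rho_cap = Inf) {
  list(max_iter = max_iter, feas_tol = feas_tol, opt_tol = opt_tol,
       ineq_tol = ineq_tol, fd_eps = fd_eps, verbose = verbose,
       levenberg0 = levenberg0, working_set = working_set, soc = soc,
       rho_cap = rho_cap)
}

elem_rows <- function(elems) {
  n <- vapply(elems, `[[`, 0L, "n")
  off <- cumsum(c(0L, n))
  lapply(seq_along(elems), function(i)
    if (n[i] > 0) (off[i] + 1L):off[i + 1L] else integer())
}

eval_elems <- function(elems, v) {
  out <- numeric(sum(vapply(elems, `[[`, 0L, "n")))
  pos <- 0L
  for (el in elems) {
    val <- tryCatch(el$fun(v), error = function(e) NULL)
    if (is.null(val) || anyNA(val) || !all(is.finite(val)))
      return(NULL)
    out[pos + seq_len(el$n)] <- val
    pos <- pos + el$n
  }
  out
}

jac_elems <- function(elems, v, base, rows, nv, eps) {
  J <- matrix(0, length(base), nv)
  for (i in seq_along(elems)) {
    el <- elems[[i]]
    if (el$n == 0L) next
    b <- base[rows[[i]]]
    for (d in el$deps) {
      h <- eps * max(1, abs(v[d]))
      vh <- v; vh[d] <- vh[d] + h
      val <- tryCatch(el$fun(vh), error = function(e) NULL)
      if (is.null(val)) { # fall back to a backward difference
        vh[d] <- v[d] - h
        val <- el$fun(vh)
        J[rows[[i]], d] <- (b - val) / h
      } else {
        J[rows[[i]], d] <- (val - b) / h
      }
    }
  }
  J
}

grad_elems <- function(elems, v, base, nv, eps) {
  g <- numeric(nv)
  for (i in seq_along(elems)) {
    el <- elems[[i]]
    for (d in el$deps) {
      h <- eps * max(1, abs(v[d]))
      vh <- v; vh[d] <- vh[d] + h
      g[d] <- g[d] + (el$fun(vh) - base[i]) / h
    }
  }
  g
}

hessdiag_elems <- function(elems, v, base, nv, lb, ub) {
  H <- numeric(nv)
  h0 <- 1e-3
  for (i in seq_along(elems)) {
    el <- elems[[i]]
    for (d in el$deps) {
      h <- h0 * max(1, abs(v[d]))
      vp <- v; vp[d] <- min(vp[d] + h, ub[d])
      vm <- v; vm[d] <- max(vm[d] - h, lb[d])
      if (vp[d] - vm[d] < 0.5 * h) next
      fp <- tryCatch(el$fun(vp), error = function(e) NA_real_)
      fm <- tryCatch(el$fun(vm), error = function(e) NA_real_)
      if (is.finite(fp) && is.finite(fm)) {
        hh <- (fp - 2 * base[i] + fm) / ((0.5 * (vp[d] - vm[d]))^2)
        if (is.finite(hh)) H[d] <- H[d] + hh
      }
    }
  }
  H
}

sqp_solve <- function(eq_elems, ineq_elems, obj_elems, v0, lb, ub,
                      control = sqp_control()) {
  nv <- length(v0)
  v <- pmin(pmax(v0, lb), ub)
  rows_eq <- elem_rows(eq_elems)
  lev <- control$levenberg0
  trace <- list()
  status <- "max_iter"
  feas_of <- function(ce, ci) max(c(0, abs(ce), -ci - control$ineq_tol))
  fv <- function(v) { # full evaluation; NULL on failure
    ce <- eval_elems(eq_elems, v)
    if (is.null(ce) && length(eq_elems)) return(NULL)
    ci <- eval_elems(ineq_elems, v)
    if (is.null(ci) && length(ineq_elems)) return(NULL)
    fo <- eval_elems(obj_elems, v)
    if (is.null(fo) && length(obj_elems)) return(NULL)
    list(ce = ce %||% numeric(), ci = ci %||% numeric(),
         fo = fo %||% numeric(), f = sum(fo))
  }
  cur <- fv(v)
  if (is.null(cur)) stop("initial point is not evaluable (integrator failure)")
  it <- 0
  stat_norm <- NA_real_
  feas_best <- feas_of(cur$ce, cur$ci)
  best <- list(v = v, cur = cur, feas = feas_best)
  B <- NULL         # damped BFGS approximation of the Lagrangian Hessian
  prev <- NULL      # (v, gL) of the previous iterate for the BFGS update
  for (it in seq_len(control$max_iter)) {
    feas <- feas_of(cur$ce, cur$ci)
    Jeq <- jac_elems(eq_elems, v, cur$ce, rows_eq, nv, control$fd_eps)
    g <- grad_elems(obj_elems, v, cur$fo, nv, control$fd_eps)
    if (is.null(B)) {
      Hd <- hessdiag_elems(obj_elems, v, cur$fo, nv, lb, ub)
      B <- diag(pmin(pmax(Hd, 1e-3), 1e8), nv)
    }
    # violated inequalities enter as linearized equalities
    viol <- which(cur$ci < -control$ineq_tol - control$feas_tol * 0.1)
    A <- Jeq; cvec <- cur$ce
    if (length(viol)) {
      rows_in <- elem_rows(ineq_elems)
      Jin <- jac_elems(ineq_elems, v, cur$ci, rows_in, nv, control$fd_eps)
      A <- rbind(A, Jin[viol, , drop = FALSE])
      cvec <- c(cvec, cur$ci[viol])
    }
    m <- nrow(A)
    # stationarity from least-squares multipliers, projected onto the box
    y_ls <- if (m > 0) {
      yy <- tryCatch(qr.coef(qr(t(A), LAPACK = TRUE), g),
                     error = function(e) rep(0, m))
      yy[is.na(yy)] <- 0
      yy
    } else numeric()
    r <- g - if (m > 0) drop(t(A) %*% y_ls) else 0
    gL <- r
    at_lb <- v <= lb + 1e-12 & r > 0
    at_ub <- v >= ub - 1e-12 & r < 0
    r[at_lb | at_ub] <- 0
    stat_norm <- max(abs(r)) / max(1, max(abs(g)))
    accepted <- FALSE
    if (feas < control$feas_tol && stat_norm < control$opt_tol) {
      status <- "converged"
      accepted <- TRUE
    }
    for (try_lev in 1:6) {
      if (accepted) break
      # working-set treatment of the box: variables at a bound whose step
      # points outside are frozen and the KKT system re-solved without them
      frozen <- rep(FALSE, nv)
      d <- NULL; K <- NULL
      ws_max <- if (isTRUE(control$working_set)) 4 else 1
      for (ws in 1:ws_max) {
        free <- which(!frozen)
        Bf <- B[free, free, drop = FALSE] + diag(lev, length(free))
        Af <- A[, free, drop = FALSE]
        K <- rbind(cbind(Bf, t(Af)), cbind(Af, diag(-1e-10, m)))
        rhs <- c(-g[free], -cvec)
        sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
        if (is.null(sol)) sol <- tryCatch(qr.solve(K, rhs, tol = 1e-14),
                                          error = function(e) NULL)
        if (is.null(sol)) break
        d <- numeric(nv)
        d[free] <- sol[seq_along(free)]
        if (ws == ws_max) break
        hit <- (v <= lb + 1e-12 & d < -1e-14) | (v >= ub - 1e-12 & d > 1e-14)
        hit <- hit & !frozen
        if (!any(hit)) break
        frozen <- frozen | hit
      }
      if (is.null(d)) { lev <- lev * 10; next }
      free <- which(!frozen)
      # acceptance by an infinity-norm merit function (objective plus a
      # multiplier-scaled penalty on the worst violation), with a cap that
      # keeps iterates from wandering far off the constraint manifold
      rho <- min(control$rho_cap,
                 max(10, 2 * if (m > 0) max(abs(y_ls)) else 0))
      feas_cap <- max(2 * feas_best, 1e-3)
      phi0 <- cur$f + rho * feas
      step_ok <- FALSE
      alpha <- 1
      for (ls in 1:14) {
        vt <- pmin(pmax(v + alpha * d, lb), ub)
        cand <- fv(vt)
        if (!is.null(cand)) {
          feas_t <- feas_of(cand$ce, cand$ci)
          phit <- cand$f + rho * feas_t
          if (phit < phi0 - 1e-10 * max(1, abs(phi0)) && feas_t <= feas_cap) {
            v <- vt; cur <- cand; step_ok <- TRUE
            feas_best <- min(feas_best, feas_t)
            break
          }
          if (ls == 1 && isTRUE(control$soc)) {
            # second-order correction: re-evaluate the constraints at the
            # full step and solve for a correction in the same KKT system
            c2 <- c(cand$ce, if (length(viol)) cand$ci[viol] else numeric())
            solc <- tryCatch(solve(K, c(numeric(length(free)), -c2)),
                             error = function(e) NULL)
            if (!is.null(solc)) {
              dc <- numeric(nv); dc[free] <- solc[seq_along(free)]
              vtc <- pmin(pmax(vt + dc, lb), ub)
              cand2 <- fv(vtc)
              if (!is.null(cand2)) {
                feas_t2 <- feas_of(cand2$ce, cand2$ci)
                phit2 <- cand2$f + rho * feas_t2
                if (phit2 < phi0 - 1e-10 * max(1, abs(phi0)) &&
                    feas_t2 <= feas_cap) {
                  v <- vtc; cur <- cand2; step_ok <- TRUE
                  feas_best <- min(feas_best, feas_t2)
                  break
                }
              }
            }
          }
        }
        alpha <- alpha / 2
      }
      if (!step_ok) {
        # restoration: a pure feasibility step (objective-blind Gauss-Newton
        # on the violated constraints); the physics may demand objective
        # growth to close dynamics defects, which the merit search refuses
        solr <- tryCatch(solve(K, c(numeric(length(free)), -cvec)),
                         error = function(e) NULL)
        if (!is.null(solr)) {
          dr <- numeric(nv); dr[free] <- solr[seq_along(free)]
          alpha <- 1
          for (ls in 1:14) {
            vt <- pmin(pmax(v + alpha * dr, lb), ub)
            cand <- fv(vt)
            if (!is.null(cand)) {
              feas_t <- feas_of(cand$ce, cand$ci)
              if (feas_t < feas - max(0.001 * feas, 1e-12)) {
                v <- vt; cur <- cand; step_ok <- TRUE
                feas_best <- min(feas_best, feas_t)
                break
              }
            }
            alpha <- alpha / 2
          }
        }
      }
      if (step_ok) {
        accepted <- TRUE
        lev <- max(lev / 3, 1e-8)
        # damped BFGS update with the step just taken
        if (!is.null(prev)) {
          sv <- v - prev$v
          yv <- gL - prev$gL
          Bs <- drop(B %*% sv)
          sBs <- sum(sv * Bs)
          sy <- sum(sv * yv)
          if (is.finite(sBs) && sBs > 1e-14) {
            if (sy < 0.2 * sBs) {
              th <- 0.8 * sBs / (sBs - sy)
              yv <- th * yv + (1 - th) * Bs
              sy <- sum(sv * yv)
            }
            if (sy > 1e-14)
              B <- B - tcrossprod(Bs) / sBs + tcrossprod(yv) / sy
          }
        }
        prev <- list(v = v, gL = gL)
        break
      }
      lev <- lev * 10
    }
    feas_now <- feas_of(cur$ce, cur$ci)
    if (feas_now < best$feas - 1e-12 ||
        (feas_now <= max(best$feas, control$feas_tol) && cur$f < best$cur$f))
      best <- list(v = v, cur = cur, feas = feas_now)
    trace[[it]] <- c(f = cur$f, feas = feas_now,
                     stat = stat_norm, lev = lev)
    if (control$verbose)
      message(sprintf("it %3d  f %.6e  feas %.3e  stat %.3e  lev %.1e",
                      it, cur$f, trace[[it]]["feas"], stat_norm, lev))
    if (status == "converged") break
    if (!accepted) { status <- "stalled"; break }
  }
  v_last <- v
  if (status != "converged" && best$feas <= feas_of(cur$ce, cur$ci)) {
    v <- best$v; cur <- best$cur   # report the best iterate seen
  }
  feas <- feas_of(cur$ce, cur$ci)
  list(v = v, f = cur$f, ce = cur$ce, ci = cur$ci,
       feasibility = feas, stationarity = stat_norm,
       iterations = it, status = status, v_last = v_last,
       trace = do.call(rbind, trace))
}
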