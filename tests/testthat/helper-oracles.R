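# Independent oracles, deliberately written with a different derivation
# than the package internals: forward kinematics with complex-step
# differentiation gives exact segment velocities, from which the kinetic
# energy, mass matrix (second differences of a quadratic) and bias forces
# (finite-differenced Lagrange equations) follow without any Jacobian
# assembly.

# positions and orientations of the 7 segment COMs; works for complex q
or_kin <- function(body, q) {
  R <- function(th, v) c(cos(th) * v[1] - sin(th) * v[2],
                         sin(th) * v[1] + cos(th) * v[2])
  hip <- q[1:2]
  phi <- c(q[3], q[3] + q[4], q[3] + q[4] + q[5], q[3] + q[4] + q[5] + q[6],
           q[3] + q[7], q[3] + q[7] + q[8], q[3] + q[7] + q[8] + q[9])
  kneeL <- hip + R(phi[2], c(0, -body$len_thigh))
  ankleL <- kneeL + R(phi[3], c(0, -body$len_shank))
  kneeR <- hip + R(phi[5], c(0, -body$len_thigh))
  ankleR <- kneeR + R(phi[6], c(0, -body$len_shank))
  origin <- list(hip, hip, kneeL, ankleL, hip, kneeR, ankleR)
  com <- matrix(0 + 0i, 7, 2)
  for (s in 1:7) com[s, ] <- origin[[s]] + R(phi[s], body$com[s, ])
  list(com = com, phi = phi)
}

# exact kinetic energy via complex-step velocities
or_ke <- function(body, q, qd) {
  eps <- 1e-20
  k <- or_kin(body, q + 1i * eps * qd)
  v <- Im(k$com) / eps
  w <- Im(k$phi) / eps
  sum(0.5 * body$mass * (v[, 1]^2 + v[, 2]^2)) + sum(0.5 * body$inertia * w^2)
}

or_pe <- function(body, q) {
  k <- or_kin(body, q)
  sum(body$mass * body$g * Re(k$com[, 2]))
}

# mass matrix: exact second differences of the (quadratic) kinetic energy
or_mass_matrix <- function(body, q) {
  M <- matrix(0, 9, 9)
  e <- diag(9)
  ke0 <- or_ke(body, q, rep(0, 9))
  kei <- vapply(1:9, function(i) or_ke(body, q, e[i, ]), 0)
  for (i in 1:9) {
    M[i, i] <- 2 * kei[i]
    for (j in seq_len(i - 1)) {
      kij <- or_ke(body, q, e[i, ] + e[j, ])
      M[i, j] <- M[j, i] <- kij - kei[i] - kei[j] + ke0
    }
  }
  M
}

# bias forces from the Lagrange equations with q(t) = q + t*qd, qddot = 0
or_bias <- function(body, q, qd) {
  h <- 1
  pk <- function(qq) vapply(1:9, function(k) {
    e <- numeric(9); e[k] <- h
    (or_ke(body, qq, qd + e) - or_ke(body, qq, qd - e)) / (2 * h)
  }, 0)
  eps <- 1e-6
  dpdt <- (pk(q + eps * qd) - pk(q - eps * qd)) / (2 * eps)
  hq <- 1e-6
  dTdq <- vapply(1:9, function(k) {
    e <- numeric(9); e[k] <- hq
    (or_ke(body, q + e, qd) - or_ke(body, q - e, qd)) / (2 * hq)
  }, 0)
  dVdq <- vapply(1:9, function(k) {
    e <- numeric(9); e[k] <- hq
    (or_pe(body, q + e) - or_pe(body, q - e)) / (2 * hq)
  }, 0)
  dpdt - dTdq + dVdq
}

# dense KKT oracle for the constrained forward dynamics
or_kkt <- function(model, state, tau, cs, gains = c(100, 20)) {
  M <- mass_matrix(model, state$q)
  cv <- bias_forces(model, state)
  G <- cs$G
  m <- nrow(G)
  rhs_c <- -cs$gamma - gains[2] * cs$velocity
  rhs_c[cs$kind == "contact"] <- rhs_c[cs$kind == "contact"] -
    gains[1] * cs$gap[cs$kind == "contact"]
  K <- rbind(cbind(M, -t(G)), cbind(G, matrix(0, m, m)))
  sol <- solve(K, c(tau - cv, rhs_c))
  list(qdd = sol[1:9], lambda = sol[10:(9 + m)])
}

# Gauss-principle oracle for the plastic impact
or_impact <- function(model, state, cs) {
  M <- mass_matrix(model, state$q)
  G <- cs$G
  Minv <- solve(M)
  S <- G %*% Minv %*% t(G)
  lam <- solve(S, G %*% state$qdot)
  as.numeric(state$qdot - Minv %*% t(G) %*% lam)
}

# densely sampled lowest boundary point of an ellipse in world orientation
# psi (polar boundary form, brute force over the angle grid)
or_ellipse_lowest_z <- function(r_x, r_y, psi, centre_z, n = 1e6) {
  phi <- seq(-pi, pi, length.out = n)
  rs <- r_x * r_y / sqrt((r_y * cos(phi))^2 + (r_x * sin(phi))^2)
  centre_z + min(rs * sin(phi + psi))
}
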