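test_that("mass matrix is symmetric positive definite and translation-invariant", {
  body <- tm_body()
  set.seed(1)
  for (i in 1:25) {
    q <- rand_q()
    M <- mass_matrix(body, q)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  # pure forward translation at 1 m/s carries KE = m_total/2 at any posture
  q <- rand_q()
  M <- mass_matrix(body, q)
  expect_equal(M[1, 1], sum(body$mass), tolerance = 1e-12)
  expect_equal(M[2, 2], sum(body$mass), tolerance = 1e-12)
  expect_error(mass_matrix(body, c(NA, rand_q()[-1])), "non-finite")
})

test_that("mass matrix matches the energy-based oracle", {
  body <- tm_body()
  set.seed(2)
  for (i in 1:10) {
    q <- rand_q()
    expect_equal(mass_matrix(body, q), or_mass_matrix(body, q),
                 tolerance = 1e-9)
  }
})

test_that("bias forces: gravity resultant and Lagrangian oracle", {
  body <- tm_body()
  # at rest the bias reduces to the generalized gravity load
  cv <- bias_forces(body, model_state(rand_q(), rep(0, 9)))
  expect_equal(cv[2], sum(body$mass) * body$g, tolerance = 1e-10)
  # gravity off, at rest: identically zero
  b0 <- body_parameters(body$mass, body$inertia, body$len_thigh,
                        body$len_shank, body$com, g = 0)
  expect_equal(bias_forces(b0, model_state(rand_q(), rep(0, 9))), rep(0, 9),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    st <- rand_state()
    expect_equal(bias_forces(body, st), or_bias(body, st$q, st$qdot),
                 tolerance = 1e-6)
  }
})

test_that("unconstrained dynamics reduce to M^{-1}(tau - c); free fall", {
  m <- tm_ellipse()
  st <- rand_state()
  tau <- c(0, 0, 0, runif(6, -20, 20))
  fd <- constrained_forward_dynamics(m, st, tau = tau)
  expect_equal(fd$qdd,
               as.numeric(solve(mass_matrix(m, st$q), tau - bias_forces(m, st))),
               tolerance = 1e-10)
  # free fall of the base
  fd0 <- constrained_forward_dynamics(m, model_state(rand_q(), rep(0, 9)),
                                      tau = rep(0, 9))
  expect_lt(abs(fd0$qdd[2] + 9.81), 1e-9)
  expect_error(constrained_forward_dynamics(m, st, tau = c(1, rep(0, 8))),
               "leading three")
})

test_that("statics: a torque-balanced model standing on both feet carries its weight", {
  # circular foot with the contact directly below the ankle: at the neutral
  # posture every gravity torque vanishes, so the single contact must carry
  # exactly the weight with zero acceleration (an unstable equilibrium, but
  # an equilibrium)
  m <- gait_model(tm_balanced_body(),
                  ellipse_foot(c(0, -0.08), 0, 0.04, 0.04))
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")[1]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  st <- model_state(c(0, z0, rep(0, 7)))
  fd <- constrained_forward_dynamics(m, st,
                                     modes = c("ellipse_roll", "airborne"))
  lamN <- fd$lambda[fd$constraints$kind == "contact"]
  expect_equal(sum(lamN), sum(m$body$mass) * m$body$g, tolerance = 1e-6)
  expect_equal(max(abs(fd$qdd)), 0, tolerance = 1e-6)
  # perfectly symmetric double stance duplicates constraint directions and
  # is rejected as rank deficient
  expect_error(constrained_forward_dynamics(m, st,
                 modes = c("ellipse_roll", "ellipse_roll")),
               "rank-deficient")
})

test_that("constrained dynamics agree with an independent dense KKT solve", {
  m <- tm_ellipse()
  set.seed(4)
  for (i in 1:20) {
    st <- rand_state()
    cs <- constraint_set(m, st, c("ellipse_roll", "airborne"))
    fd <- constrained_forward_dynamics(m, st, tau = rep(0, 9),
                                       modes = c("ellipse_roll", "airborne"))
    ref <- or_kkt(m, st, rep(0, 9), cs)
    expect_equal(fd$qdd, ref$qdd, tolerance = 1e-10)
    expect_equal(as.numeric(fd$lambda), as.numeric(ref$lambda),
                 tolerance = 1e-8)
  }
})

test_that("plastic impact: no-op on the manifold, dissipative, Gauss-principle oracle, idempotent", {
  m <- tm_ellipse()
  set.seed(5)
  for (i in 1:20) {
    st <- rand_state()
    im <- plastic_impact(m, st, c("ellipse_roll", "airborne"))
    # post-impact constraint velocities vanish
    cs2 <- constraint_set(m, im$state, c("ellipse_roll", "airborne"))
    expect_lt(max(abs(cs2$velocity)), 1e-9)
    # dissipativity and the momentum-balance identity
    expect_lte(im$dKE, 1e-10)
    cs <- constraint_set(m, st, c("ellipse_roll", "airborne"))
    M <- mass_matrix(m, st$q)
    expect_equal(as.numeric(M %*% (im$qdot_post - st$qdot)),
                 as.numeric(t(cs$G) %*% im$impulses), tolerance = 1e-8)
    # Gauss-principle oracle
    expect_equal(im$qdot_post, or_impact(m, st, cs), tolerance = 1e-10)
    # idempotence and fixed point of an already-consistent state
    im2 <- plastic_impact(m, im$state, c("ellipse_roll", "airborne"))
    expect_equal(im2$qdot_post, im$qdot_post, tolerance = 1e-10)
    expect_lt(max(abs(im2$impulses)), 1e-8)
  }
})

test_that("total energy at rest is potential only and is conserved in free fall", {
  m <- tm_ellipse()
  q <- rand_q()
  e <- total_energy(m, model_state(q))
  expect_equal(attr(e, "kinetic"), 0)
  expect_equal(as.numeric(e), attr(e, "potential"))
  x0 <- c(q, c(0.3, 0, 0.1, rep(0, 6)), rep(0, 12))
  out <- integrate_phase(m, x0, c("airborne", "airborne"), 0.4)
  e1 <- total_energy(m, model_state(out$x_end[1:9], out$x_end[10:18]))
  expect_equal(as.numeric(e1), as.numeric(total_energy(m, model_state(x0[1:9], x0[10:18]))),
               tolerance = 1e-7)
})

test_that("rolling contact is workless: energy drift < 0.1% over 1 s of passive rocking", {
  m <- tm_ellipse()   # passive: no MTGs, no damping
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")[1]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  x0 <- c(c(0, z0, rep(0, 7)), rep(0, 9), rep(0, 12))
  x0[12] <- 0.3   # pitch rate starts the rock
  im <- plastic_impact(m, model_state(x0[1:9], x0[10:18]),
                       c("ellipse_roll", "airborne"))
  x0[10:18] <- im$qdot_post
  e0 <- as.numeric(total_energy(m, model_state(x0[1:9], x0[10:18])))
  ts <- seq(0, 1, length.out = 21)
  out <- integrate_phase(m, x0, c("ellipse_roll", "airborne"), 1, record = ts)
  for (i in seq_along(ts)) {
    st <- model_state(out$X[1:9, i], out$X[10:18, i])
    expect_lt(abs(as.numeric(total_energy(m, st)) - e0) / abs(e0), 1e-3)
    # rolling without slipping: contact material speed stays tiny
    cs <- constraint_set(m, st, c("ellipse_roll", "airborne"))
    expect_lt(max(abs(cs$velocity)), 1e-6)
    # workless constraints: qdot' G' lambda ~ 0
    fd <- constrained_forward_dynamics(m, st, tau = rep(0, 9),
                                       modes = c("ellipse_roll", "airborne"))
    expect_lt(abs(sum(st$qdot * as.numeric(t(cs$G) %*% fd$lambda))), 0.05)
  }
})

test_that("mirror_map is an involution fixing symmetric states", {
  x <- c(rand_q(), rand_qd(), runif(12))
  expect_equal(mirror_map(mirror_map(x)), x)
  xs <- x
  xs[7:9] <- xs[4:6]; xs[16:18] <- xs[13:15]; xs[25:30] <- xs[19:24]
  expect_equal(mirror_map(xs), xs)
})
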