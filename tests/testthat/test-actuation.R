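test_that("MTG torque: normalization, zero activation, monotone force-velocity", {
  p <- mtg_params(tau_o = 120, omega_max = 30, sign = 1, theta_opt = 0.2,
                  width = 1.5)
  expect_equal(mtg_torque(p, 0, 0.7, 3), 0)
  expect_equal(mtg_torque(p, 1, 0.2, 0), 120)      # optimal angle, isometric
  pm <- mtg_params(100, 25, -1, -0.1, 2)
  expect_equal(mtg_torque(pm, 1, -0.1, 0), -100)
  # |torque| non-increasing with shortening speed at fixed activation/angle
  om <- seq(0, 35, length.out = 200)
  tq <- mtg_torque(p, 0.7, 0.2, om)
  expect_true(all(diff(tq) <= 1e-12))
  expect_equal(tq[length(tq)], 0)                  # beyond omega_max
  # eccentric side saturates at the configured plateau
  expect_equal(mtg_torque(p, 1, 0.2, -60), 120 * 1.35)
  expect_error(mtg_torque(p, 1.2, 0, 0), "\\[0, 1\\]")
})

test_that("torque curves are C2 across their segment joins", {
  p <- mtg_params(100, 30, 1, 0, 1.2)
  f <- function(th) mtg_torque(p, 1, th, 0)
  g <- function(om) mtg_torque(p, 1, 0, om)
  h <- 1e-4
  for (x0 in c(-1.2, 0, 1.2)) {      # bell edges and peak
    d2 <- function(ff, x) (ff(x + h) - 2 * ff(x) + ff(x - h)) / h^2
    expect_lt(abs(d2(f, x0 + h) - d2(f, x0 - h)), 1e-2 * 100 / 1.2^2 + 1e-6)
  }
  for (w0 in c(-30, 0, 30)) {        # velocity-curve joins
    d2 <- function(ff, x) (ff(x + h) - 2 * ff(x) + ff(x - h)) / h^2
    expect_lt(abs(d2(g, w0 + h) - d2(g, w0 - h)), 1e-2 * 100 / 30^2 + 1e-4)
  }
})

test_that("activation dynamics: equilibrium, rate, closed form, bounds", {
  expect_equal(activation_rate(0.5, 0.5), 0)
  expect_equal(activation_rate(1, 0), 1 / 0.0325, tolerance = 1e-12)
  # numeric integration matches the closed-form first-order lag to 1e-8
  a0 <- 0.12; e <- 0.9
  a <- a0; dt <- 1e-4
  for (i in 1:5000) {
    k1 <- activation_rate(e, a)
    k2 <- activation_rate(e, a + dt / 2 * k1)
    k3 <- activation_rate(e, a + dt / 2 * k2)
    k4 <- activation_rate(e, a + dt * k3)
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(a, e + (a0 - e) * exp(-0.5 / 0.0325), tolerance = 1e-8)
  # trajectories driven by admissible excitations stay inside [0, 1]
  set.seed(21)
  for (rep in 1:5) {
    a <- runif(1); amin <- a; amax <- a
    for (i in 1:2000) {
      ee <- runif(1)
      a <- a + 1e-3 * activation_rate(ee, a)
      amin <- min(amin, a); amax <- max(amax, a)
    }
    expect_gte(amin, -1e-9); expect_lte(amax, 1 + 1e-9)
  }
  # the switched variant uses the fast constant when exciting
  expect_gt(activation_rate(1, 0, variant = "switched"),
            activation_rate(1, 0, variant = "mean"))
})

test_that("strength-scaled damping: identity, homogeneity, defaults in band", {
  fl <- mtg_params(100, 10, 1); ex <- mtg_params(100, 10, -1)
  j <- joint_actuator(fl, ex, eta = 2)
  expect_equal(j$beta, 2 * 200 / 20)
  expect_equal(joint_damping(j), j$beta)
  expect_equal(joint_actuator(fl, ex, eta = 0)$beta, 0)
  # doubling strengths doubles beta; doubling speeds halves it
  j2 <- joint_actuator(mtg_params(200, 10, 1), mtg_params(200, 10, -1), 2)
  expect_equal(j2$beta, 2 * j$beta)
  j3 <- joint_actuator(mtg_params(100, 20, 1), mtg_params(100, 20, -1), 2)
  expect_equal(j3$beta, j$beta / 2)
  expect_error(joint_actuator(fl, mtg_params(50, 10, 1)), "opposite")
  # every configured joint satisfies the identity exactly and lies in the
  # 2.7-7.3 N m s/rad band
  acts <- default_actuators()
  for (ja in acts$joints) {
    expect_equal(ja$beta,
                 acts$eta * (ja$flexor$tau_o + ja$extensor$tau_o) /
                   (ja$flexor$omega_max + ja$extensor$omega_max))
    expect_gte(ja$beta, 2.7); expect_lte(ja$beta, 7.3)
  }
})

test_that("net joint torque: antagonist cancellation and damping decay", {
  fl <- mtg_params(100, 20, 1, theta_opt = 0.1, width = 2)
  ex <- mtg_params(100, 20, -1, theta_opt = 0.1, width = 2)
  j <- joint_actuator(fl, ex, eta = 2)
  expect_equal(net_joint_torque(j, 0, 0, 0.3, 0), 0)
  # equal co-activation at the shared optimal angle, isometric: cancels
  expect_equal(net_joint_torque(j, 0.6, 0.6, 0.1, 0), 0)
  # passive pendulum with only (light) damping: the amplitude decay rate
  # matches the linearized damped oscillator's beta/(2 I) to 1%
  jl <- joint_actuator(mtg_params(4, 40, 1), mtg_params(4, 40, -1), eta = 2)
  I <- 0.5; mgl <- 6; beta <- jl$beta
  th <- 0.1; w <- 0; dt <- 1e-4
  ths <- numeric(50000)
  for (i in 1:50000) {
    acc <- (-mgl * th + net_joint_torque(jl, 0, 0, th, w)) / I
    w1 <- w + dt * acc
    th <- th + dt * (w + w1) / 2
    w <- w1
    ths[i] <- th
  }
  # successive swing peaks decay at the linearized rate beta / (2 I)
  pk <- which(diff(sign(diff(abs(ths)))) == -2) + 1
  pkt <- pk * dt; pkv <- abs(ths[pk])
  expect_true(all(diff(pkv) < 0))     # monotone amplitude decay
  rate <- -unname(coef(lm(log(pkv) ~ pkt))[2])
  expect_equal(rate, beta / (2 * I), tolerance = 0.01)
})

test_that("generalized forces place zero load on the base coordinates", {
  m <- tm_ellipse(actuated = TRUE)
  set.seed(22)
  st <- rand_state()
  a <- runif(12)
  tau <- generalized_forces(m, st, a)
  expect_equal(tau[1:3], rep(0, 3))
  # consistency with the joint-level composition
  acts <- m$actuators$joints
  for (j in 1:6) {
    expect_equal(tau[3 + j],
                 net_joint_torque(acts[[j]], a[2 * j - 1], a[2 * j],
                                  st$q[3 + j], st$qdot[3 + j]),
                 tolerance = 1e-12)
  }
})
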