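test_that("ellipse lowest point: circle symmetry and axis-aligned cases", {
  r <- 0.07
  circ <- ellipse_foot(c(0, 0), 0, r, r)
  for (a in c(-1.2, -0.3, 0, 0.4, 1.5)) {
    lp <- ellipse_lowest_point(circ, ankle_pose(c(0.2, 0.3), a))
    expect_equal(lp$point, c(0.2, 0.3 - r), tolerance = 1e-12)
  }
  ell <- ellipse_foot(c(0, 0), 0, 0.1525, 0.0403)
  lp <- ellipse_lowest_point(ell, ankle_pose(c(0, 0.2), 0))
  expect_equal(lp$point, c(0, 0.2 - 0.0403), tolerance = 1e-12)
})

test_that("ellipse lowest point beats dense boundary sampling", {
  set.seed(11)
  f <- default_foot("ellipse")
  for (i in 1:40) {
    pose <- ankle_pose(c(runif(1, -1, 1), runif(1, 0.05, 0.3)),
                       runif(1, -2.5, 2.5))
    lp <- ellipse_lowest_point(f, pose)
    centre <- pose$r_A + rigidfoot:::rot2v(pose$alpha_A, f$r_E)
    zmin <- or_ellipse_lowest_z(f$r_x, f$r_y, pose$alpha_A + f$theta_E,
                                centre[2], n = 2e5)
    expect_lt(abs(lp$height - zmin), 1e-8)
  }
})

test_that("ellipse constraint rows: stationary and translating cases", {
  m <- tm_ellipse()
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")[1]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  st <- model_state(c(0, z0, rep(0, 7)))
  cs <- ellipse_constraints(m, st, "left")
  expect_equal(nrow(cs$G), 2L)
  expect_equal(cs$velocity, c(0, 0), tolerance = 1e-12)
  expect_equal(cs$gap[cs$kind == "contact"], 0, tolerance = 1e-10)
  # foot translating straight up at 1 m/s
  st2 <- model_state(st$q, c(0, 1, rep(0, 7)))
  cs2 <- ellipse_constraints(m, st2, "left")
  expect_equal(cs2$velocity[cs2$kind == "contact"], 1, tolerance = 1e-12)
  expect_equal(cs2$velocity[cs2$kind == "rolling"], 0, tolerance = 1e-12)
})

test_that("constraint rows are the gradient of the material-point velocity", {
  # residual = G qdot must match finite differences of the contact material
  # point's world position along the flow for every generalized velocity
  m <- tm_ellipse()
  set.seed(12)
  for (i in 1:8) {
    st <- rand_state()
    cs <- constraint_set(m, st, c("ellipse_roll", "airborne"))
    p0 <- cs$points[1, ]
    # material point: fixed location in the foot frame
    q <- st$q
    afoot <- q[3] + q[4] + q[5] + q[6]
    ank <- rigidfoot:::ankle_position(m, q, "left")
    local <- rigidfoot:::rot2v(-afoot, p0 - ank)
    h <- 1e-7
    for (j in 1:9) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      pw <- function(qq) {
        rigidfoot:::ankle_position(m, qq, "left") +
          rigidfoot:::rot2v(qq[3] + qq[4] + qq[5] + qq[6], local)
      }
      dpdqj <- (pw(qp) - pw(qm)) / (2 * h)
      expect_equal(cs$G[1, j], dpdqj[2], tolerance = 1e-6)  # contact row: e_Z
      expect_equal(cs$G[2, j], dpdqj[1], tolerance = 1e-6)  # rolling row: e_X
    }
  }
})

test_that("circle constraints: row counts, rank, stationary residuals", {
  m <- tm_dc()
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")["heel"]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  st <- model_state(c(0, z0, rep(0, 7)))
  cs <- circle_constraints(m, st, "heel_roll", "left")
  expect_equal(nrow(cs$G), 2L)
  expect_equal(cs$velocity, c(0, 0), tolerance = 1e-12)
  # dual-contact mode: exactly 3 rows, full rank
  af <- rigidfoot:::dc_flat_angle(m$foot)
  qf <- c(0, 0.9, 0, 0, 0, af, 0, 0, 0)
  ff <- function(z) { qf[2] <- z; contact_gap(m, model_state(qf), "left")["heel"] }
  qf[2] <- uniroot(ff, c(0.7, 1.1), tol = 1e-14)$root
  csd <- circle_constraints(m, model_state(qf), "heel_roll_forefoot_touch", "left")
  expect_equal(nrow(csd$G), 3L)
  expect_equal(qr(csd$G)$rank, 3L)
  expect_lt(max(abs(csd$gap), na.rm = TRUE), 1e-6)
  expect_error(circle_constraints(m, st, "ellipse_roll", "left"),
               "not a circle-contact mode")
  expect_equal(nrow(circle_constraints(m, st, "airborne", "left")$G), 0L)
})

test_that("a single circle in rolling contact keeps its material point still", {
  m <- tm_dc()
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")["heel"]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  x0 <- c(c(0, z0, rep(0, 7)), rep(0, 9), rep(0, 12))
  x0[12] <- 0.4
  im <- plastic_impact(m, model_state(x0[1:9], x0[10:18]), c("heel_roll", "airborne"))
  x0[10:18] <- im$qdot_post
  ts <- seq(0, 0.5, length.out = 26)
  out <- integrate_phase(m, x0, c("heel_roll", "airborne"), 0.5, record = ts)
  for (i in seq_along(ts)) {
    st <- model_state(out$X[1:9, i], out$X[10:18, i])
    cs <- constraint_set(m, st, c("heel_roll", "airborne"))
    expect_lt(max(abs(cs$velocity)), 1e-6)
  }
})

test_that("contact gaps: circle at height r, ellipse consistency, pose interface", {
  m <- tm_dc()
  # heel circle centre exactly at its radius above ground: gap 0
  pose <- ankle_pose(c(0, 0) - rigidfoot:::rot2v(0.1, m$foot$r_H) +
                       c(0, m$foot$rad_H), 0.1)
  g <- contact_gap(m, pose = pose, foot = m$foot)
  expect_equal(unname(g["heel"]), 0, tolerance = 1e-12)
  me <- tm_ellipse()
  st <- rand_state()
  ge <- contact_gap(me, st, "left")
  ank <- rigidfoot:::ankle_position(me, st$q, "left")
  al <- rigidfoot:::foot_alpha(st$q, "left")
  lp <- ellipse_lowest_point(me$foot, ankle_pose(ank, al))
  expect_equal(unname(ge["ellipse"]), lp$height, tolerance = 1e-12)
})

test_that("touchdown located by the integrator matches the gap zero crossing", {
  m <- tm_ellipse()
  # drop the model from slightly above the ground and find touchdown
  f <- function(z) contact_gap(m, model_state(c(0, z, rep(0, 7))), "left")[1]
  z0 <- uniroot(f, c(0.8, 1.1), tol = 1e-14)$root
  x0 <- c(c(0, z0 + 0.01, rep(0, 7)), rep(0, 18 + 3))
  ts <- seq(0, 0.2, length.out = 401)
  out <- integrate_phase(m, x0, c("airborne", "airborne"), 0.2, record = ts)
  gaps <- vapply(seq_along(ts), function(i)
    contact_gap(m, model_state(out$X[1:9, i]), "left")[1], 0)
  i0 <- which(gaps <= 0)[1]
  # free fall: gap(t) = 0.01 - g t^2 / 2 in closed form
  t_true <- sqrt(2 * 0.01 / 9.81)
  expect_lt(abs(ts[i0] - t_true), 1e-3)
  # refine by bisection to the stated event accuracy
  tl <- ts[i0 - 1]; th <- ts[i0]
  for (k in 1:40) {
    tm <- (tl + th) / 2
    om <- integrate_phase(m, x0, c("airborne", "airborne"), tm)
    if (contact_gap(m, model_state(om$x_end[1:9]), "left")[1] > 0) tl <- tm else th <- tm
  }
  expect_lt(abs((tl + th) / 2 - t_true), 1e-6)
})

test_that("CoP and ground force recovery from multipliers", {
  m <- tm_ellipse()
  # single contact: the CoP is that contact point and forces map through
  st <- rand_state()
  cs <- constraint_set(m, st, c("ellipse_roll", "airborne"))
  out <- cop_and_ground_force(cs, c(100, 10))
  expect_equal(out$f_P, c(10, 100))
  expect_equal(out$r_P[1], cs$points[1, 1])
  # all normal forces non-positive: undefined CoP
  expect_error(cop_and_ground_force(cs, c(-5, 3)), "CoP undefined")
  expect_error(cop_and_ground_force(cs, c(1, 2, 3)), "does not match")
})

test_that("two equal normal forces place the CoP at the midpoint; wrench equivalence", {
  m <- tm_ellipse()
  set.seed(13)
  for (i in 1:20) {
    # a double-stance state projected onto the ground
    x <- c(rand_q(), rep(0, 9), rep(0, 12))
    x <- project_state(m, x, c("ellipse_roll", "ellipse_roll"))
    st <- model_state(x[1:9], x[10:18])
    cs <- constraint_set(m, st, c("ellipse_roll", "ellipse_roll"))
    lam <- c(80, 5, 80, -7)
    out <- cop_and_ground_force(cs, lam)
    expect_equal(out$r_P[1], mean(cs$points[cs$kind == "contact", 1]),
                 tolerance = 1e-10)
    # net wrench about the origin matches t(G) lambda's base components
    Q <- as.numeric(t(cs$G) %*% lam)
    expect_equal(out$f_P, Q[1:2], tolerance = 1e-9)
    torque_origin <- Q[3] + st$q[1] * Q[2] - st$q[2] * Q[1]
    expect_equal(out$r_P[1] * out$f_P[2], torque_origin, tolerance = 1e-6)
  }
})

test_that("ellipse with equal semi-axes behaves as a circle throughout", {
  r <- 0.05
  body <- tm_body()
  mc <- gait_model(body, ellipse_foot(c(0.02, -0.07), 0.3, r, r))
  set.seed(14)
  for (i in 1:10) {
    st <- rand_state()
    cs <- constraint_set(mc, st, c("ellipse_roll", "airborne"))
    # contact point must sit exactly r below the circle centre
    ank <- rigidfoot:::ankle_position(mc, st$q, "left")
    ctr <- ank + rigidfoot:::rot2v(rigidfoot:::foot_alpha(st$q, "left"),
                                   c(0.02, -0.07))
    expect_equal(cs$points[1, ], ctr - c(0, r), tolerance = 1e-10)
  }
})

test_that("CoP advances monotonically while the foot rolls forward", {
  g <- generate_stance_record(stance_generator_config(default_foot("ellipse")))
  expect_true(all(diff(g$clean$cop_x) >= -1e-12))
  g2 <- generate_stance_record(stance_generator_config(default_foot("double_circle")))
  expect_true(all(diff(g2$clean$cop_x) >= -1e-12))
})
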