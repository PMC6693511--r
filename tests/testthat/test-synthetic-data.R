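test_that("double-hump force: configured peaks, zero endpoints, friction bound, C2", {
  cfg <- stance_generator_config(default_foot("ellipse"))
  T <- cfg$duration
  f <- double_hump_force(c(0, cfg$t_frac1 * T, cfg$t_frac2 * T, T), cfg)
  expect_equal(unname(f[1, "force_z"]), 0)
  expect_equal(unname(f[4, "force_z"]), 0)
  # at the first hump's centre the second hump contributes nothing (supports
  # are disjoint around the centres), so the peak magnitude is recovered
  expect_equal(unname(f[2, "force_z"]),
               cfg$peak1 + cfg$peak2 *
                 max(0, 1 - ((cfg$t_frac1 - cfg$t_frac2) / cfg$w_frac)^2)^3)
  tt <- seq(0, T, length.out = 2001)
  ff <- double_hump_force(tt, cfg)
  expect_true(all(ff[, "force_z"] >= 0))
  expect_true(all(abs(ff[, "force_x"]) <= 0.8 * ff[, "force_z"] + 1e-12))
  # numerical second derivative has no jumps at the bump joins
  h <- tt[2] - tt[1]
  d2 <- diff(ff[, "force_z"], differences = 2) / h^2
  expect_lt(max(abs(diff(d2))), max(abs(d2)) * 0.05 + 1e-6)
})

test_that("stance generation is seed-reproducible with shared noise-free channels", {
  cfg1 <- stance_generator_config(default_foot("ellipse"), sigma_pos = 1e-3,
                                  sigma_ang = 1e-3, seed = 42)
  g1 <- generate_stance_record(cfg1)
  g2 <- generate_stance_record(cfg1)
  expect_identical(g1$record, g2$record)           # same seed, same bytes
  cfg2 <- stance_generator_config(default_foot("ellipse"), sigma_pos = 1e-3,
                                  sigma_ang = 1e-3, seed = 43)
  g3 <- generate_stance_record(cfg2)
  expect_false(identical(g1$record$cop_x, g3$record$cop_x))
  expect_identical(g1$clean, g3$clean)             # noise-free channels agree
  expect_false(identical(g1$record$cop_x, g1$clean$cop_x))
})

test_that("reference gait rollout: exact node defects and event boundaries", {
  skip_if_not(file.exists(test_path("helper-ocp.R")))
  m <- tm_ellipse(actuated = TRUE)
  res <- study_reference()          # cached designer + generator run
  traj <- res$trajectory
  expect_length(traj$phases, 2L)
  expect_length(traj$impacts, 2L)
  # shooting defects vanish under the emitted discretization
  for (ph in traj$phases) {
    n <- ncol(ph$X)
    h <- ph$duration / (n - 1)
    for (k in 1:(n - 1)) {
      out <- integrate_phase(m, ph$X[, k], ph$modes, h,
                             cbind(ph$U[, k], ph$U[, k + 1]), c(0, h),
                             fixed_steps = 8)
      expect_lt(max(abs(out$x_end - ph$X[, k + 1])), 1e-12)
    }
  }
  # touchdown boundary: the swing-foot gap closes exactly at the final node
  xe <- traj$phases[[2]]$X[, ncol(traj$phases[[2]]$X)]
  expect_lt(abs(contact_gap(m, model_state(xe[1:9]), "right")[["ellipse"]]),
            1e-7)
  # normal impulses: the landing foot takes a solidly positive impulse; the
  # trailing rolling foot can carry a tiny negative one (the bilateral
  # rolling constraint holds it through the touchdown), bounded at the
  # tens-of-mN s artifact scale
  expect_gt(max(traj$impacts[[1]]$impulses[c(1, 3)]), 0.5)
  expect_gte(min(traj$impacts[[1]]$impulses[c(1, 3)]), -0.05)
})

test_that("ground impulse balances gravity impulse over the rollout", {
  m <- tm_ellipse(actuated = TRUE)
  res <- study_reference()
  traj <- res$trajectory
  W <- sum(m$body$mass) * m$body$g
  # quadrature of the vertical ground force over both phases + impulses
  imp <- 0
  for (ph in traj$phases) {
    n <- ncol(ph$X)
    h <- ph$duration / (n - 1)
    fz <- vapply(seq_len(n), function(k)
      rigidfoot:::node_dynamics(m, ph$X[, k], ph$modes)$fz, 0)
    imp <- imp + sum(c(0.5, rep(1, n - 2), 0.5) * fz) * h
  }
  imp <- imp + sum(traj$impacts[[1]]$impulses[c(1, 3)])
  T <- sum(vapply(traj$phases, `[[`, 0, "duration"))
  # momentum balance up to the net vertical velocity change of the step
  x0 <- traj$phases[[1]]$X[, 1]
  xe <- traj$phases[[2]]$X[, ncol(traj$phases[[2]]$X)]
  pz <- function(x) {
    st <- model_state(x[1:9], x[10:18])
    # vertical momentum: d(KE)/d(base z rate)
    as.numeric(mass_matrix(m, x[1:9])[2, ] %*% x[10:18])
  }
  expect_equal(imp - W * T, pz(xe) - pz(x0), tolerance = 0.01 * W * T)
})
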