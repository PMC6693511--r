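test_that("stance segmentation keeps exactly the loaded contiguous block", {
  g <- generate_stance_record(stance_generator_config(default_foot("ellipse")))
  rec <- g$clean
  seg <- segment_stance(rec, 0.05)
  thr <- 0.05 * max(rec$force_z)
  expect_identical(nrow(seg), sum(rec$force_z > thr))   # brute-force count
  expect_true(all(seg$force_z > thr))
  # everything above threshold: unchanged
  rec2 <- rec; rec2$force_z <- rec2$force_z + max(rec$force_z)
  expect_identical(nrow(segment_stance(rec2, 0.05)), nrow(rec2))
  # two loaded episodes are rejected
  rec3 <- rec
  mid <- seq(floor(nrow(rec3) / 2) - 2, floor(nrow(rec3) / 2) + 2)
  rec3$force_z[mid] <- 0
  expect_error(segment_stance(rec3, 0.05), "contiguous")
  expect_error(segment_stance(rec, 0.99999), NA)
})

test_that("rollback: circle rolling gives orientation change arc/r exactly", {
  r <- 0.06
  foot <- ellipse_foot(c(0, -0.02), 0, r, r)
  n <- 21
  alpha <- seq(0.3, -0.3, length.out = n)
  cop <- r * (alpha[1] - alpha)          # arc length of a circle
  ank <- t(vapply(seq_len(n), function(i)
    rigidfoot:::ankle_from_contact(foot, alpha[i], cop[i]), c(0, 0)))
  rec <- stance_record(t = seq(0, 1, length.out = n), cop_x = cop,
                       force_x = rep(0, n), force_z = rep(100, n),
                       ankle_x = ank[, 1], ankle_z = ank[, 2],
                       ankle_angle = alpha)
  rb <- rollback_reconstruct(foot, rec)
  expect_equal(rb$alpha, alpha, tolerance = 1e-10)
  expect_equal(rb$ankle_x, ank[, 1], tolerance = 1e-10)
})

test_that("generator round trip: rollback reproduces the generated ankle path", {
  for (model in c("ellipse", "double_circle")) {
    foot <- default_foot(model)
    g <- generate_stance_record(stance_generator_config(foot))
    rb <- rollback_reconstruct(foot, g$clean)
    expect_lt(max(abs(rb$alpha - g$clean$ankle_angle)), 1e-10)
    expect_lt(max(abs(rb$ankle_x - g$clean$ankle_x)), 1e-10)
    expect_lt(max(abs(rb$ankle_z - g$clean$ankle_z)), 1e-10)
    expect_lt(fit_cost(foot, g$clean), 1e-16)
  }
})

test_that("double-circle flat span fixes the ankle while the CoP advances", {
  foot <- default_foot("double_circle")
  g <- generate_stance_record(stance_generator_config(foot))
  af <- rigidfoot:::dc_flat_angle(foot)
  flat <- abs(g$clean$ankle_angle - af) < 1e-12
  expect_gt(sum(flat), 5)
  expect_lt(diff(range(g$clean$ankle_x[flat])), 1e-12)
  expect_gt(diff(range(g$clean$cop_x[flat])), 0.1)
  rb <- rollback_reconstruct(foot, g$clean)
  expect_equal(rb$alpha[flat], rep(af, sum(flat)), tolerance = 1e-12)
})

test_that("rollback rejects CoP displacements beyond the rolling range", {
  foot <- default_foot("ellipse")
  g <- generate_stance_record(stance_generator_config(foot))
  rec <- g$clean
  rec$cop_x[1] <- rec$cop_x[1] - 10   # would need to roll past the extremity
  expect_error(rollback_reconstruct(foot, rec), "rolling arc|ahead")
})

test_that("fit cost: weighting, invariances, hand-computed two-sample case", {
  foot <- default_foot("ellipse")
  g <- generate_stance_record(stance_generator_config(foot))
  rec <- g$clean
  cfg <- fit_config()
  # a single sample at peak force with a 1 cm position error scores 1:
  # shift the whole record's ankle data by 1 cm in z
  rec1 <- rec; rec1$ankle_z <- rec1$ankle_z + 0.01
  w <- rec$force_z / max(rec$force_z)
  expect_equal(fit_cost(foot, rec1, cfg), sum(w * cfg$w_r * 0.01^2),
               tolerance = 1e-10)
  # an orientation error of pi/14 at every sample scores sum(w) * 1
  rec2 <- rec; rec2$ankle_angle <- rec2$ankle_angle + pi / 14
  # (the rollback matches the recorded angle at the anchor, so shift only
  # the ankle pose channels instead)
  rec2 <- rec; rec2$ankle_x <- rec2$ankle_x + 0.01 / sqrt(2)
  rec2$ankle_z <- rec2$ankle_z + 0.01 / sqrt(2)
  expect_equal(fit_cost(foot, rec2, cfg), sum(w), tolerance = 1e-10)
  # rigid translation of CoP and ankle data together leaves the cost unchanged
  rec3 <- rec; rec3$cop_x <- rec3$cop_x + 0.37; rec3$ankle_x <- rec3$ankle_x + 0.37
  expect_equal(fit_cost(foot, rec3, cfg), fit_cost(foot, rec, cfg),
               tolerance = 1e-10)
  # scaling all forces leaves the cost unchanged (peak normalization)
  rec4 <- rec1; rec4$force_z <- 3.7 * rec4$force_z; rec4$force_x <- 3.7 * rec4$force_x
  expect_equal(fit_cost(foot, rec4, cfg), fit_cost(foot, rec1, cfg),
               tolerance = 1e-10)
  # two-sample hand computation
  foot_c <- ellipse_foot(c(0, 0), 0, 0.05, 0.05)
  a2 <- c(0.1, -0.1); cop2 <- 0.05 * (0.1 - a2)
  ank2 <- t(vapply(1:2, function(i)
    rigidfoot:::ankle_from_contact(foot_c, a2[i], cop2[i]), c(0, 0)))
  rec5 <- stance_record(t = c(0, 1), cop_x = cop2, force_x = c(0, 0),
                        force_z = c(50, 100), ankle_x = ank2[, 1] + c(0.002, 0),
                        ankle_z = ank2[, 2], ankle_angle = a2 + c(0.03, 0))
  # reconstruction anchors at sample 2 exactly; sample 1 carries the errors
  hand <- 0.5 * (cfg$w_r * 0.002^2 + cfg$w_alpha * 0.03^2)
  expect_equal(fit_cost(foot_c, rec5, cfg), hand, tolerance = 1e-8)
})

test_that("noise-free fits recover the generating parameters (both models)", {
  set.seed(31)
  # ellipse: perturbed start, constrained length
  foot <- default_foot("ellipse")
  g <- generate_stance_record(stance_generator_config(foot))
  init <- ellipse_foot(foot$r_E + c(0.012, -0.008), 0.06, 0.1525, 0.055)
  fit <- fit_foot(init, g$clean)
  expect_true(fit$converged)
  expect_equal(fit$foot$r_x, 0.1525)   # length constraint eliminated exactly
  expect_lt(max(abs(fit$foot$r_E - foot$r_E)), 1e-3)
  expect_lt(abs(fit$foot$r_y - foot$r_y), 1e-3)
  expect_lt(abs(fit$foot$theta_E - foot$theta_E), 1e-3)
  expect_lte(fit$cost, fit$initial_cost)
  # double circle
  dc <- default_foot("double_circle")
  g2 <- generate_stance_record(stance_generator_config(dc))
  init2 <- double_circle_foot(dc$r_H + c(0.008, 0.006), dc$rad_H + 0.008,
                              dc$r_F + c(-0.007, 0.005), dc$rad_F - 0.01)
  fit2 <- fit_foot(init2, g2$clean)
  expect_lt(max(abs(coef(fit2) - unlist(dc[c("r_H", "rad_H", "r_F", "rad_F")]))),
            1e-3)
  # refitting from the converged solution stays put
  fit3 <- fit_foot(fit$foot, g$clean)
  expect_lt(max(abs(coef(fit3) - coef(fit))), 1e-4)
})

test_that("fitted-parameter error grows continuously from zero with noise", {
  foot <- default_foot("ellipse")
  errs <- vapply(c(0, 1e-4, 1e-3), function(sg) {
    g <- generate_stance_record(stance_generator_config(foot, sigma_pos = sg,
                                                        seed = 5))
    fit <- fit_foot(foot, g$record)
    max(abs(coef(fit)[c("r_E_x", "r_E_z", "r_y")] -
              c(foot$r_E, foot$r_y)))
  }, 0)
  expect_lt(errs[1], 1e-6)
  expect_lt(errs[2], 5e-3)
  expect_lt(errs[3], 5e-2)
})

test_that("error statistics summarize per-sample errors correctly", {
  fake <- structure(list(pos_err = c(0.01, 0.02, 0.03),
                         ang_err = c(0.1, 0.1, 0.4)), class = "foot_fit")
  st <- error_statistics(fake)
  expect_equal(st["position", "mean"], 0.02)
  expect_equal(st["position", "sd"], 0.01)
  expect_equal(st["position", "max"], 0.03)
  expect_equal(st["orientation", "mean"], 0.2)
  expect_equal(st["orientation", "max"], 0.4)
  # zero errors
  z <- structure(list(pos_err = rep(0, 5), ang_err = rep(0, 5)),
                 class = "foot_fit")
  expect_true(all(as.matrix(error_statistics(z)) == 0))
  # agreement with independent routines on random vectors
  set.seed(32)
  e1 <- runif(40); e2 <- runif(40)
  r <- structure(list(pos_err = e1, ang_err = e2), class = "foot_fit")
  st2 <- error_statistics(r)
  expect_equal(st2["position", "sd"], sqrt(sum((e1 - mean(e1))^2) / 39))
  expect_equal(st2["orientation", "mean"], sum(e2) / 40)
})
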