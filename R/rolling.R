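# Rolling-contact geometry for a foot shape on the ground plane, as used by
# the stance generator and the CoP-rollback fitting procedure.  Convention:
# x forward, z up, CCW angles positive, so rolling the foot FORWARD (CoP
# advancing) corresponds to a DECREASING ankle-frame orientation alpha.

# orientation at which both circles of a double-circle foot touch the ground
dc_flat_angle <- function(foot) {
  d <- foot$r_F - foot$r_H
  A <- atan2(d[2], d[1])
  s <- (foot$rad_F - foot$rad_H) / sqrt(sum(d^2))
  if (abs(s) >= 1) stop("double-circle foot has no flat pose")
  asin(s) - A
}

# horizontal distance between the heel and forefoot contact points at the
# flat pose (the CoP span traversed while the foot is flat)
dc_flat_span <- function(foot) {
  af <- dc_flat_angle(foot)
  d <- rot2v(af, foot$r_F - foot$r_H)
  d[1]
}

# cumulative boundary arc length of the ellipse as a spline A(phi), built on
# a wide polar-angle grid (adaptive enough for fitting-scale accuracy)
ell_arc_fun <- function(foot, n = 2001) {
  a <- foot$r_x; b <- foot$r_y
  grid <- seq(-2 * pi - 3, 2 * pi + 3, length.out = n)
  D <- b^2 * cos(grid)^2 + a^2 * sin(grid)^2
  rs <- a * b / sqrt(D)
  rs1 <- -(a * b / 2) * (a^2 - b^2) * sin(2 * grid) / D^1.5
  ds <- sqrt(rs^2 + rs1^2)
  h <- grid[2] - grid[1]
  A <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * h))
  splinefun(grid, A, method = "natural")
}

# ellipse-frame polar angle of the contact point for ankle orientation alpha
ell_contact_phi <- function(foot, alpha) {
  rf_ellipse_lowest(foot$r_x, foot$r_y, alpha + foot$theta_E)$phi
}

# ankle-frame offset of the instantaneous contact point
contact_offset <- function(foot, alpha, shape = NULL) {
  if (inherits(foot, "ellipse_foot")) {
    sol <- rf_ellipse_lowest(foot$r_x, foot$r_y, alpha + foot$theta_E)
    b <- sol$boundary
    foot$r_E + rot2v(foot$theta_E, b)
  } else {
    shape <- shape %||% if (alpha > dc_flat_angle(foot)) "heel" else "forefoot"
    ctr <- if (shape == "heel") foot$r_H else foot$r_F
    rad <- if (shape == "heel") foot$rad_H else foot$rad_F
    ctr + rot2v(-alpha, c(0, -rad))
  }
}

# relative contact-point ground position xi(alpha): monotone decreasing in
# alpha; differences equal rolled arc length (rolling without slipping).
# For the double-circle foot the flat pose is a jump of width dc_flat_span()
# (the CoP sweeps the span while the orientation is fixed).
roll_contact_x <- function(foot, alpha, arc = NULL) {
  if (inherits(foot, "ellipse_foot")) {
    arc <- arc %||% ell_arc_fun(foot)
    vapply(alpha, function(a) arc(ell_contact_phi(foot, a)), 0)
  } else {
    af <- dc_flat_angle(foot)
    span <- dc_flat_span(foot)
    vapply(alpha, function(a)
      if (a >= af) -foot$rad_H * (a - af) else span + foot$rad_F * (af - a), 0)
  }
}

# ankle pose implied by rolling contact: orientation alpha with the active
# contact point at ground position (x_c, 0)
ankle_from_contact <- function(foot, alpha, x_c, shape = NULL) {
  off <- contact_offset(foot, alpha, shape)
  c(x_c, 0) - rot2v(alpha, off)
}
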