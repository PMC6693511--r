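# shared fixtures: models and random-state generators (all built in code)

tm_body <- function() default_body_parameters(81.7, 1.72)

tm_ellipse <- function(actuated = FALSE)
  gait_model(tm_body(), default_foot("ellipse"),
             if (actuated) default_actuators() else NULL)

tm_dc <- function(actuated = FALSE)
  gait_model(tm_body(), default_foot("double_circle"),
             if (actuated) default_actuators() else NULL)

# a torque-balanced body: every segment COM lies on its joint axis line, so
# at the neutral posture all gravity joint torques vanish (used for statics)
tm_balanced_body <- function() {
  b <- tm_body()
  com <- b$com
  com[1, ] <- c(0, 0.35)
  com[c(4, 7), ] <- 0          # foot COM at the ankle
  body_parameters(b$mass, b$inertia, b$len_thigh, b$len_shank, com, b$g)
}

rand_q <- function() {
  c(runif(1, -0.5, 0.5), runif(1, 0.6, 1.1), runif(1, -0.4, 0.4),
    runif(1, -0.7, 0.7), runif(1, -1.2, 0.05), runif(1, -0.6, 0.6),
    runif(1, -0.7, 0.7), runif(1, -1.2, 0.05), runif(1, -0.6, 0.6))
}
rand_qd <- function() runif(9, -2, 2)
rand_state <- function() model_state(rand_q(), rand_qd())
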