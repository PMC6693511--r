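# small planar-geometry helpers shared across modules

rot2 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, -s, c), 2, 2)
}

rot2v <- function(theta, v) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# omega x r in the sagittal plane (CCW positive)
perp2 <- function(v) c(-v[2], v[1])

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
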