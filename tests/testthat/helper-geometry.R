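# Shared fixtures, built in code.

# Random rotation matrix (uniform via quaternion) from the current RNG.
rand_rotation <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# Thorax markers that give an identity thorax frame with origin at IJ.
identity_thorax <- function() {
  list(IJ = c(0, 0, 0), C7 = c(0, -100, 0),
       PX = c(0, 0, -150), T8 = c(0, -100, -150))
}

# A tiny complete trial data.frame: all 14 markers over `frames` frames,
# static at distinct positions.
static_trial_df <- function(frames = 2L) {
  pos <- lapply(seq_along(MARKER_LABELS), function(i) c(10 * i, -i, i^2))
  names(pos) <- MARKER_LABELS
  do.call(rbind, lapply(0:(frames - 1L), function(f) {
    do.call(rbind, lapply(MARKER_LABELS, function(lab) {
      data.frame(frame = f, label = lab, x_mm = pos[[lab]][1L],
                 y_mm = pos[[lab]][2L], z_mm = pos[[lab]][3L],
                 visible = TRUE, stringsAsFactors = FALSE)
    }))
  }))
}

# Horner evaluation written independently of the package internals.
horner_oracle <- function(coefs_desc, x) {
  acc <- 0
  for (ck in coefs_desc) acc <- acc * x + ck
  acc
}

# Independent evaluation of a polynomial/rational axis spec.
axis_eval_oracle <- function(spec, x) {
  if (spec$kind == "polynomial") return(horner_oracle(spec$coefficients, x))
  off <- if (is.null(spec$offset)) 0 else spec$offset
  horner_oracle(spec$numerator, x) / horner_oracle(spec$denominator, x) + off
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
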