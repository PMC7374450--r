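# Klopcar shoulder-girdle reference model and model-to-model comparison.

#' Construct the Klopcar shoulder-girdle model
#'
#' A piecewise-linear model of the girdle angles during humeral
#' elevation: the elevation/depression angle phi_ed is 0 up to 30 degrees
#' then 0.36 phi - 10.8 (and -0.3 phi for negative elevation), the
#' protraction/retraction angle phi_pr is 0 up to 70 degrees then
#' -0.22 phi + 15.4 (0.35 phi for negative elevation); girdle length
#' scales as 1 + 3e-4 phi - 1.6e-5 phi^k with k = 1 under the literal
#' (linear) reading and k = 2 under the quadratic reading; displacements
#' are scaled by the sternum-to-girdle factor 0.75.
#'
#' @param d0 natural-posture sternum-to-GH distance (mm); kept for
#'   dimensional bookkeeping (displacement ratios do not depend on it).
#' @param exponent_reading `"linear"` (default) or `"quadratic"`; see
#'   above.
#' @param sternum_scale the sternum-to-G scale factor (default 0.75).
#' @return An object of class `klopcar_model`.
#' @export
klopcar_model <- function(d0 = 170,
                          exponent_reading = c("linear", "quadratic"),
                          sternum_scale = 0.75) {
  exponent_reading <- match.arg(exponent_reading)
  structure(list(
    ed = list(slope_neg = -0.3, slope_pos = 0.36, offset = -10.8,
              breaks = c(0, 30)),
    pr = list(slope_neg = 0.35, slope_pos = -0.22, offset = 15.4,
              breaks = c(0, 70)),
    girdle_coefs = c(-1.6e-5, 3e-4),
    exponent_reading = exponent_reading,
    sternum_scale = sternum_scale,
    d0 = d0,
    validity_deg = c(0, 150)),
    class = "klopcar_model")
}

#' @export
print.klopcar_model <- function(x, ...) {
  cat(sprintf("<klopcar_model> exponent reading: %s, scale %.2f, d0 %.1f mm\n",
              x$exponent_reading, x$sternum_scale, x$d0))
  invisible(x)
}

#' Klopcar girdle angles
#'
#' Piecewise evaluation of the elevation/depression and
#' protraction/retraction girdle angles; both pieces join continuously at
#' their breakpoints (30 and 70 degrees).
#'
#' @param phi humeral elevation angle(s), degrees.
#' @param model a [klopcar_model()].
#' @return list with vectors `phi_ed` and `phi_pr` (degrees).
#' @export
klopcar_girdle_angles <- function(phi, model = klopcar_model()) {
  phi <- as.numeric(phi)
  stopifnot(all(is.finite(phi)))
  ed <- model$ed; pr <- model$pr
  phi_ed <- ifelse(phi < ed$breaks[1L], ed$slope_neg * phi,
                   ifelse(phi <= ed$breaks[2L], 0,
                          ed$slope_pos * phi + ed$offset))
  phi_pr <- ifelse(phi < pr$breaks[1L], pr$slope_neg * phi,
                   ifelse(phi <= pr$breaks[2L], 0,
                          pr$slope_pos * phi + pr$offset))
  list(phi_ed = phi_ed, phi_pr = phi_pr)
}

#' Klopcar GH-centre displacement ratios
#'
#' Combines the girdle angles with the girdle-length scaling into
#' dimensionless displacement ratios in the thorax frame:
#' x = s (g cos(ed) cos(pr) - 1), y = s g cos(ed) sin(pr),
#' z = s g sin(ed), d = sqrt(x^2 + y^2 + z^2), where g is the girdle
#' length ratio and s the sternum scale. All four are zero at zero
#' elevation under either exponent reading.
#'
#' @param phi humeral elevation angle(s), degrees, in \[0, 150\].
#' @param model a [klopcar_model()].
#' @return Matrix `length(phi)` x 4 with columns x, y, z, d.
#' @export
klopcar_displacement <- function(phi, model = klopcar_model()) {
  phi <- as.numeric(phi)
  if (any(phi < model$validity_deg[1L] - 1e-9 |
          phi > model$validity_deg[2L] + 1e-9)) {
    stop_cond("range_error", "phi outside model validity range [%g, %g]",
              model$validity_deg[1L], model$validity_deg[2L])
  }
  k <- if (model$exponent_reading == "linear") 1 else 2
  g <- 1 + model$girdle_coefs[2L] * phi + model$girdle_coefs[1L] * phi^k
  ang <- klopcar_girdle_angles(phi, model)
  ed <- deg2rad(ang$phi_ed); pr <- deg2rad(ang$phi_pr)
  s <- model$sternum_scale
  x <- s * (g * cos(ed) * cos(pr) - 1)
  y <- s * g * cos(ed) * sin(pr)
  z <- s * g * sin(ed)
  cbind(x = x, y = y, z = z, d = sqrt(x^2 + y^2 + z^2))
}

eval_model_axes <- function(model, grid, remove_constant) {
  if (inherits(model, "coupling_model")) {
    v <- evaluate_coupling(model, grid, remove_constant = remove_constant)
    v[, intersect(c("x", "y", "z"), colnames(v)), drop = FALSE]
  } else if (inherits(model, "klopcar_model")) {
    v <- klopcar_displacement(grid, model)[, c("x", "y", "z"), drop = FALSE]
    if (remove_constant) {
      v0 <- klopcar_displacement(0, model)[, c("x", "y", "z")]
      v <- sweep(v, 2L, v0)
    }
    v
  } else {
    stop("models must be coupling_model or klopcar_model objects")
  }
}

model_validity <- function(model) model$validity_deg

#' Compare two coupling/reference models on a grid
#'
#' Evaluates both models' x, y, z displacement-ratio curves on the grid
#' (optionally after removing each model's zero-elevation constant, so
#' both describe pure displacement) and reports the per-axis gap
#' a(theta) - b(theta) and its maximum absolute value.
#'
#' @param a,b [coupling_model()] or [klopcar_model()] objects.
#' @param grid elevation angles (deg); must lie in both validity ranges.
#' @param remove_constant remove each model's theta = 0 value first
#'   (default `TRUE`).
#' @return An object of class `model_comparison` with `grid`, `gap`
#'   (matrix, columns x, y, z), `max_abs_gap` (named vector) and the
#'   `remove_constant` flag.
#' @export
compare_models <- function(a, b, grid = seq(0, 150, by = 1),
                           remove_constant = TRUE) {
  grid <- sort(as.numeric(grid))
  va <- model_validity(a); vb <- model_validity(b)
  lo <- max(va[1L], vb[1L]); hi <- min(vb[2L], va[2L])
  if (lo > hi) stop_cond("range_error", "disjoint validity ranges")
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9) {
    stop_cond("range_error",
              "grid outside the shared validity range [%g, %g]", lo, hi)
  }
  gap <- eval_model_axes(a, grid, remove_constant) -
    eval_model_axes(b, grid, remove_constant)
  structure(list(grid = grid, gap = gap,
                 max_abs_gap = apply(abs(gap), 2L, max),
                 remove_constant = remove_constant),
            class = "model_comparison")
}

#' @export
as.data.frame.model_comparison <- function(x, ...) {
  data.frame(theta_deg = x$grid, gap_x = x$gap[, "x"],
             gap_y = x$gap[, "y"], gap_z = x$gap[, "z"])
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d grid points, constants %s\n",
              length(x$grid),
              if (x$remove_constant) "removed" else "kept"))
  cat("  max |gap|:",
      paste(sprintf("%s=%.4g", names(x$max_abs_gap), x$max_abs_gap),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.model_comparison <- function(x, ...) {
  graphics::matplot(x$grid, x$gap, type = "l", lty = 1,
                    xlab = "elevation angle [deg]",
                    ylab = "ratio gap", ...)
  graphics::legend("topleft", legend = colnames(x$gap), col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}
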