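# Thorax anatomical coordinate frame from C7, T8, IJ, PX.

# Batch construction of thorax axes from n x 3 marker matrices. Returns
# unit axis matrices X, Y, Z (rows are the per-frame global axis vectors),
# the origin (IJ) and a per-frame skew diagnostic: the angle in degrees by
# which the raw cross-product x axis had to be tilted to orthogonalize the
# triad (O(noise) on real data, 0 on perfect data).
thorax_axes_batch <- function(C7, T8, IJ, PX, tol = 1e-9) {
  xr <- rowwise_cross(IJ - PX, C7 - PX)
  nx <- row_norms(xr)
  z <- 0.5 * (IJ + C7) - 0.5 * (PX + T8)
  nz <- row_norms(z)
  bad <- !is.finite(nx) | !is.finite(nz) | nx < tol | nz < tol
  if (any(bad)) {
    stop_cond("degenerate_thorax",
              "degenerate thorax marker geometry at frame row %d",
              which(bad)[1L])
  }
  xu <- xr / nx
  zu <- z / nz
  y <- rowwise_cross(zu, xu)
  ny <- row_norms(y)
  if (any(ny < tol)) {
    stop_cond("degenerate_thorax",
              "thorax x and z axes are parallel at frame row %d",
              which(ny < tol)[1L])
  }
  yu <- y / ny
  x <- rowwise_cross(yu, zu)   # exact orthonormal triad, z primary
  skew <- rad2deg(acos(clamp1(rowSums(x * xu))))
  list(X = x, Y = yu, Z = zu, origin = IJ, skew_deg = skew)
}

# Map global points P (n x 3) into thorax coordinates for per-frame axes.
to_thorax_batch <- function(axes, P) {
  d <- P - axes$origin
  cbind(rowSums(d * axes$X), rowSums(d * axes$Y), rowSums(d * axes$Z))
}

#' Build the thorax anatomical coordinate frame
#'
#' Constructs the ISB-style thorax frame from one frame's C7, T8, IJ and
#' PX marker positions. The x axis points laterally (right), derived from
#' the cross product of IJ-PX and C7-PX; the z axis points cranially along
#' the line from the mid-sternum/spine midpoint at the caudal level to the
#' cranial one; y completes a right-handed triad. Because noisy markers do
#' not give an exactly orthogonal raw triad, z is kept as the primary
#' axis, y = z x x_raw, and x is re-derived as y x z; the tilt applied to
#' x is recorded as `skew_deg`.
#'
#' @param C7,T8,IJ,PX global marker positions, numeric 3-vectors (mm).
#' @return An object of class `thorax_frame` with unit axes `x_t`, `y_t`,
#'   `z_t` (global coordinates), `origin` (IJ), the 4 x 4 homogeneous
#'   `transform` mapping global to thorax coordinates, and `skew_deg`.
#' @export
build_thorax_frame <- function(C7, T8, IJ, PX) {
  C7 <- as_point3(C7); T8 <- as_point3(T8)
  IJ <- as_point3(IJ); PX <- as_point3(PX)
  if (!all(is.finite(c(C7, T8, IJ, PX)))) {
    stop_cond("degenerate_thorax", "thorax markers must be finite")
  }
  ax <- thorax_axes_batch(rbind(C7), rbind(T8), rbind(IJ), rbind(PX))
  R <- rbind(ax$X[1L, ], ax$Y[1L, ], ax$Z[1L, ])  # rows = thorax axes
  Tm <- rbind(cbind(R, -as.vector(R %*% IJ)), c(0, 0, 0, 1))
  structure(list(x_t = ax$X[1L, ], y_t = ax$Y[1L, ], z_t = ax$Z[1L, ],
                 origin = IJ, transform = Tm, skew_deg = ax$skew_deg[1L]),
            class = "thorax_frame")
}

#' @export
print.thorax_frame <- function(x, ...) {
  cat("<thorax_frame>\n  origin (IJ):", sprintf("%.3f", x$origin), "mm\n")
  cat(sprintf("  orthogonalization skew: %.3g deg\n", x$skew_deg))
  invisible(x)
}

#' Transform points into thorax coordinates
#'
#' Applies the global-to-thorax rigid transform; the IJ marker maps to the
#' origin and distances are preserved.
#'
#' @param frame a [build_thorax_frame()] result.
#' @param point numeric 3-vector or n x 3 matrix of global positions (mm).
#' @return Local coordinates with the same shape as `point`.
#' @export
to_thorax_coordinates <- function(frame, point) {
  stopifnot(inherits(frame, "thorax_frame"))
  R <- frame$transform[1:3, 1:3]
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    sweep(point, 2L, frame$origin) %*% t(R)
  } else {
    as.vector(R %*% (as_point3(point) - frame$origin))
  }
}
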