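# Humeral axis, elevation angles, Euler conversions and the
# floating-centre forward model.

#' Humeral long axis from the epicondyles and the GH centre
#'
#' The distal axis runs from the GH centre to the elbow midpoint
#' E = (EL + EM) / 2. All inputs in thorax coordinates (mm).
#'
#' @param EL,EM lateral/medial epicondyle positions (3-vectors, mm).
#' @param J GH centre position (3-vector, mm).
#' @return The axis vector D = E - J (mm). Warns if its length is below
#'   100 mm (implausible upper arm).
#' @export
humeral_axis <- function(EL, EM, J) {
  D <- 0.5 * (as_point3(EL) + as_point3(EM)) - as_point3(J)
  if (sqrt(sum(D^2)) < 100) {
    warn_cond("implausible_arm",
              "humeral axis length %.3g mm is implausibly short",
              sqrt(sum(D^2)))
  }
  D
}

axis_rows <- function(D) {
  if (is.matrix(D)) D else matrix(D, nrow = 1L)
}

#' Humeral elevation angle
#'
#' Angle of the humeral long axis away from the hanging posture:
#' theta = arccos(D . (-z_t) / |D|), so a hanging arm (along the caudal
#' -z_t) gives 0 degrees, horizontal gives 90 and overhead 180. Invariant
#' to uniform scaling of D.
#'
#' @param D humeral axis, 3-vector or n x 3 matrix, thorax coordinates
#'   (or global coordinates when `frame` is supplied).
#' @param frame optional [build_thorax_frame()] object; when given, D is
#'   treated as a global free vector and rotated into the thorax frame.
#' @return Elevation angle(s) in degrees, in \[0, 180\].
#' @export
elevation_angle <- function(D, frame = NULL) {
  D <- axis_rows(D)
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "thorax_frame"))
    D <- D %*% t(frame$transform[1:3, 1:3])
  }
  n <- row_norms(D)
  if (any(!is.finite(n) | n == 0)) {
    stop_cond("undefined_angle", "zero or non-finite humeral axis")
  }
  rad2deg(acos(clamp1(-D[, 3L] / n)))
}

#' Elevation-plane angle
#'
#' The azimuth of the humeral axis around the cranial thorax axis:
#' eta = atan2(D . y_t, D . x_t). 0 degrees is frontal-plane abduction
#' (lateral, +x_t) and 90 degrees forward flexion (anterior, +y_t),
#' matching the guided planes 0-135 degrees. Near the hanging posture the
#' projection degenerates, so the plane is undefined (returned as `NA`)
#' when the elevation angle is at or below `min_elevation`.
#'
#' @inheritParams elevation_angle
#' @param min_elevation elevation (deg) below which the plane is flagged
#'   undefined; default 5.
#' @return Plane angle(s) in degrees in (-180, 180\], `NA` where undefined.
#' @export
elevation_plane_angle <- function(D, frame = NULL, min_elevation = 5) {
  D <- axis_rows(D)
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "thorax_frame"))
    D <- D %*% t(frame$transform[1:3, 1:3])
  }
  theta <- elevation_angle(D)
  eta <- rad2deg(atan2(D[, 2L], D[, 1L]))
  eta[theta <= min_elevation] <- NA_real_
  eta
}

#' ISB-style humeral rotation matrix
#'
#' Composes the humeral orientation as Rz(eta) . Ry(-theta) . Rz(psi)
#' (plane of elevation, negative elevation, axial rotation), chosen so
#' that eta = 0 elevates the right arm laterally (+x_t) and eta = 90
#' anteriorly (+y_t).
#'
#' @param eta,theta,psi angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
isb_rotation <- function(eta, theta, psi) {
  rot_z(eta) %*% rot_y(-theta) %*% rot_z(psi)
}

#' Anatomical rotation matrix
#'
#' Composes Ry(alpha) . Rx(beta) . Rz(gamma): abduction/adduction about
#' the sagittal axis (y), flexion/extension about the coronal axis (x),
#' internal/external rotation about the vertical axis (z).
#'
#' @param alpha,beta,gamma angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
anatomical_rotation <- function(alpha, beta, gamma) {
  rot_y(alpha) %*% rot_x(beta) %*% rot_z(gamma)
}

#' Convert ISB angles to anatomical angles
#'
#' Solves Ry(alpha) Rx(beta) Rz(gamma) = Rz(eta) Ry(-theta) Rz(psi) for
#' the anatomical triple. Near gimbal lock (|beta| -> 90 deg) the split
#' between alpha and gamma is degenerate; the canonical solution with
#' gamma = 0 is returned and flagged.
#'
#' @param eta,theta,psi ISB angles in degrees.
#' @return list with `alpha`, `beta`, `gamma` (degrees), logical
#'   `degenerate`, and `recomposition_error` (Frobenius norm of the
#'   difference between the source rotation and the recomposed one).
#' @export
isb_to_anatomical <- function(eta, theta, psi) {
  R <- isb_rotation(eta, theta, psi)
  s_beta <- clamp1(-R[2L, 3L])
  beta <- asin(s_beta)
  degenerate <- abs(s_beta) > 1 - 1e-9
  if (degenerate) {
    gamma <- 0
    alpha <- atan2(-R[3L, 1L], R[1L, 1L])
  } else {
    alpha <- atan2(R[1L, 3L], R[3L, 3L])
    gamma <- atan2(R[2L, 1L], R[2L, 2L])
  }
  out <- list(alpha = rad2deg(alpha), beta = rad2deg(beta),
              gamma = rad2deg(gamma), degenerate = degenerate)
  out$recomposition_error <-
    sqrt(sum((anatomical_rotation(out$alpha, out$beta, out$gamma) - R)^2))
  out
}

#' Forward elbow position under the floating-centre model
#'
#' The humeral pointing combines a translational part -- the rest GH
#' centre plus the coupling model's constant-removed displacement
#' d0 * (c(theta) - c(0)) -- with the rotation of the rest humeral vector:
#' r_E = q1_rest + d0 * Delta(theta) + R(eta, theta, psi) . D_rest.
#' Because D_rest lies on the humeral long axis, the result is
#' independent of the axial rotation psi.
#'
#' @param model a [coupling_model()] (e.g. [builtin_coupling_model()]).
#' @param q1_rest rest (hanging) GH centre, thorax coordinates (mm).
#' @param D_rest rest humeral axis vector, thorax coordinates (mm);
#'   typically (0, 0, -L).
#' @param eta,theta,psi ISB angles in degrees; `theta` may be a vector
#'   (with `eta`/`psi` recycled).
#' @param d0 normalization distance (mm).
#' @return A named 3-vector for scalar `theta`, otherwise an n x 3 matrix.
#' @export
forward_elbow_position <- function(model, q1_rest, D_rest, eta, theta,
                                   psi = 0, d0) {
  stopifnot(inherits(model, "coupling_model"))
  q1_rest <- as_point3(q1_rest); D_rest <- as_point3(D_rest)
  n <- max(length(eta), length(theta), length(psi))
  eta <- rep_len(eta, n); theta <- rep_len(theta, n); psi <- rep_len(psi, n)
  if (any(theta < model$validity_deg[1L] - 1e-9 |
          theta > model$validity_deg[2L] + 1e-9)) {
    stop_cond("range_error", "theta outside model validity range [%g, %g]",
              model$validity_deg[1L], model$validity_deg[2L])
  }
  delta <- evaluate_coupling(model, theta, remove_constant = TRUE)
  out <- t(vapply(seq_len(n), function(i) {
    q1_rest + d0 * delta[i, c("x", "y", "z")] +
      as.vector(isb_rotation(eta[i], theta[i], psi[i]) %*% D_rest)
  }, numeric(3L)))
  colnames(out) <- c("x", "y", "z")
  if (n == 1L) out[1L, ] else out
}
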