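# GH joint-centre estimation by the dual-cluster invariance regression.
#
# The centre has constant local coordinates in both the scapula and the
# humerus cluster frames. Writing the centre at time K as
#   J = q4 + a q1 + b q2 + c q3   (scapula triple basis)
#   J = q8 + d q5 + e q6 + f q7   (humerus triple basis)
# with q1 = P1-P2, q2 = P1-P3, q3 = q1 x q2, q4 = P1 (and likewise for
# the humerus), equating the two gives, per frame, three linear equations
#   [q1 q2 q3 -q5 -q6 -q7] (a,b,c,d,e,f)' = q8 - q4
# which are stacked over frames and solved by least squares.

#' Build the per-frame regression basis from two marker triples
#'
#' @param scap_triple,hum_triple 3 x 3 matrices (rows = the three triple
#'   markers, thorax coordinates, mm).
#' @param area_tol collinearity tolerance on triangle area (mm^2).
#' @return An object of class `frame_basis`: difference vectors `q1`,
#'   `q2`, `q5`, `q6` (mm), cross products `q3`, `q7` (mm^2) and anchors
#'   `q4`, `q8` (mm).
#' @export
build_frame_basis <- function(scap_triple, hum_triple, area_tol = 1) {
  scap_triple <- as.matrix(scap_triple); hum_triple <- as.matrix(hum_triple)
  stopifnot(all(dim(scap_triple) == c(3L, 3L)), all(dim(hum_triple) == c(3L, 3L)))
  q1 <- scap_triple[1L, ] - scap_triple[2L, ]
  q2 <- scap_triple[1L, ] - scap_triple[3L, ]
  q3 <- cross3(q1, q2)
  q5 <- hum_triple[1L, ] - hum_triple[2L, ]
  q6 <- hum_triple[1L, ] - hum_triple[3L, ]
  q7 <- cross3(q5, q6)
  if (0.5 * sqrt(sum(q3^2)) < area_tol) {
    stop_cond("collinear_triple", "scapula triple is collinear")
  }
  if (0.5 * sqrt(sum(q7^2)) < area_tol) {
    stop_cond("collinear_triple", "humerus triple is collinear")
  }
  structure(list(q1 = q1, q2 = q2, q3 = q3, q4 = scap_triple[1L, ],
                 q5 = q5, q6 = q6, q7 = q7, q8 = hum_triple[1L, ]),
            class = "frame_basis")
}

# Batch form used internally: lists of n x 3 matrices.
bases_batch <- function(scap, hum) {
  q1 <- scap[[1L]] - scap[[2L]]
  q2 <- scap[[1L]] - scap[[3L]]
  q5 <- hum[[1L]] - hum[[2L]]
  q6 <- hum[[1L]] - hum[[3L]]
  list(q1 = q1, q2 = q2, q3 = rowwise_cross(q1, q2), q4 = scap[[1L]],
       q5 = q5, q6 = q6, q7 = rowwise_cross(q5, q6), q8 = hum[[1L]])
}

as_bases_batch <- function(bases) {
  if (is.list(bases) && !is.null(bases$q1) && is.matrix(bases$q1)) {
    return(bases)
  }
  if (inherits(bases, "frame_basis")) bases <- list(bases)
  stopifnot(all(vapply(bases, inherits, logical(1L), "frame_basis")))
  nm <- paste0("q", 1:8)
  out <- lapply(nm, function(q) {
    do.call(rbind, lapply(bases, `[[`, q))
  })
  names(out) <- nm
  out
}

#' Assemble the centre-regression linear system
#'
#' Each usable frame contributes three scalar rows; the humerus columns
#' enter negated so that the solved (d, e, f) are genuine humerus-local
#' coordinates, and the right-hand side is q8 - q4 per frame.
#'
#' @param bases a list of [build_frame_basis()] objects, or the internal
#'   batch form (named `q1`..`q8` matrices, n x 3).
#' @return list with `A` (3K x 6 matrix) and `B` (3K vector).
#' @export
assemble_center_system <- function(bases) {
  b <- as_bases_batch(bases)
  K <- nrow(b$q1)
  if (K < 2L) {
    stop_cond("insufficient_data",
              "need at least 2 usable frames, got %d", K)
  }
  A <- cbind(as.vector(t(b$q1)), as.vector(t(b$q2)), as.vector(t(b$q3)),
             -as.vector(t(b$q5)), -as.vector(t(b$q6)), -as.vector(t(b$q7)))
  colnames(A) <- letters[1:6]
  list(A = A, B = as.vector(t(b$q8 - b$q4)))
}

#' Solve the centre regression
#'
#' Minimum-norm least squares via the singular value decomposition; on
#' well-conditioned systems this agrees with the explicit normal-equations
#' solution \eqn{(A^T A)^{-1} A^T B} to high relative accuracy while
#' remaining stable when A is nearly rank deficient.
#'
#' @param A 3K x 6 design matrix; `B` right-hand side of length 3K.
#' @param B numeric vector.
#' @param rank_tol singular values below `rank_tol` times the largest are
#'   treated as zero; default 1e-8.
#' @return An object of class `center_regression` with `params` (named
#'   a..f), `residual_rms` (mm), `condition_number`, `n_frames` and
#'   `singular_values`.
#' @export
solve_center_regression <- function(A, B, rank_tol = 1e-8) {
  stopifnot(is.matrix(A), ncol(A) == 6L, length(B) == nrow(A))
  s <- svd(A)
  if (s$d[6L] < rank_tol * s$d[1L]) {
    stop_cond("rank_deficient",
              paste0("insufficient relative rotation between segments: ",
                     "smallest singular value %.3g (largest %.3g)"),
              s$d[6L], s$d[1L])
  }
  X <- as.vector(s$v %*% ((t(s$u) %*% B) / s$d))
  names(X) <- letters[1:6]
  r <- A %*% X - B
  structure(list(params = X,
                 residual_rms = sqrt(mean(r^2)),
                 condition_number = s$d[1L] / s$d[6L],
                 n_frames = nrow(A) / 3L,
                 singular_values = s$d),
            class = "center_regression")
}

#' @export
print.center_regression <- function(x, ...) {
  cat("<center_regression>\n  params:",
      paste(sprintf("%s=%.5g", names(x$params), x$params), collapse = " "), "\n")
  cat(sprintf("  residual RMS %.4g mm, condition %.3g, %d frames\n",
              x$residual_rms, x$condition_number, x$n_frames))
  invisible(x)
}

#' Per-frame GH-centre series, displacement and magnification ratios
#'
#' Reconstructs the centre from the scapula side (a, b, c) and the
#' humerus side (d, e, f) per frame; the reported centre is the midpoint
#' of the two, with their disagreement kept as a per-frame quality metric.
#' Displacement is taken relative to the reference frame (the first
#' usable frame by default, i.e. the natural hanging posture in a raising
#' trial), and magnification ratios are the displacement components
#' divided by d0, the IJ-to-centre distance at the reference (the thorax
#' origin is IJ, so d0 is the norm of the reference centre).
#'
#' @param solution a [solve_center_regression()] result.
#' @param bases per-frame bases (list of `frame_basis` or batch form).
#' @param d0 normalization distance in mm; computed from the reference
#'   frame when `NULL`.
#' @param reference_frame row index of the reference frame (default 1).
#' @return An object of class `gh_center_series`: matrices `J`, `J_scap`,
#'   `J_hum`, `displacement`, `ratio` (n x 3), vector `discrepancy` (mm)
#'   and scalar `d0` (mm).
#' @export
gh_center_series <- function(solution, bases, d0 = NULL, reference_frame = 1L) {
  stopifnot(inherits(solution, "center_regression"))
  b <- as_bases_batch(bases)
  p <- solution$params
  J_scap <- b$q4 + p["a"] * b$q1 + p["b"] * b$q2 + p["c"] * b$q3
  J_hum <- b$q8 + p["d"] * b$q5 + p["e"] * b$q6 + p["f"] * b$q7
  J <- 0.5 * (J_scap + J_hum)
  colnames(J) <- colnames(J_scap) <- colnames(J_hum) <- c("x", "y", "z")
  discrepancy <- row_norms(J_scap - J_hum)
  dJ <- sweep(J, 2L, J[reference_frame, ])
  if (is.null(d0)) d0 <- sqrt(sum(J[reference_frame, ]^2))
  if (!is.finite(d0) || d0 < 50) {
    stop_cond("implausible_geometry",
              "IJ-to-GH distance d0 = %.3g mm is implausibly small", d0)
  }
  structure(list(J = J, J_scap = J_scap, J_hum = J_hum,
                 discrepancy = discrepancy, displacement = dJ,
                 d0 = d0, ratio = dJ / d0,
                 reference_frame = as.integer(reference_frame)),
            class = "gh_center_series")
}

#' @export
as.data.frame.gh_center_series <- function(x, ...) {
  data.frame(frame = seq_len(nrow(x$J)),
             Jx = x$J[, 1L], Jy = x$J[, 2L], Jz = x$J[, 3L],
             dJx = x$displacement[, 1L], dJy = x$displacement[, 2L],
             dJz = x$displacement[, 3L],
             ratio_x = x$ratio[, 1L], ratio_y = x$ratio[, 2L],
             ratio_z = x$ratio[, 3L],
             discrepancy_mm = x$discrepancy)
}

#' @export
print.gh_center_series <- function(x, ...) {
  cat(sprintf("<gh_center_series> %d frames, d0 = %.2f mm\n", nrow(x$J), x$d0))
  cat(sprintf("  median side discrepancy %.4g mm\n", median(x$discrepancy)))
  invisible(x)
}
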