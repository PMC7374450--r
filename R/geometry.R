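# Small 3-D geometry helpers shared across modules. Internal.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Cross product of two 3-vectors
#' @param a,b numeric 3-vectors.
#' @return numeric 3-vector `a x b`.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two n x 3 matrices.
rowwise_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

row_norms <- function(A) sqrt(rowSums(A^2))

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Elementary rotation matrices; `deg` in degrees. Right-handed, active.
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

as_point3 <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) != 3L) {
    stop(sprintf("'%s' must be a numeric 3-vector", name))
  }
  x
}

stop_cond <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ghfloat_error")))
}

warn_cond <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "ghfloat_warning")))
}
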