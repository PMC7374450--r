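# Coupling models (magnification ratio vs elevation angle), phase
# segmentation, cross-trial averaging and fitting.

poly_eval <- function(coefficients, x) {
  # Horner, coefficients in descending degree
  out <- rep(coefficients[1L], length(x))
  for (ck in coefficients[-1L]) out <- out * x + ck
  out
}

axis_eval <- function(spec, theta) {
  switch(spec$kind,
         polynomial = poly_eval(spec$coefficients, theta),
         rational = {
           off <- if (is.null(spec$offset)) 0 else spec$offset
           poly_eval(spec$numerator, theta) /
             poly_eval(spec$denominator, theta) + off
         },
         stop(sprintf("unknown curve kind '%s'", spec$kind)))
}

#' Construct a coupling model
#'
#' A coupling model holds one parametric curve per displacement axis
#' relating the dimensionless magnification ratio of the GH-centre
#' displacement (in the thorax frame) to the humeral elevation angle.
#'
#' @param axes named list (names are axis labels, usually `x`, `y`, `z`);
#'   each element is a list with `kind = "polynomial"` and `coefficients`
#'   (descending degree), or `kind = "rational"` with `numerator`,
#'   `denominator` (descending degree) and optional additive `offset`.
#' @param phase phase tag (`"raising"`, `"lowering"`, `"RAL"`, ...).
#' @param validity_deg validity range of the elevation angle, degrees.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(axes, phase = "raising", validity_deg = c(0, 150)) {
  stopifnot(is.list(axes), length(axes) >= 1L, !is.null(names(axes)))
  for (nm in names(axes)) {
    spec <- axes[[nm]]
    if (!spec$kind %in% c("polynomial", "rational")) {
      stop(sprintf("axis '%s': unknown kind '%s'", nm, spec$kind))
    }
    if (spec$kind == "rational") {
      check_denominator_poles(spec$denominator, validity_deg)
    }
  }
  structure(list(axes = axes, phase = phase,
                 validity_deg = as.numeric(validity_deg)),
            class = "coupling_model")
}

check_denominator_poles <- function(den, range, tol = 1e-8) {
  r <- polyroot(rev(den))
  real <- r[abs(Im(r)) < tol * pmax(1, abs(r))]
  inside <- Re(real) >= range[1L] - tol & Re(real) <= range[2L] + tol
  if (any(inside)) {
    stop_cond("pole_in_range",
              "rational denominator has a root at %.4g inside [%g, %g]",
              Re(real[inside][1L]), range[1L], range[2L])
  }
  invisible(TRUE)
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("<coupling_model> phase=%s, valid on [%g, %g] deg\n",
              x$phase, x$validity_deg[1L], x$validity_deg[2L]))
  for (nm in names(x$axes)) {
    spec <- x$axes[[nm]]
    deg <- if (spec$kind == "polynomial") length(spec$coefficients) - 1L
           else length(spec$numerator) - 1L
    cat(sprintf("  %s: %s (degree %d)\n", nm, spec$kind, deg))
  }
  invisible(x)
}

#' Evaluate a coupling model
#'
#' @param model a [coupling_model()].
#' @param theta elevation angle(s), degrees, within the validity range.
#' @param remove_constant subtract the theta = 0 value per axis, so the
#'   curve describes pure displacement from the hanging posture.
#' @return Matrix `length(theta)` x n_axes with axis names as columns.
#' @export
evaluate_coupling <- function(model, theta, remove_constant = FALSE) {
  stopifnot(inherits(model, "coupling_model"))
  theta <- as.numeric(theta)
  tol <- 1e-9
  if (any(theta < model$validity_deg[1L] - tol |
          theta > model$validity_deg[2L] + tol)) {
    stop_cond("range_error",
              "theta outside model validity range [%g, %g]",
              model$validity_deg[1L], model$validity_deg[2L])
  }
  out <- vapply(model$axes, function(spec) {
    v <- axis_eval(spec, theta)
    if (remove_constant) v <- v - axis_eval(spec, 0) else v
  }, numeric(length(theta)))
  if (length(theta) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(model$axes)))
  out
}

#' Packaged coupling models
#'
#' Loads the built-in phase-specific coupling models shipped with the
#' package: the raising, lowering and RAL (raising-and-lowering) cubic /
#' quartic polynomial models, and the four-plane comparative ("CAK")
#' model whose y axis is a quadratic-over-quadratic rational curve and
#' which carries an additional resultant-magnitude axis `d`.
#'
#' @param phase one of `"raising"`, `"lowering"`, `"ral"`, `"cak"`.
#' @return A [coupling_model()].
#' @export
builtin_coupling_model <- function(phase = c("raising", "lowering", "ral", "cak")) {
  phase <- match.arg(phase)
  path <- system.file("extdata", "models", paste0(phase, ".json"),
                      package = "ghfloat", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  axes <- lapply(doc$axes, function(a) a[!vapply(a, is.null, logical(1L))])
  coupling_model(axes, phase = doc$phase, validity_deg = doc$validity_deg)
}

#' Construct a ratio curve
#'
#' One phase's magnification-ratio curve: per-angle 3-vectors of the
#' dimensionless x, y, z displacement ratios over a grid of elevation
#' angles. Angles are sorted increasing and duplicate angles are averaged.
#'
#' @param theta elevation angles (deg), within \[0, 150\].
#' @param ratios n x 3 matrix (columns x, y, z).
#' @param phase phase tag.
#' @param provenance free-form list of subject/plane/rep tags.
#' @return An object of class `ratio_curve`.
#' @export
ratio_curve <- function(theta, ratios, phase = "raising", provenance = list()) {
  theta <- as.numeric(theta)
  ratios <- as.matrix(ratios)
  stopifnot(length(theta) == nrow(ratios), ncol(ratios) == 3L)
  if (!all(is.finite(theta)) || !all(is.finite(ratios))) {
    stop_cond("invalid_curve", "ratio curve has non-finite values")
  }
  # clip to the elevation validity range; angles within a hair of the
  # bounds (acos round-trip error) are clamped rather than dropped
  tol <- 1e-6
  keep <- theta >= -tol & theta <= 150 + tol
  theta <- pmin(pmax(theta[keep], 0), 150)
  ratios <- ratios[keep, , drop = FALSE]
  if (length(theta) < 2L) {
    stop_cond("invalid_curve", "ratio curve needs >= 2 points in [0, 150]")
  }
  o <- order(theta)
  theta <- theta[o]; ratios <- ratios[o, , drop = FALSE]
  if (anyDuplicated(theta)) {
    agg <- rowsum(cbind(1, ratios), group = theta, reorder = TRUE)
    theta <- as.numeric(rownames(agg))
    ratios <- agg[, -1L, drop = FALSE] / agg[, 1L]
  }
  colnames(ratios) <- c("x", "y", "z")
  structure(list(theta = theta, ratios = ratios, phase = phase,
                 provenance = provenance),
            class = "ratio_curve")
}

#' @export
print.ratio_curve <- function(x, ...) {
  cat(sprintf("<ratio_curve> phase=%s, %d points on [%.1f, %.1f] deg\n",
              x$phase, length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Split a trial into raising and lowering ratio curves
#'
#' Splits the trial at the global elevation maximum. The lowering segment
#' is re-indexed so its curve is expressed over increasing elevation, as
#' when all phases are reported over 0-150 degrees. Segments spanning
#' less than `min_span` degrees are dropped.
#'
#' @param theta per-frame elevation angles (deg).
#' @param ratios n x 3 matrix of magnification ratios.
#' @param phase phase tag recorded on the curves (segment tags
#'   `"raising"` / `"lowering"` are set per output).
#' @param provenance forwarded to [ratio_curve()].
#' @param min_span minimum angular span (deg) for a segment to count.
#' @return list with elements `raising` and/or `lowering` (ratio curves);
#'   absent phases are omitted.
#' @export
segment_phases <- function(theta, ratios, phase = "RAL",
                           provenance = list(), min_span = 5) {
  theta <- as.numeric(theta)
  ratios <- as.matrix(ratios)
  stopifnot(length(theta) == nrow(ratios))
  i_pk <- which.max(theta)
  out <- list()
  # a noisy segment may collapse to < 2 in-range points once clipped to
  # [0, 150]; such slivers are dropped, not fatal
  seg_curve <- function(idx, tag) {
    tryCatch(ratio_curve(theta[idx], ratios[idx, , drop = FALSE],
                         phase = tag, provenance = provenance),
             invalid_curve = function(e) NULL)
  }
  if (theta[i_pk] - theta[1L] > min_span && i_pk >= 2L) {
    out$raising <- seg_curve(1:i_pk, "raising")
  }
  n <- length(theta)
  if (i_pk <= n - 1L && theta[i_pk] - theta[n] > min_span) {
    out$lowering <- seg_curve(n:i_pk, "lowering")  # reversed: increasing
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    stop_cond("missing_phase",
              "elevation series spans neither a rise nor a fall > %g deg",
              min_span)
  }
  out
}

#' Resample ratio curves onto a grid and average
#'
#' Linear interpolation of each curve onto the grid, then the unweighted
#' mean across curves. Curves that do not cover the whole grid span are
#' excluded with a warning.
#'
#' @param curves list of [ratio_curve()] objects.
#' @param grid angle grid (deg); default 0, 1, ..., 150.
#' @return A [ratio_curve()] holding the mean, with the number of
#'   averaged curves in its provenance.
#' @export
resample_and_average <- function(curves, grid = seq(0, 150, by = 1)) {
  if (inherits(curves, "ratio_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1L), "ratio_curve")))
  grid <- sort(as.numeric(grid))
  eps <- 1e-9
  covers <- vapply(curves, function(cv) {
    min(cv$theta) <= min(grid) + eps && max(cv$theta) >= max(grid) - eps
  }, logical(1L))
  if (!all(covers)) {
    warn_cond("curve_excluded",
              "%d of %d curves do not cover the grid span and were excluded",
              sum(!covers), length(curves))
    curves <- curves[covers]
  }
  if (!length(curves)) {
    stop_cond("no_coverage", "no curve covers the requested grid")
  }
  arr <- vapply(curves, function(cv) {
    vapply(1:3, function(j) {
      # rule = 2: the coverage guard above limits extrapolation to the
      # eps-sized float slack at the grid ends
      approx(cv$theta, cv$ratios[, j], xout = grid, ties = mean, rule = 2)$y
    }, numeric(length(grid)))
  }, matrix(0, length(grid), 3L))
  mean_mat <- apply(arr, c(1L, 2L), mean)
  ratio_curve(grid, mean_mat, phase = curves[[1L]]$phase,
              provenance = list(n_curves = length(curves)))
}

#' Fit-quality report
#'
#' The four curve-fitting indexes used for model selection: SSE, RMSE,
#' R-square and degree-of-freedom-adjusted R-square. RMSE uses n - p
#' degrees of freedom by default (curve-fitting-toolbox convention);
#' `df_adjust = FALSE` gives the plain sqrt(SSE / n). When the response
#' has zero variance, R-square is defined as 0.
#'
#' @param y observed values; `yhat` fitted values.
#' @param yhat numeric vector.
#' @param n_params number of fitted parameters p.
#' @param df_adjust logical; see above.
#' @return An object of class `fit_report` with `SSE`, `RMSE`,
#'   `R_square`, `adjusted_R_square`, `n_points`, `n_params`.
#' @export
fit_report <- function(y, yhat, n_params, df_adjust = TRUE) {
  n <- length(y)
  stopifnot(length(yhat) == n, n_params >= 1L, n > n_params)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_params)
  rmse <- if (df_adjust) sqrt(sse / (n - n_params)) else sqrt(sse / n)
  structure(list(SSE = sse, RMSE = rmse, R_square = r2,
                 adjusted_R_square = adj, n_points = n, n_params = n_params),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("SSE=%.4g RMSE=%.4g R2=%.5f adjR2=%.5f (n=%d, p=%d)\n",
              x$SSE, x$RMSE, x$R_square, x$adjusted_R_square,
              x$n_points, x$n_params))
  invisible(x)
}

report_passes <- function(rep, criteria) {
  rep$R_square > criteria$min_r2 &&
    rep$adjusted_R_square > criteria$min_r2 &&
    rep$SSE < criteria$max_err &&
    rep$RMSE < criteria$max_err
}

# Least-squares polynomial fit on theta scaled to [0, 1] for conditioning;
# returns coefficients in descending degree on the original scale.
poly_ls <- function(theta, y, degree) {
  scale <- max(abs(theta), 1)
  t_s <- theta / scale
  Xm <- outer(t_s, degree:0, `^`)
  cf <- qr.solve(Xm, y)
  cf / scale^(degree:0)
}

#' Fit per-axis polynomial coupling models
#'
#' Fits least-squares polynomials of each candidate degree per axis and
#' selects, per axis, the lowest degree whose fit indexes meet the
#' criteria (R-square and adjusted R-square above `min_r2`, SSE and RMSE
#' below `max_err`); if no candidate passes, the degree minimizing RMSE
#' is used (near-misses are common on real mean curves).
#'
#' @param mean_curve a [ratio_curve()] (typically the cohort mean).
#' @param degrees candidate degrees: a numeric vector applied to every
#'   axis, or a named list (`x`, `y`, `z`) of per-axis candidates (a
#'   single degree per axis pins the model order, e.g. for recovery
#'   studies at known order).
#' @param criteria list with `min_r2` (default 0.995) and `max_err`
#'   (default 0.005).
#' @param df_adjust forwarded to [fit_report()].
#' @return list with `model` (a [coupling_model()]) and `reports`: per
#'   axis, the selected degree, whether it passed, and a [fit_report()]
#'   per candidate degree.
#' @export
fit_polynomial_model <- function(mean_curve, degrees = 2:5,
                                 criteria = list(min_r2 = 0.995,
                                                 max_err = 0.005),
                                 df_adjust = TRUE) {
  stopifnot(inherits(mean_curve, "ratio_curve"))
  theta <- mean_curve$theta
  if (diff(range(theta)) <= 0) {
    stop_cond("degenerate_grid", "constant elevation grid; cannot fit")
  }
  axes_names <- colnames(mean_curve$ratios)
  deg_list <- if (is.list(degrees)) degrees else
    setNames(rep(list(as.integer(degrees)), length(axes_names)), axes_names)
  if (length(theta) < max(unlist(deg_list)) + 2L) {
    stop_cond("insufficient_data",
              "need at least max(degree) + 2 points, got %d", length(theta))
  }
  axes <- list()
  reports <- list()
  for (ax in axes_names) {
    cands <- sort(as.integer(deg_list[[ax]]))
    y <- mean_curve$ratios[, ax]
    fits <- lapply(cands, function(d) {
      cf <- poly_ls(theta, y, d)
      list(degree = d, coefficients = cf,
           report = fit_report(y, poly_eval(cf, theta), n_params = d + 1L,
                               df_adjust = df_adjust))
    })
    pass <- vapply(fits, function(f) report_passes(f$report, criteria),
                   logical(1L))
    sel <- if (any(pass)) which(pass)[1L] else
      which.min(vapply(fits, function(f) f$report$RMSE, numeric(1L)))
    axes[[ax]] <- list(kind = "polynomial",
                       coefficients = fits[[sel]]$coefficients)
    reports[[ax]] <- list(
      selected_degree = fits[[sel]]$degree,
      selected_passed = pass[sel],
      candidates = setNames(lapply(fits, `[[`, "report"),
                            paste0("degree_", cands)))
  }
  list(model = coupling_model(axes, phase = mean_curve$phase,
                              validity_deg = range(theta)),
       reports = reports)
}

#' Fit a rational (quadratic over monic quadratic) coupling curve
#'
#' Fits y(theta) = (n2 t^2 + n1 t + n0) / (t^2 + d1 t + d0) by nonlinear
#' least squares. Initialization is the classic linearization (multiply
#' through by the denominator and solve the resulting linear system);
#' the refined fit is rejected if the denominator has a real root inside
#' the data range.
#'
#' @param theta elevation angles (deg); `y` the response.
#' @param y numeric vector.
#' @param max_iter iteration budget for the Levenberg-Marquardt refinement.
#' @param df_adjust forwarded to [fit_report()].
#' @return list with `axis_spec` (a rational curve spec usable inside
#'   [coupling_model()]) and `report` (a [fit_report()]).
#' @export
fit_rational_model <- function(theta, y, max_iter = 200, df_adjust = TRUE) {
  theta <- as.numeric(theta); y <- as.numeric(y)
  stopifnot(length(theta) == length(y))
  if (length(theta) < 7L) {
    stop_cond("insufficient_data",
              "rational 2/2 fit needs >= 7 points, got %d", length(theta))
  }
  rat_eval <- function(p, t) {
    (p[1L] * t^2 + p[2L] * t + p[3L]) / (t^2 + p[4L] * t + p[5L])
  }
  resid_fn <- function(p) y - rat_eval(p, theta)
  # start 1: classic linearization y (t^2 + d1 t + d0) = n2 t^2 + n1 t + n0
  # (ill-posed when y itself is polynomial, hence the fallback);
  # start 2: near-constant denominator carrying a plain quadratic fit
  Xl <- cbind(theta^2, theta, 1, -y * theta, -y)
  init <- tryCatch(unname(qr.solve(Xl, y * theta^2)), error = function(e) NULL)
  d0_flat <- 4 * max(theta)^2
  starts <- list(c(d0_flat * poly_ls(theta, y, 2L), 0, d0_flat))
  if (!is.null(init) && all(is.finite(init))) starts <- c(list(init), starts)
  best <- NULL
  last_err <- "no start point attempted"
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (is.null(fit)) next
    if (!fit$info %in% 1:4 || !all(is.finite(fit$par))) {
      last_err <- fit$message
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop_cond("fit_failure", "rational fit did not converge: %s", last_err)
  }
  p <- setNames(best$par, c("n2", "n1", "n0", "d1", "d0"))
  check_denominator_poles(c(1, p[["d1"]], p[["d0"]]), range(theta))
  yhat <- rat_eval(best$par, theta)
  list(axis_spec = list(kind = "rational",
                        numerator = unname(p[c("n2", "n1", "n0")]),
                        denominator = c(1, unname(p[c("d1", "d0")])),
                        offset = 0),
       report = fit_report(y, yhat, n_params = 5L, df_adjust = df_adjust))
}

#' Export a coupling model to JSON
#'
#' @param model a [coupling_model()]; `path` output file.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_coupling_model <- function(model, path) {
  stopifnot(inherits(model, "coupling_model"))
  doc <- list(phase = model$phase, validity_deg = model$validity_deg,
              axes = model$axes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a coupling model from JSON
#'
#' @param path file path produced by [write_coupling_model()].
#' @return A [coupling_model()].
#' @export
read_coupling_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  coupling_model(doc$axes, phase = doc$phase, validity_deg = doc$validity_deg)
}
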