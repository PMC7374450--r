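# Marker trajectory container, CSV dialect, and triple selection.

#' Marker vocabulary
#'
#' The fourteen marker labels used throughout the package: four thorax
#' markers (C7, T8, IJ, PX, per the ISB thorax convention), the humeral
#' epicondyles (EL lateral, EM medial), a four-marker scapula block
#' (SCA1-SCA4) on the acromion and a four-marker humerus block (UPA1-UPA4)
#' on an upper-arm flange.
#'
#' @format Character vectors of marker labels.
#' @export
MARKER_LABELS <- c("C7", "T8", "IJ", "PX", "EL", "EM",
                   paste0("SCA", 1:4), paste0("UPA", 1:4))

#' @rdname MARKER_LABELS
#' @export
SCAPULA_CLUSTER <- paste0("SCA", 1:4)

#' @rdname MARKER_LABELS
#' @export
HUMERUS_CLUSTER <- paste0("UPA", 1:4)

THORAX_MARKERS <- c("C7", "T8", "IJ", "PX")

#' Construct a marker trajectory set
#'
#' One motion-capture trial: time-indexed, labelled 3-D marker positions
#' (global coordinates, mm) with per-sample visibility flags plus trial
#' metadata.
#'
#' @param data data.frame with columns `frame` (integer, >= 0), `label`
#'   (one of [MARKER_LABELS]), `x_mm`, `y_mm`, `z_mm` (numeric; may be `NA`
#'   when invisible) and `visible` (logical or 0/1).
#' @param rate sampling frequency in Hz (> 0).
#' @param subject subject identifier.
#' @param phase one of `"raising"`, `"lowering"`, `"RAL"`.
#' @param plane_deg guided elevation-plane angle in degrees.
#' @param rep repetition index.
#' @return An object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(data, rate, subject = "S01",
                                  phase = c("raising", "lowering", "RAL"),
                                  plane_deg = 0, rep = 1L) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(data))
  needed <- c("frame", "label", "x_mm", "y_mm", "z_mm", "visible")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_cond("parse_error", "missing columns: %s",
              paste(missing_cols, collapse = ", "))
  }
  data <- data[needed]
  data$frame <- as.integer(data$frame)
  data$label <- as.character(data$label)
  data$visible <- as.logical(data$visible)
  for (cc in c("x_mm", "y_mm", "z_mm")) data[[cc]] <- as.numeric(data[[cc]])
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop_cond("invalid_rate", "'rate' must be a single positive number")
  }
  bad <- setdiff(unique(data$label), MARKER_LABELS)
  if (length(bad)) {
    stop_cond("unknown_label", "unknown marker label(s): %s",
              paste(bad, collapse = ", "))
  }
  if (any(data$frame < 0, na.rm = TRUE)) {
    stop_cond("parse_error", "negative frame indices")
  }
  if (anyDuplicated(data[c("frame", "label")])) {
    stop_cond("duplicate_sample",
              "duplicate (frame, label) samples in trial")
  }
  # positions must be finite when visible; invisible positions set to NA
  pos <- as.matrix(data[c("x_mm", "y_mm", "z_mm")])
  bad_vis <- data$visible & !apply(is.finite(pos), 1L, all)
  if (any(bad_vis)) {
    stop_cond("invalid_sample",
              "non-finite position for visible sample(s), e.g. frame %d label %s",
              data$frame[which(bad_vis)[1L]], data$label[which(bad_vis)[1L]])
  }
  data[!data$visible, c("x_mm", "y_mm", "z_mm")] <- NA_real_
  data <- data[order(data$frame, match(data$label, MARKER_LABELS)), ]
  rownames(data) <- NULL
  structure(list(data = data, rate = rate, subject = as.character(subject),
                 phase = phase, plane_deg = as.numeric(plane_deg),
                 rep = as.integer(rep)),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<marker_trajectory_set> subject=%s phase=%s plane=%g deg rep=%d\n",
    x$subject, x$phase, x$plane_deg, x$rep))
  cat(sprintf("  %d frames at %g Hz, %d samples (%d invisible)\n",
              length(unique(x$data$frame)), x$rate, nrow(x$data),
              sum(!x$data$visible)))
  invisible(x)
}

#' Frame usability
#'
#' A frame is usable when at least three markers of each of the scapula
#' and humerus clusters are visible (a rigid-body pose needs three
#' noncollinear points).
#'
#' @param set a [marker_trajectory_set()].
#' @return named logical vector indexed by frame.
#' @export
usable_frames <- function(set) {
  d <- set$data
  frames <- sort(unique(d$frame))
  ok <- vapply(frames, function(f) {
    di <- d[d$frame == f & d$visible, "label"]
    sum(di %in% SCAPULA_CLUSTER) >= 3L && sum(di %in% HUMERUS_CLUSTER) >= 3L
  }, logical(1L))
  names(ok) <- frames
  ok
}

fmt_g17 <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a marker trajectory set to the package CSV dialect
#'
#' The dialect is a single metadata header line
#' `# rate_hz=<f> subject=<id> phase=<tag> plane_deg=<f> rep=<i>` followed
#' by `frame,label,x_mm,y_mm,z_mm,visible` rows. Positions are written
#' with 17 significant digits so finite values round-trip bit-exactly.
#'
#' @param set a [marker_trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_trajectories <- function(set, path) {
  stopifnot(inherits(set, "marker_trajectory_set"))
  d <- set$data
  header <- sprintf("# rate_hz=%.17g subject=%s phase=%s plane_deg=%.17g rep=%d",
                    set$rate, set$subject, set$phase, set$plane_deg, set$rep)
  lines <- c(header, "frame,label,x_mm,y_mm,z_mm,visible")
  if (nrow(d)) {
    lines <- c(lines, paste(d$frame, d$label, fmt_g17(d$x_mm), fmt_g17(d$y_mm),
                            fmt_g17(d$z_mm), as.integer(d$visible), sep = ","))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_cond("unwritable_path", "cannot write '%s'", path)
  invisible(path)
}

#' Read marker trajectories
#'
#' Reads the package CSV dialect (see [write_marker_trajectories()]).
#' Samples with missing coordinates are marked invisible; unknown marker
#' labels are rejected.
#'
#' @param path input file path.
#' @param dialect `"csv"` (native dialect). `"c3d"` is recognised as the
#'   field-standard container but not read by this package; convert to the
#'   CSV dialect first.
#' @return A validated [marker_trajectory_set()].
#' @export
read_marker_trajectories <- function(path, dialect = c("csv", "c3d")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cond("missing_file", "no such file: '%s'", path)
  if (dialect == "c3d") {
    stop_cond("unsupported_dialect",
              "C3D reading is not provided; export the trial to the CSV dialect")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop_cond("parse_error", "'%s': truncated file", path)
  m <- regmatches(lines[1L], regexec(
    "^#\\s*rate_hz=(\\S+)\\s+subject=(\\S+)\\s+phase=(\\S+)\\s+plane_deg=(\\S+)\\s+rep=(\\S+)\\s*$",
    lines[1L]))[[1L]]
  if (length(m) != 6L) {
    stop_cond("parse_error", "'%s' line 1: malformed metadata header", path)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_cond("empty_trial", "'%s': no frames", path)
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop_cond("parse_error", "'%s' line %d: expected 6 fields, found %d",
              path, which(nf != 6L)[1L] + 2L, nf[nf != 6L][1L])
  }
  fm <- do.call(rbind, fields)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  frame <- suppressWarnings(as.integer(fm[, 1L]))
  if (anyNA(frame)) {
    stop_cond("parse_error", "'%s' line %d: bad frame index",
              path, which(is.na(frame))[1L] + 2L)
  }
  vis <- num(fm[, 6L])
  if (anyNA(vis) || !all(vis %in% c(0, 1))) {
    stop_cond("parse_error", "'%s': 'visible' must be 0 or 1", path)
  }
  d <- data.frame(frame = frame, label = fm[, 2L],
                  x_mm = num(fm[, 3L]), y_mm = num(fm[, 4L]),
                  z_mm = num(fm[, 5L]), visible = as.logical(vis),
                  stringsAsFactors = FALSE)
  # missing coordinates imply invisibility regardless of the flag
  d$visible <- d$visible & is.finite(d$x_mm) & is.finite(d$y_mm) & is.finite(d$z_mm)
  marker_trajectory_set(d, rate = as.numeric(m[2L]), subject = m[3L],
                        phase = m[4L], plane_deg = as.numeric(m[5L]),
                        rep = as.integer(m[6L]))
}

#' Select a noncollinear marker triple from a 4-marker cluster
#'
#' Picks, among the visible markers, the triple with the largest triangle
#' area, so the rigid-body basis built from it is as well conditioned as
#' possible. Ties are broken lexicographically by label and the returned
#' triple is always in lexicographic order so downstream bases are
#' reproducible.
#'
#' @param positions 4 x 3 numeric matrix of marker positions (mm) with
#'   rownames giving the labels.
#' @param visible logical 4-vector (default all visible).
#' @param area_tol triangles with area below this (mm^2) count as
#'   collinear; default 1 mm^2.
#' @return Character vector of three labels.
#' @export
select_marker_triple <- function(positions, visible = NULL, area_tol = 1) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || is.null(rownames(positions))) {
    stop("'positions' must be a labelled n x 3 matrix")
  }
  if (is.null(visible)) visible <- rep(TRUE, nrow(positions))
  if (sum(visible) < 3L) {
    stop_cond("frame_unusable",
              "fewer than 3 visible markers in cluster (%d visible)",
              sum(visible))
  }
  labs <- sort(rownames(positions)[visible])
  combos <- utils::combn(labs, 3L, simplify = FALSE)
  areas <- vapply(combos, function(tr) {
    p <- positions[tr, , drop = FALSE]
    0.5 * sqrt(sum(cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])^2))
  }, numeric(1L))
  if (max(areas) < area_tol) {
    stop_cond("collinear_cluster",
              "all candidate triples are collinear (max area %.3g mm^2)",
              max(areas))
  }
  combos[[which.max(areas)]]   # first maximum = lexicographic tie-break
}
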