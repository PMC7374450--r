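# Trial-level analysis chain: thorax transform, triple selection,
# regression bases, centre series, elevation kinematics, ratio curves.

# Wide per-label position matrices (n_frames x 3) and a visibility matrix.
trial_matrices <- function(set) {
  d <- set$data
  frames <- sort(unique(d$frame))
  n <- length(frames)
  pos <- setNames(vector("list", length(MARKER_LABELS)), MARKER_LABELS)
  vis <- matrix(FALSE, n, length(MARKER_LABELS),
                dimnames = list(NULL, MARKER_LABELS))
  idx <- match(d$frame, frames)
  for (lab in MARKER_LABELS) {
    m <- matrix(NA_real_, n, 3L)
    sel <- d$label == lab
    m[idx[sel], ] <- as.matrix(d[sel, c("x_mm", "y_mm", "z_mm")])
    pos[[lab]] <- m
    vis[idx[sel], lab] <- d$visible[sel]
  }
  list(frames = frames, pos = pos, vis = vis)
}

#' Prepare a trial for centre estimation
#'
#' Builds per-frame thorax frames, selects one noncollinear marker triple
#' per cluster on the first usable frame (held fixed for the whole trial
#' so the regression basis is consistent over time), transforms the
#' triple and epicondyle markers into thorax coordinates on the usable
#' frames, and forms the regression basis vectors.
#'
#' A frame is usable here when all four thorax markers, the selected
#' triples and both epicondyles are visible.
#'
#' @param set a [marker_trajectory_set()].
#' @param triples optional list with `scapula` and `humerus` label
#'   triples to use instead of selecting on the first usable frame. The
#'   regression pools frames under one parameter vector, so all trials
#'   pooled together must share the same triples; [analyze_cohort()]
#'   selects them on each subject's first trial and passes them here.
#' @return list with `bases` (batch q1..q8 matrices), `frames` (usable
#'   frame indices), `triples`, `EL`/`EM` (thorax coordinates, usable
#'   frames), `n_total`, `skew_deg` and the trial metadata.
#' @export
prepare_trial <- function(set, triples = NULL) {
  stopifnot(inherits(set, "marker_trajectory_set"))
  tm <- trial_matrices(set)
  thorax_ok <- rowSums(tm$vis[, THORAX_MARKERS, drop = FALSE]) == 4L
  cl_ok <- rowSums(tm$vis[, SCAPULA_CLUSTER, drop = FALSE]) >= 3L &
    rowSums(tm$vis[, HUMERUS_CLUSTER, drop = FALSE]) >= 3L
  elbow_ok <- tm$vis[, "EL"] & tm$vis[, "EM"]
  cand <- which(thorax_ok & cl_ok & elbow_ok)
  if (!length(cand)) {
    stop_cond("frame_unusable", "trial has no usable frame")
  }
  f0 <- cand[1L]
  pick <- function(cluster) {
    p <- do.call(rbind, lapply(cluster, function(l) tm$pos[[l]][f0, ]))
    rownames(p) <- cluster
    select_marker_triple(p, tm$vis[f0, cluster])
  }
  if (is.null(triples)) {
    scap_triple <- pick(SCAPULA_CLUSTER)
    hum_triple <- pick(HUMERUS_CLUSTER)
  } else {
    scap_triple <- triples$scapula
    hum_triple <- triples$humerus
    stopifnot(all(scap_triple %in% SCAPULA_CLUSTER),
              all(hum_triple %in% HUMERUS_CLUSTER))
  }
  triple_ok <- rowSums(tm$vis[, scap_triple, drop = FALSE]) == 3L &
    rowSums(tm$vis[, hum_triple, drop = FALSE]) == 3L
  usable <- which(thorax_ok & triple_ok & elbow_ok)
  if (length(usable) < 2L) {
    stop_cond("insufficient_data",
              "fewer than 2 usable frames after triple selection")
  }
  axes <- thorax_axes_batch(tm$pos$C7[usable, , drop = FALSE],
                            tm$pos$T8[usable, , drop = FALSE],
                            tm$pos$IJ[usable, , drop = FALSE],
                            tm$pos$PX[usable, , drop = FALSE])
  local <- function(lab) to_thorax_batch(axes, tm$pos[[lab]][usable, , drop = FALSE])
  bases <- bases_batch(lapply(scap_triple, local), lapply(hum_triple, local))
  list(bases = bases, frames = tm$frames[usable],
       triples = list(scapula = scap_triple, humerus = hum_triple),
       EL = local("EL"), EM = local("EM"),
       n_total = length(tm$frames), skew_deg = axes$skew_deg,
       subject = set$subject, phase = set$phase,
       plane_deg = set$plane_deg, rep = set$rep)
}

#' Estimate the GH centre from one or more prepared trials
#'
#' Pools the regression bases of all supplied trials (typically one
#' subject's trials, since the centre's local coordinates are
#' subject-specific) and solves the invariance regression.
#'
#' @param preps a [prepare_trial()] result or a list of them.
#' @param rank_tol forwarded to [solve_center_regression()].
#' @return A [solve_center_regression()] object.
#' @export
estimate_gh_center <- function(preps, rank_tol = 1e-8) {
  if (!is.null(preps$bases)) preps <- list(preps)
  systems <- lapply(preps, function(p) assemble_center_system(p$bases))
  A <- do.call(rbind, lapply(systems, `[[`, "A"))
  B <- do.call(c, lapply(systems, `[[`, "B"))
  solve_center_regression(A, B, rank_tol = rank_tol)
}

#' Per-trial kinematics from a centre solution
#'
#' Reconstructs the centre series, the humeral axis (elbow midpoint minus
#' centre), the elevation angle and the elevation-plane angle for each
#' usable frame of a prepared trial.
#'
#' @param prep a [prepare_trial()] result.
#' @param solution a [solve_center_regression()] object for the trial's
#'   subject.
#' @param d0 optional normalization distance override (mm).
#' @return list with `series` (a [gh_center_series()]), `theta`, `eta`
#'   (degrees, per usable frame) and the prepared trial's metadata.
#' @export
trial_kinematics <- function(prep, solution, d0 = NULL) {
  series <- gh_center_series(solution, prep$bases, d0 = d0)
  D <- 0.5 * (prep$EL + prep$EM) - series$J
  theta <- elevation_angle(D)
  eta <- elevation_plane_angle(D)
  list(series = series, theta = theta, eta = eta, frames = prep$frames,
       subject = prep$subject, phase = prep$phase,
       plane_deg = prep$plane_deg, rep = prep$rep)
}

#' Ratio curves from trial kinematics
#'
#' Splits the trial's magnification-ratio series into raising/lowering
#' segments over increasing elevation.
#'
#' @param kin a [trial_kinematics()] result.
#' @return list of [ratio_curve()] objects (see [segment_phases()]).
#' @export
trial_ratio_curves <- function(kin) {
  segment_phases(kin$theta, kin$series$ratio, phase = kin$phase,
                 provenance = list(subject = kin$subject,
                                   plane_deg = kin$plane_deg,
                                   rep = kin$rep))
}

#' Analyze a cohort of trials end to end
#'
#' Runs the full chain on a list of trials (simulated or read from
#' files): per-subject centre regression pooled over that subject's
#' trials (or per trial when `per_trial = TRUE`), per-trial kinematics
#' and phase segmentation, cross-trial averaging per requested phase, and
#' polynomial fitting of the mean curves.
#'
#' @param trials list of [marker_trajectory_set()] objects.
#' @param phases which segment curves to average and fit; default both
#'   raising and lowering as present.
#' @param grid resampling grid (deg); `NULL` uses the first curve's own
#'   angles (exact when all trials share an elevation program).
#' @param degrees,criteria forwarded to [fit_polynomial_model()].
#' @param per_trial fit the regression per trial instead of per subject.
#' @param d0_policy `"first_frame"` (reference frame of each trial) or
#'   `"min_theta"` (normalize by the centre norm at the frame of lowest
#'   elevation, the hanging posture, useful for lowering-only trials).
#' @return list with `solutions` (per subject), `curves`, `mean_curves`,
#'   `fits` and `counts`.
#' @export
analyze_cohort <- function(trials, phases = c("raising", "lowering"),
                           grid = seq(0, 150, by = 1), degrees = 2:5,
                           criteria = list(min_r2 = 0.995, max_err = 0.005),
                           per_trial = FALSE,
                           d0_policy = c("first_frame", "min_theta")) {
  d0_policy <- match.arg(d0_policy)
  if (inherits(trials, "shoulder_cohort")) {
    trials <- lapply(trials$trials, `[[`, "trial")
  }
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, inherits, logical(1L), "marker_trajectory_set")))
  # one triple choice per subject (from their first trial) so all pooled
  # frames share the same local-coordinate parameters
  subjects <- vapply(trials, `[[`, character(1L), "subject")
  preps <- vector("list", length(trials))
  for (sid in unique(subjects)) {
    idx <- which(subjects == sid)
    preps[[idx[1L]]] <- prepare_trial(trials[[idx[1L]]])
    for (i in idx[-1L]) {
      preps[[i]] <- prepare_trial(trials[[i]],
                                  triples = preps[[idx[1L]]]$triples)
    }
  }
  solutions <- list()
  if (per_trial) {
    kins <- lapply(preps, function(p) {
      sol <- estimate_gh_center(p)
      trial_kinematics(p, sol, d0 = policy_d0(p, sol, d0_policy))
    })
    solutions <- NULL
  } else {
    kins <- vector("list", length(preps))
    for (sid in unique(subjects)) {
      idx <- which(subjects == sid)
      sol <- estimate_gh_center(preps[idx])
      solutions[[sid]] <- sol
      for (i in idx) {
        kins[[i]] <- trial_kinematics(preps[[i]], sol,
                                      d0 = policy_d0(preps[[i]], sol, d0_policy))
      }
    }
  }
  curves <- list()
  for (kin in kins) {
    segs <- trial_ratio_curves(kin)
    for (ph in names(segs)) curves[[ph]] <- c(curves[[ph]], list(segs[[ph]]))
  }
  mean_curves <- list()
  fits <- list()
  for (ph in intersect(phases, names(curves))) {
    g <- if (is.null(grid)) curves[[ph]][[1L]]$theta else grid
    mean_curves[[ph]] <- resample_and_average(curves[[ph]], grid = g)
    fits[[ph]] <- fit_polynomial_model(mean_curves[[ph]], degrees = degrees,
                                       criteria = criteria)
  }
  list(solutions = solutions, curves = curves, mean_curves = mean_curves,
       fits = fits,
       counts = list(trials = length(trials),
                     subjects = length(unique(subjects)),
                     curves = lengths(curves)))
}

policy_d0 <- function(prep, solution, d0_policy) {
  if (d0_policy == "first_frame") return(NULL)
  series <- gh_center_series(solution, prep$bases)
  D <- 0.5 * (prep$EL + prep$EM) - series$J
  theta <- elevation_angle(D)
  sqrt(sum(series$J[which.min(theta), ]^2))
}
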