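# Synthetic motion-capture generator with full ground truth.
#
# Emulates the study protocol: guided elevation planes, smooth elevation
# ramps over 0-150 degrees at 50 Hz, a GH centre that translates in the
# thorax frame according to a phase-specific coupling model, rigid
# scapula and humerus marker blocks that both carry the centre, additive
# isotropic marker noise and Bernoulli occlusions.

default_truth_config <- function() {
  list(
    coupling = NULL,              # filled with built-in raising/lowering
    q1_rest = c(165, -25, -35),   # rest GH centre, thorax coords [mm]
    arm_length_mm = 551.5,        # cohort mean arm length
    humerus_fraction = 0.53,      # GH -> elbow-midpoint share of the arm
    epicondyle_halfwidth = 30,    # EL/EM half separation [mm]
    cluster_halfwidth = 20,       # 40 mm marker blocks
    scap_cluster_center = c(-10, -30, 40),  # block centre rel. GH, scapula frame
    upa_cluster_offset = c(0, 45, -120),    # flange centre rel. GH, humerus frame
    scap_rot_max_deg = 30,        # scapula ramp over the full elevation range
    scap_rot_axis = "x",
    thorax_markers = list(IJ = c(0, 0, 0), C7 = c(0, -100, 0),
                          PX = c(0, 0, -150), T8 = c(0, -100, -150)),
    noise_sd_mm = 0,
    noise_model = "iid",          # "iid" or "ar1" (soft-tissue-like drift)
    ar_coef = 0.98,
    dropout_prob = 0,
    dropout_markers = c(SCAPULA_CLUSTER, HUMERUS_CLUSTER),
    seed = 1L)
}

square_block <- function(center, halfwidth) {
  # 4 markers at the corners of a square in the local x-z plane
  h <- halfwidth
  rbind(center + c(-h, 0, -h), center + c(h, 0, -h),
        center + c(-h, 0, h), center + c(h, 0, h))
}

#' Build a synthetic-shoulder ground truth
#'
#' Assembles the geometry and coupling that [simulate_trial()] animates:
#' the rest GH centre (whose norm is the normalization distance d0, since
#' the thorax origin is IJ), rigid 40 mm marker blocks on the scapula and
#' the humerus, epicondyle markers, thorax markers reproducing an
#' identity thorax frame at rest, a scapula rotation program (a linear
#' ramp, default 0 to 30 degrees about the thorax x axis over the full
#' elevation range, the order of magnitude implied by the roughly 1.7:1
#' glenohumeral-to-scapulothoracic rhythm) and the phase-specific
#' coupling models (built-in raising/lowering models by default).
#'
#' @param config named list overriding any default (see the source of
#'   `ghfloat:::default_truth_config`); unknown keys are rejected.
#' @return An object of class `shoulder_ground_truth`.
#' @export
make_ground_truth <- function(config = list()) {
  base <- default_truth_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop_cond("invalid_config", "unknown ground-truth option(s): %s",
              paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(base, config)
  if (is.null(cfg$coupling)) {
    cfg$coupling <- list(raising = builtin_coupling_model("raising"),
                         lowering = builtin_coupling_model("lowering"))
  }
  d0 <- sqrt(sum(cfg$q1_rest^2))
  if (d0 < 120 || d0 > 220) {
    stop_cond("invalid_config",
              "implausible rest IJ-GH distance d0 = %.1f mm (expect 120-220)", d0)
  }
  if (cfg$arm_length_mm < 450 || cfg$arm_length_mm > 650) {
    stop_cond("invalid_config",
              "implausible arm length %.1f mm (expect 450-650)",
              cfg$arm_length_mm)
  }
  if (cfg$noise_sd_mm < 0 || cfg$dropout_prob < 0 || cfg$dropout_prob > 1) {
    stop_cond("invalid_config", "invalid noise/dropout configuration")
  }
  L <- cfg$arm_length_mm * cfg$humerus_fraction
  geom <- list(
    scap_local = square_block(cfg$scap_cluster_center, cfg$cluster_halfwidth),
    upa_local = square_block(cfg$upa_cluster_offset, cfg$cluster_halfwidth),
    EL_local = c(cfg$epicondyle_halfwidth, 0, -L),
    EM_local = c(-cfg$epicondyle_halfwidth, 0, -L),
    humerus_length = L)
  rownames(geom$scap_local) <- SCAPULA_CLUSTER
  rownames(geom$upa_local) <- HUMERUS_CLUSTER
  structure(c(cfg, list(d0 = d0, geometry = geom)),
            class = "shoulder_ground_truth")
}

#' @export
print.shoulder_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<shoulder_ground_truth> d0 = %.1f mm, humerus %.1f mm, sigma = %g mm\n",
    x$d0, x$geometry$humerus_length, x$noise_sd_mm))
  invisible(x)
}

# Elevation program over normalized time s in [0, 1]; smooth (zero-rate
# endpoints) cosine ramps.
theta_program <- function(phase, s) {
  switch(phase,
         raising = 75 * (1 - cos(pi * s)),
         lowering = 75 * (1 + cos(pi * s)),
         RAL = 75 * (1 - cos(2 * pi * s)))
}

scap_rotation <- function(truth, theta) {
  ang <- truth$scap_rot_max_deg * theta / 150
  switch(truth$scap_rot_axis,
         x = rot_x(ang), y = rot_y(ang), z = rot_z(ang))
}

# Constant-removed coupling displacement (mm) at elevation theta.
coupling_displacement <- function(truth, theta, leg) {
  model <- truth$coupling[[leg]]
  truth$d0 * evaluate_coupling(model, theta,
                               remove_constant = TRUE)[, c("x", "y", "z"),
                                                       drop = FALSE]
}

ar1_noise <- function(n, sd, phi) {
  w <- rnorm(n)
  as.vector(stats::filter(w, phi, method = "recursive")) * sd * sqrt(1 - phi^2)
}

#' Simulate one motion-capture trial
#'
#' Animates the ground truth through a smooth elevation ramp (0 to 150
#' degrees raising, the reverse lowering, or both for RAL) in a guided
#' elevation plane. The GH centre translates by the coupling model's
#' constant-removed displacement (raising-leg and lowering-leg couplings
#' are each used on their own leg, joined continuously at the peak);
#' the humerus rotates as Rz(eta) Ry(-theta) Rz(psi); all markers are
#' rigid transforms of the local geometry plus optional noise and
#' Bernoulli dropouts.
#'
#' @param truth a [make_ground_truth()] object.
#' @param phase `"raising"`, `"lowering"` or `"RAL"`.
#' @param plane_deg guided elevation-plane angle eta (deg).
#' @param rate sampling rate (Hz; study value 50).
#' @param duration trial length (s); the frame count is `rate * duration`.
#' @param psi_deg axial-rotation program: a scalar or per-frame vector.
#' @param subject,rep metadata tags.
#' @param seed RNG seed for this trial; defaults to the truth's seed.
#' @return list with `trial` (a [marker_trajectory_set()]), `truth` (a
#'   per-frame data.frame: frame, theta_deg, eta_deg, leg, Jx, Jy, Jz)
#'   and `ground_truth` (the input object).
#' @export
simulate_trial <- function(truth, phase = c("raising", "lowering", "RAL"),
                           plane_deg = 0, rate = 50, duration = 4,
                           psi_deg = 0, subject = "S01", rep = 1L,
                           seed = NULL) {
  stopifnot(inherits(truth, "shoulder_ground_truth"))
  phase <- match.arg(phase)
  n <- as.integer(round(rate * duration))
  stopifnot(n >= 2L)
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)
  s <- seq(0, 1, length.out = n)
  theta <- theta_program(phase, s)
  theta <- pmin(pmax(theta, 0), 150)   # guard fp rounding at the ends
  psi <- rep_len(psi_deg, n)
  leg <- switch(phase,
                raising = rep("raising", n),
                lowering = rep("lowering", n),
                RAL = ifelse(s <= 0.5, "raising", "lowering"))

  J <- matrix(NA_real_, n, 3L)
  up <- leg == "raising"
  if (any(up)) {
    J[up, ] <- rep(truth$q1_rest, each = sum(up)) +
      coupling_displacement(truth, theta[up], "raising")
  }
  if (any(!up)) {
    shift <- if (phase == "RAL") {
      # join the two legs continuously at the 150-degree peak
      coupling_displacement(truth, 150, "raising") -
        coupling_displacement(truth, 150, "lowering")
    } else {
      matrix(0, 1L, 3L)
    }
    J[!up, ] <- rep(truth$q1_rest + as.vector(shift), each = sum(!up)) +
      coupling_displacement(truth, theta[!up], "lowering")
  }

  geom <- truth$geometry
  markers <- c(truth$thorax_markers,
               setNames(vector("list", 10L),
                        c(SCAPULA_CLUSTER, HUMERUS_CLUSTER, "EL", "EM")))
  for (lab in names(truth$thorax_markers)) {
    markers[[lab]] <- matrix(rep(truth$thorax_markers[[lab]], each = n), n, 3L)
  }
  scap_glob <- array(NA_real_, c(n, 3L, 4L))
  hum_glob <- array(NA_real_, c(n, 3L, 4L))
  EL <- EM <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    Rs <- scap_rotation(truth, theta[i])
    Rh <- isb_rotation(plane_deg, theta[i], psi[i])
    scap_glob[i, , ] <- J[i, ] + Rs %*% t(geom$scap_local)
    hum_glob[i, , ] <- J[i, ] + Rh %*% t(geom$upa_local)
    EL[i, ] <- J[i, ] + as.vector(Rh %*% geom$EL_local)
    EM[i, ] <- J[i, ] + as.vector(Rh %*% geom$EM_local)
  }
  for (k in 1:4) {
    markers[[SCAPULA_CLUSTER[k]]] <- scap_glob[, , k]
    markers[[HUMERUS_CLUSTER[k]]] <- hum_glob[, , k]
  }
  markers$EL <- EL
  markers$EM <- EM

  if (truth$noise_sd_mm > 0) {
    for (lab in names(markers)) {
      eps <- if (truth$noise_model == "ar1") {
        cbind(ar1_noise(n, truth$noise_sd_mm, truth$ar_coef),
              ar1_noise(n, truth$noise_sd_mm, truth$ar_coef),
              ar1_noise(n, truth$noise_sd_mm, truth$ar_coef))
      } else {
        matrix(rnorm(3L * n, sd = truth$noise_sd_mm), n, 3L)
      }
      markers[[lab]] <- markers[[lab]] + eps
    }
  }
  visible <- matrix(TRUE, n, length(MARKER_LABELS),
                    dimnames = list(NULL, MARKER_LABELS))
  if (truth$dropout_prob > 0) {
    for (lab in truth$dropout_markers) {
      visible[, lab] <- runif(n) >= truth$dropout_prob
    }
  }

  d <- do.call(rbind, lapply(MARKER_LABELS, function(lab) {
    data.frame(frame = 0:(n - 1L), label = lab,
               x_mm = markers[[lab]][, 1L], y_mm = markers[[lab]][, 2L],
               z_mm = markers[[lab]][, 3L], visible = visible[, lab],
               stringsAsFactors = FALSE)
  }))
  set <- marker_trajectory_set(d, rate = rate, subject = subject,
                               phase = phase, plane_deg = plane_deg,
                               rep = rep)
  truth_tab <- data.frame(frame = 0:(n - 1L), theta_deg = theta,
                          eta_deg = plane_deg, leg = leg,
                          Jx = J[, 1L], Jy = J[, 2L], Jz = J[, 3L])
  list(trial = set, truth = truth_tab, ground_truth = truth)
}

#' Write a simulated trial and its truth table to disk
#'
#' Writes the trajectory CSV dialect plus a `<stem>_truth.csv` with
#' columns frame, theta_deg, eta_deg, Jx, Jy, Jz.
#'
#' @param sim a [simulate_trial()] result.
#' @param stem output path stem (without extension).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_simulated_trial <- function(sim, stem) {
  p1 <- paste0(stem, ".csv")
  p2 <- paste0(stem, "_truth.csv")
  write_marker_trajectories(sim$trial, p1)
  write.csv(sim$truth[c("frame", "theta_deg", "eta_deg", "Jx", "Jy", "Jz")],
            p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Simulate a full study cohort
#'
#' Generates `n_subjects` x `length(planes)` x `reps` trials per phase,
#' matching the study protocol (12 subjects, 16 guided planes between 0
#' and 135 degrees, 3 repetitions). Each subject gets seeded Gaussian
#' jitter of the rest geometry (GH-centre scale, hence d0, and arm
#' length); all trial seeds derive from the single cohort seed.
#'
#' @param truth template [make_ground_truth()] object.
#' @param n_subjects number of subjects (study value 12).
#' @param planes guided plane angles (deg); default the study's 16.
#' @param reps repetitions per subject/plane/phase (study value 3).
#' @param phases phases to simulate; default `"raising"`.
#' @param rate,duration,psi_deg forwarded to [simulate_trial()].
#' @param subject_sd relative SD of the per-subject geometry jitter.
#' @param seed cohort seed.
#' @return An object of class `shoulder_cohort`: `trials` (list of
#'   [simulate_trial()] results), `subject_truths` (per-subject ground
#'   truths) and the call parameters.
#' @export
simulate_cohort <- function(truth, n_subjects = 12,
                            planes = c(0, 10, 20, 30, 40, 45, 50, 60, 70,
                                       80, 90, 100, 110, 120, 130, 135),
                            reps = 3, phases = "raising", rate = 50,
                            duration = 4, psi_deg = 0, subject_sd = 0.03,
                            seed = 1L) {
  stopifnot(inherits(truth, "shoulder_ground_truth"), n_subjects >= 1)
  set.seed(seed)
  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  subject_truths <- list()
  for (sid in subject_ids) {
    scale_q <- max(0.8, min(1.2, rnorm(1L, 1, subject_sd)))
    scale_arm <- max(0.85, min(1.15, rnorm(1L, 1, subject_sd / 2)))
    cfg <- list(q1_rest = truth$q1_rest * scale_q,
                arm_length_mm = truth$arm_length_mm * scale_arm,
                coupling = truth$coupling,
                noise_sd_mm = truth$noise_sd_mm,
                noise_model = truth$noise_model,
                dropout_prob = truth$dropout_prob,
                seed = truth$seed)
    subject_truths[[sid]] <- make_ground_truth(cfg)
  }
  grid <- expand.grid(rep = seq_len(reps), plane = planes,
                      phase = phases, subject = subject_ids,
                      stringsAsFactors = FALSE)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  trials <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    trials[[i]] <- simulate_trial(subject_truths[[g$subject]],
                                  phase = g$phase, plane_deg = g$plane,
                                  rate = rate, duration = duration,
                                  psi_deg = psi_deg, subject = g$subject,
                                  rep = g$rep, seed = trial_seeds[i])
  }
  structure(list(trials = trials, subject_truths = subject_truths,
                 params = list(n_subjects = n_subjects, planes = planes,
                               reps = reps, phases = phases, rate = rate,
                               duration = duration, seed = seed)),
            class = "shoulder_cohort")
}

#' @export
print.shoulder_cohort <- function(x, ...) {
  cat(sprintf("<shoulder_cohort> %d trials (%d subjects x %d planes x %d reps x %d phase(s))\n",
              length(x$trials), x$params$n_subjects, length(x$params$planes),
              x$params$reps, length(x$params$phases)))
  invisible(x)
}

#' True local regression parameters for a marker-triple choice
#'
#' Solves, from the rigid local geometry, the coefficients (a, b, c) and
#' (d, e, f) expressing the GH centre in the scapula- and humerus-triple
#' bases; useful as ground truth for regression-recovery tests.
#'
#' @param truth a [make_ground_truth()] object.
#' @param scap_triple,hum_triple character triples of marker labels.
#' @return Named numeric 6-vector (a..f).
#' @export
true_center_params <- function(truth, scap_triple, hum_triple) {
  local_params <- function(local, triple) {
    p <- local[triple, , drop = FALSE]
    q1 <- p[1L, ] - p[2L, ]
    q2 <- p[1L, ] - p[3L, ]
    q3 <- cross3(q1, q2)
    as.vector(solve(cbind(q1, q2, q3), -p[1L, ]))  # centre is the local origin
  }
  out <- c(local_params(truth$geometry$scap_local, scap_triple),
           local_params(truth$geometry$upa_local, hum_triple))
  names(out) <- letters[1:6]
  out
}
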