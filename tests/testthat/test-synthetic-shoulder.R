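# Synthetic motion-capture generator: rigidity, determinism, contracts.

test_that("ground-truth construction validates its configuration", {
  truth <- make_ground_truth()
  expect_s3_class(truth, "shoulder_ground_truth")
  expect_equal(truth$d0, sqrt(sum(truth$q1_rest^2)))
  expect_error(make_ground_truth(list(q1_rest = c(10, 0, 0))),
               class = "invalid_config")
  expect_error(make_ground_truth(list(arm_length_mm = 300)),
               class = "invalid_config")
  expect_error(make_ground_truth(list(noise_sd_mm = -1)),
               class = "invalid_config")
  expect_error(make_ground_truth(list(nonsense = 1)),
               class = "invalid_config")
})

test_that("rest thorax markers reproduce the identity thorax frame", {
  truth <- make_ground_truth()
  m <- truth$thorax_markers
  fr <- build_thorax_frame(m$C7, m$T8, m$IJ, m$PX)
  expect_equal(rbind(fr$x_t, fr$y_t, fr$z_t), diag(3L),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("noise-free clusters are rigid over the whole trial", {
  truth <- make_ground_truth()
  sim <- simulate_trial(truth, phase = "RAL", plane_deg = 90, duration = 1)
  tm <- ghfloat:::trial_matrices(sim$trial)
  for (cluster in list(SCAPULA_CLUSTER, HUMERUS_CLUSTER, c("EL", "EM"))) {
    pairs <- combn(cluster, 2L, simplify = FALSE)
    for (pr in pairs) {
      d <- sqrt(rowSums((tm$pos[[pr[1L]]] - tm$pos[[pr[2L]]])^2))
      expect_lt(max(abs(d - d[1L])), 1e-9)
    }
  }
})

test_that("the GH centre has constant local coordinates in both cluster frames", {
  truth <- make_ground_truth()
  sim <- simulate_trial(truth, phase = "raising", plane_deg = 30,
                        duration = 1)
  tm <- ghfloat:::trial_matrices(sim$trial)
  J <- as.matrix(sim$truth[, c("Jx", "Jy", "Jz")])
  # express the centre in each cluster's affine triple basis per frame
  for (cluster in list(SCAPULA_CLUSTER[1:3], HUMERUS_CLUSTER[1:3])) {
    coords <- t(vapply(seq_len(nrow(J)), function(i) {
      p1 <- tm$pos[[cluster[1L]]][i, ]
      q1 <- p1 - tm$pos[[cluster[2L]]][i, ]
      q2 <- p1 - tm$pos[[cluster[3L]]][i, ]
      q3 <- c(q1[2L] * q2[3L] - q1[3L] * q2[2L],
              q1[3L] * q2[1L] - q1[1L] * q2[3L],
              q1[1L] * q2[2L] - q1[2L] * q2[1L])
      solve(cbind(q1, q2, q3), J[i, ] - p1)
    }, numeric(3L)))
    expect_lt(max(abs(sweep(coords, 2L, coords[1L, ]))), 1e-9)
  }
})

test_that("commanded elevation is recovered from simulated geometry", {
  truth <- make_ground_truth()
  sim <- simulate_trial(truth, phase = "lowering", plane_deg = 100,
                        duration = 1)
  tm <- ghfloat:::trial_matrices(sim$trial)
  J <- as.matrix(sim$truth[, c("Jx", "Jy", "Jz")])
  D <- 0.5 * (tm$pos$EL + tm$pos$EM) - J
  expect_lt(max(abs(elevation_angle(D) - sim$truth$theta_deg)), 1e-6)
  eta <- elevation_plane_angle(D)
  expect_lt(max(abs(eta[!is.na(eta)] - 100)), 1e-6)
})

test_that("a fixed seed reproduces trials and cohorts exactly", {
  truth <- make_ground_truth(list(noise_sd_mm = 2, dropout_prob = 0.05))
  s1 <- simulate_trial(truth, phase = "raising", duration = 0.5, seed = 9L)
  s2 <- simulate_trial(truth, phase = "raising", duration = 0.5, seed = 9L)
  expect_identical(s1$trial$data, s2$trial$data)
  c1 <- simulate_cohort(truth, n_subjects = 2, planes = c(0, 90), reps = 1,
                        duration = 0.5, seed = 5L)
  c2 <- simulate_cohort(truth, n_subjects = 2, planes = c(0, 90), reps = 1,
                        duration = 0.5, seed = 5L)
  expect_identical(lapply(c1$trials, function(t) t$trial$data),
                   lapply(c2$trials, function(t) t$trial$data))
})

test_that("frame counts follow rate x duration and the protocol shape", {
  truth <- make_ground_truth()
  sim <- simulate_trial(truth, phase = "raising", rate = 50, duration = 10)
  expect_equal(length(unique(sim$trial$data$frame)), 500L)
  co <- simulate_cohort(truth, n_subjects = 2, planes = c(0, 45, 90),
                        reps = 2, duration = 0.5, seed = 3L)
  expect_length(co$trials, 2L * 3L * 2L)
  expect_length(co$subject_truths, 2L)
})

test_that("marker noise matches the configured sigma within 10 percent", {
  sd_target <- 2
  clean <- simulate_trial(make_ground_truth(), phase = "raising",
                          duration = 5, seed = 77L)
  noisy <- simulate_trial(make_ground_truth(list(noise_sd_mm = sd_target)),
                          phase = "raising", duration = 5, seed = 77L)
  resid <- as.matrix(noisy$trial$data[, c("x_mm", "y_mm", "z_mm")]) -
    as.matrix(clean$trial$data[, c("x_mm", "y_mm", "z_mm")])
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - sd_target) / sd_target, 0.10)
})

test_that("AR(1) soft-tissue mode keeps the stationary noise scale", {
  sd_target <- 3
  clean <- simulate_trial(make_ground_truth(), phase = "raising",
                          duration = 5, seed = 78L)
  drift <- simulate_trial(make_ground_truth(list(noise_sd_mm = sd_target,
                                                 noise_model = "ar1")),
                          phase = "raising", duration = 5, seed = 78L)
  resid <- as.matrix(drift$trial$data[, c("x_mm", "y_mm", "z_mm")]) -
    as.matrix(clean$trial$data[, c("x_mm", "y_mm", "z_mm")])
  expect_lt(abs(sd(resid) - sd_target) / sd_target, 0.25)
  # successive samples are strongly correlated, unlike the iid mode
  r1 <- resid[drift$trial$data$label == "EL", 1L]
  expect_gt(cor(r1[-1L], r1[-length(r1)]), 0.8)
})

test_that("a fully occluded block marker degrades to the 3-marker path", {
  truth <- make_ground_truth(list(dropout_prob = 1,
                                  dropout_markers = "SCA4"))
  sim <- simulate_trial(truth, phase = "raising", duration = 1.5)
  prep <- prepare_trial(sim$trial)
  expect_false("SCA4" %in% prep$triples$scapula)
  sol <- estimate_gh_center(prep)
  series <- gh_center_series(sol, prep$bases)
  J_true <- as.matrix(sim$truth[, c("Jx", "Jy", "Jz")])
  expect_lt(max(abs(series$J - J_true)), 1e-6)
})
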