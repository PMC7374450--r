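# Trajectory container, CSV dialect, triple selection.

test_that("a complete two-frame CSV parses into 28 validated samples", {
  set <- marker_trajectory_set(static_trial_df(2L), rate = 50,
                               subject = "S07", phase = "RAL",
                               plane_deg = 45, rep = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_trajectories(set, path)
  got <- read_marker_trajectories(path)
  expect_equal(nrow(got$data), 28L)
  expect_equal(got$rate, 50)
  expect_equal(got$subject, "S07")
  expect_equal(got$phase, "RAL")
  expect_equal(got$plane_deg, 45)
  expect_equal(got$rep, 2L)
})

test_that("a frame missing one cluster marker stays usable through 3-of-4", {
  d <- static_trial_df(2L)
  i <- which(d$frame == 1L & d$label == "SCA3")
  d[i, c("x_mm", "y_mm", "z_mm")] <- NA
  d$visible[i] <- FALSE
  set <- marker_trajectory_set(d, rate = 50)
  expect_false(set$data$visible[set$data$frame == 1L &
                                  set$data$label == "SCA3"])
  expect_true(all(usable_frames(set)))
})

test_that("write -> read round-trips a simulated trial bit-exactly", {
  truth <- make_ground_truth(list(noise_sd_mm = 1.5, seed = 7L))
  sim <- simulate_trial(truth, phase = "lowering", plane_deg = 135,
                        duration = 0.5, subject = "S03", rep = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_trajectories(sim$trial, path)
  got <- read_marker_trajectories(path)
  expect_identical(got$data$x_mm, sim$trial$data$x_mm)
  expect_identical(got$data$y_mm, sim$trial$data$y_mm)
  expect_identical(got$data$z_mm, sim$trial$data$z_mm)
  expect_identical(got$data$visible, sim$trial$data$visible)
  expect_identical(got[c("rate", "subject", "phase", "plane_deg", "rep")],
                   sim$trial[c("rate", "subject", "phase", "plane_deg", "rep")])
})

test_that("an empty set writes a header-only file; reading it errors", {
  set <- marker_trajectory_set(static_trial_df(1L)[0, ], rate = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_trajectories(set, path)
  expect_length(readLines(path), 2L)
  expect_error(read_marker_trajectories(path), class = "empty_trial")

  one <- marker_trajectory_set(static_trial_df(1L), rate = 50)
  write_marker_trajectories(one, path)
  expect_length(readLines(path), 2L + 14L)
})

test_that("malformed input is rejected with a useful message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate_hz=50 subject=S01 phase=raising plane_deg=0 rep=1",
               "frame,label,x_mm,y_mm,z_mm,visible",
               "0,C7,1,2,3,1",
               "0,T8,1,2"), path)
  expect_error(read_marker_trajectories(path), "line 4", class = "parse_error")

  writeLines(c("# rate_hz=50 subject=S01 phase=raising plane_deg=0 rep=1",
               "frame,label,x_mm,y_mm,z_mm,visible",
               "0,BADLABEL,1,2,3,1"), path)
  expect_error(read_marker_trajectories(path), "BADLABEL",
               class = "unknown_label")
  expect_error(read_marker_trajectories(path, dialect = "c3d"),
               class = "unsupported_dialect")
  expect_error(read_marker_trajectories(file.path(tempdir(), "nope.csv")),
               class = "missing_file")
})

test_that("the set constructor enforces its invariants", {
  d <- static_trial_df(1L)
  expect_error(marker_trajectory_set(rbind(d, d[1L, ]), rate = 50),
               class = "duplicate_sample")
  d2 <- d; d2$x_mm[1L] <- NA  # visible but non-finite
  expect_error(marker_trajectory_set(d2, rate = 50),
               class = "invalid_sample")
  expect_error(marker_trajectory_set(d, rate = 0), class = "invalid_rate")
})

test_that("triple selection maximizes area with a lexicographic tie-break", {
  square <- rbind(SCA1 = c(0, 0, 0), SCA2 = c(100, 0, 0),
                  SCA3 = c(100, 100, 0), SCA4 = c(0, 100, 0))
  # all four triples of a square have equal area: first lexicographic wins
  expect_equal(select_marker_triple(square), c("SCA1", "SCA2", "SCA3"))

  collinear3 <- rbind(UPA1 = c(0, 0, 0), UPA2 = c(100, 0, 0),
                      UPA3 = c(200, 0, 0), UPA4 = c(0, 100, 0))
  # brute-force oracle over the four candidate triples
  combos <- combn(sort(rownames(collinear3)), 3L, simplify = FALSE)
  areas <- vapply(combos, function(tr) {
    p <- collinear3[tr, ]
    v1 <- p[2L, ] - p[1L, ]; v2 <- p[3L, ] - p[1L, ]
    cr <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
            v1[3L] * v2[1L] - v1[1L] * v2[3L],
            v1[1L] * v2[2L] - v1[2L] * v2[1L])
    0.5 * sqrt(sum(cr^2))
  }, numeric(1L))
  expect_equal(select_marker_triple(collinear3), combos[[which.max(areas)]])
  expect_false("UPA3" %in% select_marker_triple(collinear3) &&
                 "UPA2" %in% select_marker_triple(collinear3) &&
                 "UPA1" %in% select_marker_triple(collinear3))
})

test_that("triple selection handles degenerate visibility", {
  square <- rbind(SCA1 = c(0, 0, 0), SCA2 = c(100, 0, 0),
                  SCA3 = c(100, 100, 0), SCA4 = c(0, 100, 0))
  expect_equal(select_marker_triple(square, c(FALSE, TRUE, TRUE, TRUE)),
               c("SCA2", "SCA3", "SCA4"))
  expect_error(select_marker_triple(square, c(FALSE, FALSE, TRUE, TRUE)),
               class = "frame_unusable")
  line4 <- rbind(SCA1 = c(0, 0, 0), SCA2 = c(10, 0, 0),
                 SCA3 = c(20, 0, 0), SCA4 = c(30, 0, 0))
  expect_error(select_marker_triple(line4), class = "collinear_cluster")
})

test_that("triple selection is invariant to input row permutation", {
  set.seed(11)
  for (k in 1:20) {
    p <- matrix(rnorm(12L, sd = 50), 4L, 3L)
    rownames(p) <- SCAPULA_CLUSTER
    perm <- sample(4L)
    expect_equal(select_marker_triple(p),
                 select_marker_triple(p[perm, , drop = FALSE]))
  }
})
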