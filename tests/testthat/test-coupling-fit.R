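# Phase segmentation, averaging, polynomial/rational fitting, built-ins.

test_that("a rise-and-fall series splits into two equal-span segments", {
  th <- c(seq(0, 150, length.out = 60), seq(150, 0, length.out = 60)[-1L])
  ratios <- cbind(th / 1000, -th / 2000, th^2 / 1e5)
  segs <- segment_phases(th, ratios)
  expect_named(segs, c("raising", "lowering"))
  expect_equal(range(segs$raising$theta), c(0, 150))
  expect_equal(range(segs$lowering$theta), c(0, 150))
  # lowering is re-indexed over increasing elevation
  expect_true(all(diff(segs$lowering$theta) > 0))
})

test_that("a pure raising series yields only a raising segment", {
  th <- seq(0, 150, length.out = 50)
  segs <- segment_phases(th, cbind(th, th, th) / 1000)
  expect_named(segs, "raising")
  expect_error(segment_phases(rep(10, 10), matrix(0, 10L, 3L)),
               class = "missing_phase")
})

test_that("RAL trials with distinct leg couplings recover each leg's own curve", {
  truth <- make_ground_truth()
  sim <- simulate_trial(truth, phase = "RAL", plane_deg = 45, duration = 3)
  prep <- prepare_trial(sim$trial)
  kin <- trial_kinematics(prep, estimate_gh_center(prep))
  segs <- trial_ratio_curves(kin)
  expect_named(segs, c("raising", "lowering"))
  for (ph in names(segs)) {
    v_true <- evaluate_coupling(truth$coupling[[ph]], segs[[ph]]$theta,
                                remove_constant = TRUE)
    # the trial-referenced ratio differs from the generator coupling by a
    # per-axis constant; align and compare shapes (the split frame at the
    # peak may carry the other leg's coupling, hence the tolerance)
    dev <- segs[[ph]]$ratios - v_true
    expect_lt(max(abs(sweep(dev, 2L, dev[1L, ]))), 1e-4)
  }
})

test_that("averaging interpolates single curves exactly and cancels mirrors", {
  th <- seq(0, 150, by = 5)
  vals <- cbind(sin(th / 40), cos(th / 40), th / 100)
  cv <- ratio_curve(th, vals)
  m1 <- resample_and_average(list(cv), grid = th)
  expect_equal(m1$ratios, cv$ratios, tolerance = 1e-12)
  cv_neg <- ratio_curve(th, -vals)
  m2 <- resample_and_average(list(cv, cv_neg), grid = th)
  expect_lt(max(abs(m2$ratios)), 1e-15)
  # curves not covering the grid are excluded with a warning
  short <- ratio_curve(seq(10, 140, by = 5), vals[3:29, ])
  expect_warning(m3 <- resample_and_average(list(cv, short), grid = th),
                 class = "curve_excluded")
  expect_equal(m3$provenance$n_curves, 1L)
})

test_that("the mean of noisy copies converges to the underlying cubic", {
  set.seed(51)
  th <- 0:150
  cubic <- 2e-7 * th^3 - 3e-5 * th^2 + 4e-3 * th - 0.01
  sigma <- 0.02
  curves <- lapply(1:50, function(k) {
    ratio_curve(th, cbind(cubic + rnorm(151L, sd = sigma),
                          cubic + rnorm(151L, sd = sigma),
                          cubic + rnorm(151L, sd = sigma)))
  })
  m <- resample_and_average(curves, grid = th)
  dev <- abs(m$ratios - cubic)
  # pointwise Monte-Carlo bound: 3 sigma/sqrt(n) per point; a few of the
  # 453 points may exceed a 3-sd band, so check coverage plus the RMS
  expect_gt(mean(dev <= 3 * sigma / sqrt(50)), 0.99)
  expect_lt(sqrt(mean(dev^2)), 1.5 * sigma / sqrt(50))
})

test_that("fit reports satisfy their defining identities", {
  set.seed(52)
  y <- rnorm(40L); yhat <- y + rnorm(40L, sd = 0.3)
  rep <- fit_report(y, yhat, n_params = 3L)
  sse <- sum((y - yhat)^2); sst <- sum((y - mean(y))^2)
  expect_equal(rep$SSE, sse, tolerance = 1e-12)
  expect_equal(rep$R_square, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(rep$adjusted_R_square,
               1 - (1 - rep$R_square) * 39 / 37, tolerance = 1e-12)
  expect_equal(rep$RMSE, sqrt(sse / 37), tolerance = 1e-12)
  expect_lte(rep$adjusted_R_square, rep$R_square)
  expect_equal(fit_report(y, yhat, 3L, df_adjust = FALSE)$RMSE,
               sqrt(sse / 40), tolerance = 1e-12)
  # zero-variance guard
  expect_equal(fit_report(rep(1, 10L), rep(1, 10L), 1L)$R_square, 0)
})

test_that("polynomial fitting recovers exact printed coefficients", {
  th <- 0:150
  for (ph in c("raising", "lowering", "ral")) {
    gt <- builtin_coupling_model(ph)
    curve <- ratio_curve(th, evaluate_coupling(gt, th), phase = ph)
    degs <- lapply(gt$axes, function(a) length(a$coefficients) - 1L)
    fit <- fit_polynomial_model(curve, degrees = degs)
    for (ax in c("x", "y", "z")) {
      expect_rel_equal(fit$model$axes[[ax]]$coefficients,
                       gt$axes[[ax]]$coefficients, 1e-9)
      expect_lt(fit$reports[[ax]]$candidates[[1L]]$SSE, 1e-20)
      expect_equal(fit$reports[[ax]]$candidates[[1L]]$R_square, 1)
    }
  }
})

test_that("degree selection takes the lowest passing degree with RMSE fallback", {
  th <- 0:150
  # strong cubic: a quadratic fit misses the thresholds, the cubic is exact
  y3 <- 5e-7 * th^3 - 2e-5 * th^2 + 1e-3 * th
  curve <- ratio_curve(th, cbind(y3, y3, y3))
  fit <- fit_polynomial_model(curve, degrees = 2:5)
  expect_equal(fit$reports$x$selected_degree, 3L)
  expect_true(fit$reports$x$selected_passed)
  expect_gt(fit$reports$x$candidates$degree_2$RMSE, 0.005)
  # no candidate passes: fall back to the RMSE minimizer
  set.seed(53)
  ynoisy <- y3 + rnorm(151L, sd = 0.05)
  fitn <- fit_polynomial_model(ratio_curve(th, cbind(ynoisy, ynoisy, ynoisy)),
                               degrees = 2:4)
  expect_false(fitn$reports$x$selected_passed)
  rmses <- vapply(fitn$reports$x$candidates, `[[`, numeric(1L), "RMSE")
  expect_equal(paste0("degree_", fitn$reports$x$selected_degree),
               names(which.min(rmses)))
  expect_error(fit_polynomial_model(ratio_curve(c(0, 0, 0, 1e-9),
                                                matrix(0, 4L, 3L)),
                                    degrees = 2),
               class = "insufficient_data")
})

test_that("rational fitting reproduces the printed rational curve", {
  th <- 0:150
  cak <- builtin_coupling_model("cak")
  y <- evaluate_coupling(cak, th)[, "y"]
  fr <- fit_rational_model(th, y)
  spec <- fr$axis_spec
  yhat <- axis_eval_oracle(spec, th)
  expect_lt(sqrt(mean((yhat - y)^2)), 1e-6)
  expect_lt(fr$report$RMSE, 1e-10)
})

test_that("rational fitting nests polynomials and rejects interior poles", {
  th <- 0:150
  yq <- 1e-5 * th^2 - 2e-3 * th + 0.01
  fr <- fit_rational_model(th, yq)
  expect_lt(max(abs(axis_eval_oracle(fr$axis_spec, th) - yq)), 1e-6)
  # data with an interior pole cannot be represented by a pole-free fit
  expect_error(fit_rational_model(th, 1 / (th - 74.5)),
               class = "ghfloat_error")
  expect_error(coupling_model(list(
    y = list(kind = "rational", numerator = c(0, 0, 1),
             denominator = c(1, -150, 5600))),   # roots at 70 and 80
    validity_deg = c(0, 150)),
    class = "pole_in_range")
})

test_that("built-in models evaluate to the printed values", {
  raising <- builtin_coupling_model("raising")
  v0 <- evaluate_coupling(raising, 0)
  expect_equal(unname(v0[1L, c("x", "y", "z")]),
               c(-0.001883, -0.009944, 0.007573))
  ral <- builtin_coupling_model("ral")
  expect_equal(unname(evaluate_coupling(ral, 0)[1L, c("x", "y", "z")]),
               c(-0.004244, 0.001629, 0.005731))
  # independent Horner evaluation of the raising z cubic at full elevation
  z150 <- horner_oracle(c(-7.088e-8, 1.623e-5, 1.819e-3, 0.007573), 150)
  expect_equal(unname(evaluate_coupling(raising, 150)[1L, "z"]), z150,
               tolerance = 1e-12)
  expect_equal(round(z150, 6L), 0.406378)
})

test_that("constant removal zeroes every model at zero elevation", {
  for (ph in c("raising", "lowering", "ral", "cak")) {
    m <- builtin_coupling_model(ph)
    v <- evaluate_coupling(m, 0, remove_constant = TRUE)
    expect_equal(max(abs(v)), 0)
  }
  expect_error(evaluate_coupling(builtin_coupling_model("raising"), 151),
               class = "range_error")
})

test_that("coupling models round-trip through their JSON files", {
  m <- builtin_coupling_model("cak")
  path <- withr::local_tempfile(fileext = ".json")
  write_coupling_model(m, path)
  m2 <- read_coupling_model(path)
  th <- seq(0, 150, by = 3)
  expect_equal(evaluate_coupling(m2, th), evaluate_coupling(m, th),
               tolerance = 1e-15)
})
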