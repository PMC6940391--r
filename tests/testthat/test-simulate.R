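test_that("noiseless kernel-mixture cells reproduce their programmed tuning", {
  M <- M_default
  cells <- simulate_cell_responses(as.numeric(rownames(M) == "KS4"), M,
                                   gain = 0.4, noise_sd = 0, n_trials = 3)
  means <- tapply(cells$dff, cells$stimulus, mean)[colnames(M)]
  expect_equal(as.vector(means), unname(0.4 * M["KS4", ]))
  # identical across trials without noise
  spread <- tapply(cells$dff, cells$stimulus, function(v) diff(range(v)))
  expect_equal(unname(spread), rep(0, 11), ignore_attr = TRUE)
  # the RPI endpoint logic carries through the generator
  expect_equal(response_projection_index(means, "KF", "KS4", M), 1)
  expect_error(simulate_cell_responses(c(-1, rep(1, 9)), M), "nonnegative")
})

test_that("noisy mixtures estimate their programmed means within sampling error", {
  M <- M_default
  w <- rep(0.1, 10)
  cells <- simulate_cell_responses(w, M, gain = 0.5, noise_sd = 0.05,
                                   n_trials = 8, seed = 61)
  mu <- 0.5 * drop(w %*% unclass(M))
  means <- tapply(cells$dff, cells$stimulus, mean)[colnames(M)]
  se <- 0.05 / sqrt(8)
  expect_true(all(abs(means - mu) < 3 * se))
})

test_that("direction-trial generation inverts the tuning model", {
  tr <- simulate_direction_trials(90, di_true = 1, C = 0.07, gain = 0.5,
                                  noise_sd = 0, n_trials = 2)
  null_mean <- mean(tr$response[!is.na(tr$angle) & tr$angle == 270])
  expect_equal(null_mean, 0.07, tolerance = 1e-6) # Rn = 0 at DI = 1
  tr2 <- simulate_direction_trials(90, 0.4, noise_sd = 0)
  fit <- fit_double_gaussian(tr2)
  expect_equal(coef(fit)[["theta_pref"]], 90, tolerance = 1e-3)
  expect_equal(fit$di, 0.4, tolerance = 1e-3)
  expect_error(simulate_direction_trials(0, 1.5), "0, 1")
})

test_that("generators are pure functions of their seed", {
  M <- M_default
  a <- simulate_cell_responses(rep(0.1, 10), M, seed = 62)
  b <- simulate_cell_responses(rep(0.1, 10), M, seed = 62)
  expect_identical(a, b)
  s1 <- simulate_animal(n_cells_before = 5, n_cells_after = 5, seed = 63)
  s2 <- simulate_animal(n_cells_before = 5, n_cells_after = 5, seed = 63)
  expect_identical(s1$family_before, s2$family_before)
  expect_identical(s1$direction_after, s2$direction_after)
})

test_that("the OSI calibration hits its target on the noiseless curve", {
  for (target in c(0.2, 0.4, 0.6)) {
    sig <- calibrate_sigma_for_osi(target, C = 0.05, Rp = 0.5)
    ang <- seq(0, 315, by = 45)
    got <- orientation_selectivity(
      dg_curve(ang, 0.05, 0.5, 0.5 * 0.7, 0, sig), ang)
    expect_equal(got, target, tolerance = 1e-6)
  }
  expect_warning(s <- calibrate_sigma_for_osi(0.999), "above")
  expect_equal(s, 5)
})

test_that("animal simulation realizes the two plasticity regimes", {
  M <- M_default
  instr <- simulate_animal(40, 40, regime = "instructive",
                           training_effect = 0.6, M = M, seed = 64)
  r_i <- analyze_animal(instr, M, n_boot = 2000, seed = 65)
  expect_gt(r_i$delta_rpi, 0.1)
  expect_true(r_i$rpi_significant)
  expect_lte(r_i$delta_di, 0.05) # no DI maturation under instructive training
  perm <- simulate_animal(40, 40, regime = "permissive", M = M, seed = 66)
  r_p <- analyze_animal(perm, M, n_boot = 2000, seed = 67)
  expect_gt(r_p$delta_di, 0.1)
  expect_true(r_p$di_significant)
  expect_lt(abs(r_p$delta_rpi), 0.2)
  # permissive regime ignores training_effect by construction
  expect_identical(perm$record$training_effect, 0)
})

test_that("exchangeable populations center the RPI change on zero", {
  M <- M_default
  deltas <- vapply(1:5, function(i) {
    sim <- simulate_animal(30, 30, regime = "instructive",
                           training_effect = 0, M = M, seed = 70 + i)
    analyze_animal(sim, M, what = "rpi", n_boot = 500, seed = 80 + i)$delta_rpi
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.1)
})

test_that("fluorescence traces encode the schedule and respect seeds", {
  cells <- tibble::tibble(cell_id = "c1", stimulus = rep(c("F", "blank"), 2),
                          trial = rep(1:2, each = 2),
                          dff = c(0.5, 0, 0.5, 0))
  rec <- simulate_fluorescence_traces(cells, noise_sd = 0, seed = 68)
  expect_true(all(diff(rec$schedule$onset) > 0))
  expect_identical(nrow(rec$schedule), 4L)
  # a zero-response condition leaves the trace at baseline
  dff <- compute_dff(rec$traces, rec$schedule, rec$frame_interval)
  # bounded by the residual decay of the preceding trial at 10 s ISI
  expect_lt(max(abs(dff$dff[dff$stimulus == "blank"])), 1e-3)
  expect_gt(min(dff$dff[dff$stimulus == "F"]), 0.4)
  rec2 <- simulate_fluorescence_traces(cells, noise_sd = 0, seed = 68)
  expect_identical(rec$traces, rec2$traces)
  expect_error(simulate_fluorescence_traces(cells, tau_decay = 0), "positive")
})
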