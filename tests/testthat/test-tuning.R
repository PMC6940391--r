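test_that("selectivity index normalizes the 10-stimulus response", {
  labs <- family_labels()
  expect_equal(unname(selectivity_index(setNames(rep(2, 10), labs))),
               rep(0.1, 10))
  onehot <- setNames(c(rep(0, 5), 1, rep(0, 4)), labs) # only S4
  expect_equal(selectivity_index(onehot, "S4"), 1)
  # sums to 1 whenever defined, with negatives clamped
  withr::with_seed(41, {
    for (i in 1:5) {
      r <- setNames(rnorm(10, 0.3, 0.3), labs)
      expect_equal(sum(selectivity_index(r)), 1)
    }
  })
  expect_warning(si <- selectivity_index(setNames(rep(-1, 10), labs)),
                 "not positive")
  expect_true(all(is.na(si)))
})

test_that("ideal-kernel cells peak at moderate selectivity indices", {
  # family stimuli are mutually correlated, so even perfectly kernel-tuned
  # cells spread their response and SI peaks well below 1
  peaks <- apply(unclass(M_default), 1, function(r) max(selectivity_index(
    setNames(r, colnames(M_default)))))
  expect_true(all(peaks > 0.15 & peaks < 0.4))
})

test_that("RPI hits its endpoints on the referent vectors themselves", {
  M <- M_default
  expect_equal(response_projection_index(M["KF", ], "KF", "KB", M), -1)
  expect_equal(response_projection_index(M["KB", ], "KF", "KB", M), 1)
  expect_lt(abs(response_projection_index(M["KS6", ], "KF", "KB", M)), 0.1)
  # bare stimulus labels resolve to kernel rows too
  expect_equal(response_projection_index(M["KF", ], "F", "B", M), -1)
})

test_that("RPI is antisymmetric in its referents and scale-invariant", {
  M <- M_default
  withr::with_seed(42, {
    for (i in 1:5) {
      r <- runif(10, 0, 1)
      v <- response_projection_index(r, "KF", "KS4", M)
      expect_equal(response_projection_index(r, "KS4", "KF", M), -v)
      expect_equal(response_projection_index(3.3 * r, "KF", "KS4", M), v)
      expect_gte(v, -1); expect_lte(v, 1)
    }
  })
  expect_warning(v <- response_projection_index(rep(0, 10), "KF", "KB", M),
                 "zero response")
  expect_true(is.na(v))
  expect_warning(v2 <- response_projection_index(runif(10), "KF", "KF", M),
                 "collinear")
  expect_true(is.na(v2))
})

test_that("orientation selectivity follows the circular-variance formula", {
  ang <- c(0, 90, 180, 270)
  expect_equal(orientation_selectivity(c(1, 0, 1, 0), ang), 1)
  expect_equal(orientation_selectivity(c(2, 2, 2, 2), ang), 0)
  # hand evaluation: |2 - 1 + 2 - 1| / 6 = 1/3 in doubled-angle space
  expect_equal(orientation_selectivity(c(2, 1, 2, 1), ang), 1 / 3)
  # blank subtraction and scale invariance
  expect_equal(orientation_selectivity(c(3, 2, 3, 2), ang, blank_mean = 1),
               1 / 3)
  expect_equal(orientation_selectivity(5 * c(2, 1, 2, 1), ang), 1 / 3)
  expect_warning(v <- orientation_selectivity(c(0, 0, 0, 0), ang), "undefined")
  expect_true(is.na(v))
  expect_error(orientation_selectivity(c(1, 1), c(0, 90)), "at least 4")
})

test_that("the Hotelling gate detects oriented responses and enforces preconditions", {
  tuned <- simulate_direction_trials(45, 0.8, gain = 0.5, noise_sd = 0.05,
                                     seed = 43)
  ht <- hotelling_orientation_test(tuned)
  expect_lt(ht$p_value, 1e-3)
  expect_identical(ht$df1, 2)
  expect_identical(ht$df2, ht$n_trials - 2)
  expect_error(hotelling_orientation_test(matrix(rnorm(16), 2, 8)),
               "at least 3")
  # identical trials: singular covariance is flagged, not crashed
  expect_warning(hs <- hotelling_orientation_test(
    matrix(rep(c(1, 2, 3, 1, 0, 0, 0, 0), each = 4), 4, 8)), "singular")
  expect_true(is.na(hs$p_value))
})

test_that("the double-Gaussian fit recovers its own curve", {
  th <- seq(0, 315, by = 45)
  truth <- c(C = 0.08, Rp = 0.9, Rn = 0.35, theta_pref = 112, sigma = 27)
  y <- dg_curve(th, truth[1], truth[2], truth[3], truth[4], truth[5])
  fit <- fit_double_gaussian(y, angles = th)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-3)
  expect_equal(fit$halfwidth, sqrt(log(4)) * coef(fit)[["sigma"]])
  expect_equal(predict(fit, th), y, tolerance = 1e-6)
})

test_that("direction index follows its clamped definition", {
  expect_equal(direction_index(10, 0), 1)
  expect_equal(direction_index(10, 5), 0.5)
  expect_equal(direction_index(10, -3), 1)
  expect_warning(v <- direction_index(0, 1), "Rp <= 0")
  expect_true(is.na(v))
  fit <- fit_double_gaussian(dg_curve(seq(0, 315, 45), 0, 1, 0.5, 90, 30),
                             angles = seq(0, 315, 45))
  expect_equal(fit$di, 0.5, tolerance = 1e-3)
})

test_that("direction index is recovered across its range at realistic noise", {
  errs <- c()
  withr::with_seed(44, {
    for (di in c(0, 0.25, 0.5, 0.75, 1)) {
      for (rep in 1:8) {
        tr <- simulate_direction_trials(runif(1, 0, 360), di, gain = 0.5,
                                        noise_sd = 0.05)
        fit <- fit_double_gaussian(tr)
        errs <- c(errs, abs(fit$di - di))
      }
    }
  })
  expect_lte(median(errs), 0.05)
})

test_that("per-cell family summaries report SI and RPI per referent pair", {
  M <- M_default
  # one-hot kernel mixtures: noiseless mean responses equal the kernel rows
  tbl <- dplyr::bind_rows(
    simulate_cell_responses(as.numeric(rownames(M) == "KF"), M, noise_sd = 0,
                            cell_id = "pure_F"),
    simulate_cell_responses(as.numeric(rownames(M) == "KB"), M, noise_sd = 0,
                            cell_id = "pure_B"))
  out <- summarize_cell_tuning(tbl, M, referents = list(c("F", "B"),
                                                        c("F", "S4")))
  expect_identical(nrow(out), 2L)
  expect_true(all(c("p_responsive", "responsive", "si",
                    "rpi_F_vs_B", "rpi_F_vs_S4") %in% names(out)))
  expect_equal(out$rpi_F_vs_B[out$cell_id == "pure_F"], -1)
  expect_equal(out$rpi_F_vs_B[out$cell_id == "pure_B"], 1)
  expect_equal(sum(out$si[[1]]), 1)
})
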