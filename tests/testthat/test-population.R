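test_that("bootstrap deltas handle degenerate and null populations", {
  b <- bootstrap_delta(c(1, 1, 1), c(2, 2, 2), n_boot = 200, seed = 51)
  expect_equal(b$mean_delta, 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  expect_true(b$significant)
  expect_identical(b$direction, 1L)
  x <- rnorm(50)
  b0 <- bootstrap_delta(x, x, n_boot = 2000, seed = 52)
  expect_lte(b0$ci_low, 0); expect_gte(b0$ci_high, 0)
  expect_false(b0$significant)
  expect_error(bootstrap_delta(numeric(0), 1:3), "non-empty")
})

test_that("bootstrap results are reproducible per seed and leave the RNG alone", {
  before <- rnorm(30); after <- rnorm(40, 0.5)
  b1 <- bootstrap_delta(before, after, n_boot = 500, seed = 53)
  b2 <- bootstrap_delta(before, after, n_boot = 500, seed = 53)
  expect_identical(b1$deltas, b2$deltas)
  withr::with_seed(1, {
    u1 <- runif(1)
    invisible(bootstrap_delta(before, after, n_boot = 100, seed = 99))
    u2 <- runif(1)
  })
  withr::with_seed(1, {
    v1 <- runif(1); v2 <- runif(1)
  })
  expect_identical(c(u1, u2), c(v1, v2))
})

test_that("bootstrap interval width shrinks roughly as 1/sqrt(n)", {
  withr::with_seed(54, {
    width_at <- function(n) {
      w <- replicate(20, {
        b <- bootstrap_delta(rnorm(n), rnorm(n), n_boot = 1000)
        b$ci_high - b$ci_low
      })
      mean(w)
    }
    ratio <- width_at(25) / width_at(100)
  })
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.6)
})

test_that("tidy and glance summarize a bootstrap result", {
  b <- bootstrap_delta(1:5, 6:10, n_boot = 100, seed = 55)
  td <- tidy(b)
  expect_identical(names(td), c("mean_delta", "ci_low", "ci_high",
                                "significant", "direction"))
  expect_identical(glance(b)$n_boot, 100L)
})

test_that("covariate correlations match closed-form values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(covariate_correlation(x, 2 * x + 1)$rho, 1)
  expect_equal(covariate_correlation(x, -x)$rho, -1)
  # textbook check on a 3-point set: r, t = r sqrt(df/(1-r^2)), p from t_1
  x3 <- c(1, 2, 3); y3 <- c(1, 3, 2)
  ct <- covariate_correlation(x3, y3)
  r_hand <- sum((x3 - 2) * (y3 - 2)) /
    sqrt(sum((x3 - 2)^2) * sum((y3 - 2)^2))
  t_hand <- r_hand * sqrt(1 / (1 - r_hand^2))
  expect_equal(ct$rho, r_hand)
  expect_identical(ct$df, 1L)
  expect_equal(ct$p_value, 2 * stats::pt(-abs(t_hand), df = 1))
  expect_error(covariate_correlation(1:2, 2:3), "at least 3")
  expect_warning(cz <- covariate_correlation(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(cz$rho))
})

test_that("null covariate correlations reject at the nominal rate", {
  withr::with_seed(56, {
    p <- replicate(500, covariate_correlation(rnorm(10), rnorm(10))$p_value)
  })
  expect_gt(mean(p < 0.05), 0.02); expect_lt(mean(p < 0.05), 0.08)
})

test_that("group t-tests match the pooled-variance textbook formula", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  tt <- group_ttest(a, b)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_hand)
  expect_identical(tt$df, 4)
  expect_equal(tt$p_value, 2 * stats::pt(-abs(t_hand), 4))
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_ttest(1, c(1, 2)), "at least 2")
  withr::with_seed(57, {
    hits <- replicate(100, group_ttest(rnorm(10), rnorm(10, 5))$p_value < 1e-3)
  })
  expect_gte(mean(hits), 0.99)
})

test_that("the principal-plane projection preserves planar configurations", {
  M <- M_default
  # points confined to the plane spanned by the (unit) KF and KS6 rows
  u <- M["KF", ] / sqrt(sum(M["KF", ]^2))
  v <- M["KS6", ] / sqrt(sum(M["KS6", ]^2))
  withr::with_seed(58, {
    pts <- t(replicate(6, {
      w <- runif(2); p <- w[1] * u + w[2] * v; p / sqrt(sum(p^2))
    }))
  })
  # fitting on these points alone keeps the configuration lossless
  fake_M <- pts[1:3, ]
  rownames(fake_M) <- c("KA", "KB2", "KC")
  class(fake_M) <- c("kernel_response_matrix", class(fake_M))
  pr <- pca_project(pts, fake_M)
  sc <- as.matrix(pr[, c("pc1", "pc2")])
  all_orig <- rbind(pts / sqrt(rowSums(pts^2)), pts[1:3, ])
  d_orig <- as.matrix(dist(all_orig))
  d_proj <- as.matrix(dist(sc))
  expect_equal(d_proj, d_orig, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the projection is deterministic, ordered, and anchors kernels", {
  M <- M_default
  means <- tibble::tibble(
    id = c("a_before", "a_after"),
    response = list(M["KF", ] + 0.01, unname(M["KS4", ])))
  pr1 <- pca_project(means, M)
  pr2 <- pca_project(means, M)
  expect_identical(pr1, pr2)
  ve <- attr(pr1, "variance_explained")
  expect_gte(ve[1], ve[2])
  # an after-population sitting exactly on KS4 projects onto KS4's point
  ks4 <- pr1[pr1$id == "KS4" & pr1$type == "kernel", c("pc1", "pc2")]
  aft <- pr1[pr1$id == "a_after", c("pc1", "pc2")]
  expect_equal(unlist(aft), unlist(ks4), ignore_attr = TRUE)
  # degenerate rank errors out
  flatM <- matrix(1, 3, 10)
  rownames(flatM) <- c("K1", "K2", "K3")
  class(flatM) <- c("kernel_response_matrix", class(flatM))
  expect_error(pca_project(matrix(1, 2, 10), flatM), "rank")
})

test_that("per-reference RPI changes isolate a shift toward the trained kernel", {
  M <- M_default
  mk_pop <- function(weight_rows, n = 6) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      w <- weight_rows[[(i - 1) %% length(weight_rows) + 1]]
      simulate_cell_responses(w, M, noise_sd = 0,
                              cell_id = sprintf("c%02d", i))
    }))
  }
  smooth_w <- list(as.numeric(rownames(M) == "KF"),
                   as.numeric(rownames(M) == "KB"))
  st_w <- list(as.numeric(rownames(M) == "KS4"))
  before <- mk_pop(smooth_w)
  d0 <- delta_rpi_by_stimulus(before, before, M, trained = "S4")
  expect_false("S4" %in% d0$reference) # self pair excluded, 0 by definition
  expect_identical(nrow(d0), 9L)
  expect_equal(d0$delta_rpi, rep(0, 9))
  d1 <- delta_rpi_by_stimulus(before, mk_pop(st_w), M, trained = "S4")
  # after sitting on the trained kernel, RPI(X vs ST) rises for references
  # poorly correlated with the trained stimulus
  expect_gt(d1$delta_rpi[d1$reference == "F"], 0.5)
  expect_gt(d1$delta_rpi[d1$reference == "B"], 0.5)
})
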