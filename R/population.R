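# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Bootstrap confidence interval on a before/after difference
#'
#' Each of `n_boot` replicates resamples `N` values from the before
#' population and `M` from the after population (both with replacement) and
#' records the difference of means, `delta = mean(after*) - mean(before*)`.
#' The mean of the `delta` distribution is reported with its empirical 5th
#' and 95th percentiles as the low and high confidence bounds. The
#' difference is declared significant when the low bound exceeds 0; a
#' decrease (high bound below 0) is also flagged, with `direction = -1`.
#'
#' @param before,after Numeric vectors of per-cell statistic values
#'   (non-empty; `NA`s dropped).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Optional seed; with a seed the result is bit-reproducible.
#' @param probs Percentiles reported as the interval (default
#'   `c(0.05, 0.95)`), computed with type-7 linear interpolation.
#' @return An object of class `"bootstrap_result"`: `mean_delta`,
#'   `ci_low`, `ci_high`, `significant`, `direction` (+1, -1, or 0),
#'   `n_before`, `n_after`, `n_boot`, `seed`, and the replicate `deltas`.
#' @examples
#' b <- bootstrap_delta(rnorm(40), rnorm(40, 1), n_boot = 1000, seed = 1)
#' tidy(b)
#' @export
bootstrap_delta <- function(before, after, n_boot = 10000L, seed = NULL,
                            probs = c(0.05, 0.95)) {
  before <- before[is.finite(before)]
  after <- after[is.finite(after)]
  if (length(before) == 0 || length(after) == 0) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  deltas <- with_seed(seed, {
    bm <- matrix(sample(before, length(before) * n_boot, replace = TRUE),
                 nrow = n_boot)
    am <- matrix(sample(after, length(after) * n_boot, replace = TRUE),
                 nrow = n_boot)
    rowMeans(am) - rowMeans(bm)
  })
  ci <- unname(stats::quantile(deltas, probs = probs, type = 7))
  direction <- if (ci[1] > 0) 1L else if (ci[2] < 0) -1L else 0L
  structure(list(
    mean_delta = mean(deltas), ci_low = ci[1], ci_high = ci[2],
    significant = direction != 0L, direction = direction,
    n_before = length(before), n_after = length(after),
    n_boot = n_boot, seed = seed, deltas = deltas
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap delta: ", signif(x$mean_delta, 4), " [",
      signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "] (",
      x$n_boot, " resamples, N=", x$n_before, ", M=", x$n_after, ") ",
      if (x$significant) {
        if (x$direction > 0) "significant increase" else "significant decrease"
      } else "not significant", "\n", sep = "")
  invisible(x)
}

#' @rdname bootstrap_delta
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(mean_delta = x$mean_delta, ci_low = x$ci_low,
                 ci_high = x$ci_high, significant = x$significant,
                 direction = x$direction)
}

#' @rdname bootstrap_delta
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(n_before = x$n_before, n_after = x$n_after,
                 n_boot = x$n_boot,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Pearson correlation between an animal covariate and an effect
#'
#' Pearson correlation with its standard t-based p-value on `n - 2`
#' degrees of freedom, as used for relating per-animal maturity covariates
#' (age, days since eye opening, initial orientation selectivity) to
#' training-induced changes.
#'
#' @param x,y Paired numeric vectors (at least 3 complete pairs).
#' @return A tibble with `rho`, `p_value`, `df`, `n`.
#' @export
covariate_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          df = length(x) - 2L, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 df = unname(ct$parameter), n = length(x))
}

#' Two-sample t-test between animal groups
#'
#' Unpaired two-sample t-test with pooled variance (the classical form),
#' used to compare effect sizes between groups of animals.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return A tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
group_ttest <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Project 10-dimensional response vectors to the principal plane
#'
#' Unit-normalizes every input response vector together with the rows of
#' the kernel response matrix, mean-centers them jointly, and projects all
#' points onto the top two principal components of the combined set, so
#' measured population means can be displayed in the same plane as the
#' ideal-kernel responses. The sign of each component is fixed by making
#' its largest-magnitude loading positive, so the projection is
#' deterministic.
#'
#' @param means A tibble with an `id` column and a `response` list-column
#'   of 10-vectors, or a numeric matrix with one vector per row.
#' @param M A [kernel_response_matrix()] (its rows are projected too).
#' @param fit_on `"all"` (default: inputs and kernel rows jointly) or
#'   `"kernels"` (principal axes from the kernel rows only).
#' @return A tibble with `id`, `type` (`"input"` or `"kernel"`), `pc1`,
#'   `pc2`; the proportion of variance explained is in the
#'   `variance_explained` attribute.
#' @export
pca_project <- function(means, M, fit_on = c("all", "kernels")) {
  fit_on <- match.arg(fit_on)
  if (is.data.frame(means)) {
    ids <- as.character(means$id)
    X <- do.call(rbind, lapply(means$response, as.numeric))
  } else {
    X <- as.matrix(means)
    ids <- if (is.null(rownames(X))) paste0("v", seq_len(nrow(X))) else rownames(X)
  }
  if (nrow(X) < 2L) stop("need at least 2 input vectors", call. = FALSE)
  if (ncol(X) != ncol(M)) stop("vectors must match the kernel matrix dimension", call. = FALSE)
  unit <- function(A) A / sqrt(rowSums(A^2))
  X <- unit(X)
  K <- unit(unclass(M))
  all_pts <- rbind(X, K)
  fit_pts <- if (fit_on == "all") all_pts else K
  ctr <- colMeans(fit_pts)
  sv <- svd(sweep(fit_pts, 2, ctr))
  if (sum(sv$d > max(sv$d) * 1e-10) < 2L) stop("combined point set has rank < 2", call. = FALSE)
  V <- sv$v[, 1:2, drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scores <- sweep(all_pts, 2, ctr) %*% V
  out <- tibble::tibble(
    id = c(ids, rownames(M)),
    type = rep(c("input", "kernel"), c(nrow(X), nrow(K))),
    pc1 = scores[, 1], pc2 = scores[, 2]
  )
  attr(out, "variance_explained") <- (sv$d[1:2]^2) / sum(sv$d^2)
  out
}

#' Change in RPI against the trained stimulus, per reference stimulus
#'
#' For every family stimulus `X` other than the trained stimulus `ST`,
#' computes the mean RPI(X vs ST) over cells after training minus the mean
#' before. The self pair (ST vs ST) is excluded, being 0 by definition.
#' Cells whose RPI is undefined are dropped with a message.
#'
#' @param before,after Tibbles of trial responses (`cell_id`, `stimulus`,
#'   `trial`, `dff`) or tibbles with `cell_id` + `mean_response`
#'   list-column as produced by [summarize_cell_tuning()].
#' @param M A [kernel_response_matrix()].
#' @param trained Trained stimulus label (must be a family stimulus).
#' @return A tibble with one row per reference stimulus: `reference`,
#'   `mean_before`, `mean_after`, `delta_rpi`, `n_before`, `n_after`.
#' @export
delta_rpi_by_stimulus <- function(before, after, M, trained) {
  trained <- sub("^K", "", as.character(trained))
  if (!trained %in% colnames(M)) stop("`trained` must be a family stimulus", call. = FALSE)
  cell_means <- function(tbl) {
    if ("mean_response" %in% names(tbl)) return(tbl$mean_response)
    tbl |>
      dplyr::filter(.data$stimulus %in% colnames(M)) |>
      dplyr::group_by(.data$cell_id, .data$stimulus) |>
      dplyr::summarise(m = mean(.data$dff), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stimulus", values_from = "m") |>
      (\(w) lapply(seq_len(nrow(w)),
                   function(r) unlist(w[r, colnames(M)])))()
  }
  mb <- cell_means(before); ma <- cell_means(after)
  refs <- setdiff(colnames(M), trained)
  rows <- lapply(refs, function(ref) {
    rb <- vapply(mb, function(r) suppressWarnings(
      response_projection_index(r, ref, trained, M)), numeric(1))
    ra <- vapply(ma, function(r) suppressWarnings(
      response_projection_index(r, ref, trained, M)), numeric(1))
    nd <- sum(!is.finite(rb)) + sum(!is.finite(ra))
    if (nd > 0) message(nd, " undefined RPI value(s) dropped for reference ", ref)
    tibble::tibble(reference = ref,
                   mean_before = mean(rb, na.rm = TRUE),
                   mean_after = mean(ra, na.rm = TRUE),
                   n_before = sum(is.finite(rb)), n_after = sum(is.finite(ra)))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(delta_rpi = .data$mean_after - .data$mean_before,
                  .after = "mean_after")
}
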