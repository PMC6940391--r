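#' Selectivity index over the stimulus family
#'
#' The selectivity index of stimulus `n` is that stimulus's share of the
#' cell's summed mean response across the whole 10-stimulus family. It
#' ranges from 0 (no response to `n`) to 1 (exclusive response), but peaks
#' near 0.2-0.3 in practice because many family stimuli are mutually
#' correlated. Negative mean responses are clamped to 0 by default
#' (firing-rate semantics) before forming the ratio.
#'
#' @param responses Named numeric vector of mean responses, one per family
#'   stimulus.
#' @param stimulus Optional single label; if omitted the full SI vector is
#'   returned (it sums to 1 whenever defined).
#' @param negative `"clamp"` (default) or `"raw"`.
#' @return A named SI vector, or a single SI value if `stimulus` is given;
#'   `NA` with a warning when the summed response is not positive.
#' @examples
#' r <- stats::setNames(rep(1, 10), family_labels())
#' selectivity_index(r) # 0.1 everywhere
#' @export
selectivity_index <- function(responses, stimulus = NULL,
                              negative = c("clamp", "raw")) {
  negative <- match.arg(negative)
  r <- as.numeric(responses)
  names(r) <- names(responses)
  if (negative == "clamp") r <- pmax(r, 0)
  denom <- sum(r)
  if (!is.finite(denom) || denom <= 0) {
    warning("selectivity index undefined: summed response is not positive")
    si <- rep(NA_real_, length(r))
    names(si) <- names(r)
  } else {
    si <- r / denom
  }
  if (is.null(stimulus)) si else si[[as.character(stimulus)]]
}

#' Response projection index (RPI)
#'
#' Locates a cell's 10-dimensional response vector between the lines
#' spanned by two ideal-kernel response vectors. With `u1`, `u2` the
#' unit-normalized referent rows of the kernel response matrix, `D1` and
#' `D2` are the Euclidean distances from `R` to its projections on those
#' lines, and `RPI = (D1 - D2) / (D1 + D2)`. A response identical to the
#' first referent gives -1, identical to the second gives +1; the index is
#' invariant to positive rescaling of `R` and antisymmetric in its
#' referents.
#'
#' @param responses Numeric response vector in the kernel matrix's stimulus
#'   order (names, if present, are checked against the matrix columns).
#' @param ref_i,ref_j Referent labels (`"KF"`/`"F"` style both accepted).
#' @param M A [kernel_response_matrix()].
#' @return A single value in `[-1, 1]`, or `NA` (with a warning) when `R`
#'   is zero or the referents are collinear.
#' @examples
#' M <- kernel_response_matrix(build_family())
#' response_projection_index(M["KF", ], "KF", "KB", M) # -1
#' @export
response_projection_index <- function(responses, ref_i, ref_j, M) {
  R <- as.numeric(responses)
  if (length(R) != ncol(M)) stop("`responses` must have one value per stimulus", call. = FALSE)
  if (!is.null(names(responses)) && !identical(names(responses), colnames(M))) {
    R <- as.numeric(responses[colnames(M)])
  }
  v1 <- as.numeric(kernel_row(M, ref_i))
  v2 <- as.numeric(kernel_row(M, ref_j))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0 || sum(R^2) == 0) {
    warning("RPI undefined: zero response or referent vector")
    return(NA_real_)
  }
  u1 <- v1 / n1; u2 <- v2 / n2
  if (isTRUE(all.equal(abs(sum(u1 * u2)), 1))) {
    warning("RPI undefined: collinear referents")
    return(NA_real_)
  }
  d1 <- sqrt(sum((R - sum(R * u1) * u1)^2))
  d2 <- sqrt(sum((R - sum(R * u2) * u2)^2))
  (d1 - d2) / (d1 + d2)
}

# wrap an angular difference (degrees) onto [0, 180]
ang_diff <- function(x) {
  d <- abs(x) %% 360
  pmin(d, 360 - d)
}

#' Orientation selectivity as one minus the circular variance
#'
#' `1 - CirVar = | sum_k R(theta_k) exp(2i theta_k) / sum_k R(theta_k) |`,
#' computed in orientation space (angles doubled, so opposite directions
#' reinforce). Responses enter blank-subtracted. The value lies in `[0, 1]`
#' for nonnegative responses: 0 for an isotropic cell, 1 for a response
#' confined to a single orientation.
#'
#' @param responses Mean response at each direction angle.
#' @param angles Direction angles in degrees (full 0-360 sweep, at least 4).
#' @param blank_mean Mean blank response to subtract (default 0).
#' @return A single value; `NA` (with a warning) when the summed response
#'   is 0.
#' @export
orientation_selectivity <- function(responses, angles, blank_mean = 0) {
  stopifnot(length(responses) == length(angles))
  if (length(angles) < 4L) stop("need at least 4 angles spanning orientation space", call. = FALSE)
  r <- as.numeric(responses) - blank_mean
  s <- sum(r)
  if (s == 0) {
    warning("orientation selectivity undefined: summed response is 0")
    return(NA_real_)
  }
  Mod(sum(r * exp(2i * angles * pi / 180)) / s)
}

#' Hotelling T-squared test for significant orientation tuning
#'
#' Each trial's responses across the direction sweep are collapsed to one
#' point in the complex orientation plane, `z_t = sum_k R_t(theta_k)
#' exp(2i theta_k)`; untuned cells scatter around the origin while tuned
#' cells displace coherently. A one-sample Hotelling T-squared test of the
#' mean of `(Re z, Im z)` against the origin gives the gating p-value.
#'
#' @param trials A trials-by-angles numeric matrix, or a long tibble with
#'   columns `trial`, `angle`, `response`.
#' @param angles Direction angles in degrees (for matrix input; defaults to
#'   an even sweep over 0-360).
#' @return A list of class `"hotelling_test"` with `statistic` (T-squared),
#'   `f`, `df1`, `df2`, `p_value`, and `n_trials`; `p_value` is `NA` when
#'   the trial covariance is singular.
#' @export
hotelling_orientation_test <- function(trials, angles = NULL) {
  m <- direction_trial_matrix(trials, angles)
  angles <- attr(m, "angles")
  n <- nrow(m)
  if (n < 3L) stop("Hotelling test needs at least 3 trials", call. = FALSE)
  z <- m %*% exp(2i * angles * pi / 180)
  X <- cbind(Re(z), Im(z))
  xbar <- colMeans(X)
  S <- stats::cov(X)
  t2 <- tryCatch(n * drop(t(xbar) %*% solve(S, xbar)), error = function(e) NA_real_)
  if (!is.finite(t2)) {
    warning("Hotelling test undefined: singular trial covariance")
    f <- p <- NA_real_
  } else {
    f <- (n - 2) / (2 * (n - 1)) * t2
    p <- stats::pf(f, 2, n - 2, lower.tail = FALSE)
  }
  structure(list(statistic = t2, f = f, df1 = 2, df2 = n - 2,
                 p_value = p, n_trials = n),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat("One-sample Hotelling T2 (orientation space): T2 =",
      signif(x$statistic, 4), ", p =", signif(x$p_value, 4),
      "on", x$n_trials, "trials\n")
  invisible(x)
}

# normalize direction-trial input to a trials x angles matrix
# (blank trials, angle = NA, are dropped)
direction_trial_matrix <- function(trials, angles = NULL) {
  if (is.data.frame(trials)) {
    stopifnot(all(c("trial", "angle", "response") %in% names(trials)))
    trials <- trials[!is.na(trials$angle), ]
    angles <- sort(unique(trials$angle))
    trs <- sort(unique(trials$trial))
    m <- matrix(NA_real_, length(trs), length(angles))
    m[cbind(match(trials$trial, trs), match(trials$angle, angles))] <-
      trials$response
  } else {
    m <- as.matrix(trials)
    if (is.null(angles)) angles <- seq(0, 360, length.out = ncol(m) + 1L)[-(ncol(m) + 1L)]
  }
  stopifnot(length(angles) == ncol(m))
  structure(m, angles = angles)
}

#' Double-Gaussian direction tuning curve
#'
#' `R(theta) = C + Rp exp(-ang_diff(theta - theta_pref)^2 / (2 sigma^2)) +
#' Rn exp(-ang_diff(theta + 180 - theta_pref)^2 / (2 sigma^2))`, with
#' angular differences wrapped onto 0-180 degrees.
#'
#' @param theta Direction angles, degrees.
#' @param C,Rp,Rn,theta_pref,sigma Curve parameters (degrees for
#'   `theta_pref` and `sigma`).
#' @return Response at each angle.
#' @export
dg_curve <- function(theta, C, Rp, Rn, theta_pref, sigma) {
  C + Rp * exp(-ang_diff(theta - theta_pref)^2 / (2 * sigma^2)) +
    Rn * exp(-ang_diff(theta + 180 - theta_pref)^2 / (2 * sigma^2))
}

#' Fit a double-Gaussian direction tuning curve
#'
#' Least-squares fit of `R(theta) = C + Rp exp(-ang_diff(theta -
#' theta_pref)^2 / (2 sigma^2)) + Rn exp(-ang_diff(theta + 180 -
#' theta_pref)^2 / (2 sigma^2))` to per-angle mean responses, where
#' `ang_diff` wraps angular differences onto 0-180 degrees. `C` is a
#' constant offset, `Rp` and `Rn` the above-offset responses in the
#' preferred and null directions, and the tuning half-width at half-height
#' is `sqrt(log 4) * sigma`. The fit initializes `theta_pref` at the
#' peak-response angle and `sigma` at 30 degrees, restarts from a small
#' deterministic grid of widths, and constrains `sigma` to 5-90 degrees.
#'
#' @param trials A trials-by-angles matrix, a long tibble with columns
#'   `trial`, `angle`, `response`, or a numeric vector of per-angle means.
#' @param angles Direction angles in degrees (for matrix/vector input).
#' @param n_restarts Number of width restarts (default 5).
#' @return An object of class `"dg_fit"`: coefficients `C`, `Rp`, `Rn`,
#'   `theta_pref` (degrees, in `[0, 360)`), `sigma` (degrees), plus
#'   `halfwidth`, `di` (see [direction_index()]), `sse`, `converged`, and
#'   the per-angle means used.
#' @examples
#' th <- seq(0, 315, by = 45)
#' y <- dg_curve(th, C = 0.1, Rp = 1, Rn = 0.4, theta_pref = 90, sigma = 30)
#' fit <- fit_double_gaussian(y, angles = th)
#' coef(fit)
#' @export
fit_double_gaussian <- function(trials, angles = NULL, n_restarts = 5L) {
  if (is.numeric(trials) && is.null(dim(trials)) && !is.data.frame(trials)) {
    if (is.null(angles)) angles <- seq(0, 360, length.out = length(trials) + 1L)[-(length(trials) + 1L)]
    means <- as.numeric(trials)
  } else {
    m <- direction_trial_matrix(trials, angles)
    angles <- attr(m, "angles")
    means <- colMeans(m)
  }
  stopifnot(length(means) >= 5L) # 5 free parameters
  theta0 <- angles[which.max(means)]
  c0 <- min(means)
  rp0 <- max(means) - c0
  null_i <- which.min(ang_diff(angles - (theta0 + 180)))
  rn0 <- max(means[null_i] - c0, 0)
  rng <- max(diff(range(means)), 1e-6)
  resid_fn <- function(p) means - dg_curve(angles, p[1], p[2], p[3], p[4], p[5])
  lower <- c(c0 - rng, 1e-9, -2 * rng, theta0 - 180, 5)
  upper <- c(max(means), 4 * rng, 2 * rng, theta0 + 180, 90)
  sigmas <- c(30, 15, 45, 60, 10)[seq_len(max(1L, n_restarts))]
  best <- NULL
  for (s0 in sigmas) {
    start <- c(c0, max(rp0, 1e-6), rn0, theta0, s0)
    fit <- tryCatch(
      minpack.lm::nls.lm(start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    value <- sum(fit$fvec^2)
    if (is.null(best) || value < best$value) {
      prev <- if (is.null(best)) Inf else best$value
      best <- list(par = fit$par, value = value,
                   convergence = as.integer(!fit$info %in% 1:4))
      # restarts guard against local minima; once two starts agree on the
      # optimum (or the fit is essentially exact) further starts add nothing
      if (prev - value <= 1e-10 * (1 + value)) break
    } else if (value - best$value <= 1e-10 * (1 + best$value)) {
      break
    }
    if (best$value <= 1e-20) break
  }
  if (is.null(best)) {
    warning("double-Gaussian fit failed to converge")
    co <- c(C = NA_real_, Rp = NA_real_, Rn = NA_real_,
            theta_pref = NA_real_, sigma = NA_real_)
    return(structure(list(coefficients = co, halfwidth = NA_real_,
                          di = NA_real_, sse = NA_real_, converged = FALSE,
                          angles = angles, means = means), class = "dg_fit"))
  }
  p <- best$par
  p[4] <- p[4] %% 360
  co <- c(C = p[1], Rp = p[2], Rn = p[3], theta_pref = p[4], sigma = p[5])
  structure(list(
    coefficients = co,
    halfwidth = sqrt(log(4)) * p[5],
    di = unname((p[2] - max(p[3], 0)) / p[2]),
    sse = best$value,
    converged = best$convergence == 0,
    angles = angles, means = means
  ), class = "dg_fit")
}

#' @export
coef.dg_fit <- function(object, ...) object$coefficients

#' @export
predict.dg_fit <- function(object, newdata = NULL, ...) {
  th <- if (is.null(newdata)) object$angles else {
    if (is.data.frame(newdata)) newdata$angle else as.numeric(newdata)
  }
  co <- object$coefficients
  dg_curve(th, co[["C"]], co[["Rp"]], co[["Rn"]], co[["theta_pref"]], co[["sigma"]])
}

#' @export
print.dg_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Double-Gaussian direction fit: theta_pref =", signif(co[["theta_pref"]], 4),
      "deg, sigma =", signif(co[["sigma"]], 4),
      "deg (half-width", signif(x$halfwidth, 4), "deg), DI =",
      signif(x$di, 3), "\n")
  invisible(x)
}

#' Direction index from a tuning fit
#'
#' `DI = (Rp - max(Rn, 0)) / Rp`: 1 for a fully direction-selective cell
#' (no null response above offset), 0 for equal preferred and null
#' responses. The `max` clamps `DI` at 1 when the fitted null response is
#' negative.
#'
#' @param fit A [fit_double_gaussian()] object, or the `Rp` value.
#' @param Rn Null-direction response (when `fit` is numeric).
#' @return The direction index, at most 1; `NA` with a warning if
#'   `Rp <= 0`.
#' @examples
#' direction_index(10, 5) # 0.5
#' @export
direction_index <- function(fit, Rn = NULL) {
  if (inherits(fit, "dg_fit")) {
    rp <- fit$coefficients[["Rp"]]; rn <- fit$coefficients[["Rn"]]
  } else {
    rp <- as.numeric(fit); rn <- as.numeric(Rn)
  }
  if (!is.finite(rp) || rp <= 0) {
    warning("direction index undefined: Rp <= 0")
    return(NA_real_)
  }
  (rp - max(rn, 0)) / rp
}

#' Per-cell tuning summary over the stimulus family
#'
#' Data-frame-first wrapper: takes a trial response table and a kernel
#' response matrix and returns one row per cell with responsiveness
#' p-value (one-way ANOVA over all stimuli plus blank), mean responses,
#' selectivity indices and RPIs for the requested referent pairs.
#'
#' @param responses Tibble with columns `cell_id`, `stimulus`, `trial`,
#'   `dff` (stimulus `"blank"` included for the responsiveness gate).
#' @param M A [kernel_response_matrix()].
#' @param referents List of length-2 character vectors of referent labels,
#'   e.g. `list(c("F", "B"), c("F", "S4"))`.
#' @param alpha Responsiveness threshold (default 0.05).
#' @param negative Negative-response policy for the selectivity index.
#' @return A tibble, one row per cell: `cell_id`, `p_responsive`,
#'   `responsive`, `mean_response` and `si` list-columns (named vectors in
#'   family order), and one `rpi_<i>_vs_<j>` column per referent pair.
#' @export
summarize_cell_tuning <- function(responses, M,
                                  referents = list(c("F", "B")),
                                  alpha = 0.05, negative = "clamp") {
  stopifnot(all(c("cell_id", "stimulus", "trial", "dff") %in% names(responses)))
  labs <- colnames(M)
  anova_tbl <- responsiveness_test(responses, alpha = alpha)
  means <- responses |>
    dplyr::filter(.data$stimulus %in% labs) |>
    dplyr::group_by(.data$cell_id, .data$stimulus) |>
    dplyr::summarise(mean_dff = mean(.data$dff), .groups = "drop")
  per_cell <- means |>
    tidyr::nest(data = -"cell_id") |>
    dplyr::mutate(
      mean_response = purrr::map(.data$data, function(d) {
        stats::setNames(d$mean_dff[match(labs, d$stimulus)], labs)
      })
    ) |>
    dplyr::select(-"data")
  per_cell$si <- purrr::map(per_cell$mean_response, selectivity_index,
                            negative = negative)
  for (rf in referents) {
    col <- paste0("rpi_", rf[1], "_vs_", rf[2])
    per_cell[[col]] <- purrr::map_dbl(
      per_cell$mean_response,
      function(r) suppressWarnings(response_projection_index(r, rf[1], rf[2], M)))
  }
  dplyr::left_join(anova_tbl, per_cell, by = "cell_id")
}

#' Per-cell direction tuning summary
#'
#' Runs the direction-sweep pipeline per cell: orientation selectivity
#' (1 - circular variance, blank-subtracted), the Hotelling orientation
#' gate, and — for every cell, with the gate recorded alongside — the
#' double-Gaussian fit and direction index.
#'
#' @param trials Tibble with columns `cell_id`, `trial`, `angle`,
#'   `response`; rows with `angle = NA` (or a `"blank"` stimulus column)
#'   are treated as blank trials.
#' @param alpha Hotelling gate threshold.
#' @return A tibble, one row per cell: `osi_1mcv`, `hotelling_p`,
#'   `tuned`, fitted `C`, `Rp`, `Rn`, `theta_pref`, `sigma`, `halfwidth`,
#'   `di`, `converged`.
#' @export
summarize_direction_tuning <- function(trials, alpha = 0.05) {
  stopifnot(all(c("cell_id", "trial", "angle", "response") %in% names(trials)))
  trials |>
    tidyr::nest(data = -"cell_id") |>
    dplyr::mutate(res = purrr::map(.data$data, function(d) {
      blank <- d$response[is.na(d$angle)]
      d <- d[!is.na(d$angle), ]
      m <- direction_trial_matrix(d)
      angles <- attr(m, "angles")
      ht <- hotelling_orientation_test(m, angles)
      fit <- fit_double_gaussian(m, angles)
      co <- fit$coefficients
      tibble::tibble(
        osi_1mcv = orientation_selectivity(
          colMeans(m), angles,
          blank_mean = if (length(blank)) mean(blank) else 0),
        hotelling_p = ht$p_value,
        tuned = is.finite(ht$p_value) && ht$p_value < alpha,
        C = co[["C"]], Rp = co[["Rp"]], Rn = co[["Rn"]],
        theta_pref = co[["theta_pref"]], sigma = co[["sigma"]],
        halfwidth = fit$halfwidth, di = fit$di, converged = fit$converged
      )
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")
}
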