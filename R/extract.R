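#' Trial-level dF/F responses from fluorescence traces
#'
#' For every scheduled trial and every cell, the response is
#' `(F_stim - F_base) / F_base`, where `F_stim` is the mean fluorescence in
#' the response window after stimulus onset (default `[0, 5]` s; a
#' `[0, 7]` s window suits cells whose responses outlast the stimulus) and
#' `F_base` is the mean over the final `baseline_window` seconds of the
#' interstimulus interval preceding onset. Because the imaging frame period
#' (~1.5 s) is coarse relative to these windows, a frame is assigned to a
#' window when its acquisition midpoint falls inside the half-open
#' interval `[t0, t1)`.
#'
#' Trials whose baseline is not positive are dropped (and flagged in the
#' returned table) rather than imputed; a trial with no baseline frames is
#' an error.
#'
#' @param traces Long tibble of fluorescence samples: columns `time`
#'   (frame acquisition start, seconds), `cell_id`, `f`.
#' @param schedule Tibble of trials: columns `stimulus`, `onset`
#'   (seconds), `duration` (seconds). Trial indices are assigned per
#'   stimulus in onset order. A `"blank"` stimulus is allowed and treated
#'   like any other condition.
#' @param frame_interval Frame period in seconds (used to form frame
#'   midpoints).
#' @param response_window Two numbers, seconds post-onset (default
#'   `c(0, 5)`).
#' @param baseline_window Length of the pre-onset baseline, seconds
#'   (default 3).
#' @return A tibble with columns `cell_id`, `stimulus`, `trial`, `dff`,
#'   `f_stim`, `f_base`, `valid`. Invalid trials carry `dff = NA`.
#' @export
compute_dff <- function(traces, schedule, frame_interval,
                        response_window = c(0, 5), baseline_window = 3) {
  stopifnot(all(c("time", "cell_id", "f") %in% names(traces)),
            all(c("stimulus", "onset", "duration") %in% names(schedule)),
            frame_interval > 0, length(response_window) == 2L,
            response_window[2] > response_window[1], baseline_window > 0)
  schedule <- dplyr::arrange(tibble::as_tibble(schedule), .data$onset)
  if (any(diff(schedule$onset) <= 0)) stop("schedule onsets must be strictly increasing", call. = FALSE)
  schedule$trial <- stats::ave(seq_len(nrow(schedule)), schedule$stimulus,
                               FUN = seq_along)
  mid <- traces$time + frame_interval / 2
  per_trial <- function(onset) {
    stim_i <- mid >= onset + response_window[1] & mid < onset + response_window[2]
    base_i <- mid >= onset - baseline_window & mid < onset
    list(stim = stim_i, base = base_i)
  }
  out <- lapply(seq_len(nrow(schedule)), function(r) {
    w <- per_trial(schedule$onset[r])
    if (!any(w$base)) stop("trial at onset ", schedule$onset[r],
                           " s has no baseline frames", call. = FALSE)
    st <- traces[w$stim, ] |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(f_stim = mean(.data$f), .groups = "drop")
    ba <- traces[w$base, ] |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(f_base = mean(.data$f), .groups = "drop")
    dplyr::inner_join(st, ba, by = "cell_id") |>
      dplyr::mutate(stimulus = schedule$stimulus[r], trial = schedule$trial[r])
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::mutate(
      valid = .data$f_base > 0,
      dff = dplyr::if_else(.data$valid,
                           (.data$f_stim - .data$f_base) / .data$f_base,
                           NA_real_)
    ) |>
    dplyr::select("cell_id", "stimulus", "trial", "dff", "f_stim", "f_base",
                  "valid")
  n_bad <- sum(!out$valid)
  if (n_bad > 0) {
    warning(n_bad, " trial(s) with non-positive baseline dropped from dF/F")
  }
  out
}

#' Visual responsiveness gate (one-way ANOVA)
#'
#' A cell is "visually responsive" when a classical one-way fixed-effects
#' ANOVA of its trial dF/F values over all stimulus conditions plus the
#' blank rejects at `alpha`. No transform is applied to the responses.
#'
#' @param responses Tibble with columns `cell_id`, `stimulus`, `trial`,
#'   `dff` (blank included as its own condition).
#' @param alpha Rejection threshold (default 0.05).
#' @return A tibble with one row per cell: `p_responsive` (`NA`, flagged,
#'   when every condition has zero within-group variance) and
#'   `responsive`.
#' @export
responsiveness_test <- function(responses, alpha = 0.05) {
  stopifnot(all(c("cell_id", "stimulus", "dff") %in% names(responses)))
  responses |>
    dplyr::filter(is.finite(.data$dff)) |>
    tidyr::nest(data = -"cell_id") |>
    dplyr::mutate(p_responsive = purrr::map_dbl(.data$data, function(d) {
      counts <- table(d$stimulus)
      if (length(counts) < 2L) stop("responsiveness test needs >= 2 conditions", call. = FALSE)
      if (any(counts < 2L)) stop("responsiveness test needs >= 2 trials per condition", call. = FALSE)
      wss <- sum(tapply(d$dff, d$stimulus, function(v) sum((v - mean(v))^2)))
      if (wss == 0) return(NA_real_) # degenerate: no within-group variance
      fit <- stats::oneway.test(dff ~ stimulus, data = d, var.equal = TRUE)
      unname(fit$p.value)
    })) |>
    dplyr::select(-"data") |>
    dplyr::mutate(responsive = is.finite(.data$p_responsive) &
                    .data$p_responsive < alpha)
}
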