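# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate one cell's trial responses to the stimulus family
#'
#' A simulated cell is a noisy mixture of ideal kernels: its expected
#' response to stimulus `j` is `gain * sum_k w_k M[k, j]`, and each trial
#' adds independent Gaussian noise on the dF/F scale. Blank trials are
#' noise only.
#'
#' @param weights Nonnegative mixture weights over the kernels (rows of
#'   `M`); normalized to sum to 1.
#' @param M A [kernel_response_matrix()].
#' @param gain dF/F scale of the cell's maximal ideal response.
#' @param noise_sd Trial noise SD (additive, dF/F units).
#' @param n_trials Trials per stimulus (default 8).
#' @param cell_id Identifier written into the table.
#' @param seed Optional seed (reproducible per seed).
#' @return A tibble with columns `cell_id`, `stimulus` (family labels plus
#'   `"blank"`), `trial`, `dff`.
#' @export
simulate_cell_responses <- function(weights, M, gain = 0.5, noise_sd = 0.05,
                                    n_trials = 8L, cell_id = "cell1",
                                    seed = NULL) {
  w <- as.numeric(weights)
  if (length(w) != nrow(M) || anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("`weights` must be nonnegative, one per kernel, with positive sum",
         call. = FALSE)
  }
  stopifnot(gain > 0, noise_sd >= 0, n_trials >= 1)
  w <- w / sum(w)
  mu <- c(gain * drop(w %*% unclass(M)), blank = 0)
  labs <- c(colnames(M), "blank")
  with_seed(seed, tibble::tibble(
    cell_id = cell_id,
    stimulus = rep(labs, each = n_trials),
    trial = rep(seq_len(n_trials), times = length(labs)),
    dff = rep(mu, each = n_trials) +
      stats::rnorm(length(labs) * n_trials, sd = noise_sd)
  ))
}

#' Simulate direction-sweep trials from the double-Gaussian model
#'
#' Inverts the tuning model: per-angle means follow the double-Gaussian
#' curve with `Rp = gain` and `Rn = Rp * (1 - di_true)`, so the programmed
#' direction index is exactly `di_true`; trials add Gaussian noise, and
#' blank trials (angle `NA`) are noise only.
#'
#' @param theta_pref Preferred direction, degrees.
#' @param di_true Programmed direction index in `[0, 1]`.
#' @param sigma Tuning width parameter, degrees.
#' @param C Constant offset (dF/F).
#' @param gain Above-offset preferred-direction response `Rp` (dF/F).
#' @param noise_sd Trial noise SD.
#' @param n_angles Number of equally spaced directions over 0-360
#'   (default 8).
#' @param n_trials Trials per angle (default 8).
#' @param n_blank Blank trials (default `n_trials`).
#' @param cell_id Identifier written into the table.
#' @param seed Optional seed.
#' @return A tibble with columns `cell_id`, `trial`, `angle` (`NA` for
#'   blanks), `response`.
#' @export
simulate_direction_trials <- function(theta_pref, di_true, sigma = 30,
                                      C = 0.05, gain = 0.5, noise_sd = 0.05,
                                      n_angles = 8L, n_trials = 8L,
                                      n_blank = n_trials, cell_id = "cell1",
                                      seed = NULL) {
  if (!is.finite(di_true) || di_true < 0 || di_true > 1) {
    stop("`di_true` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(gain > 0, sigma > 0, noise_sd >= 0, n_angles >= 4, n_trials >= 1)
  angles <- seq(0, 360, length.out = n_angles + 1L)[-(n_angles + 1L)]
  mu <- dg_curve(angles, C, gain, gain * (1 - di_true), theta_pref, sigma)
  with_seed(seed, {
    stim <- tibble::tibble(
      cell_id = cell_id,
      trial = rep(seq_len(n_trials), each = n_angles),
      angle = rep(angles, times = n_trials),
      response = rep(mu, times = n_trials) +
        stats::rnorm(n_angles * n_trials, sd = noise_sd)
    )
    blank <- tibble::tibble(
      cell_id = cell_id, trial = seq_len(n_blank), angle = NA_real_,
      response = stats::rnorm(n_blank, sd = noise_sd)
    )
    dplyr::bind_rows(stim, blank)
  })
}

#' Tuning width that yields a target orientation selectivity
#'
#' The documented calibration behind `initial_osi_target`: for a noiseless
#' double-Gaussian curve with the given offset ratio and direction index,
#' orientation selectivity (1 - circular variance) decreases
#' monotonically with `sigma`; this solves for the `sigma` (within 5-90
#' degrees) whose curve attains the target, clamping (with a warning) when
#' the target is outside the achievable range.
#'
#' @param target_osi Desired 1 - CirVar of the noiseless tuning curve.
#' @param n_angles Directions in the sweep.
#' @param C,Rp Curve offset and preferred response.
#' @param di Direction index of the calibration curve.
#' @return Tuning width `sigma` in degrees.
#' @export
calibrate_sigma_for_osi <- function(target_osi, n_angles = 8L, C = 0.05,
                                    Rp = 0.5, di = 0.3) {
  angles <- seq(0, 360, length.out = n_angles + 1L)[-(n_angles + 1L)]
  osi_of <- function(sigma) {
    orientation_selectivity(
      dg_curve(angles, C, Rp, Rp * (1 - di), 0, sigma), angles)
  }
  lo <- osi_of(90); hi <- osi_of(5)
  if (target_osi >= hi) {
    warning("target OSI above achievable range; using sigma = 5")
    return(5)
  }
  if (target_osi <= lo) {
    warning("target OSI below achievable range; using sigma = 90")
    return(90)
  }
  stats::uniroot(function(s) osi_of(s) - target_osi, c(5, 90))$root
}

#' Simulate an animal's before/after recording epochs
#'
#' Generates two cell populations with the statistical structure the
#' pipeline assumes. Every cell's 10-stimulus tuning is a noisy kernel
#' mixture whose weights are drawn from a smooth-motion-dominated
#' Dirichlet distribution (immature cortex responds best to drifting
#' gratings), and every cell also receives a direction sweep generated
#' from the double-Gaussian model.
#'
#' The two plasticity regimes differ in what training changes:
#' * `"instructive"`: after-epoch mixture weights are pulled toward the
#'   trained stimulus's kernel by `training_effect` (`w' = (1 - e) w +
#'   e 1_ST`), while direction selectivity does not mature — expected
#'   change in RPI(F vs ST) is positive, expected change in DI
#'   non-positive.
#' * `"permissive"`: after-epoch weights are fresh draws from the same
#'   distribution (training does not sculpt pattern selectivity) while
#'   the DI distribution matures upward — expected change in RPI is ~0
#'   and in DI positive.
#'
#' @param n_cells_before,n_cells_after Cells per epoch (default 100).
#' @param trained Trained stimulus label (default `"S4"`).
#' @param regime `"instructive"` or `"permissive"`.
#' @param training_effect Weight shift toward the trained kernel in
#'   `[0, 1]`; applied only in the instructive regime.
#' @param M Kernel response matrix (default: the default family's).
#' @param gain,noise_sd,n_trials Trial-level response parameters.
#' @param di_range_before,di_range_after Uniform DI ranges for the two
#'   epochs; `di_range_after` defaults to `di_range_before` in the
#'   instructive regime and to a matured range in the permissive regime.
#' @param initial_osi_target Optional mean orientation selectivity to aim
#'   for via [calibrate_sigma_for_osi()]; otherwise `sigma = 30` degrees.
#' @param animal_id,age,eo Metadata written into the record: age in
#'   postnatal days and `eo` = days since eye opening (0 = opened
#'   prematurely).
#' @param seed Optional seed; the whole animal is reproducible per seed.
#' @return A list of class `"sim_animal"`: `family_before`,
#'   `family_after` (trial response tables including blanks),
#'   `direction_before`, `direction_after` (direction-sweep tables), and
#'   `record`, a one-row tibble of animal metadata and generator truth.
#' @export
simulate_animal <- function(n_cells_before = 100L, n_cells_after = 100L,
                            trained = "S4",
                            regime = c("instructive", "permissive"),
                            training_effect = 0.5,
                            M = NULL,
                            gain = 0.5, noise_sd = 0.05, n_trials = 8L,
                            di_range_before = c(0.1, 0.5),
                            di_range_after = NULL,
                            initial_osi_target = NULL,
                            animal_id = "animal1", age = 35, eo = 5,
                            seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(M)) M <- kernel_response_matrix(build_family())
  trained <- sub("^K", "", as.character(trained))
  if (!trained %in% colnames(M)) stop("`trained` must be a family stimulus", call. = FALSE)
  if (training_effect < 0 || training_effect > 1) {
    stop("`training_effect` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(di_range_after)) {
    di_range_after <- if (regime == "permissive") c(0.4, 0.8) else di_range_before
  }
  sigma <- if (is.null(initial_osi_target)) 30 else {
    calibrate_sigma_for_osi(initial_osi_target, C = 0.05, Rp = gain)
  }
  alpha <- stats::setNames(rep(0.25, ncol(M)), colnames(M))
  alpha[c("F", "B")] <- 2 # immature population favors smooth motion
  with_seed(seed, {
    gen_epoch <- function(n_cells, epoch) {
      fam <- vector("list", n_cells); dir <- vector("list", n_cells)
      for (i in seq_len(n_cells)) {
        id <- sprintf("%s_%s_c%03d", animal_id, epoch, i)
        w <- rdirichlet1(alpha)
        if (epoch == "after" && regime == "instructive") {
          w <- (1 - training_effect) * w +
            training_effect * as.numeric(colnames(M) == trained)
        }
        di_rng <- if (epoch == "after") di_range_after else di_range_before
        fam[[i]] <- simulate_cell_responses(w, M, gain = gain,
                                            noise_sd = noise_sd,
                                            n_trials = n_trials, cell_id = id)
        dir[[i]] <- simulate_direction_trials(
          theta_pref = stats::runif(1, 0, 360),
          di_true = stats::runif(1, di_rng[1], di_rng[2]),
          sigma = sigma, C = 0.05, gain = gain, noise_sd = noise_sd,
          n_trials = n_trials, cell_id = id)
      }
      list(family = dplyr::bind_rows(fam), direction = dplyr::bind_rows(dir))
    }
    bef <- gen_epoch(n_cells_before, "before")
    aft <- gen_epoch(n_cells_after, "after")
    structure(list(
      family_before = bef$family, family_after = aft$family,
      direction_before = bef$direction, direction_after = aft$direction,
      record = tibble::tibble(
        animal_id = animal_id, age = age, eo = eo,
        trained_stimulus = trained, regime = regime,
        training_effect = if (regime == "instructive") training_effect else 0,
        n_cells_before = n_cells_before, n_cells_after = n_cells_after,
        sigma = sigma,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      )
    ), class = "sim_animal")
  })
}

#' @export
print.sim_animal <- function(x, ...) {
  r <- x$record
  cat("<sim_animal> ", r$animal_id, ": ", r$regime, " regime, trained on ",
      r$trained_stimulus, ", ", r$n_cells_before, "/", r$n_cells_after,
      " cells before/after\n", sep = "")
  invisible(x)
}

#' Analyse a simulated animal end to end
#'
#' Runs the measurement pipeline on a [simulate_animal()] object: per-cell
#' RPI(F vs trained) via [summarize_cell_tuning()], per-cell DI via
#' [summarize_direction_tuning()], and bootstrap confidence intervals on
#' the before/after change of each.
#'
#' @param sim A `sim_animal`.
#' @param M Kernel response matrix matching the one used to simulate.
#' @param what Which statistics to compute (`"rpi"`, `"di"`, or both).
#' @param n_boot,seed Bootstrap settings, see [bootstrap_delta()].
#' @return A one-row tibble: animal metadata plus `initial_osi`,
#'   `delta_rpi`, `rpi_ci_low`, `rpi_ci_high`, `rpi_significant`,
#'   `delta_di`, `di_ci_low`, `di_ci_high`, `di_significant` (columns
#'   `NA` when not requested).
#' @export
analyze_animal <- function(sim, M = NULL, what = c("rpi", "di"),
                           n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(sim, "sim_animal"))
  if (is.null(M)) M <- kernel_response_matrix(build_family())
  trained <- sim$record$trained_stimulus
  out <- sim$record
  out$initial_osi <- NA_real_
  out$delta_rpi <- out$rpi_ci_low <- out$rpi_ci_high <- NA_real_
  out$rpi_significant <- NA
  out$delta_di <- out$di_ci_low <- out$di_ci_high <- NA_real_
  out$di_significant <- NA
  if ("rpi" %in% what) {
    rcol <- paste0("rpi_F_vs_", trained)
    tb <- summarize_cell_tuning(sim$family_before, M,
                                referents = list(c("F", trained)))
    ta <- summarize_cell_tuning(sim$family_after, M,
                                referents = list(c("F", trained)))
    b <- bootstrap_delta(tb[[rcol]], ta[[rcol]], n_boot = n_boot, seed = seed)
    out$delta_rpi <- b$mean_delta
    out$rpi_ci_low <- b$ci_low; out$rpi_ci_high <- b$ci_high
    out$rpi_significant <- b$direction > 0 # stated one-sided rule
  }
  if ("di" %in% what) {
    db <- summarize_direction_tuning(sim$direction_before)
    da <- summarize_direction_tuning(sim$direction_after)
    out$initial_osi <- mean(db$osi_1mcv, na.rm = TRUE)
    b <- bootstrap_delta(db$di, da$di, n_boot = n_boot,
                         seed = if (is.null(seed)) NULL else seed + 1L)
    out$delta_di <- b$mean_delta
    out$di_ci_low <- b$ci_low; out$di_ci_high <- b$ci_high
    out$di_significant <- b$direction > 0
  }
  out
}

# evoked-response time course: saturating rise during the stimulus,
# exponential decay after offset
evoked_timecourse <- function(t, onset, duration, tau_rise, tau_decay) {
  g <- numeric(length(t))
  rel <- t - onset
  on <- rel >= 0 & rel < duration
  g[on] <- if (tau_rise > 0) 1 - exp(-rel[on] / tau_rise) else 1
  post <- rel >= duration
  g_off <- if (tau_rise > 0) 1 - exp(-duration / tau_rise) else 1
  g[post] <- g_off * exp(-(rel[post] - duration) / tau_decay)
  g
}

#' Simulate fluorescence traces from programmed trial responses
#'
#' Emulates slow calcium-indicator recordings of the stimulus protocol:
#' each trial's programmed dF/F amplitude drives a transient that rises
#' with time constant `tau_rise` during the 5 s stimulus and decays
#' exponentially with `tau_decay` afterwards; the trace is `baseline * (1
#' + sum of transients)` plus Gaussian noise, sampled at the imaging frame
#' rate. Trials are organised in blocks (one presentation of every
#' stimulus per block, order shuffled within block), so trial indices
#' recovered by [compute_dff()] match the programmed ones.
#'
#' @param responses Tibble of programmed amplitudes: columns `cell_id`,
#'   `stimulus`, `trial`, `dff` (e.g. from [simulate_cell_responses()]).
#' @param frame_interval Imaging frame period, seconds (default 1.5).
#' @param stim_duration Stimulus-on time, seconds (default 5).
#' @param isi Interstimulus interval, seconds (default 10, which leaves
#'   the 3 s baseline window essentially free of the preceding trial's
#'   decay at the default `tau_decay`).
#' @param tau_rise,tau_decay Indicator rise/decay time constants, seconds.
#' @param baseline Baseline fluorescence (arbitrary units, > 0).
#' @param noise_sd Trace noise SD as a fraction of baseline.
#' @param seed Optional seed (shuffling and noise).
#' @return A list of class `"trace_recording"`: `traces` (tibble `time`,
#'   `cell_id`, `f`), `schedule` (tibble `stimulus`, `onset`,
#'   `duration`), and `frame_interval`.
#' @export
simulate_fluorescence_traces <- function(responses, frame_interval = 1.5,
                                         stim_duration = 5, isi = 10,
                                         tau_rise = 0.2, tau_decay = 1,
                                         baseline = 100, noise_sd = 0.01,
                                         seed = NULL) {
  stopifnot(all(c("cell_id", "stimulus", "trial", "dff") %in% names(responses)),
            frame_interval > 0, baseline > 0, tau_rise >= 0)
  if (tau_decay <= 0) stop("`tau_decay` must be positive", call. = FALSE)
  labs <- unique(responses$stimulus)
  n_blocks <- max(responses$trial)
  with_seed(seed, {
    order_by_block <- lapply(seq_len(n_blocks), function(b) sample(labs))
    schedule <- tibble::tibble(
      stimulus = unlist(order_by_block),
      onset = isi + (seq_len(n_blocks * length(labs)) - 1L) *
        (stim_duration + isi),
      duration = stim_duration
    )
    schedule$trial <- stats::ave(seq_len(nrow(schedule)), schedule$stimulus,
                                 FUN = seq_along)
    total_t <- max(schedule$onset) + stim_duration + isi
    times <- seq(0, total_t, by = frame_interval)
    mids <- times + frame_interval / 2
    cells <- unique(responses$cell_id)
    amp <- dplyr::left_join(schedule,
                            responses[c("cell_id", "stimulus", "trial", "dff")],
                            by = c("stimulus", "trial"),
                            relationship = "many-to-many")
    traces <- lapply(cells, function(cid) {
      a <- amp[amp$cell_id == cid, ]
      sig <- rep(0, length(times))
      for (r in seq_len(nrow(a))) {
        sig <- sig + a$dff[r] *
          evoked_timecourse(mids, a$onset[r], a$duration[r], tau_rise, tau_decay)
      }
      tibble::tibble(
        time = times, cell_id = cid,
        f = baseline * (1 + sig) +
          stats::rnorm(length(times), sd = noise_sd * baseline)
      )
    })
    structure(list(traces = dplyr::bind_rows(traces),
                   schedule = schedule[c("stimulus", "onset", "duration")],
                   frame_interval = frame_interval),
              class = "trace_recording")
  })
}
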