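# X-T frame matrix of one cycle: row i is the spatial sinusoid shown at
# sequence position i. "sensible" treats the step as a phase offset,
# sin(2*pi*(x + (s-1)/n)); "as_printed" is the literal frequency-scaling
# kernel sin(2*pi*((s-1)/n)*x) kept for auditability (its first frame is
# identically zero).
sequence_frames <- function(steps, x, mode = c("sensible", "as_printed"),
                            phase_offset = 0) {
  mode <- match.arg(mode)
  steps <- as.integer(steps)
  n <- length(steps)
  if (mode == "sensible") {
    t(vapply(steps, function(s) sin(2 * pi * (x + (s - 1) / n) + phase_offset),
             numeric(length(x))))
  } else {
    t(vapply(steps, function(s) sin(2 * pi * ((s - 1) / n) * x + phase_offset),
             numeric(length(x))))
  }
}

# Gram matrix of the n single-step spatial profiles on the grid x:
# G[p, q] = sum_x profile_p(x) * profile_q(x). The best-aligned correlation
# between two sequences is then a sum of Gram entries, which makes scoring
# the full enumeration cheap.
phase_gram <- function(n_steps, x, mode = "sensible") {
  profiles <- sequence_frames(seq_len(n_steps), x, mode = mode)
  profiles %*% t(profiles)
}

#' Default spatial sample grid for sequence correlations
#'
#' Eleven samples `(0:10)/10` across one spatial cycle, the grid used when
#' scoring similarity between phase sequences.
#' @return Numeric vector of length 11.
#' @export
correlation_x_grid <- function() seq(0, 10) / 10

#' Best-aligned correlation between two phase sequences
#'
#' The correlation between the sinusoidal frames of two sequences, maximized
#' over all circular rotations of the second sequence (a repeating stimulus
#' has no privileged starting frame). At each candidate alignment the score
#' is the sum over frames and spatial samples of the product of the two
#' spatial sinusoids. In normalized form the score is divided by the
#' geometric mean of the two self-products so that self-correlation is 1.
#'
#' @param a,b Phase sequences with the same number of steps.
#' @param mode `"sensible"` (default) renders frame `i` as
#'   `sin(2*pi*(x + (step_i - 1)/n))`; `"as_printed"` uses the literal
#'   frequency-scaled form `sin(2*pi*((step_i - 1)/n) * x)`.
#' @param x Spatial sample grid (default [correlation_x_grid()]).
#' @param normalize Divide by `sqrt(self(a) * self(b))` (default `TRUE`);
#'   `FALSE` returns the raw summed product.
#' @return A single correlation value; in `[-1, 1]` when normalized.
#' @examples
#' f <- forward_sequence(8)
#' best_aligned_correlation(f, f) # 1
#' @export
best_aligned_correlation <- function(a, b, mode = c("sensible", "as_printed"),
                                     x = correlation_x_grid(),
                                     normalize = TRUE) {
  mode <- match.arg(mode)
  a <- unclass(phase_sequence(a)); b <- unclass(phase_sequence(b))
  n <- length(a)
  if (length(b) != n) stop("sequences must have the same number of steps", call. = FALSE)
  G <- phase_gram(n, x, mode = mode)
  best <- max(vapply(seq_len(n) - 1L, function(r) {
    brot <- b[((seq_len(n) - 1L + r) %% n) + 1L]
    sum(G[cbind(a, brot)])
  }, numeric(1)))
  if (normalize) {
    best / sqrt(sum(G[cbind(a, a)]) * sum(G[cbind(b, b)]))
  } else {
    best
  }
}

#' Similarity of a sequence to smooth motion
#'
#' Best-aligned correlations of a sequence against smooth forward (`1:n`)
#' and backward (`n:1`) motion, and their average — the summary used when
#' selecting scrambled sequences for a stimulus family.
#'
#' @inheritParams best_aligned_correlation
#' @param seq A phase sequence.
#' @return A tibble with columns `corr_F`, `corr_B`, `corr_smooth_avg`.
#' @export
smooth_motion_metrics <- function(seq, mode = "sensible",
                                  x = correlation_x_grid()) {
  s <- phase_sequence(seq)
  n <- length(s)
  cf <- best_aligned_correlation(s, forward_sequence(n), mode = mode, x = x)
  cb <- best_aligned_correlation(s, backward_sequence(n), mode = mode, x = x)
  tibble::tibble(corr_F = cf, corr_B = cb, corr_smooth_avg = (cf + cb) / 2)
}

#' Summed total phase interval of a sequence
#'
#' The sum, over consecutive frame pairs treated circularly (including the
#' wrap from the last frame back to the first), of the circular phase
#' distance `min(|d|, n - |d|) * 2*pi/n` between successive steps. Smooth
#' sequences take unit steps everywhere and attain the minimum, `2*pi`;
#' scrambled sequences take larger jumps and score higher.
#'
#' @param seq A phase sequence.
#' @return Total phase distance travelled per cycle, in radians.
#' @examples
#' summed_phase_interval(forward_sequence(8)) # 2*pi
#' @export
summed_phase_interval <- function(seq) {
  s <- unclass(phase_sequence(seq))
  n <- length(s)
  d <- abs(diff(c(s, s[1L])))
  sum(pmin(d, n - d)) * 2 * pi / n
}

#' Spatiotemporal motion energy of a sequence
#'
#' Renders one cycle of the sequence as an X-T luminance array, takes its
#' 2-D discrete Fourier transform, and sums the absolute values of all
#' coefficients whose temporal frequency is nonzero (the zero temporal
#' frequency component is a static grating and carries no motion). Because
#' every frame is a unit-amplitude sinusoid, total spectral power is the
#' same for all sequences; smooth motion concentrates it at a single
#' spatiotemporal frequency and so minimizes this L1 measure, while
#' scrambled sequences spread power across temporal frequencies and score
#' higher.
#'
#' @param seq A phase sequence.
#' @param spatial_samples_per_cycle Spatial samples across one grating cycle
#'   (default 16; must be at least 2).
#' @param mode Frame-rendering mode, see [best_aligned_correlation()].
#' @return Nonnegative motion energy (unitless).
#' @export
motion_energy <- function(seq, spatial_samples_per_cycle = 16L,
                          mode = "sensible") {
  m <- as.integer(spatial_samples_per_cycle)
  if (is.na(m) || m < 2L) stop("`spatial_samples_per_cycle` must be >= 2", call. = FALSE)
  s <- unclass(phase_sequence(seq))
  frames <- sequence_frames(s, x = (seq_len(m) - 1L) / m, mode = mode)
  xt_motion_energy(frames)
}

# motion energy of an arbitrary X-T array (time in rows)
xt_motion_energy <- function(frames) {
  co <- Mod(stats::fft(frames))
  sum(co) - sum(co[1L, ]) # row 1 = zero temporal frequency
}

#' Irregularity metrics for a table of sequences
#'
#' Data-frame-first scoring of many phase sequences at once: smooth-motion
#' correlations, summed phase interval, and motion energy, appended as
#' columns. Designed to take [enumerate_sequences()] output directly.
#'
#' @param sequences A tibble with a `sequence` list-column (as produced by
#'   [enumerate_sequences()]), or a list of phase sequences.
#' @inheritParams best_aligned_correlation
#' @inheritParams motion_energy
#' @return The input tibble with columns `corr_F`, `corr_B`,
#'   `corr_smooth_avg`, `summed_phase_interval`, `motion_energy` added.
#' @examples
#' enumerate_sequences(4) |> sequence_metrics()
#' @export
sequence_metrics <- function(sequences, mode = "sensible",
                             x = correlation_x_grid(),
                             spatial_samples_per_cycle = 16L) {
  if (is.data.frame(sequences)) {
    df <- tibble::as_tibble(sequences)
    seqs <- df$sequence
  } else {
    seqs <- sequences
    df <- tibble::tibble(
      sequence = lapply(seqs, phase_sequence),
      sequence_str = vapply(seqs, seq_string, character(1))
    )
  }
  stopifnot(length(seqs) > 0)
  n <- length(seqs[[1L]])
  G <- phase_gram(n, x, mode = mode)
  fwd <- seq_len(n); bwd <- rev(fwd)
  self_smooth <- c(F = sum(G[cbind(fwd, fwd)]), B = sum(G[cbind(bwd, bwd)]))
  rot <- function(v, r) v[((seq_len(n) - 1L + r) %% n) + 1L]
  fwd_rots <- vapply(seq_len(n) - 1L, function(r) rot(fwd, r), integer(n))
  bwd_rots <- vapply(seq_len(n) - 1L, function(r) rot(bwd, r), integer(n))
  score <- function(s) {
    self <- sum(G[cbind(s, s)])
    cf <- max(vapply(seq_len(n), function(j) sum(G[cbind(s, fwd_rots[, j])]),
                     numeric(1))) / sqrt(self * self_smooth[["F"]])
    cb <- max(vapply(seq_len(n), function(j) sum(G[cbind(s, bwd_rots[, j])]),
                     numeric(1))) / sqrt(self * self_smooth[["B"]])
    c(cf, cb)
  }
  cc <- vapply(seqs, function(s) score(as.integer(s)), numeric(2))
  df$corr_F <- cc[1L, ]
  df$corr_B <- cc[2L, ]
  df$corr_smooth_avg <- (cc[1L, ] + cc[2L, ]) / 2
  df$summed_phase_interval <- vapply(seqs, summed_phase_interval, numeric(1))
  df$motion_energy <- vapply(
    seqs, motion_energy, numeric(1),
    spatial_samples_per_cycle = spatial_samples_per_cycle, mode = mode)
  df
}
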