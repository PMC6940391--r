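#' Stimulus specifications
#'
#' A stimulus is either a `sequence` stimulus — a sinusoidal grating stepping
#' through a phase sequence — or a `counterphase` stimulus, the frame-wise
#' mean of the smooth forward and backward gratings at a fixed spatial phase
#' (a contrast-reversing standing grating). Each phase step is shown for
#' `1 / (temporal_frequency * n_steps)` seconds; at the default 2 Hz and 8
#' steps that is 0.0625 s, and 10 cycles give a 5 s stimulus.
#'
#' @param label Stimulus label (e.g. `"F"`, `"S4"`, `"CP1"`).
#' @param kind `"sequence"` or `"counterphase"`.
#' @param sequence A [phase_sequence()] (required for `kind = "sequence"`).
#' @param spatial_phase_offset Spatial phase of a counterphase stimulus, in
#'   radians.
#' @param temporal_frequency Cycle repetition rate, Hz.
#' @param n_cycles Number of repeats of the sequence.
#' @param n_steps Phase steps per cycle (taken from `sequence` when given).
#' @return A list of class `"stimulus_spec"` with an additional
#'   `step_duration` field (seconds).
#' @export
stimulus_spec <- function(label, kind = c("sequence", "counterphase"),
                          sequence = NULL, spatial_phase_offset = 0,
                          temporal_frequency = 2, n_cycles = 10L,
                          n_steps = 8L) {
  kind <- match.arg(kind)
  if (kind == "sequence") {
    sequence <- phase_sequence(sequence)
    n_steps <- length(sequence)
  } else {
    n_steps <- as.integer(n_steps)
  }
  stopifnot(temporal_frequency > 0, n_cycles >= 1)
  structure(list(
    label = as.character(label), kind = kind, sequence = sequence,
    spatial_phase_offset = spatial_phase_offset,
    temporal_frequency = temporal_frequency, n_cycles = as.integer(n_cycles),
    n_steps = n_steps,
    step_duration = 1 / (temporal_frequency * n_steps)
  ), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec> ", x$label, " (", x$kind, ")",
      if (x$kind == "sequence") paste0(" [", seq_string(x$sequence), "]"),
      " ", x$temporal_frequency, " Hz, ", x$n_cycles, " cycles, step ",
      signif(x$step_duration, 4), " s\n", sep = "")
  invisible(x)
}

#' Render a stimulus as an X-T movie
#'
#' Sequence stimuli render frame `i` as `sin(2*pi*(x + (step_i - 1)/n))`;
#' counterphase stimuli are the element-wise mean of the forward and
#' backward movies rendered at the configured spatial phase offset. Frames
#' are stacked over `n_cycles` repeats.
#'
#' @param spec A [stimulus_spec()].
#' @param spatial_samples_per_cycle Spatial samples across one grating cycle.
#' @param n_cycles Override the spec's cycle count (e.g. 1 for kernel
#'   construction).
#' @return A numeric matrix (time x space, values in `[-1, 1]`) of class
#'   `"stimulus_movie"` with attributes `frame_duration` (s), `label`, and
#'   `spatial_samples_per_cycle`.
#' @examples
#' fam <- build_family()
#' m <- render_movie(fam$spec[[1]])
#' dim(m) # 80 frames x 16 samples
#' @export
render_movie <- function(spec, spatial_samples_per_cycle = 16L,
                         n_cycles = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  m <- as.integer(spatial_samples_per_cycle)
  if (is.na(m) || m < 2L) stop("`spatial_samples_per_cycle` must be >= 2", call. = FALSE)
  nc <- if (is.null(n_cycles)) spec$n_cycles else as.integer(n_cycles)
  x <- (seq_len(m) - 1L) / m
  one <- if (spec$kind == "sequence") {
    sequence_frames(spec$sequence, x)
  } else {
    ff <- sequence_frames(seq_len(spec$n_steps), x,
                          phase_offset = spec$spatial_phase_offset)
    bb <- sequence_frames(rev(seq_len(spec$n_steps)), x,
                          phase_offset = spec$spatial_phase_offset)
    (ff + bb) / 2
  }
  frames <- one[rep(seq_len(nrow(one)), nc), , drop = FALSE]
  structure(frames, class = c("stimulus_movie", class(frames)),
            frame_duration = spec$step_duration, label = spec$label,
            spatial_samples_per_cycle = m)
}

#' Select scrambled sequences for a stimulus family
#'
#' The documented selection rule behind the default S1-S5: score the full
#' circular-unique enumeration by average smooth-motion correlation, drop
#' forward, backward, the fixed S6, and anything too similar to smooth
#' motion (`corr_smooth_avg > ceiling`); then take the two least
#' smooth-correlated sequences as S4 and S5 (the "high irregularity" end)
#' and, for S1-S3, the sequences whose `corr_smooth_avg` is closest to the
#' intermediate targets. Ties are broken by enumeration order, so the rule
#' is deterministic.
#'
#' @param n_steps Phase steps per cycle.
#' @param targets Intermediate `corr_smooth_avg` targets for S1-S3.
#' @param ceiling Maximum admissible `corr_smooth_avg`.
#' @param s6 The fixed S6 sequence.
#' @return Named list of six `phase_sequence`s, `S1`-`S6`.
#' @export
select_scrambled_sequences <- function(n_steps = 8L,
                                       targets = c(S1 = 0.45, S2 = 0.35, S3 = 0.25),
                                       ceiling = 0.8,
                                       s6 = phase_sequence(c(8, 3, 6, 2, 7, 4, 1, 5))) {
  met <- sequence_metrics(enumerate_sequences(n_steps))
  s6c <- seq_string(canonicalize(s6))
  met <- met[!(met$sequence_str %in%
                 c(seq_string(forward_sequence(n_steps)),
                   seq_string(canonicalize(backward_sequence(n_steps))), s6c)), ]
  met <- met[met$corr_smooth_avg <= ceiling, ]
  if (nrow(met) < 5L) stop("fewer than 5 candidate sequences under the ceiling", call. = FALSE)
  picked <- integer(0)
  ord <- order(met$corr_smooth_avg)  # stable: ties keep enumeration order
  s4 <- ord[1L]; s5 <- ord[2L]
  picked <- c(s4, s5)
  sel <- c(picked[1L], picked[2L])
  out <- list(S4 = met$sequence[[s4]], S5 = met$sequence[[s5]])
  for (nm in names(targets)) {
    d <- abs(met$corr_smooth_avg - targets[[nm]])
    d[sel] <- Inf
    i <- which.min(d)
    sel <- c(sel, i)
    out[[nm]] <- met$sequence[[i]]
  }
  out$S6 <- canonicalize(s6)
  out[c("S1", "S2", "S3", "S4", "S5", "S6")]
}

# Fixed output of select_scrambled_sequences() with default bands
# (corr_smooth_avg: S1 0.450, S2 0.354, S3 0.250, S4/S5 ~ 0).
.default_s1_s5 <- list(
  S1 = c(1L, 2L, 6L, 5L, 7L, 8L, 4L, 3L),
  S2 = c(1L, 4L, 8L, 2L, 3L, 5L, 6L, 7L),
  S3 = c(1L, 2L, 4L, 8L, 6L, 3L, 7L, 5L),
  S4 = c(1L, 5L, 2L, 7L, 4L, 8L, 3L, 6L),
  S5 = c(1L, 6L, 3L, 8L, 4L, 7L, 2L, 5L)
)

#' Default scrambled sequences S1-S6
#'
#' S6 is the canonical form of `[8 3 6 2 7 4 1 5]`; S1-S5 are the fixed
#' output of [select_scrambled_sequences()] with its default bands,
#' spanning intermediate to very low correlation with smooth motion.
#' @return Named list of six `phase_sequence`s.
#' @export
default_scrambled_sequences <- function() {
  lapply(list(
    S1 = .default_s1_s5$S1, S2 = .default_s1_s5$S2, S3 = .default_s1_s5$S3,
    S4 = .default_s1_s5$S4, S5 = .default_s1_s5$S5,
    S6 = c(1L, 5L, 8L, 3L, 6L, 2L, 7L, 4L)
  ), phase_sequence)
}

#' Build the 10-stimulus family
#'
#' Assembles the family used throughout the pipeline: smooth forward (F)
#' and backward (B) motion, six scrambled sequences (S1-S6), and two
#' counterphase stimuli (CP1, CP2) at quadrature spatial phases.
#'
#' @param scrambled Named list of six sequences (`S1`-`S6`); defaults to
#'   [default_scrambled_sequences()].
#' @param cp_offsets Spatial phase offsets (radians) for CP1 and CP2.
#' @param temporal_frequency,n_cycles,n_steps Shared stimulus timing.
#' @return A tibble with one row per stimulus: `label`, `kind`,
#'   `sequence_str`, and a `spec` list-column of [stimulus_spec()] objects.
#' @examples
#' build_family()$label
#' @export
build_family <- function(scrambled = default_scrambled_sequences(),
                         cp_offsets = c(CP1 = 0, CP2 = pi / 2),
                         temporal_frequency = 2, n_cycles = 10L,
                         n_steps = 8L) {
  if (length(scrambled) != 6L) {
    stop("`scrambled` must supply exactly 6 sequences (S1-S6)", call. = FALSE)
  }
  if (is.null(names(scrambled)) || !setequal(names(scrambled), paste0("S", 1:6))) {
    names(scrambled) <- paste0("S", 1:6)
  }
  scrambled <- lapply(scrambled, phase_sequence)
  if (any(vapply(scrambled, length, 1L) != n_steps)) {
    stop("scrambled sequences must have `n_steps` steps", call. = FALSE)
  }
  if (length(cp_offsets) != 2L) stop("`cp_offsets` must have length 2", call. = FALSE)
  seqs <- c(list(F = forward_sequence(n_steps), B = backward_sequence(n_steps)),
            scrambled[paste0("S", 1:6)])
  specs <- c(
    lapply(names(seqs), function(nm) {
      stimulus_spec(nm, "sequence", sequence = seqs[[nm]],
                    temporal_frequency = temporal_frequency, n_cycles = n_cycles)
    }),
    lapply(1:2, function(i) {
      stimulus_spec(paste0("CP", i), "counterphase",
                    spatial_phase_offset = unname(cp_offsets[i]),
                    temporal_frequency = temporal_frequency,
                    n_cycles = n_cycles, n_steps = n_steps)
    })
  )
  tibble::tibble(
    label = vapply(specs, `[[`, character(1), "label"),
    kind = vapply(specs, `[[`, character(1), "kind"),
    sequence_str = vapply(specs, function(s) {
      if (is.null(s$sequence)) NA_character_ else seq_string(s$sequence)
    }, character(1)),
    spec = specs
  )
}

#' Labels of the default stimulus family
#' @return Character vector `F, B, S1..S6, CP1, CP2`.
#' @export
family_labels <- function() c("F", "B", paste0("S", 1:6), "CP1", "CP2")

#' Read a stimulus family from a YAML or JSON config
#'
#' The config may contain `temporal_frequency`, `n_cycles`, `n_steps`,
#' `cp_offsets` (two numbers), and `scrambled` (a named map `S1`-`S6` of
#' integer sequences). Missing fields fall back to the package defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A family tibble, as from [build_family()].
#' @export
read_family_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$scrambled)) args$scrambled <- lapply(cfg$scrambled, as.integer)
  if (!is.null(cfg$cp_offsets)) args$cp_offsets <- as.numeric(unlist(cfg$cp_offsets))
  for (f in c("temporal_frequency", "n_cycles", "n_steps")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  do.call(build_family, args)
}
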