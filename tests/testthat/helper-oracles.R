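# Independent brute-force oracles: deliberately written as explicit loops
# over the defining formulas, sharing no code with the package internals.

# frame-wise sinusoid product correlation, maximized over circular offsets
oracle_best_corr <- function(a, b, mode = "sensible", x = seq(0, 10) / 10,
                             normalize = TRUE) {
  a <- as.integer(a); b <- as.integer(b)
  n <- length(a)
  frame_of <- function(s) {
    if (mode == "sensible") sin(2 * pi * (x + (s - 1) / n))
    else sin(2 * pi * ((s - 1) / n) * x)
  }
  corr_at <- function(aa, bb) {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + sum(frame_of(aa[i]) * frame_of(bb[i]))
    tot
  }
  best <- -Inf
  for (r in 0:(n - 1)) {
    brot <- b[((seq_len(n) - 1L + r) %% n) + 1L]
    best <- max(best, corr_at(a, brot))
  }
  if (normalize) best / sqrt(corr_at(a, a) * corr_at(b, b)) else best
}

# DFT-by-definition motion energy of an X-T frame matrix (time in rows)
oracle_motion_energy <- function(frames) {
  Tn <- nrow(frames); Xn <- ncol(frames)
  tot <- 0
  for (ft in 0:(Tn - 1)) {
    if (ft == 0) next
    for (fx in 0:(Xn - 1)) {
      co <- 0 + 0i
      for (tt in 0:(Tn - 1)) {
        for (xx in 0:(Xn - 1)) {
          co <- co + frames[tt + 1, xx + 1] *
            exp(-2i * pi * (ft * tt / Tn + fx * xx / Xn))
        }
      }
      tot <- tot + Mod(co)
    }
  }
  tot
}

# one-cycle X-T frames of a family stimulus, straight from the definitions
oracle_frames <- function(spec, m = 16L) {
  x <- (seq_len(m) - 1L) / m
  n <- spec$n_steps
  seq_frames <- function(steps, off = 0) {
    mat <- matrix(0, length(steps), m)
    for (i in seq_along(steps)) {
      mat[i, ] <- sin(2 * pi * (x + (steps[i] - 1) / n) + off)
    }
    mat
  }
  if (spec$kind == "sequence") {
    seq_frames(as.integer(spec$sequence))
  } else {
    (seq_frames(1:n, spec$spatial_phase_offset) +
       seq_frames(n:1, spec$spatial_phase_offset)) / 2
  }
}

# normalized ideal-kernel response by direct loop over temporal alignments
oracle_kernel_response <- function(pref_spec, target_spec, m = 16L,
                                   rectify = TRUE) {
  A <- oracle_frames(pref_spec, m)
  B <- oracle_frames(target_spec, m)
  n <- nrow(A)
  best_vs <- function(target) {
    best <- -Inf
    for (r in 0:(n - 1)) {
      tot <- 0
      for (i in seq_len(n)) {
        tot <- tot + sum(A[i, ] * target[((i - 1 + r) %% n) + 1, ])
      }
      best <- max(best, tot)
    }
    best
  }
  val <- best_vs(B) / best_vs(A)
  if (rectify) max(val, 0) else val
}

seq_string <- function(s) paste(as.integer(s), collapse = " ")

# shared fixtures
fam_default <- build_family()
M_default <- kernel_response_matrix(fam_default)
spec_of <- function(label) fam_default$spec[[match(label, fam_default$label)]]
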