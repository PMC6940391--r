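#' Phase sequences
#'
#' A phase sequence is an ordering of the `n` discretized spatial phases of
#' one grating cycle: smooth forward motion is `1:n`, smooth backward motion
#' `n:1`, and any other permutation is a "scrambled" sequence. Because a
#' stimulus repeats the sequence cyclically, two sequences that are circular
#' rotations of one another are the same stimulus; the canonical
#' representative is the rotation that starts with phase step 1.
#'
#' @param steps Integer vector: a permutation of `1:n_steps`.
#' @return `phase_sequence()` returns an integer vector of class
#'   `"phase_sequence"`.
#' @examples
#' phase_sequence(c(8, 3, 6, 2, 7, 4, 1, 5))
#' canonicalize(phase_sequence(c(2, 3, 4, 5, 6, 7, 8, 1)))
#' @export
phase_sequence <- function(steps) {
  steps <- as.integer(steps)
  n <- length(steps)
  if (n < 2L || anyNA(steps) || !setequal(steps, seq_len(n))) {
    stop("`steps` must be a permutation of 1..n (n >= 2), got: ",
         paste(steps, collapse = " "), call. = FALSE)
  }
  structure(steps, class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat("<phase_sequence> [", paste(unclass(x), collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' @rdname phase_sequence
#' @param seq A `phase_sequence` or plain permutation vector.
#' @return `canonicalize()` returns the circular rotation of `seq` that
#'   begins with step 1 (unique because the elements are distinct);
#'   idempotent.
#' @export
canonicalize <- function(seq) {
  s <- phase_sequence(seq)
  i <- which(unclass(s) == 1L)
  phase_sequence(unclass(s)[c(i:length(s), seq_len(i - 1L))[seq_along(s)]])
}

#' @rdname phase_sequence
#' @param a,b Two phase sequences (any rotation).
#' @return `sequences_equivalent()` returns `TRUE` iff one sequence is a
#'   circular rotation of the other.
#' @export
sequences_equivalent <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  identical(unclass(canonicalize(a)), unclass(canonicalize(b)))
}

seq_string <- function(steps) paste(as.integer(steps), collapse = " ")

#' Smooth forward and backward sequences
#'
#' @param n_steps Number of phase steps per cycle.
#' @return A `phase_sequence`: `1:n` (forward) or `n:1` (backward).
#' @export
forward_sequence <- function(n_steps = 8L) phase_sequence(seq_len(n_steps))

#' @rdname forward_sequence
#' @export
backward_sequence <- function(n_steps = 8L) phase_sequence(rev(seq_len(n_steps)))

# all n! permutations of v, one per row
permutation_matrix <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], permutation_matrix(v[-i]), deparse.level = 0)
  }))
}

#' Enumerate circular-unique phase sequences
#'
#' Generates all `n!` orderings of the `n` phase steps and collapses circular
#' rotations to one canonical representative each (the rotation starting with
#' step 1), giving `n!/n` unique stimuli. For `n = 8` this is 5040 sequences;
#' for `n = 4`, only 6 are possible (forward and backward included).
#'
#' @param n_steps Number of phase steps, between 2 and 10 (the factorial
#'   growth makes larger `n` impractical).
#' @return A tibble with one row per canonical sequence: `sequence`
#'   (list-column of `phase_sequence`), `sequence_str`, and `n_steps`. The
#'   number of raw permutations examined is recorded in the
#'   `n_permutations` attribute.
#' @examples
#' nrow(enumerate_sequences(4)) # 6
#' @export
enumerate_sequences <- function(n_steps = 8L) {
  n_steps <- as.integer(n_steps)
  if (length(n_steps) != 1L || is.na(n_steps) || n_steps < 2L || n_steps > 10L) {
    stop("`n_steps` must be a single integer in 2..10", call. = FALSE)
  }
  perms <- permutation_matrix(seq_len(n_steps))
  # rotate every permutation so step 1 leads, then deduplicate
  lead <- max.col(perms == 1L, ties.method = "first")
  idx <- (outer(seq_len(n_steps) - 1L, lead - 1L, `+`) %% n_steps) + 1L
  canon <- t(vapply(seq_len(nrow(perms)),
                    function(r) perms[r, idx[, r]], integer(n_steps)))
  keys <- apply(canon, 1L, paste, collapse = " ")
  keep <- !duplicated(keys)
  canon <- canon[keep, , drop = FALSE]
  out <- tibble::tibble(
    sequence = lapply(seq_len(nrow(canon)), function(r) phase_sequence(canon[r, ])),
    sequence_str = keys[keep],
    n_steps = n_steps
  )
  attr(out, "n_permutations") <- nrow(perms)
  out
}
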