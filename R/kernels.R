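#' Ideal linear kernels for family stimuli
#'
#' The ideal kernel for a stimulus is a linear space-time receptive field
#' whose X-T profile matches one cycle of the stimulus, reversed in time:
#' the matched filter, and hence the receptive field that responds maximally
#' to its own stimulus under convolution.
#'
#' @param spec A [stimulus_spec()].
#' @param spatial_samples_per_cycle Spatial samples across one grating cycle.
#' @return A list of class `"kernel"` with fields `label` (`"K"` + stimulus
#'   label), `profile` (time-reversed one-cycle X-T matrix), and `spec`.
#' @examples
#' fam <- build_family()
#' k <- make_kernel(fam$spec[[1]])
#' k$label # "KF"
#' @export
make_kernel <- function(spec, spatial_samples_per_cycle = 16L) {
  one <- render_movie(spec, spatial_samples_per_cycle, n_cycles = 1L)
  profile <- unclass(one)[rev(seq_len(nrow(one))), , drop = FALSE]
  structure(list(label = paste0("K", spec$label), profile = profile,
                 spec = spec),
            class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat("<kernel> ", x$label, " (", nrow(x$profile), " x ", ncol(x$profile),
      " X-T profile)\n", sep = "")
  invisible(x)
}

# raw best-aligned response of a kernel to a one-cycle movie: the kernel
# acts by convolution, so its time-reversed profile (= the original
# stimulus cycle) is correlated with the movie over all circular temporal
# shifts and the maximum is taken.
kernel_response_raw <- function(kernel, movie) {
  flt <- kernel$profile[rev(seq_len(nrow(kernel$profile))), , drop = FALSE]
  m <- unclass(movie)
  if (!identical(dim(flt), dim(m))) {
    stop("kernel and stimulus sampling do not match", call. = FALSE)
  }
  n <- nrow(m)
  max(vapply(seq_len(n) - 1L, function(r) {
    sum(flt * m[((seq_len(n) - 1L + r) %% n) + 1L, , drop = FALSE])
  }, numeric(1)))
}

#' Ideal response of a kernel to a stimulus
#'
#' The correlation between the kernel and one cycle of the stimulus at the
#' optimal circular temporal alignment, normalized so the kernel's response
#' to its own (preferred) stimulus is 1. With `rectify = TRUE` (the
#' default, firing-rate semantics) negative values clamp to 0.
#'
#' @param kernel A [make_kernel()] object.
#' @param spec Stimulus to respond to.
#' @param rectify Clamp negative responses to 0.
#' @param spatial_samples_per_cycle Must match the kernel's sampling.
#' @return A single response value; 1 for the preferred stimulus.
#' @export
kernel_response <- function(kernel, spec, rectify = TRUE,
                            spatial_samples_per_cycle = 16L) {
  stopifnot(inherits(kernel, "kernel"))
  own <- kernel_response_raw(
    kernel, render_movie(kernel$spec, spatial_samples_per_cycle, n_cycles = 1L))
  r <- kernel_response_raw(
    kernel, render_movie(spec, spatial_samples_per_cycle, n_cycles = 1L)) / own
  if (rectify) max(r, 0) else r
}

#' Kernel response matrix of a stimulus family
#'
#' The 10 x 10 matrix of ideal responses: row `k`, column `j` is the
#' normalized response of the kernel optimized for stimulus `k` to stimulus
#' `j`. The diagonal is exactly 1 and rows are maximal on the diagonal.
#' These rows are the referent vectors of the response projection index.
#'
#' @param family A family tibble from [build_family()].
#' @param rectify Clamp negative responses to 0 (default).
#' @param spatial_samples_per_cycle Spatial sampling for rendering.
#' @return A numeric matrix with rownames `K<label>` and colnames
#'   `<label>`, of class `"kernel_response_matrix"`.
#' @examples
#' M <- kernel_response_matrix(build_family())
#' diag(M) # all 1
#' @export
kernel_response_matrix <- function(family, rectify = TRUE,
                                   spatial_samples_per_cycle = 16L) {
  specs <- family$spec
  labels <- family$label
  if (anyDuplicated(labels)) stop("duplicate stimulus labels", call. = FALSE)
  movies <- lapply(specs, render_movie,
                   spatial_samples_per_cycle = spatial_samples_per_cycle,
                   n_cycles = 1L)
  kernels <- lapply(specs, make_kernel,
                    spatial_samples_per_cycle = spatial_samples_per_cycle)
  M <- t(vapply(kernels, function(k) {
    vapply(movies, function(m) kernel_response_raw(k, m), numeric(1))
  }, numeric(length(movies))))
  M <- M / diag(M) # normalize each kernel's preferred response to 1
  if (rectify) M[M < 0] <- 0
  dimnames(M) <- list(paste0("K", labels), labels)
  class(M) <- c("kernel_response_matrix", class(M))
  M
}

# resolve a referent name ("KF" or "F") to a row of the kernel matrix
kernel_row <- function(M, ref) {
  ref <- as.character(ref)
  rn <- rownames(M)
  i <- match(ref, rn)
  if (is.na(i)) i <- match(paste0("K", ref), rn)
  if (is.na(i)) stop("unknown kernel/stimulus label: ", ref, call. = FALSE)
  M[i, ]
}

#' Tidy a kernel response matrix
#'
#' @param x A [kernel_response_matrix()].
#' @param ... Unused.
#' @return A long tibble with columns `kernel`, `stimulus`, `response`.
#' @export
tidy.kernel_response_matrix <- function(x, ...) {
  tibble::tibble(
    kernel = rep(rownames(x), times = ncol(x)),
    stimulus = rep(colnames(x), each = nrow(x)),
    response = as.vector(unclass(x))
  )
}
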