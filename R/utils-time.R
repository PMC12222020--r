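# Time-axis conventions used throughout the package.
#
# Epochs run on a half-open axis [t0, t0 + n/srate) ms; sample i (1-based)
# sits at t0 + (i - 1) * 1000 / srate.  A window [a, b) ms maps to sample
# indices by flooring, so e.g. [-500, -260) ms at 512 Hz covers exactly
# floor(0.24 * 512) = 122 samples.

#' Sample indices of a half-open time window
#'
#' @param t0 epoch start time in ms.
#' @param srate sampling rate in Hz.
#' @param nSamples number of samples in the epoch.
#' @param window numeric length-2 vector \code{c(a, b)} in ms; the window is
#'   half-open \code{[a, b)}.
#' @return integer vector of 1-based sample indices.
#' @keywords internal
windowIndices <- function(t0, srate, nSamples, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  first <- floor((window[1] - t0) * srate / 1000) + 1L
  last <- floor((window[2] - t0) * srate / 1000)
  if (first < 1L || last > nSamples)
    stop("window [", window[1], ", ", window[2], ") ms lies outside the epoch")
  seq.int(first, last)
}

#' Time axis of an epoch in ms
#' @keywords internal
sampleTimes <- function(t0, srate, nSamples) {
  t0 + (seq_len(nSamples) - 1) * 1000 / srate
}

# Derive a stream-specific 31-bit seed from a master seed and a label, so
# that all randomness flows from one explicit seed via a documented split.
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
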