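#' EpochSet: epoched multi-channel EEG with trial metadata
#'
#' The central data container: per-subject arrays of epoched voltage
#' (trials x channels x samples, microvolts) sharing one channel montage,
#' sampling rate and time axis, together with a design table aligned to the
#' trial axes and a provenance log of applied operations. Trial counts may
#' differ between subjects (e.g. after artifact rejection), which is why the
#' voltage data live in a per-subject list rather than one 4-D array.
#'
#' @slot data named list (one element per subject) of 3-D numeric arrays
#'   with dimensions trials x channels x samples, in microvolts.
#' @slot design \code{data.frame} with one row per trial across all
#'   subjects, in the same order as the trial axes; must contain a
#'   \code{subject} column plus the trial metadata (identity, emotion,
#'   fnmes, ...).
#' @slot channels character vector of channel names (the montage order of
#'   the channel axis).
#' @slot srate sampling rate in Hz.
#' @slot t0 time of the first sample relative to stimulus onset, in ms.
#' @slot log list of provenance records, one per applied operation.
#' @export
setClass("EpochSet",
  representation(data = "list", design = "data.frame",
                 channels = "character", srate = "numeric",
                 t0 = "numeric", log = "list"))

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (length(object@srate) != 1L || object@srate <= 0)
    msg <- c(msg, "srate must be a single positive number")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (!"subject" %in% names(object@design))
    msg <- c(msg, "design must have a 'subject' column")
  ns <- vapply(object@data, function(a) dim(a)[3], numeric(1))
  if (length(object@data)) {
    if (is.null(names(object@data)) || anyDuplicated(names(object@data)))
      msg <- c(msg, "data must be a named list with unique subject names")
    if (length(unique(ns)) > 1L)
      msg <- c(msg, "all subjects must share the same number of samples")
    nc <- vapply(object@data, function(a) dim(a)[2], numeric(1))
    if (any(nc != length(object@channels)))
      msg <- c(msg, "channel axis must match the channel name vector")
    nt <- vapply(object@data, function(a) dim(a)[1], numeric(1))
    tab <- table(factor(as.character(object@design$subject),
                        levels = names(object@data)))
    if (!all(as.numeric(tab) == nt))
      msg <- c(msg, "design rows per subject must match trial axis lengths")
  }
  if (length(msg)) msg else TRUE
})

#' StatMap: mass-univariate statistic map
#'
#' Channel-by-time (or frequency-by-time) maps of t statistics, raw and
#' adjusted p values, and the significance mask after multiplicity
#' correction.
#'
#' @slot t,p,padj numeric matrices of equal dimension (rows = channels or
#'   frequencies, columns = time points).
#' @slot mask logical matrix; \code{TRUE} iff adjusted p <= alpha.
#' @slot df degrees of freedom of the t tests.
#' @slot alpha significance level.
#' @slot correction multiplicity correction used (\code{"BH-FDR"}).
#' @slot times numeric vector of column times in ms.
#' @export
setClass("StatMap",
  representation(t = "matrix", p = "matrix", padj = "matrix",
                 mask = "matrix", df = "numeric", alpha = "numeric",
                 correction = "character", times = "numeric"))

setValidity("StatMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@t), dim(object@p)) ||
      !identical(dim(object@t), dim(object@mask)))
    msg <- c(msg, "t, p and mask must share one shape")
  if (any(object@mask & object@padj > object@alpha, na.rm = TRUE))
    msg <- c(msg, "mask may only mark cells with adjusted p <= alpha")
  if (length(msg)) msg else TRUE
})

#' TFCoherenceMap: time-frequency coherence for one ROI pair
#'
#' Across-trial magnitude coherence on a frequency x time grid for one
#' subject, fNMES condition, categorisation choice and ROI pair. Cells whose
#' analysis window was not fully supported by the epoch are \code{NA}.
#'
#' @slot coh numeric matrix frequencies x times, values in [0, 1] or NA.
#' @slot freqs,times grid axes (Hz, ms).
#' @slot subject,fnmes,choice,roiPair metadata labels.
#' @slot nTrials number of trials pooled into the estimate.
#' @export
setClass("TFCoherenceMap",
  representation(coh = "matrix", freqs = "numeric", times = "numeric",
                 subject = "character", fnmes = "character",
                 choice = "character", roiPair = "character",
                 nTrials = "integer"))

setValidity("TFCoherenceMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@coh),
                 c(length(object@freqs), length(object@times))))
    msg <- c(msg, "coh must be freqs x times")
  v <- object@coh[is.finite(object@coh)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "coherence must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: Monte-Carlo cluster permutation test result
#'
#' @slot clusters list of clusters, each a list with elements \code{cells}
#'   (two-column matrix of (freq index, time index) members), \code{mass}
#'   (sum of member t values) and \code{p} (Monte-Carlo p value).
#' @slot tmap the observed dependent-samples t map (freqs x times).
#' @slot freqs,times grid axes.
#' @slot params list: \code{nPerm}, \code{clusterAlpha}, \code{alpha},
#'   \code{tails}.
#' @slot seed permutation seed.
#' @export
setClass("ClusterResult",
  representation(clusters = "list", tmap = "matrix", freqs = "numeric",
                 times = "numeric", params = "list", seed = "numeric"))

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  lo <- 1 / (object@params$nPerm + 1)
  for (cl in object@clusters) {
    if (cl$p < lo - 1e-12 || cl$p > 1 + 1e-12)
      msg <- c(msg, "cluster p values must lie in [1/(nPerm+1), 1]")
    if (any(cl$cells[, 1] < 1) || any(cl$cells[, 1] > length(object@freqs)) ||
        any(cl$cells[, 2] < 1) || any(cl$cells[, 2] > length(object@times)))
      msg <- c(msg, "cluster cells must lie within the grid")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' ModelFit: coefficient table of a (generalised) mixed or linear model
#'
#' @slot terms \code{data.frame} with one row per fixed-effect term and
#'   columns \code{term}, \code{b}, \code{se}, \code{z}, \code{p},
#'   \code{ci_low}, \code{ci_high}, \code{d} (Cohen's d approximation
#'   b / (pi / sqrt(3)), logistic models only).
#' @slot formula character representation of the fitted model formula.
#' @slot nObs,nSubjects observation and subject counts.
#' @slot converged logical convergence flag.
#' @slot singular logical; random-effects variance hit the boundary.
#' @slot simplified character; random-structure simplification path taken
#'   ("" when the requested structure fitted cleanly).
#' @slot fit the underlying fitted model object.
#' @export
setClass("ModelFit",
  representation(terms = "data.frame", formula = "character",
                 nObs = "integer", nSubjects = "integer",
                 converged = "logical", singular = "logical",
                 simplified = "character", fit = "ANY"))

setValidity("ModelFit", function(object) {
  need <- c("term", "b", "se", "z", "p", "ci_low", "ci_high", "d")
  if (!all(need %in% names(object@terms)))
    return("terms must have columns term, b, se, z, p, ci_low, ci_high, d")
  bad <- with(object@terms, is.finite(ci_low) & is.finite(ci_high) &
                ci_low > ci_high)
  if (any(bad)) return("confidence bounds must be ordered")
  TRUE
})
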