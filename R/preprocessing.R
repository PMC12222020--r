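# Deterministic epoch preprocessing: filtering, baseline correction,
# threshold rejection, average reference, neighbour interpolation.
#
# Every operation appends a provenance record to the EpochSet log. The
# canonical order follows the acquisition pipeline: bandpass -> (epoch
# arithmetic) -> rejectTrials -> baselineCorrect -> final low-pass ->
# rereferenceAverage; applying an op out of that order warns but proceeds.

canonicalOrder <- c("bandpass", "rejectTrials", "baselineCorrect",
                    "lowpassFinal", "rereferenceAverage")

recordOp <- function(epochs, op, detail = list()) {
  prev <- vapply(epochs@log, `[[`, "", "op")
  prev <- prev[prev %in% canonicalOrder]
  pos <- match(op, canonicalOrder)
  if (!is.na(pos) && length(prev) &&
      any(match(prev, canonicalOrder) > pos))
    warning("preprocessing op '", op,
            "' applied out of the canonical pipeline order", call. = FALSE)
  epochs@log <- c(epochs@log, list(c(list(op = op), detail)))
  epochs
}

# Apply fun(channels x samples matrix) -> matrix to every trial.
mapTrials <- function(epochs, fun) {
  for (s in names(epochs@data)) {
    a <- epochs@data[[s]]
    for (ti in seq_len(dim(a)[1])) {
      m <- array(a[ti, , ], dim = dim(a)[2:3])
      a[ti, , ] <- fun(m)
    }
    epochs@data[[s]] <- a
  }
  epochs
}

#' Zero-phase band-pass filtering of epochs
#'
#' High-pass and low-pass 4th-order Butterworth filters applied in cascade,
#' each forward and backward (zero-phase; the effective magnitude response
#' is the squared single-pass response, so a 4th-order design attenuates a
#' 60 Hz tone by about 28 dB through the 40 Hz low pass). Either cutoff may
#' be \code{NULL} to apply only the other; \code{lowpassFinal} is the
#' convenience wrapper for the final 40 Hz smoothing pass.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param hpHz,lpHz high- and low-pass cutoffs in Hz (must be below
#'   Nyquist).
#' @param order Butterworth order per pass.
#' @return the filtered \code{EpochSet}.
#' @examples
#' d <- buildTrialDesign(1, seed = 1)[1:2, ]
#' ep <- simulateEpochs(d, seed = 1,
#'                      noise = list(alpha = 1, pinkSd = 1, whiteSd = 1))
#' bandpass(ep, 0.5, 80)
#' @export
bandpass <- function(epochs, hpHz = 0.5, lpHz = 80, order = 4) {
  ny <- samplingRate(epochs) / 2
  if (!is.null(hpHz) && hpHz >= ny) stop("high-pass cutoff at/above Nyquist")
  if (!is.null(lpHz) && lpHz >= ny) stop("low-pass cutoff at/above Nyquist")
  hp <- if (!is.null(hpHz)) butterCoef(order, hpHz / ny, "high")
  lp <- if (!is.null(lpHz)) butterCoef(order, lpHz / ny, "low")
  epochs <- mapTrials(epochs, function(m) {
    for (ch in seq_len(nrow(m))) {
      x <- m[ch, ]
      if (!is.null(hp)) x <- filtfilt_(hp$b, hp$a, x)
      if (!is.null(lp)) x <- filtfilt_(lp$b, lp$a, x)
      m[ch, ] <- x
    }
    m
  })
  recordOp(epochs, "bandpass",
           list(hpHz = hpHz, lpHz = lpHz, order = order,
                realisation = "Butterworth forward-backward"))
}

#' @rdname bandpass
#' @export
lowpassFinal <- function(epochs, lpHz = 40, order = 4) {
  ny <- samplingRate(epochs) / 2
  if (lpHz >= ny) stop("low-pass cutoff at/above Nyquist")
  lp <- butterCoef(order, lpHz / ny, "low")
  epochs <- mapTrials(epochs, function(m) {
    for (ch in seq_len(nrow(m))) m[ch, ] <- filtfilt_(lp$b, lp$a, m[ch, ])
    m
  })
  recordOp(epochs, "lowpassFinal", list(lpHz = lpHz, order = order))
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (default -500 to -260 ms, a pre-stimulus period free of early
#' fNMES). The window is half-open \code{[a, b)}; at 512 Hz the default
#' covers exactly 122 samples. Idempotent.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param window baseline window in ms.
#' @return the baseline-corrected \code{EpochSet}.
#' @export
baselineCorrect <- function(epochs, window = c(-500, -260)) {
  n <- length(timeAxis(epochs))
  idx <- windowIndices(epochs@t0, samplingRate(epochs), n, window)
  if (!length(idx)) stop("empty baseline window")
  epochs <- mapTrials(epochs, function(m) {
    m - rowMeans(m[, idx, drop = FALSE])
  })
  recordOp(epochs, "baselineCorrect",
           list(window = window, nSamplesUsed = length(idx)))
}

#' Amplitude-threshold trial rejection
#'
#' Drops a trial iff any channel sample strictly exceeds the threshold in
#' absolute value (\code{|v| > threshold}; a sample at exactly the
#' threshold is retained).
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param thresholdUv rejection threshold in uV (> 0).
#' @return list with elements \code{epochs} (the pruned
#'   \code{\link{EpochSet}}) and \code{report}, a list holding
#'   \code{dropped} (data.frame of subject / trial_index pairs) and
#'   \code{retained} (per subject x fnmes retained trial counts).
#' @export
rejectTrials <- function(epochs, thresholdUv = 100) {
  stopifnot(thresholdUv > 0)
  design <- epochs@design
  keepAll <- logical(nrow(design))
  dropped <- list()
  for (s in names(epochs@data)) {
    a <- epochs@data[[s]]
    rows <- which(as.character(design$subject) == s)
    keep <- vapply(seq_len(dim(a)[1]), function(ti)
      max(abs(a[ti, , ])) <= thresholdUv, logical(1))
    keepAll[rows] <- keep
    if (any(!keep))
      dropped[[s]] <- data.frame(subject = s,
                                 trial_index = design$trial_index[rows[!keep]])
    epochs@data[[s]] <- a[keep, , , drop = FALSE]
  }
  epochs@design <- design[keepAll, , drop = FALSE]
  droppedDf <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(subject = character(0), trial_index = integer(0))
  rownames(droppedDf) <- NULL
  retained <- table(subject = epochs@design$subject,
                    fnmes = epochs@design$fnmes)
  epochs <- recordOp(epochs, "rejectTrials",
                     list(thresholdUv = thresholdUv,
                          nDropped = nrow(droppedDf)))
  list(epochs = epochs, report = list(dropped = droppedDf,
                                      retained = retained))
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean at each sample is zero. Linear and idempotent.
#'
#' @param epochs an \code{\link{EpochSet}} with at least two channels.
#' @return the re-referenced \code{EpochSet}.
#' @export
rereferenceAverage <- function(epochs) {
  if (length(epochs@channels) < 2) stop("need >= 2 channels")
  epochs <- mapTrials(epochs, function(m) {
    sweep(m, 2, colMeans(m))
  })
  recordOp(epochs, "rereferenceAverage", list())
}

#' Neighbour interpolation of bad channels
#'
#' Replaces each listed channel with the inverse-distance-weighted mean of
#' its good neighbours on the built-in template grid (weights sum to one).
#' Good channels are untouched. A bad channel with fewer than
#' \code{minNeighbours} good neighbours raises an error.
#'
#' @param epochs an \code{\link{EpochSet}} on the standard montage.
#' @param bad character vector of channels to interpolate.
#' @param minNeighbours minimum number of good neighbours required.
#' @return the \code{EpochSet} with bad channels replaced.
#' @export
interpolateChannels <- function(epochs, bad, minNeighbours = 3) {
  if (!length(bad)) return(recordOp(epochs, "interpolateChannels",
                                    list(bad = character(0))))
  montage <- standardMontage()
  montage <- montage[match(epochs@channels, montage$channel), , drop = FALSE]
  if (anyNA(montage$channel))
    stop("epochs are not on the standard montage template")
  if (!all(bad %in% epochs@channels))
    stop("unknown channels: ", paste(setdiff(bad, epochs@channels),
                                     collapse = ", "))
  nb <- montageNeighbours(montage)
  weights <- lapply(bad, function(ch) {
    good <- setdiff(nb[[ch]], bad)
    if (length(good) < minNeighbours)
      stop("channel ", ch, " has fewer than ", minNeighbours,
           " good neighbours")
    i <- match(ch, montage$channel)
    j <- match(good, montage$channel)
    d <- sqrt((montage$x[j] - montage$x[i])^2 +
                (montage$y[j] - montage$y[i])^2)
    w <- (1 / d) / sum(1 / d)
    setNames(w, good)
  })
  names(weights) <- bad
  epochs <- mapTrials(epochs, function(m) {
    orig <- m
    for (ch in bad) {
      w <- weights[[ch]]
      m[match(ch, epochs@channels), ] <-
        as.numeric(w %*% orig[match(names(w), epochs@channels), ,
                              drop = FALSE])
    }
    m
  })
  recordOp(epochs, "interpolateChannels",
           list(bad = bad, weights = weights))
}
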