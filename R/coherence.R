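# Time-frequency cross-spectra and magnitude coherence between electrode
# regions of interest.

#' Time-frequency analysis grid
#'
#' The coherence analysis grid: frequencies 5-40 Hz in 0.5 Hz steps, times
#' 0-1000 ms in 10 ms steps, and for each frequency a Hanning window
#' spanning 5 cycles (so lower frequencies use longer windows). Windows are
#' centred on the time point and may draw on samples outside 0-1000 ms,
#' which the -1000 to +1200 ms epochs provide; cells whose window would
#' leave the epoch are marked missing rather than zero-padded.
#'
#' @param fmin,fmax,fstep frequency axis in Hz.
#' @param tmin,tmax,tstep time axis in ms.
#' @param cycles Hanning window length in cycles per frequency.
#' @return list of class \code{"TFGrid"} with \code{freqs}, \code{times},
#'   \code{cycles}.
#' @examples
#' g <- tfGrid()
#' length(g$freqs)   # 71
#' length(g$times)   # 101
#' @export
tfGrid <- function(fmin = 5, fmax = 40, fstep = 0.5,
                   tmin = 0, tmax = 1000, tstep = 10, cycles = 5) {
  stopifnot(fmin > 0, fmax > fmin, cycles > 0)
  structure(list(freqs = seq(fmin, fmax, by = fstep),
                 times = seq(tmin, tmax, by = tstep),
                 cycles = cycles),
            class = "TFGrid")
}

#' Short-time Fourier transform of epochs
#'
#' Computes, per trial and channel, the complex Fourier coefficient at each
#' grid cell: the Hanning-tapered segment of length \code{cycles / f}
#' seconds centred on the time point, demodulated at frequency f. Cells
#' whose segment is not fully supported by the epoch are \code{NA}.
#' Implemented as FFT convolution with the tapered complex kernel, which
#' equals the direct tapered DFT of the segment.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param grid a \code{\link{tfGrid}}.
#' @param channels channels to transform (default: all).
#' @return list with \code{spectra} (per-subject complex arrays
#'   trial x channel x freq x time), \code{freqs}, \code{times},
#'   \code{channels}.
#' @export
tfTransform <- function(epochs, grid = tfGrid(), channels = NULL) {
  if (is.null(channels)) channels <- epochs@channels
  missing <- setdiff(channels, epochs@channels)
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  srate <- samplingRate(epochs)
  nSamples <- length(timeAxis(epochs))
  tIdx <- floor((grid$times - epochs@t0) * srate / 1000) + 1
  if (any(tIdx < 1 | tIdx > nSamples))
    stop("grid times outside the epoch")
  winLens <- pmax(3L, round(grid$cycles / grid$freqs * srate))
  nfft <- 2^ceiling(log2(nSamples + max(winLens)))
  kernFfts <- lapply(seq_along(grid$freqs), function(fi) {
    L <- winLens[fi]
    j <- seq_len(L)
    taper <- 0.5 - 0.5 * cos(2 * pi * (j - 1) / (L - 1))   # Hanning
    cIdx <- floor(L / 2) + 1
    k <- taper * exp(-1i * 2 * pi * grid$freqs[fi] * (j - cIdx) / srate)
    fft(c(rev(k), rep(0, nfft - L)))
  })
  ic <- match(channels, epochs@channels)
  spectra <- lapply(names(epochs@data), function(s) {
    a <- epochs@data[[s]]
    nt <- dim(a)[1]
    sig <- matrix(0, nfft, nt * length(ic))
    for (ti in seq_len(nt))
      sig[seq_len(nSamples), (ti - 1) * length(ic) + seq_along(ic)] <-
        t(array(a[ti, ic, ], dim = c(length(ic), nSamples)))
    SIG <- stats::mvfft(sig)
    out <- array(NA_complex_,
                 dim = c(nt, length(ic), length(grid$freqs),
                         length(grid$times)))
    for (fi in seq_along(grid$freqs)) {
      L <- winLens[fi]
      cIdx <- floor(L / 2) + 1
      conv <- stats::mvfft(SIG * kernFfts[[fi]], inverse = TRUE) / nfft
      rowPick <- tIdx + L - cIdx          # conv index of each grid time
      lo <- tIdx - cIdx + 1               # first sample the window touches
      hi <- tIdx - cIdx + L
      valid <- lo >= 1 & hi <= nSamples
      for (w in seq_along(grid$times)[valid])
        out[, , fi, w] <- matrix(conv[rowPick[w], ],
                                 nrow = nt, byrow = TRUE)
    }
    out
  })
  names(spectra) <- names(epochs@data)
  list(spectra = spectra, freqs = grid$freqs, times = grid$times,
       channels = channels)
}

#' Across-trial magnitude coherence for electrode pairs
#'
#' For each pair (X, Y), computes
#' \code{coh(f, t) = |sum_trials X conj(Y)| / sqrt(sum |X|^2 sum |Y|^2)},
#' the magnitude (not squared) of the normalised trial-averaged
#' cross-spectrum; values lie in [0, 1]. Missing spectra cells and
#' zero-power cells propagate as \code{NA}.
#'
#' @param spectra complex array trial x channel x freq x time (one
#'   subject's entry of \code{\link{tfTransform}}'s \code{spectra}).
#' @param pairs two-column matrix of channel indices (or a list of length-2
#'   vectors of channel names resolved against \code{channels}).
#' @param channels channel names of the spectra's channel axis (needed when
#'   \code{pairs} holds names).
#' @param squared return squared coherence instead of magnitude.
#' @return list of freq x time coherence matrices, one per pair.
#' @export
pairwiseCoherence <- function(spectra, pairs, channels = NULL,
                              squared = FALSE) {
  if (dim(spectra)[1] < 2) stop("need >= 2 trials")
  if (is.list(pairs)) {
    stopifnot(!is.null(channels))
    pairs <- do.call(rbind, lapply(pairs, function(p)
      match(p, channels)))
  }
  lapply(seq_len(nrow(pairs)), function(k) {
    X <- spectra[, pairs[k, 1], , , drop = FALSE]
    Y <- spectra[, pairs[k, 2], , , drop = FALSE]
    dim(X) <- dim(X)[c(1, 3, 4)]
    dim(Y) <- dim(Y)[c(1, 3, 4)]
    cross <- apply(X * Conj(Y), c(2, 3), sum)
    px <- apply(Mod(X)^2, c(2, 3), sum)
    py <- apply(Mod(Y)^2, c(2, 3), sum)
    den <- sqrt(px * py)
    coh <- Mod(cross) / den
    coh[!is.finite(coh)] <- NA_real_
    if (squared) coh^2 else coh
  })
}

#' Average pair coherences within ROI pairs
#'
#' Pairs every electrode of the central ROI (Cz, C1, C2, C3, C4) with every
#' electrode of the left (7), middle (3) and right (7) occipital ROIs and
#' arithmetically averages the pair coherence maps within each central x
#' region set (35, 15 and 35 pairs). Missing cells propagate: a cell is
#' \code{NA} in the ROI average iff it is \code{NA} in any contributing
#' pair map (all pairs share the epoch support, so in practice all or
#' none).
#'
#' @param cohMaps list of pair coherence maps from
#'   \code{\link{pairwiseCoherence}} computed over the full central x
#'   occipital pair list, in the order returned by \code{\link{roiPairs}}.
#' @param pairInfo the \code{data.frame} returned by \code{\link{roiPairs}}.
#' @return named list of freq x time matrices, one per ROI pair
#'   (\code{central.left}, \code{central.middle}, \code{central.right}).
#' @export
roiAverage <- function(cohMaps, pairInfo) {
  stopifnot(length(cohMaps) == nrow(pairInfo))
  out <- lapply(split(seq_len(nrow(pairInfo)), pairInfo$region),
                function(idx) {
    Reduce(`+`, cohMaps[idx]) / length(idx)
  })
  out[unique(pairInfo$region)]
}

#' Enumerate central x occipital electrode pairs
#'
#' @param rois ROI definition list (\code{\link{coherenceRois}}).
#' @return \code{data.frame} with columns \code{central}, \code{occipital},
#'   \code{region} (\code{central.left} etc.), one row per pair.
#' @export
roiPairs <- function(rois = coherenceRois()) {
  do.call(rbind, lapply(c("left", "middle", "right"), function(r) {
    expand.grid(central = rois$central, occipital = rois[[r]],
                stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, 1:2] |>
      transform(region = paste0("central.", r))
  }))
}

#' Subject x condition x choice ROI coherence maps
#'
#' The full coherence stage: transforms the ROI channels of each subject,
#' splits trials by fNMES condition and categorisation choice, estimates
#' across-trial pair coherences per cell and averages them into the three
#' ROI-pair maps. Cells with fewer than \code{minTrials} trials are
#' dropped.
#'
#' @param epochs an \code{\link{EpochSet}} whose design has \code{fnmes}
#'   and \code{choice} columns.
#' @param grid a \code{\link{tfGrid}}.
#' @param rois ROI definitions.
#' @param emotion restrict to one stimulus emotion (default
#'   \code{"neutral"}, the study's analysis set); \code{NULL} keeps all.
#' @param minTrials minimum trials per cell.
#' @return list of \code{\link{TFCoherenceMap}} objects.
#' @export
roiCoherence <- function(epochs, grid = tfGrid(), rois = coherenceRois(),
                         emotion = "neutral", minTrials = 10) {
  pairInfo <- roiPairs(rois)
  chans <- unique(c(pairInfo$central, pairInfo$occipital))
  tf <- tfTransform(epochs, grid, channels = chans)
  pairsIdx <- cbind(match(pairInfo$central, chans),
                    match(pairInfo$occipital, chans))
  design <- epochs@design
  maps <- list()
  for (s in names(tf$spectra)) {
    d <- design[as.character(design$subject) == s, , drop = FALSE]
    keep <- !is.na(d$choice)
    if (!is.null(emotion)) keep <- keep & d$emotion %in% emotion
    cells <- unique(d[keep, c("fnmes", "choice")])
    for (i in seq_len(nrow(cells))) {
      idx <- which(keep & d$fnmes == cells$fnmes[i] &
                     d$choice == cells$choice[i])
      if (length(idx) < minTrials) next
      sp <- tf$spectra[[s]][idx, , , , drop = FALSE]
      cohs <- pairwiseCoherence(sp, pairsIdx)
      avg <- roiAverage(cohs, pairInfo)
      for (rp in names(avg))
        maps[[length(maps) + 1L]] <-
          new("TFCoherenceMap", coh = avg[[rp]], freqs = tf$freqs,
              times = tf$times, subject = s,
              fnmes = as.character(cells$fnmes[i]),
              choice = as.character(cells$choice[i]), roiPair = rp,
              nTrials = length(idx))
    }
  }
  maps
}
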