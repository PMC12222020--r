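# Fixture builders shared across the suite; everything is generated in code.

# Minimal EpochSet from an explicit trials x channels x samples array.
toyEpochSet <- function(arr, channels, design = NULL, srate = 512,
                        t0 = -1000) {
  n <- dim(arr)[1]
  if (is.null(design))
    design <- data.frame(subject = 1, trial_index = seq_len(n),
                         identity = 1L, emotion = "neutral", fnmes = "off",
                         repetition = 1L)
  new("EpochSet", data = list(`1` = arr), design = design,
      channels = channels, srate = srate, t0 = t0, log = list())
}

# Design with explicit condition x choice cells (coherence pipeline tests).
cellDesign <- function(nSubjects, perCell,
                       fnmes = c("off", "late"),
                       choices = c("happy", "sad")) {
  cells <- expand.grid(fnmes = fnmes, choice = choices,
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nSubjects), function(s) {
    d <- cells[rep(seq_len(nrow(cells)), each = perCell), ]
    data.frame(subject = s, trial_index = seq_len(nrow(d)), identity = 1L,
               emotion = "neutral", fnmes = d$fnmes, repetition = 1L,
               choice = d$choice)
  }))
}

noiseFree <- list(alpha = 1, pinkSd = 0, whiteSd = 0)

# Params with only the N170 component active (no beta coupling).
n170OnlyParams <- function(...) {
  effectParams(betaCoupling = c(off = 0, early = 0, late = 0,
                                stim_only = 0), ...)
}

roiChannels <- function() {
  r <- coherenceRois()
  unique(c(r$central, r$left, r$middle, r$right))
}

# Brute-force tapered DFT of one grid cell (independent STFT oracle).
bruteStftCell <- function(x, srate, t0, f, tms, cycles = 5) {
  L <- max(3L, round(cycles / f * srate))
  j <- seq_len(L)
  taper <- 0.5 - 0.5 * cos(2 * pi * (j - 1) / (L - 1))
  cIdx <- floor(L / 2) + 1
  tIdx <- floor((tms - t0) * srate / 1000) + 1
  idx <- tIdx - cIdx + j
  if (any(idx < 1) || any(idx > length(x))) return(NA_complex_)
  sum(x[idx] * taper * exp(-1i * 2 * pi * f * (j - cIdx) / srate))
}
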