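#' Effect parameters of the synthetic-data generator
#'
#' Bundles the ground-truth effect structure planted into synthetic epochs
#' and choices. Defaults are the published estimates where the study prints
#' them (choice log-odds b_early = 0.17, b_late = 0.133, b_happy = 5.50,
#' b_sad = -4.23; beta band 13-22 Hz with coupling from 650 ms post
#' stimulus; condition-mean coherence levels around 0.32-0.34; N170 window
#' 150-200 ms over the 18 listed electrodes) and field-realistic choices
#' elsewhere (N170 base amplitude -5 uV; subject intercept SD 1.36 log-odds,
#' back-derived from the published conditional R-squared of 0.36).
#'
#' @param n170BaseAmp N170 amplitude for neutral faces, uV (negative).
#' @param n170EmotionDelta named uV increments per emotion (negative =
#'   larger N170).
#' @param n170FnmesDelta named uV increments per fNMES level (positive =
#'   reduced N170, as observed under early stimulation).
#' @param n170Interaction optional matrix (emotions x fNMES levels, dimnames
#'   required) of additional uV increments; the additive default (NULL)
#'   cancels exactly in the double subtraction.
#' @param n170Window,n170Channels analysis window (ms, half-open) and
#'   electrode set of the planted deflection.
#' @param betaBand beta band in Hz.
#' @param betaCoupling named coupling strengths in [0, 1): target
#'   common-source coherence between central and left-occipital channels,
#'   keyed \code{"<fnmes>.<choice>"} (fallback key \code{"<fnmes>"}).
#' @param betaOnset coupling onset in ms post stimulus.
#' @param betaAmp amplitude (uV RMS) of the band-limited beta components.
#' @param choiceB named log-odds fixed effects of the choice generator:
#'   \code{early}, \code{late}, \code{happy}, \code{sad}.
#' @param subjectSd SD of subject-level random intercepts, log-odds.
#' @return a list of class \code{"EffectParams"}.
#' @examples
#' p <- effectParams()
#' p$choiceB[["early"]]   # 0.17
#' @export
effectParams <- function(
    n170BaseAmp = -5,
    n170EmotionDelta = c(neutral = 0, happy = -1, sad = -1.5),
    n170FnmesDelta = c(off = 0, early = 1.5, late = 0, stim_only = 0),
    n170Interaction = NULL,
    n170Window = c(150, 200),
    n170Channels = n170Electrodes(),
    betaBand = c(13, 22),
    betaCoupling = c(off.happy = 0.340, off.sad = 0.316,
                     early.happy = 0.318, early.sad = 0.330,
                     late.happy = 0.318, late.sad = 0.332,
                     stim_only = 0),
    betaOnset = 650,
    betaAmp = 3,
    choiceB = c(early = 0.17, late = 0.133, happy = 5.50, sad = -4.23),
    subjectSd = 1.36) {
  stopifnot(all(betaCoupling >= 0), all(betaCoupling < 1),
            length(n170Window) == 2L, n170Window[2] > n170Window[1],
            all(is.finite(c(n170BaseAmp, n170EmotionDelta, n170FnmesDelta,
                            betaBand, betaOnset, betaAmp, choiceB,
                            subjectSd))))
  if (!is.null(n170Interaction) && is.null(dimnames(n170Interaction)))
    stop("n170Interaction needs dimnames (emotions x fnmes levels)")
  structure(list(n170BaseAmp = n170BaseAmp,
                 n170EmotionDelta = n170EmotionDelta,
                 n170FnmesDelta = n170FnmesDelta,
                 n170Interaction = n170Interaction,
                 n170Window = n170Window, n170Channels = n170Channels,
                 betaBand = betaBand, betaCoupling = betaCoupling,
                 betaOnset = betaOnset, betaAmp = betaAmp,
                 choiceB = choiceB, subjectSd = subjectSd),
            class = "EffectParams")
}

# Coupling strength for one trial: key "<fnmes>.<choice>", falling back to
# "<fnmes>" and then 0 (e.g. when choices have not been simulated yet).
couplingFor <- function(params, fnmes, choice) {
  key <- paste0(fnmes, ".", choice)
  cp <- params$betaCoupling
  if (!is.na(choice) && key %in% names(cp)) return(unname(cp[key]))
  if (fnmes %in% names(cp)) return(unname(cp[fnmes]))
  0
}

# Planted N170 amplitude (uV) for one trial; NA-safe for stim-only trials.
n170AmplitudeFor <- function(params, emotion, fnmes) {
  if (emotion == "none") return(0)
  amp <- params$n170BaseAmp +
    unname(params$n170EmotionDelta[emotion]) +
    unname(params$n170FnmesDelta[fnmes])
  if (!is.null(params$n170Interaction) &&
      emotion %in% rownames(params$n170Interaction) &&
      fnmes %in% colnames(params$n170Interaction))
    amp <- amp + params$n170Interaction[emotion, fnmes]
  amp
}

# 1/f^alpha noise, one column per signal, unit-SD columns scaled by sdOut.
# Generated at the next power-of-two length (fast FFT) and truncated.
pinkNoise <- function(nSamples, nSignals, alpha, sdOut) {
  if (sdOut == 0) return(matrix(0, nSamples, nSignals))
  nfft <- 2^ceiling(log2(nSamples))
  w <- matrix(rnorm(nfft * nSignals), nfft, nSignals)
  sp <- stats::mvfft(w)
  k <- c(0, seq_len(nfft - 1))
  k <- pmin(k, nfft - k)              # two-sided frequency index
  g <- c(0, k[-1]^(-alpha / 2))
  x <- Re(stats::mvfft(sp * g, inverse = TRUE))[seq_len(nSamples), ,
                                                drop = FALSE] / nfft
  sc <- apply(x, 2, sd)
  sc[sc == 0] <- 1
  sweep(x, 2, sc / sdOut, "/")
}

# Band-limited Gaussian noise columns with unit SD (FFT brick-wall band,
# power-of-two length, truncated to nSamples).
bandNoise <- function(nSamples, nSignals, srate, band) {
  nfft <- 2^ceiling(log2(nSamples))
  w <- matrix(rnorm(nfft * nSignals), nfft, nSignals)
  sp <- stats::mvfft(w)
  f <- (seq_len(nfft) - 1) * srate / nfft
  f <- pmin(f, srate - f)
  keep <- f >= band[1] & f <= band[2]
  sp[!keep, ] <- 0
  x <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(nSamples), ,
                                            drop = FALSE] / nfft
  sc <- apply(x, 2, sd)
  sc[sc == 0] <- 1
  sweep(x, 2, sc, "/")
}

#' Simulate EEG epochs with planted N170 and beta-coupling effects
#'
#' Generates an \code{\link{EpochSet}} carrying the statistical structure
#' the downstream analyses assume: (i) 1/f plus white background noise,
#' (ii) a Gaussian-windowed negative occipito-temporal deflection centred in
#' the N170 window whose amplitude is base + emotion increment + fNMES
#' increment (+ optional interaction), normalised so that the window mean of
#' the planted component equals the nominal amplitude exactly, and (iii) a
#' shared band-limited beta source added to the central and left-occipital
#' ROI channels from \code{betaOnset} onward, mixed so that the analytic
#' common-source coherence between the two ROIs equals the trial's coupling
#' strength. Ground truth (\code{n170_true}, \code{coupling_true}) is
#' recorded in the design table.
#'
#' @param design trial design (\code{\link{buildTrialDesign}}); an optional
#'   \code{choice} column (e.g. from \code{\link{simulateChoices}}) selects
#'   choice-dependent couplings.
#' @param params an \code{\link{effectParams}} object.
#' @param noise list with elements \code{alpha} (1/f exponent),
#'   \code{pinkSd} and \code{whiteSd} (uV); set SDs to 0 for noise-free
#'   construction.
#' @param seed integer master seed.
#' @param channels montage; defaults to the full 64-channel template.
#' @param srate,tlim sampling rate (Hz) and epoch limits (ms, half-open
#'   \code{[tlim[1], tlim[2])}).
#' @return an \code{\link{EpochSet}}.
#' @examples
#' d <- buildTrialDesign(1, seed = 1)[1:6, ]
#' ep <- simulateEpochs(d, effectParams(),
#'                      noise = list(alpha = 1, pinkSd = 0, whiteSd = 0),
#'                      seed = 1)
#' ep
#' @export
simulateEpochs <- function(design, params = effectParams(),
                           noise = list(alpha = 1, pinkSd = 5, whiteSd = 2),
                           seed,
                           channels = standardMontage()$channel,
                           srate = 512, tlim = c(-1000, 1200)) {
  stopifnot(inherits(params, "EffectParams"))
  if (!all(params$n170Channels %in% channels))
    stop("unknown channel names in n170Channels: ",
         paste(setdiff(params$n170Channels, channels), collapse = ", "))
  nSamples <- floor((tlim[2] - tlim[1]) / 1000 * srate)
  times <- sampleTimes(tlim[1], srate, nSamples)
  win <- windowIndices(tlim[1], srate, nSamples, params$n170Window)

  # temporal profile of the planted deflection: Gaussian bump, rescaled so
  # its mean over the analysis window is exactly 1
  centre <- mean(params$n170Window)
  sdms <- diff(params$n170Window) / 6
  bump <- exp(-(times - centre)^2 / (2 * sdms^2))
  bump <- bump / mean(bump[win])

  # beta-coupling envelope: on from betaOnset to 1100 ms with 50 ms ramps
  env <- couplingEnvelope(times, params$betaOnset, 1100, 50)
  rois <- coherenceRois()
  iCen <- match(intersect(rois$central, channels), channels)
  iOcc <- match(intersect(rois$left, channels), channels)
  nCh <- length(channels)

  subjects <- unique(design$subject)
  data <- vector("list", length(subjects))
  names(data) <- as.character(subjects)
  design$n170_true <- NA_real_
  design$coupling_true <- NA_real_

  for (si in seq_along(subjects)) {
    s <- subjects[si]
    set.seed(deriveSeed(seed, paste0("epochs", s)))
    d <- design[design$subject == s, , drop = FALSE]
    nt <- nrow(d)
    arr <- array(0, dim = c(nt, nCh, nSamples))
    hasChoice <- "choice" %in% names(d)
    for (ti in seq_len(nt)) {
      x <- matrix(0, nSamples, nCh)
      if (noise$pinkSd > 0)
        x <- x + pinkNoise(nSamples, nCh, noise$alpha, noise$pinkSd)
      if (noise$whiteSd > 0)
        x <- x + matrix(rnorm(nSamples * nCh, sd = noise$whiteSd),
                        nSamples, nCh)
      amp <- n170AmplitudeFor(params, d$emotion[ti], d$fnmes[ti])
      if (amp != 0) {
        ic <- match(params$n170Channels, channels)
        x[, ic] <- x[, ic] + amp * bump
      }
      ch <- if (hasChoice) as.character(d$choice[ti]) else NA_character_
      cc <- couplingFor(params, d$fnmes[ti], ch)
      if (cc > 0 && length(iCen) && length(iOcc)) {
        src <- bandNoise(nSamples, 1L, srate, params$betaBand)[, 1]
        etaC <- bandNoise(nSamples, length(iCen), srate, params$betaBand)
        etaO <- bandNoise(nSamples, length(iOcc), srate, params$betaBand)
        mix <- function(eta) params$betaAmp *
          (sqrt(cc) * src + sqrt(1 - cc) * eta) * env
        x[, iCen] <- x[, iCen] + mix(etaC)
        x[, iOcc] <- x[, iOcc] + mix(etaO)
      }
      arr[ti, , ] <- t(x)
      idx <- which(design$subject == s)[ti]
      design$n170_true[idx] <- amp
      design$coupling_true[idx] <- cc
    }
    data[[si]] <- arr
  }

  new("EpochSet", data = data, design = design, channels = channels,
      srate = srate, t0 = tlim[1],
      log = list(list(op = "simulateEpochs", seed = seed,
                      noise = noise,
                      params = unclass(params)[c("n170BaseAmp", "betaBand",
                                                 "betaOnset", "betaAmp")])))
}

# Cosine-ramped on/off envelope in [0, 1].
couplingEnvelope <- function(times, onMs, offMs, rampMs) {
  e <- numeric(length(times))
  e[times >= onMs & times < offMs] <- 1
  up <- times >= onMs - rampMs & times < onMs
  e[up] <- 0.5 * (1 + cos(pi * (onMs - times[up]) / rampMs))
  dn <- times >= offMs & times < offMs + rampMs
  e[dn] <- 0.5 * (1 + cos(pi * (times[dn] - offMs) / rampMs))
  e
}

#' Specification of the fNMES pulse-train artifact
#'
#' Describes the stimulation artifact: a 500 ms train of biphasic square
#' pulses delivered at 70 Hz (35 pulses), 100 us per phase, within the early
#' (-250 to 250 ms) or late (500 to 1000 ms) stimulation window. At EEG
#' sampling rates far below the 100 us pulse width, each biphasic pulse is
#' realised as a +amplitude sample followed by a -amplitude sample.
#'
#' @param fnmes targeted condition level, \code{"early"} or \code{"late"}
#'   (sets the default window).
#' @param rate pulse rate in Hz.
#' @param trainMs train duration in ms; \code{rate * trainMs / 1000} must be
#'   an integer pulse count.
#' @param pulseWidthUs single-phase pulse width in microseconds.
#' @param window stimulation window in ms (defaults by \code{fnmes} level);
#'   its length must equal \code{trainMs}.
#' @param amplitude artifact amplitude in uV at unit spatial gain.
#' @param spatialProfile named per-channel gain vector; default is largest
#'   over anterior/temporal sites and small occipitally.
#' @return a list of class \code{"ArtifactSpec"}.
#' @examples
#' artifactSpec("early")$nPulses   # 35
#' @export
artifactSpec <- function(fnmes = c("early", "late"), rate = 70,
                         trainMs = 500, pulseWidthUs = 100,
                         window = NULL, amplitude = 40,
                         spatialProfile = NULL) {
  fnmes <- match.arg(fnmes)
  if (is.null(window))
    window <- if (fnmes == "early") c(-250, 250) else c(500, 1000)
  if (!isTRUE(all.equal(diff(window), trainMs)))
    stop("window length must equal trainMs")
  nPulses <- rate * trainMs / 1000
  if (!isTRUE(all.equal(nPulses, round(nPulses))))
    stop("rate x train duration must give an integer pulse count")
  if (is.null(spatialProfile)) {
    m <- standardMontage()
    # anterior and temporal channels pick up most of the stimulation
    # artifact; occipital sites only a residue
    g <- 0.1 + 0.9 * (m$y + 5) / 9
    spatialProfile <- setNames(g, m$channel)
  }
  structure(list(fnmes = fnmes, rate = rate, trainMs = trainMs,
                 pulseWidthUs = pulseWidthUs, window = window,
                 amplitude = amplitude, nPulses = as.integer(round(nPulses)),
                 spatialProfile = spatialProfile),
            class = "ArtifactSpec")
}

#' Inject the stimulation artifact into synthetic epochs
#'
#' Adds the identical biphasic pulse-train waveform, scaled by the
#' per-channel spatial profile, to every trial of the targeted fNMES level.
#' Because the waveform is identical across emotions within a condition, it
#' is strictly additive and emotion-symmetric, so the happy-minus-sad
#' difference wave cancels it to machine precision -- the rationale for the
#' double-subtraction analysis.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param spec an \code{\link{artifactSpec}}.
#' @return the \code{EpochSet} with the artifact added.
#' @export
injectFnmesArtifact <- function(epochs, spec) {
  stopifnot(is(epochs, "EpochSet"), inherits(spec, "ArtifactSpec"))
  times <- timeAxis(epochs)
  if (spec$window[1] < times[1] ||
      spec$window[2] > epochs@t0 + length(times) * 1000 / epochs@srate)
    stop("artifact window lies outside the epoch")
  nSamples <- length(times)
  wave <- numeric(nSamples)
  onsets <- spec$window[1] + (seq_len(spec$nPulses) - 1) * 1000 / spec$rate
  for (on in onsets) {
    i <- floor((on - epochs@t0) * epochs@srate / 1000) + 1
    wave[i] <- wave[i] + spec$amplitude
    if (i + 1 <= nSamples) wave[i + 1] <- wave[i + 1] - spec$amplitude
  }
  gain <- spec$spatialProfile[epochs@channels]
  if (anyNA(gain)) stop("spatialProfile is missing channels")
  add <- outer(unname(gain), wave)      # channels x samples
  design <- epochs@design
  for (s in names(epochs@data)) {
    d <- design[as.character(design$subject) == s, , drop = FALSE]
    hit <- which(d$fnmes == spec$fnmes)
    for (ti in hit)
      epochs@data[[s]][ti, , ] <- epochs@data[[s]][ti, , ] + add
  }
  epochs@log <- c(epochs@log,
                  list(list(op = "injectFnmesArtifact", fnmes = spec$fnmes,
                            nPulses = spec$nPulses, window = spec$window)))
  epochs
}

#' Simulate binary categorisation choices
#'
#' Draws happy/sad choices from the subject-level logistic model
#' \code{logit P(happy) = intercept_s + emotion term + fNMES term}, with
#' subject intercepts drawn from N(0, subjectSd^2). Stimulation-only trials
#' receive no choice.
#'
#' @param design a trial design.
#' @param params an \code{\link{effectParams}} (fields \code{choiceB},
#'   \code{subjectSd}).
#' @param seed integer master seed.
#' @return the design with added columns \code{prob_happy} and
#'   \code{choice} (\code{"happy"} / \code{"sad"}, \code{NA} for
#'   stimulation-only trials).
#' @examples
#' d <- buildTrialDesign(1, seed = 2, orderConstraints = FALSE)
#' ch <- simulateChoices(d, effectParams(), seed = 2)
#' table(ch$emotion, ch$choice)
#' @export
simulateChoices <- function(design, params = effectParams(), seed) {
  stopifnot(inherits(params, "EffectParams"))
  subjects <- unique(design$subject)
  set.seed(deriveSeed(seed, "choiceIntercepts"))
  intercepts <- setNames(rnorm(length(subjects), 0, params$subjectSd),
                         as.character(subjects))
  b <- params$choiceB
  eta <- intercepts[as.character(design$subject)] +
    ifelse(design$emotion == "happy", b[["happy"]],
           ifelse(design$emotion == "sad", b[["sad"]], 0)) +
    ifelse(design$fnmes == "early", b[["early"]],
           ifelse(design$fnmes == "late", b[["late"]], 0))
  p <- plogis(eta)
  set.seed(deriveSeed(seed, "choiceDraws"))
  y <- rbinom(nrow(design), 1L, p)
  design$prob_happy <- unname(p)
  design$choice <- ifelse(y == 1L, "happy", "sad")
  stim <- design$fnmes == "stim_only"
  design$prob_happy[stim] <- NA_real_
  design$choice[stim] <- NA_character_
  design
}

#' Simulate OpenFace-style action-unit intensity traces
#'
#' Produces per-trial AU4/AU6/AU12/AU15 intensity time series in the
#' OpenFace CSV column layout (\code{AU04_r}, \code{AU06_r}, \code{AU12_r},
#' \code{AU15_r}). Each clip spans 2 s before to 2 s after stimulation
#' onset; the first second serves as baseline. During the 500 ms
#' stimulation window, AU12 (lip corner puller, zygomaticus major) is
#' lifted by \code{gain[fnmes]} as a proportion of its baseline level,
#' emulating fNMES-induced smiling; additive Gaussian noise rides on all
#' traces.
#'
#' @param design a trial design.
#' @param gain named proportion-of-baseline AU12 lifts per fNMES level;
#'   defaults are the published condition means (off 0.002, early 0.137,
#'   late 0.156).
#' @param seed integer master seed.
#' @param fps sampling rate of the traces, frames per second.
#' @param baselineLevel resting AU intensity (OpenFace intensity units).
#' @param noiseSd additive noise SD.
#' @return long \code{data.frame}: \code{subject}, \code{trial_index},
#'   \code{fnmes}, \code{emotion}, \code{frame}, \code{timestamp} (s),
#'   and the four AU columns.
#' @export
simulateAuTimeseries <- function(design,
                                 gain = c(off = 0.002, early = 0.137,
                                          late = 0.156, stim_only = 0.137),
                                 seed, fps = 30, baselineLevel = 1,
                                 noiseSd = 0.05) {
  nFrames <- as.integer(4 * fps)
  tsec <- (seq_len(nFrames) - 1) / fps
  stimWin <- tsec >= 2 & tsec < 2.5
  set.seed(deriveSeed(seed, "au"))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    g <- gain[[design$fnmes[i]]]
    if (is.null(g) || is.na(g)) g <- 0
    au12 <- baselineLevel * (1 + g * stimWin) + rnorm(nFrames, sd = noiseSd)
    mk <- function() baselineLevel + rnorm(nFrames, sd = noiseSd)
    out[[i]] <- data.frame(subject = design$subject[i],
                           trial_index = design$trial_index[i],
                           fnmes = design$fnmes[i],
                           emotion = design$emotion[i],
                           frame = seq_len(nFrames), timestamp = tsec,
                           AU04_r = mk(), AU06_r = mk(), AU12_r = au12,
                           AU15_r = mk())
  }
  do.call(rbind, out)
}
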