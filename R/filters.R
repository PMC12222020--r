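# Zero-phase IIR filtering primitives.
#
# No DSP package is assumed: Butterworth designs come from the standard
# analog prototype + bilinear transform, and filtfilt applies the filter
# forward and backward over odd-reflection padding, which squares the
# magnitude response and cancels the phase (standard ERP practice).

polyFromRoots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Butterworth digital filter coefficients.
# n: order; Wn: cutoff as a fraction of Nyquist (0..1); type: "low"/"high".
butterCoef <- function(n, Wn, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(Wn > 0, Wn < 1)
  fs <- 2
  warped <- 2 * fs * tan(pi * Wn / fs)
  # analog prototype: n poles on the unit circle, left half plane
  p <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  if (type == "low") {
    p <- warped * p
    z <- complex(0)
    k <- warped^n
  } else {
    p <- warped / p
    z <- rep(0 + 0i, n)
    k <- 1
  }
  # bilinear transform
  fs2 <- 2 * fs
  pd <- (1 + p / fs2) / (1 - p / fs2)
  zd <- (1 + z / fs2) / (1 - z / fs2)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(kd * polyFromRoots(zd))
  a <- Re(polyFromRoots(pd))
  list(b = b, a = a)
}

# Causal IIR filter y[t] = sum(b x[t-j]) - sum(a y[t-j]), zero initial state.
iirFilter <- function(b, a, x) {
  nb <- length(b)
  bx <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                      sides = 1)
  bx <- as.numeric(bx)[-seq_len(nb - 1)]
  if (length(a) > 1) {
    y <- stats::filter(bx, -a[-1], method = "recursive")
    as.numeric(y)
  } else bx
}

# Forward-backward (zero-phase) filtering with odd-reflection padding.
filtfilt_ <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 512L)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xe <- c(pre, x, post)
  y <- iirFilter(b, a, xe)
  y <- rev(iirFilter(b, a, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

# Squared-magnitude response of b/a at frequency f (Hz) -- the effective
# response of one filtfilt pass.
filterGain <- function(b, a, f, srate) {
  w <- exp(-1i * 2 * pi * f / srate)
  h <- vapply(seq_along(f), function(i) {
    num <- sum(b * w[i]^(seq_along(b) - 1))
    den <- sum(a * w[i]^(seq_along(a) - 1))
    Mod(num / den)
  }, numeric(1))
  h^2
}
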