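srate <- 512
tvec <- (0:1125) / srate

test_that("band-pass preserves in-band tones and removes DC / high bands", {
  arr <- array(0, dim = c(1, 3, 1126))
  arr[1, 1, ] <- sin(2 * pi * 10 * tvec)   # in band
  arr[1, 2, ] <- sin(2 * pi * 60 * tvec)   # above the final low pass
  arr[1, 3, ] <- 7                         # DC
  ep <- toyEpochSet(arr, c("Cz", "Pz", "Oz"))
  out <- bandpass(ep, 0.5, 80)
  mid <- 200:900                           # avoid edge transients
  # RMS-based amplitude: insensitive to the residual high-pass transient
  amp10 <- sqrt(2 * mean(epochData(out, 1)[1, 1, mid]^2))
  expect_lt(abs(amp10 - 1), 0.01)
  # 60 Hz tone through the 40 Hz low pass: >= 20 dB down
  out40 <- lowpassFinal(ep, 40)
  att <- -20 * log10(max(abs(epochData(out40, 1)[1, 2, mid])))
  expect_gt(att, 20)
  # DC through the 0.5 Hz high pass: steady-state mean ~ 0
  expect_lt(abs(mean(epochData(out, 1)[1, 3, mid])), 0.1)
  expect_error(bandpass(ep, 0.5, 300), "Nyquist")
})

test_that("single-pass Butterworth magnitude matches the analytic response", {
  ny <- srate / 2
  lp <- fnmesEEG:::butterCoef(4, 40 / ny, "low")
  f <- c(5, 20, 40, 60, 100)
  got <- sqrt(fnmesEEG:::filterGain(lp$b, lp$a, f, srate))
  # analytic |H| of an order-4 Butterworth at the pre-warped frequencies
  warp <- function(fr) tan(pi * fr / srate)
  expected <- 1 / sqrt(1 + (warp(f) / warp(40))^8)
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  arr <- array(7, dim = c(2, 2, 1126))
  ep <- toyEpochSet(arr, c("Cz", "Pz"),
                    design = data.frame(subject = 1, trial_index = 1:2,
                                        identity = 1L, emotion = "neutral",
                                        fnmes = "off", repetition = 1L))
  out <- baselineCorrect(ep)
  expect_equal(max(abs(epochData(out, 1))), 0)
  # half-open window [-500, -260) at 512 Hz uses exactly 122 samples
  idx <- fnmesEEG:::windowIndices(-1000, 512, 1126, c(-500, -260))
  expect_equal(length(idx), 122)
  # idempotence on arbitrary data
  arr2 <- array(rnorm(2 * 2 * 1126), dim = c(2, 2, 1126))
  ep2 <- toyEpochSet(arr2, c("Cz", "Pz"),
                     design = epochDesign(ep))
  once <- baselineCorrect(ep2)
  twice <- baselineCorrect(once)
  expect_equal(epochData(twice, 1), epochData(once, 1), tolerance = 1e-12)
  win <- epochData(once, 1)[1, 1, idx]
  expect_lt(abs(mean(win)), 1e-12)
})

test_that("trial rejection uses a strict threshold and matches a brute scan", {
  set.seed(31)
  arr <- array(rnorm(20 * 3 * 1126, sd = 10), dim = c(20, 3, 1126))
  arr[3, 2, 100] <- 101          # just over
  arr[5, 1, 50] <- 100           # exactly at threshold: retained
  des <- data.frame(subject = 1, trial_index = 1:20, identity = 1L,
                    emotion = "neutral",
                    fnmes = rep(c("off", "early"), 10), repetition = 1L)
  ep <- toyEpochSet(arr, c("Cz", "Pz", "Oz"), design = des)
  res <- rejectTrials(ep, 100)
  # exhaustive oracle over all samples
  keepOracle <- vapply(1:20, function(ti) max(abs(arr[ti, , ])) <= 100,
                       logical(1))
  expect_equal(sort(res$report$dropped$trial_index), which(!keepOracle))
  expect_equal(unname(nTrials(res$epochs)), sum(keepOracle))
  expect_true(5 %in% epochDesign(res$epochs)$trial_index)
  expect_false(3 %in% epochDesign(res$epochs)$trial_index)
})

test_that("average reference zeroes the channel mean and is linear", {
  arr <- array(0, dim = c(1, 2, 4))
  arr[1, 1, ] <- 3; arr[1, 2, ] <- -1
  ep <- toyEpochSet(arr, c("Cz", "Pz"),
                    design = data.frame(subject = 1, trial_index = 1,
                                        identity = 1L, emotion = "neutral",
                                        fnmes = "off", repetition = 1L))
  out <- rereferenceAverage(ep)
  expect_equal(epochData(out, 1)[1, 1, ], rep(2, 4))
  expect_equal(epochData(out, 1)[1, 2, ], rep(-2, 4))

  set.seed(5)
  a1 <- array(rnorm(1 * 4 * 50), dim = c(1, 4, 50))
  a2 <- array(rnorm(1 * 4 * 50), dim = c(1, 4, 50))
  des1 <- data.frame(subject = 1, trial_index = 1, identity = 1L,
                     emotion = "neutral", fnmes = "off", repetition = 1L)
  ch4 <- c("Cz", "Pz", "Oz", "Fz")
  f <- function(a) epochData(rereferenceAverage(toyEpochSet(a, ch4, des1)), 1)
  lhs <- f(2 * a1 + 3 * a2)
  rhs <- 2 * f(a1) + 3 * f(a2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(f(a1)[1, , ]))), 1e-9)
})

test_that("neighbour interpolation weights sum to one and recover constants", {
  d <- buildTrialDesign(1, seed = 1)[1:2, ]
  ep <- simulateEpochs(d, n170OnlyParams(), noise = noiseFree, seed = 1)
  # set all channels to 5 uV; a bad channel must come back as exactly 5
  for (s in "1") ep@data[[s]][] <- 5
  ep@data[["1"]][1, match("Pz", channelNames(ep)), ] <- 250
  out <- interpolateChannels(ep, "Pz")
  expect_equal(epochData(out, 1)[1, match("Pz", channelNames(ep)), ],
               rep(5, 1126))
  w <- epochLog(out)[[length(epochLog(out))]]$weights$Pz
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gte(length(w), 3)
  # zero bad channels: identity
  out0 <- interpolateChannels(ep, character(0))
  expect_equal(epochData(out0, 1), epochData(ep, 1))
  expect_error(interpolateChannels(ep, "NoChan"), "unknown")
})

test_that("out-of-order preprocessing warns via the pipeline log", {
  arr <- array(rnorm(1 * 2 * 1126), dim = c(1, 2, 1126))
  ep <- toyEpochSet(arr, c("Cz", "Pz"),
                    design = data.frame(subject = 1, trial_index = 1,
                                        identity = 1L, emotion = "neutral",
                                        fnmes = "off", repetition = 1L))
  ok <- rereferenceAverage(baselineCorrect(ep))
  expect_warning(baselineCorrect(ok), "canonical")
})
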