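test_that("noise-free planted N170 is recovered exactly", {
  d <- buildTrialDesign(1, seed = 2)[1:12, ]
  p <- n170OnlyParams(n170BaseAmp = -5,
                      n170EmotionDelta = c(neutral = 0, happy = 0, sad = 0),
                      n170FnmesDelta = c(off = 0, early = 0, late = 0,
                                         stim_only = 0))
  ep <- simulateEpochs(d, p, noise = noiseFree, seed = 1)
  rec <- extractN170(ep)
  expect_equal(rec$n170_uv, rep(-5, nrow(rec)), tolerance = 1e-12)
  # and the design carries the ground truth
  expect_equal(unique(epochDesign(ep)$n170_true[epochDesign(ep)$emotion != "none"]), -5)
})

test_that("planted amplitudes follow base + emotion + fnmes (+ interaction)", {
  d <- data.frame(subject = 1, trial_index = 1:4, identity = 1L,
                  emotion = c("neutral", "happy", "sad", "happy"),
                  fnmes = c("off", "off", "early", "early"),
                  repetition = 1L)
  inter <- matrix(0, 3, 3, dimnames = list(c("neutral", "happy", "sad"),
                                           c("off", "early", "late")))
  inter["happy", "early"] <- 2
  p <- n170OnlyParams(n170BaseAmp = -5,
                      n170EmotionDelta = c(neutral = 0, happy = -1, sad = -1.5),
                      n170FnmesDelta = c(off = 0, early = 1.5, late = 0,
                                         stim_only = 0),
                      n170Interaction = inter)
  ep <- simulateEpochs(d, p, noise = noiseFree, seed = 1)
  rec <- extractN170(ep)
  expect_equal(rec$n170_uv, c(-5, -6, -5, -2.5), tolerance = 1e-12)
})

test_that("epoch geometry follows the half-open convention", {
  d <- buildTrialDesign(1, seed = 1)[1, , drop = FALSE]
  ep <- simulateEpochs(d, n170OnlyParams(), noise = noiseFree, seed = 1)
  expect_equal(dim(epochData(ep, 1)), c(1, 64, 1126))
  tx <- timeAxis(ep)
  expect_equal(tx[1], -1000)
  expect_lt(max(tx), 1200)
  expect_equal(length(channelNames(ep)), 64)
})

test_that("same seed is bit-identical, different seed differs", {
  d <- buildTrialDesign(1, seed = 4)[1:3, ]
  nz <- list(alpha = 1, pinkSd = 2, whiteSd = 1)
  a <- simulateEpochs(d, effectParams(), noise = nz, seed = 7)
  b <- simulateEpochs(d, effectParams(), noise = nz, seed = 7)
  c_ <- simulateEpochs(d, effectParams(), noise = nz, seed = 8)
  expect_identical(epochData(a, 1), epochData(b, 1))
  expect_false(identical(epochData(a, 1), epochData(c_, 1)))
})

test_that("unknown channels in params are rejected", {
  d <- buildTrialDesign(1, seed = 1)[1:2, ]
  p <- n170OnlyParams(n170Channels = c("Oz", "NoSuchChannel"))
  expect_error(simulateEpochs(d, p, noise = noiseFree, seed = 1),
               "unknown channel")
})

test_that("artifact pulse train has 35 pulses and spares off trials", {
  spec <- artifactSpec("early")
  expect_equal(spec$nPulses, 35)
  expect_error(artifactSpec("early", window = c(-250, 300)),
               "window length")

  d <- data.frame(subject = 1, trial_index = 1:3, identity = 1L,
                  emotion = c("happy", "sad", "happy"),
                  fnmes = c("early", "early", "off"), repetition = 1L)
  ep <- simulateEpochs(d, n170OnlyParams(), noise = noiseFree, seed = 2)
  ep2 <- injectFnmesArtifact(ep, spec)
  expect_equal(epochData(ep2, 1)[3, , ], epochData(ep, 1)[3, , ])
  expect_gt(max(abs(epochData(ep2, 1)[1, , ] - epochData(ep, 1)[1, , ])), 0)
  # 35 positive-going pulse onsets on a frontal channel
  fp <- match("Fpz", channelNames(ep2))
  delta <- epochData(ep2, 1)[1, fp, ] - epochData(ep, 1)[1, fp, ]
  expect_equal(sum(delta > 0), 35)
})

test_that("artifact cancels to machine precision in the happy-sad difference", {
  d <- data.frame(subject = 1, trial_index = 1:4, identity = 1L,
                  emotion = c("happy", "sad", "happy", "sad"),
                  fnmes = "early", repetition = 1L)
  p <- n170OnlyParams(n170BaseAmp = 0,
                      n170EmotionDelta = c(neutral = 0, happy = 0, sad = 0),
                      n170FnmesDelta = c(off = 0, early = 0, late = 0,
                                         stim_only = 0))
  ep <- injectFnmesArtifact(simulateEpochs(d, p, noise = noiseFree, seed = 3),
                            artifactSpec("early", amplitude = 80))
  dw <- differenceWaves(ep, "happy", "sad", conditions = "early")
  expect_lt(max(abs(dw$early[["1"]])), 1e-10)
})

test_that("choice generator matches closed-form logistic probabilities", {
  d <- buildTrialDesign(14, seed = 9, orderConstraints = FALSE)
  # all-zero coefficients: P(happy) = 0.5
  p0 <- effectParams(choiceB = c(early = 0, late = 0, happy = 0, sad = 0),
                     subjectSd = 0)
  ch <- simulateChoices(d, p0, seed = 1)
  face <- ch[!is.na(ch$choice), ]
  n <- nrow(face)
  mcse <- sqrt(0.25 / n)
  expect_lt(abs(mean(face$choice == "happy") - 0.5), 3 * mcse)

  # b_happy = 5.50 alone: P(happy | happy face) = plogis(5.50) ~ 0.996
  p1 <- effectParams(choiceB = c(early = 0, late = 0, happy = 5.50, sad = 0),
                     subjectSd = 0)
  ch1 <- simulateChoices(d, p1, seed = 2)
  hap <- ch1[ch1$emotion == "happy", ]
  expect_equal(unique(hap$prob_happy), plogis(5.50))
  expect_lt(abs(mean(hap$choice == "happy") - plogis(5.50)),
            3 * sqrt(plogis(5.5) * (1 - plogis(5.5)) / nrow(hap)) + 1e-3)

  # b_early = 0.17 on neutral: rate difference ~ plogis(0.17) - 0.5
  p2 <- effectParams(choiceB = c(early = 0.17, late = 0, happy = 0, sad = 0),
                     subjectSd = 0)
  ch2 <- simulateChoices(d, p2, seed = 3)
  neu <- ch2[ch2$emotion == "neutral", ]
  dRate <- mean(neu$choice[neu$fnmes == "early"] == "happy") -
    mean(neu$choice[neu$fnmes == "off"] == "happy")
  expect_lt(abs(dRate - (plogis(0.17) - 0.5)),
            3 * sqrt(2 * 0.25 / sum(neu$fnmes == "early")))
  expect_true(all(is.na(ch2$choice[ch2$fnmes == "stim_only"])))
})

test_that("AU generator plants the requested proportion-of-baseline lift", {
  d <- buildTrialDesign(1, seed = 12, orderConstraints = FALSE)
  d <- d[d$emotion != "none", ][1:240, ]
  au <- simulateAuTimeseries(d, gain = c(off = 0, early = 0.137, late = 0.156),
                             seed = 4)
  st <- au12Stats(au)
  m <- tapply(st$trialMeans$au12, st$trialMeans$fnmes, mean)
  nTr <- table(st$trialMeans$fnmes)
  # MC-SE of a per-condition mean of per-trial baseline-ratio estimates
  se <- sd(st$trialMeans$au12[st$trialMeans$fnmes == "early"]) /
    sqrt(nTr[["early"]])
  expect_lt(abs(m[["early"]] - 0.137), 2 * se + 0.005)
  expect_lt(abs(m[["off"]] - 0), 2 * se + 0.005)
})
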