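test_that("effect-size conversion reproduces the published (b, d) pairs", {
  expect_equal(round(cohensDFromLogit(5.50), 2), 3.03)
  # the published table prints d = 0.10 for b = 0.17; the formula applied
  # to the printed (rounded) coefficient gives 0.0937 -> 0.09
  expect_equal(round(cohensDFromLogit(0.17), 2), 0.09)
  expect_equal(round(cohensDFromLogit(0.133), 2), 0.07)
  expect_equal(round(cohensDFromLogit(0.14), 2), 0.08)
  expect_equal(round(cohensDFromLogit(-4.23), 2), -2.33)
  expect_equal(cohensDFromLogit(0), 0)
  # linear and sign-preserving
  b <- c(-2, -0.1, 0.3, 4)
  expect_equal(cohensDFromLogit(2 * b), 2 * cohensDFromLogit(b))
  expect_equal(sign(cohensDFromLogit(b)), sign(b))
})

test_that("RMS current density reproduces the published worked example", {
  res <- rmsCurrentDensity(22.60, 100, 70, c(16, 19))
  expect_equal(round(res$densityMaCm2, 2), 0.62)
  expect_true(res$pass)
  expect_equal(rmsCurrentDensity(0, 100, 70)$densityMaCm2, 0)
  expect_error(rmsCurrentDensity(10, 2e5, 70), "duty")
  # waveform-integration oracle: RMS of an explicitly sampled pulse train
  # over one 1/70 s period at 1 MHz resolution
  dt <- 1e-6
  period <- 1 / 70
  nSteps <- round(period / dt)
  wave <- numeric(nSteps)
  wave[1:100] <- 22.60          # 100 us on at 22.60 mA (one phase)
  rmsNum <- sqrt(mean(wave^2))
  expect_equal(res$rmsCurrentMa, rmsNum, tolerance = 1e-4)
})

test_that("choice model recovers generator coefficients (scaled-down sweep)", {
  # 3 simulations x 60 subjects: bias check at reduced scale
  bhat <- vapply(1:3, function(k) {
    d <- fnmesEEG:::neutralDesign(60, 96)
    p <- effectParams(choiceB = c(early = 0.17, late = 0.133,
                                  happy = 0, sad = 0), subjectSd = 1.36)
    ch <- simulateChoices(d, p, seed = 500 + k)
    fit <- fitChoiceModel(ch, "main", randomSlopes = FALSE)
    tt <- modelTerms(fit)
    tt$b[tt$term == "fnmesearly"]
  }, numeric(1))
  se <- sqrt(2 / (60 * 96 * 0.25)) / sqrt(3)   # approximate MC-SE of mean
  expect_lt(abs(mean(bhat) - 0.17), 4 * se + 0.02)
})

test_that("singular random-slope fits are simplified with a recorded path", {
  d <- fnmesEEG:::neutralDesign(6, 30)
  p <- effectParams(choiceB = c(early = 0, late = 0, happy = 0, sad = 0),
                    subjectSd = 0)   # no subject variance -> singular
  ch <- simulateChoices(d, p, seed = 9)
  fit <- fitChoiceModel(ch, "main", randomSlopes = TRUE)
  expect_s4_class(fit, "ModelFit")
  expect_true(nzchar(fit@simplified) || !isSingular(fit))
})

test_that("posthoc contrasts obey the Bonferroni definition", {
  d <- fnmesEEG:::neutralDesign(20, 40)
  p <- effectParams(choiceB = c(early = 0.8, late = 0.1, happy = 0, sad = 0),
                    subjectSd = 0.5)
  ch <- simulateChoices(d, p, seed = 21)
  fit <- fitChoiceModel(ch, "main", randomSlopes = FALSE)
  ctr <- posthocContrasts(fit, "fnmes")
  expect_equal(nrow(ctr), 3)           # 3 level pairs
  expect_equal(ctr$p_adj, pmin(1, 3 * ctr$p))
  # early - ref contrast equals the coefficient itself
  tt <- modelTerms(fit)
  expect_equal(ctr$estimate[ctr$contrast == "early - (ref)"],
               tt$b[tt$term == "fnmesearly"])
})

test_that("PSE follows the closed-form root of the linear predictor", {
  # deterministic construction: logit P = 1.0 + 2.0 x -> pse = -0.5
  mk <- function(a, b, n = 400, seed = 1) {
    set.seed(seed)
    x <- rep(c(-1, 0, 1), length.out = n)
    emo <- c("sad", "neutral", "happy")[match(x, c(-1, 0, 1))]
    pr <- plogis(a + b * x)
    data.frame(subject = 1, fnmes = "off", emotion = emo,
               choice = ifelse(rbinom(n, 1, pr) == 1, "happy", "sad"))
  }
  ps <- computePSE(mk(1, 2, n = 6000))
  expect_lt(abs(ps$pse - (-0.5)), 0.08)
  # intercept 0 -> pse ~ 0
  ps0 <- computePSE(mk(0, 2, n = 6000, seed = 2))
  expect_lt(abs(ps0$pse - 0), 0.08)
  # intercept shift by +delta moves pse by -delta/slope (exact in coefs)
  df <- mk(1, 2, n = 6000, seed = 3)
  g1 <- glm(I(choice == "happy") ~ I(c(sad = -1, neutral = 0,
                                       happy = 1)[emotion]),
            data = df, family = binomial())
  expect_equal(unname(-coef(g1)[1] / coef(g1)[2]),
               computePSE(df)$pse, tolerance = 1e-9)
  # degenerate cell: all one category -> flagged NA
  deg <- data.frame(subject = 2, fnmes = "off",
                    emotion = rep(c("sad", "neutral", "happy"), 10),
                    choice = "happy")
  psd <- computePSE(deg)
  expect_true(is.na(psd$pse))
  expect_true(psd$flagged)
})

test_that("power simulation saturates for large effects and is ~alpha at null", {
  pw <- powerSimulation(nGrid = 20, bEarly = 2.5, bLate = 0, subjectSd = 0.3,
                        nSims = 12, seed = 2, trialsPerCondition = 30)
  expect_gte(pw$power, 0.9)
  expect_true(pw$ci_low <= pw$power && pw$power <= pw$ci_high)
  pw0 <- powerSimulation(nGrid = 15, bEarly = 0, bLate = 0, subjectSd = 0.3,
                         nSims = 25, seed = 3, trialsPerCondition = 20)
  # null rejection rate within binomial noise of alpha
  expect_lte(pw0$power, 0.05 + 2 * sqrt(0.05 * 0.95 / 25) + 1 / 25)
})

test_that("AU12 statistics recover generator gains and the SS ratio", {
  d <- buildTrialDesign(2, seed = 30, orderConstraints = FALSE)
  d <- d[d$emotion != "none" & d$trial_index %% 3 == 0, ]
  au <- simulateAuTimeseries(d, gain = c(off = 0.002, early = 0.137,
                                         late = 0.156), seed = 6)
  st <- au12Stats(au)
  ctr <- st$contrasts
  est <- ctr$estimate[ctr$contrast == "early - off"]
  expect_lt(abs(est - (0.137 - 0.002)), 0.02)
  # eta_p2 equals the brute-force SS ratio from explicit model fits
  cell <- st$cellMeans
  fitFull <- lm(au12 ~ fnmes + emotion, data = cell)
  fitNoF <- lm(au12 ~ emotion, data = cell)
  ssF <- sum(residuals(fitNoF)^2) - sum(residuals(fitFull)^2)
  ssR <- sum(residuals(fitFull)^2)
  expect_equal(st$anova$eta_p2[st$anova$term == "fnmes"],
               ssF / (ssF + ssR), tolerance = 1e-12)
  expect_gt(st$anova$f[st$anova$term == "fnmes"], 10)

  # all gains equal -> fNMES condition contrasts ~ 0 (with only a few
  # subjects the null eta_p2 sits near df1/(df1+df2), so the contrast is
  # the cleaner zero check)
  au0 <- simulateAuTimeseries(d, gain = c(off = 0.1, early = 0.1,
                                          late = 0.1), seed = 7)
  st0 <- au12Stats(au0)
  expect_lt(max(abs(st0$contrasts$estimate)), 0.01)
})
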