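# Choice models, effect-size conversion, PSE, power simulation, AU12
# statistics and stimulation-safety arithmetic.

choice01 <- function(choice) as.integer(choice == "happy")

#' Cohen's d approximation for logistic coefficients
#'
#' Converts a log-odds coefficient to an approximate standardised effect
#' size by dividing by the standard deviation of the logistic distribution,
#' d = b / (pi / sqrt(3)). Linear and sign-preserving; the published
#' coefficient/effect-size pairs (5.50 -> 3.03, 0.17 -> 0.10,
#' 0.133 -> 0.07, 0.14 -> 0.08) are reproduced at two decimals.
#'
#' @param b log-odds coefficient(s).
#' @return numeric vector of d values.
#' @examples
#' round(cohensDFromLogit(5.50), 2)   # 3.03
#' @export
cohensDFromLogit <- function(b) {
  stopifnot(all(is.finite(b)))
  b / (pi / sqrt(3))
}

# Shared logistic mixed-model fitter with the documented simplification
# chain: requested random structure -> (1 | subject) -> fixed-effects glm.
fitLogisticMixed <- function(fixedStr, data, random = "(1 | subject)") {
  data$subject <- factor(data$subject)
  tryFit <- function(randomStr) {
    f <- as.formula(paste(fixedStr, "+", randomStr))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(f, data = data, family = binomial())))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    list(fit = fit, ok = conv && !lme4::isSingular(fit),
         conv = conv, singular = lme4::isSingular(fit))
  }
  path <- character(0)
  res <- tryCatch(tryFit(random), error = function(e) NULL)
  if ((is.null(res) || !res$ok) && random != "(1 | subject)") {
    path <- c(path, paste0(random, " -> (1 | subject)"))
    res2 <- tryCatch(tryFit("(1 | subject)"), error = function(e) NULL)
    if (!is.null(res2) && (is.null(res) || res2$ok || !is.null(res2$fit)))
      res <- res2
  }
  if (is.null(res)) {
    path <- c(path, "(1 | subject) -> fixed-effects glm")
    fit <- glm(as.formula(fixedStr), data = data, family = binomial())
    res <- list(fit = fit, ok = TRUE, conv = fit$converged,
                singular = FALSE)
  }
  buildModelFit(res$fit, data, converged = res$conv,
                singular = res$singular,
                simplified = paste(path, collapse = "; "))
}

buildModelFit <- function(fit, data, converged = TRUE, singular = FALSE,
                          simplified = "") {
  if (inherits(fit, "merMod")) {
    b <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    fstr <- deparse1(formula(fit))
  } else {
    b <- coef(fit)
    V <- vcov(fit)
    fstr <- deparse1(formula(fit))
  }
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  terms <- data.frame(term = names(b), b = unname(b), se = unname(se),
                      z = unname(z), p = unname(p),
                      ci_low = unname(b - qnorm(0.975) * se),
                      ci_high = unname(b + qnorm(0.975) * se),
                      d = unname(cohensDFromLogit(b)))
  if (any(abs(terms$b) > 15 | terms$se > 50))
    simplified <- paste(simplified, "[possible separation]")
  new("ModelFit", terms = terms, formula = fstr,
      nObs = nrow(data), nSubjects = length(unique(data$subject)),
      converged = isTRUE(converged), singular = isTRUE(singular),
      simplified = trimws(simplified), fit = fit)
}

#' Fit the categorisation choice models
#'
#' Logistic mixed models of the happy/sad choice, following the study's
#' model set. \code{"main"} restricts to neutral faces and fits
#' \code{choice ~ fnmes + (fnmes | subject)} (random slopes simplified to a
#' random intercept on singular fits); \code{"emotion"} fits
#' \code{choice ~ emotion * fnmes + (1 | subject)} on all face trials.
#' Reference levels are fnmes = off, emotion = neutral. Estimation is
#' Laplace-approximation \code{lme4::glmer}; on singular or failed fits the
#' random structure is simplified and the path is recorded in the result
#' (never silently).
#'
#' @param choices \code{data.frame} with columns \code{subject},
#'   \code{emotion}, \code{fnmes}, \code{choice} (stimulation-only rows are
#'   dropped), e.g. from \code{\link{simulateChoices}}.
#' @param model \code{"main"} or \code{"emotion"}.
#' @param randomSlopes attempt by-subject fNMES slopes for the main model.
#' @return a \code{\link{ModelFit}}; term rows carry b, SE, z, p, Wald CI
#'   and the d = b / (pi / sqrt(3)) conversion.
#' @export
fitChoiceModel <- function(choices, model = c("main", "emotion"),
                           randomSlopes = (model == "main")) {
  model <- match.arg(model)
  d <- choices[!is.na(choices$choice) & choices$emotion != "none", ,
               drop = FALSE]
  if (length(unique(d$subject)) < 2) stop("need >= 2 subjects")
  d$fnmes <- factor(d$fnmes, levels = c("off", "early", "late"))
  d$happy <- choice01(d$choice)
  if (model == "main") {
    d <- d[d$emotion == "neutral", , drop = FALSE]
    fitLogisticMixed("happy ~ fnmes", d,
                     random = if (isTRUE(randomSlopes))
                       "(fnmes | subject)" else "(1 | subject)")
  } else {
    d$emotion <- factor(d$emotion, levels = c("neutral", "happy", "sad"))
    fitLogisticMixed("happy ~ emotion * fnmes", d)
  }
}

#' Bonferroni-corrected pairwise contrasts of a factor
#'
#' Wald contrasts between all level pairs of one factor on the link scale,
#' evaluated at the reference levels of the other predictors, with
#' Bonferroni adjustment \code{p_adj = min(1, m * p)} over the m
#' comparisons.
#'
#' @param fit a \code{\link{ModelFit}}.
#' @param factor name of the factor (e.g. \code{"fnmes"}).
#' @param levels its levels, reference first; defaults to the levels found
#'   in the coefficient names plus the reference.
#' @return \code{data.frame} with columns \code{contrast}, \code{estimate},
#'   \code{se}, \code{z}, \code{p}, \code{p_adj}.
#' @export
posthocContrasts <- function(fit, factor, levels = NULL) {
  stopifnot(is(fit, "ModelFit"))
  tt <- fit@terms
  coefNames <- tt$term
  hit <- grepl(paste0("^", factor), coefNames) & !grepl(":", coefNames)
  if (is.null(levels))
    levels <- c("(ref)", sub(paste0("^", factor), "", coefNames[hit]))
  obj <- fit@fit
  V <- as.matrix(vcov(obj))
  b <- if (inherits(obj, "merMod")) lme4::fixef(obj) else coef(obj)
  colFor <- function(l) {
    v <- numeric(length(b))
    names(v) <- names(b)
    nm <- paste0(factor, l)
    if (nm %in% names(b)) v[nm] <- 1
    v
  }
  pairs <- utils::combn(levels, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    cvec <- colFor(l2) - colFor(l1)
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- if (se > 0) est / se else 0
    p <- if (se > 0) 2 * pnorm(-abs(z)) else 1
    data.frame(contrast = paste(l2, "-", l1), estimate = est, se = se,
               z = z, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p)
  out
}

#' Points of subjective equality per subject and condition
#'
#' Codes the emotion continuum as sad = -1, neutral = 0, happy = +1, fits a
#' per-cell logistic regression of choice on the continuum, and returns the
#' continuum value at which happy and sad choices are equally likely,
#' pse = -intercept / slope. Cells in which a subject gave only one
#' response category are not identifiable: their PSE is \code{NA} and the
#' subject is flagged (the study excluded three such participants).
#'
#' @param choices \code{data.frame} with \code{subject}, \code{emotion},
#'   \code{fnmes}, \code{choice}.
#' @return \code{data.frame} with columns \code{subject}, \code{fnmes},
#'   \code{pse}, \code{slope}, \code{flagged}.
#' @export
computePSE <- function(choices) {
  d <- choices[!is.na(choices$choice) & choices$emotion != "none", ,
               drop = FALSE]
  d$x <- c(sad = -1, neutral = 0, happy = 1)[d$emotion]
  d$happy <- choice01(d$choice)
  cells <- unique(d[, c("subject", "fnmes")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    di <- d[d$subject == cells$subject[i] & d$fnmes == cells$fnmes[i], ]
    if (length(unique(di$x)) < 2 || length(unique(di$happy)) < 2)
      return(data.frame(subject = cells$subject[i],
                        fnmes = cells$fnmes[i], pse = NA_real_,
                        slope = NA_real_, flagged = TRUE))
    g <- suppressWarnings(glm(happy ~ x, data = di, family = binomial()))
    a <- coef(g)[1]; s <- coef(g)[2]
    data.frame(subject = cells$subject[i], fnmes = cells$fnmes[i],
               pse = unname(if (s > 0) -a / s else NA_real_),
               slope = unname(s), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulation-based power for the early-stimulation choice effect
#'
#' For each sample size, repeatedly simulates neutral-trial choice data
#' under the assumed log-odds effects, fits the choice model and records
#' whether the early-stimulation coefficient is significant at
#' \code{alpha}; power is the proportion of significant replicates with an
#' exact binomial confidence interval. Mirrors the study's pre-registration
#' power analysis (which assumed b = 0.09 early and b = 0.18 late and found
#' 87\% power at N = 45 with 1000 simulations; the random-effect variances
#' behind that figure came from a prior study's fit and are not published,
#' so \code{subjectSd} is an explicit input here and no claim is made to
#' reproduce 87\%).
#'
#' @param nGrid integer vector of sample sizes.
#' @param bEarly,bLate assumed log-odds effects (defaults 0.09 / 0.18).
#' @param subjectSd SD of subject random intercepts, log-odds.
#' @param nSims simulations per sample size (>= 100 recommended for
#'   reporting; tests may use fewer).
#' @param alpha significance level of the Wald test on b_early.
#' @param seed integer master seed.
#' @param trialsPerCondition neutral trials per fNMES condition per subject.
#' @param randomSlopes use by-subject fNMES slopes in the fitted model
#'   (slower; default intercept-only).
#' @return \code{data.frame}: \code{n_subjects}, \code{b_assumed},
#'   \code{power}, \code{ci_low}, \code{ci_high}, \code{n_sims},
#'   \code{alpha}.
#' @export
powerSimulation <- function(nGrid, bEarly = 0.09, bLate = 0.18,
                            subjectSd = 1, nSims = 100, alpha = 0.05,
                            seed, trialsPerCondition = 96,
                            randomSlopes = FALSE) {
  rows <- lapply(nGrid, function(n) {
    sig <- logical(nSims)
    for (k in seq_len(nSims)) {
      d <- neutralDesign(n, trialsPerCondition)
      params <- effectParams(choiceB = c(early = bEarly, late = bLate,
                                         happy = 0, sad = 0),
                             subjectSd = subjectSd)
      ch <- simulateChoices(d, params,
                            seed = deriveSeed(seed, paste0("pw", n, "_", k)))
      fit <- fitChoiceModel(ch, model = "main",
                            randomSlopes = randomSlopes)
      tt <- modelTerms(fit)
      pe <- tt$p[tt$term == "fnmesearly"]
      sig[k] <- length(pe) == 1 && is.finite(pe) && pe < alpha
    }
    ci <- stats::binom.test(sum(sig), nSims)$conf.int
    data.frame(n_subjects = n, b_assumed = bEarly,
               power = mean(sig), ci_low = ci[1], ci_high = ci[2],
               n_sims = nSims, alpha = alpha)
  })
  do.call(rbind, rows)
}

# Neutral-faces-only design (choice-model simulations; order irrelevant).
neutralDesign <- function(nSubjects, trialsPerCondition) {
  one <- expand.grid(rep = seq_len(trialsPerCondition),
                     fnmes = c("off", "early", "late"),
                     stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nSubjects), function(s)
    data.frame(subject = s, trial_index = seq_len(nrow(one)),
               identity = 1L, emotion = "neutral", fnmes = one$fnmes,
               repetition = one$rep)))
}

#' AU12 smile-intensity statistics
#'
#' Summarises each trial's AU12 trace as the proportion-of-baseline change
#' during the stimulation window (window mean / baseline mean - 1, with the
#' first second of the clip as baseline), averages trials within subject x
#' fNMES x emotion, fits the linear model \code{au12 ~ fnmes + emotion},
#' and reports a type-3 ANOVA with partial eta squared
#' (SS_effect / (SS_effect + SS_residual)) plus the pairwise fNMES
#' contrasts.
#'
#' @param au long AU table from \code{\link{simulateAuTimeseries}} (or an
#'   OpenFace-style export with the same columns).
#' @param stimWindow stimulation window within the clip, seconds.
#' @param baselineWindow baseline window within the clip, seconds.
#' @return list with \code{trialMeans} (per-cell means),
#'   \code{anova} (term, df, ss, f, p, eta_p2), \code{contrasts}
#'   (fNMES pairwise differences with Bonferroni p), and \code{fit} (the
#'   underlying \code{lm}).
#' @export
au12Stats <- function(au, stimWindow = c(2, 2.5), baselineWindow = c(0, 1)) {
  au <- au[au$emotion != "none", , drop = FALSE]
  inWin <- function(t, w) t >= w[1] & t < w[2]
  key <- interaction(au$subject, au$trial_index, drop = TRUE)
  base <- tapply(au$AU12_r[inWin(au$timestamp, baselineWindow)],
                 key[inWin(au$timestamp, baselineWindow)], mean)
  stim <- tapply(au$AU12_r[inWin(au$timestamp, stimWindow)],
                 key[inWin(au$timestamp, stimWindow)], mean)
  if (any(abs(base) < 1e-12)) stop("zero baseline AU12")
  meta <- au[!duplicated(key), c("subject", "trial_index", "fnmes",
                                 "emotion")]
  meta <- meta[match(names(base), as.character(
    interaction(meta$subject, meta$trial_index, drop = TRUE))), ]
  trial <- data.frame(meta, au12 = as.numeric(stim / base - 1))
  cell <- aggregate(au12 ~ subject + fnmes + emotion, trial, mean)
  cell$fnmes <- factor(cell$fnmes, levels = c("off", "early", "late"))
  cell$emotion <- factor(cell$emotion,
                         levels = c("neutral", "happy", "sad"))
  fit <- stats::lm(au12 ~ fnmes + emotion, data = cell)
  full <- sum(residuals(fit)^2)
  dfRes <- fit$df.residual
  aovRow <- function(termDrop, label) {
    red <- stats::lm(as.formula(paste("au12 ~", termDrop)), data = cell)
    ss <- sum(residuals(red)^2) - full
    df <- red$df.residual - dfRes
    f <- (ss / df) / (full / dfRes)
    data.frame(term = label, df = df, ss = ss, f = f,
               p = pf(f, df, dfRes, lower.tail = FALSE),
               eta_p2 = ss / (ss + full))
  }
  anovaTab <- rbind(aovRow("emotion", "fnmes"), aovRow("fnmes", "emotion"))
  lvl <- levels(cell$fnmes)
  means <- tapply(cell$au12, cell$fnmes, mean)
  pairs <- utils::combn(lvl, 2)
  ctr <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- cell$au12[cell$fnmes == pairs[1, k]]
    g2 <- cell$au12[cell$fnmes == pairs[2, k]]
    tst <- stats::t.test(g2, g1)
    data.frame(contrast = paste(pairs[2, k], "-", pairs[1, k]),
               estimate = unname(means[pairs[2, k]] - means[pairs[1, k]]),
               p = tst$p.value)
  }))
  ctr$p_adj <- pmin(1, ncol(pairs) * ctr$p)
  list(trialMeans = trial, cellMeans = cell, anova = anovaTab,
       contrasts = ctr, fit = fit)
}

#' RMS current density of the stimulation pulse train
#'
#' Duty cycle = single-phase pulse width x pulse rate; RMS current =
#' peak current x sqrt(duty); current density = RMS current / electrode
#' area. With the study's parameters (22.60 mA, 100 us, 70 Hz, 16 x 19 mm
#' electrodes) this gives 0.62 RMS mA/cm2, well below the 2 RMS mA/cm2
#' safety threshold.
#'
#' @param currentMa peak current in mA.
#' @param pulseWidthUs single-phase pulse width in microseconds.
#' @param rateHz pulse rate in Hz.
#' @param electrodeMm electrode dimensions in mm (length-2).
#' @param thresholdMaCm2 safety threshold in RMS mA/cm2.
#' @return list: \code{duty}, \code{rmsCurrentMa}, \code{densityMaCm2},
#'   \code{pass} (density below threshold).
#' @examples
#' round(rmsCurrentDensity(22.60, 100, 70, c(16, 19))$densityMaCm2, 2)
#' @export
rmsCurrentDensity <- function(currentMa, pulseWidthUs, rateHz,
                              electrodeMm = c(16, 19),
                              thresholdMaCm2 = 2) {
  stopifnot(currentMa >= 0, pulseWidthUs > 0, rateHz > 0,
            all(electrodeMm > 0))
  duty <- pulseWidthUs * 1e-6 * rateHz
  if (duty >= 1) stop("duty cycle >= 1: pulse train is not a pulse train")
  rms <- currentMa * sqrt(duty)
  areaCm2 <- prod(electrodeMm) / 100
  density <- rms / areaCm2
  list(duty = duty, rmsCurrentMa = rms, densityMaCm2 = density,
       pass = density <= thresholdMaCm2)
}
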