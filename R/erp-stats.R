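# Double-subtraction difference waves, mass-univariate maps with FDR, and
# trial-level N170 extraction.

#' Per-subject emotion difference waves
#'
#' For each subject and each level of the stimulation factor, averages the
#' trials of two emotions and subtracts them (level1 minus level2 --
#' canonically happy minus sad). Any signal that is additive and identical
#' across emotions within a condition (notably the stimulation artifact)
#' cancels exactly; this is the first step of the double-subtraction
#' approach that avoids directly comparing stimulated with unstimulated
#' trials.
#'
#' @param epochs an \code{\link{EpochSet}} whose design has \code{emotion}
#'   and \code{fnmes} columns.
#' @param level1,level2 emotion levels; the result is mean(level1 trials) -
#'   mean(level2 trials).
#' @param by name of the condition column to stratify by.
#' @param conditions condition levels to compute (default: all levels with
#'   face trials).
#' @return named list (condition -> named list of subject -> channels x
#'   samples matrix).
#' @export
differenceWaves <- function(epochs, level1 = "happy", level2 = "sad",
                            by = "fnmes", conditions = NULL) {
  design <- epochs@design
  if (is.null(conditions)) {
    conditions <- unique(design[[by]][design$emotion %in% c(level1, level2)])
  }
  out <- lapply(conditions, function(cond) {
    subj <- lapply(names(epochs@data), function(s) {
      d <- design[as.character(design$subject) == s, , drop = FALSE]
      a <- epochs@data[[s]]
      i1 <- which(d$emotion == level1 & d[[by]] == cond)
      i2 <- which(d$emotion == level2 & d[[by]] == cond)
      if (!length(i1) || !length(i2))
        stop("subject ", s, ", condition ", cond,
             ": a cell has zero trials")
      trialMean(a, i1) - trialMean(a, i2)
    })
    names(subj) <- names(epochs@data)
    subj
  })
  names(out) <- conditions
  out
}

# Mean over trials -> channels x samples matrix.
trialMean <- function(a, idx) {
  m <- a[idx, , , drop = FALSE]
  array(colMeans(m, dims = 1), dim = dim(a)[2:3])
}

#' Second difference between stimulation conditions
#'
#' Subtracts the per-subject (happy - sad) difference maps of one condition
#' from another: \code{(level1 - level2)@cond1 - (level1 - level2)@cond2}.
#' The result expresses the effect of stimulation on the emotion difference
#' and is free of any emotion-independent additive contamination.
#'
#' @param diffMaps output of \code{\link{differenceWaves}}.
#' @param cond1,cond2 condition levels (canonically \code{"early"} or
#'   \code{"late"} vs \code{"off"}).
#' @return named list of subject -> channels x samples matrix.
#' @export
secondDifference <- function(diffMaps, cond1, cond2) {
  if (!cond1 %in% names(diffMaps) || !cond2 %in% names(diffMaps))
    stop("missing condition in difference maps")
  subj <- names(diffMaps[[cond1]])
  out <- lapply(subj, function(s) diffMaps[[cond1]][[s]] -
                  diffMaps[[cond2]][[s]])
  names(out) <- subj
  out
}

#' Mass-univariate statistic map with FDR correction
#'
#' One-sample t tests against zero at every map cell across subjects
#' (equivalent to a paired t test on the pre-subtracted condition maps),
#' with Benjamini-Hochberg false-discovery-rate correction applied jointly
#' over all cells. Zero-variance cells get p = 1 with a warning.
#'
#' @param maps named list of per-subject matrices (channels x times, all of
#'   one shape), e.g. from \code{\link{secondDifference}}.
#' @param alpha significance level applied to adjusted p values.
#' @param times optional numeric vector of column times (ms) stored in the
#'   result.
#' @return a \code{\link{StatMap}}.
#' @export
massUnivariate <- function(maps, alpha = 0.05, times = numeric(0)) {
  n <- length(maps)
  if (n < 3) stop("need >= 3 subjects")
  dims <- dim(maps[[1]])
  arr <- vapply(maps, identity, maps[[1]])      # dims x n
  dim(arr) <- c(prod(dims), n)
  mu <- rowMeans(arr)
  s2 <- rowSums((arr - mu)^2) / (n - 1)
  se <- sqrt(s2 / n)
  tval <- mu / se
  zeroVar <- s2 <= 0
  if (any(zeroVar)) {
    warning(sum(zeroVar), " zero-variance cell(s); p set to 1")
    tval[zeroVar] <- 0
  }
  p <- 2 * pt(abs(tval), df = n - 1, lower.tail = FALSE)
  p[zeroVar] <- 1
  padj <- p.adjust(p, method = "BH")
  shape <- function(v) {
    m <- matrix(v, dims[1], dims[2])
    dimnames(m) <- dimnames(maps[[1]])
    m
  }
  new("StatMap", t = shape(tval), p = shape(p), padj = shape(padj),
      mask = shape(padj <= alpha), df = n - 1, alpha = alpha,
      correction = "BH-FDR", times = times)
}

#' Trial-level N170 amplitude extraction
#'
#' Averages the voltage over the 18 occipito-temporal electrodes identified
#' by the mass-univariate analysis and the half-open 150-200 ms window,
#' yielding one amplitude per face trial. Stimulation-only trials (no face)
#' are skipped.
#'
#' @param epochs an \code{\link{EpochSet}} containing all requested
#'   channels.
#' @param channels electrode set (default the fixed published ROI,
#'   \code{\link{n170Electrodes}}).
#' @param window analysis window in ms, half-open.
#' @return \code{data.frame} with the design columns of each face trial
#'   plus \code{n170_uv}.
#' @export
extractN170 <- function(epochs, channels = n170Electrodes(),
                        window = c(150, 200)) {
  missing <- setdiff(channels, epochs@channels)
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  n <- length(timeAxis(epochs))
  idx <- windowIndices(epochs@t0, samplingRate(epochs), n, window)
  ic <- match(channels, epochs@channels)
  design <- epochs@design
  out <- design[design$emotion != "none", , drop = FALSE]
  out$n170_uv <- NA_real_
  for (s in names(epochs@data)) {
    a <- epochs@data[[s]]
    d <- design[as.character(design$subject) == s, , drop = FALSE]
    face <- which(d$emotion != "none")
    vals <- vapply(face, function(ti)
      mean(a[ti, ic, idx]), numeric(1))
    out$n170_uv[as.character(out$subject) == s] <- vals
  }
  rownames(out) <- NULL
  out
}

#' Choice model with N170 moderation
#'
#' Fits the logistic mixed model \code{choice ~ fnmes * n170 + (random |
#' subject)} testing whether trial-level N170 amplitude predicts the
#' happy/sad categorisation differently under stimulation. The full
#' published random structure \code{(fnmes * n170 | subject)} is attempted
#' when \code{randomSlopes = TRUE} and automatically simplified on singular
#' or non-converging fits (see \code{\link{fitChoiceModel}}).
#'
#' @param records \code{data.frame} from \code{\link{extractN170}} merged
#'   with choices: columns \code{subject}, \code{fnmes}, \code{choice},
#'   \code{n170_uv}.
#' @param conditions stimulation levels to include (reference first).
#' @param randomSlopes attempt the full random-slope structure first.
#' @return a \code{\link{ModelFit}}.
#' @export
choiceByN170Model <- function(records, conditions = c("off", "early"),
                              randomSlopes = FALSE) {
  d <- records[records$fnmes %in% conditions & !is.na(records$choice), ,
               drop = FALSE]
  if (length(unique(d$subject)) < 2) stop("need >= 2 subjects")
  if (length(unique(d$fnmes)) < 2) stop("need >= 2 fnmes levels")
  d$fnmes <- factor(d$fnmes, levels = conditions)
  d$happy <- choice01(d$choice)
  fitLogisticMixed("happy ~ fnmes * n170_uv", d,
                   random = if (randomSlopes) "(fnmes * n170_uv | subject)"
                            else "(1 | subject)")
}
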