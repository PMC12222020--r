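# Monte-Carlo cluster-based sign-flip permutation testing on subject-level
# time-frequency difference maps, mask integration, masked means, and the
# repeated-measures ANOVA on the masked coherence values.

#' Per-subject choice-by-condition coherence difference maps
#'
#' For each subject, computes \code{(happy - sad)@condition -
#' (happy - sad)@off} on the ROI coherence maps: the interaction of
#' categorisation choice with stimulation condition. Subjects missing any
#' of the four cells (e.g. because they labelled all neutral faces as one
#' category, as three participants in the study did) are excluded and
#' listed in the \code{excluded} attribute.
#'
#' @param maps list of \code{\link{TFCoherenceMap}} objects
#'   (\code{\link{roiCoherence}}).
#' @param cond stimulation condition contrasted against the reference.
#' @param ref reference condition (default \code{"off"}).
#' @param roiPair ROI pair to analyse (default \code{"central.left"}).
#' @param choices the two choice levels, minuend first.
#' @return named list of subject -> freq x time difference matrices, with
#'   attributes \code{freqs}, \code{times} and \code{excluded}.
#' @export
pairedDifferenceMaps <- function(maps, cond, ref = "off",
                                 roiPair = "central.left",
                                 choices = c("happy", "sad")) {
  maps <- Filter(function(m) m@roiPair == roiPair, maps)
  if (!length(maps)) stop("no maps for ROI pair ", roiPair)
  key <- function(m) paste(m@fnmes, m@choice, sep = ".")
  subjects <- unique(vapply(maps, function(m) m@subject, ""))
  need <- c(paste(cond, choices, sep = "."), paste(ref, choices, sep = "."))
  out <- list()
  excluded <- character(0)
  for (s in subjects) {
    ms <- Filter(function(m) m@subject == s, maps)
    got <- setNames(ms, vapply(ms, key, ""))
    if (!all(need %in% names(got))) {
      excluded <- c(excluded, s)
      next
    }
    out[[s]] <- (got[[need[1]]]@coh - got[[need[2]]]@coh) -
      (got[[need[3]]]@coh - got[[need[4]]]@coh)
  }
  if (!length(out)) stop("no subject has all four condition x choice cells")
  attr(out, "freqs") <- maps[[1]]@freqs
  attr(out, "times") <- maps[[1]]@times
  attr(out, "excluded") <- excluded
  out
}

# Dependent-samples t map across subjects; cells with any NA are NA.
subjectTMap <- function(arr) {
  # arr: cells x subjects
  n <- ncol(arr)
  mu <- rowMeans(arr)
  s2 <- rowSums((arr - mu)^2) / (n - 1)
  tv <- mu / sqrt(s2 / n)
  tv[s2 <= 0] <- 0
  tv
}

# Maximal 4-connected components among suprathreshold cells of one sign.
# cells: integer indices into an nr x nc grid; returns list of index sets.
connectedComponents <- function(cells, nr, nc) {
  if (!length(cells)) return(list())
  inSet <- logical(nr * nc)
  inSet[cells] <- TRUE
  seen <- logical(nr * nc)
  comps <- list()
  for (c0 in cells) {
    if (seen[c0]) next
    queue <- c0
    seen[c0] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      r <- (v - 1) %% nr + 1
      cc <- (v - 1) %/% nr + 1
      nb <- c(if (r > 1) v - 1, if (r < nr) v + 1,
              if (cc > 1) v - nr, if (cc < nc) v + nr)
      nb <- nb[inSet[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# Largest |cluster mass| among suprathreshold components of a t vector.
maxClusterMass <- function(tv, tcrit, nr, nc) {
  best <- 0
  for (sgn in c(1, -1)) {
    cells <- which(sgn * tv > tcrit)
    for (comp in connectedComponents(cells, nr, nc))
      best <- max(best, abs(sum(tv[comp])))
  }
  best
}

#' Monte-Carlo cluster-based sign-flip permutation test
#'
#' Tests subject-level difference maps against zero: (1) dependent-samples
#' t per cell; (2) two-tailed thresholding at the \code{clusterAlpha}
#' quantile of the t distribution; (3) 4-connected clustering of
#' suprathreshold cells, separately for positive and negative t; (4)
#' cluster mass = sum of member t values; (5) a null distribution of the
#' maximum absolute cluster mass from \code{nPerm} random whole-map
#' sign flips of subjects (exact under exchangeability of the pairing);
#' (6) Monte-Carlo p = (1 + #{null >= observed}) / (nPerm + 1), so p is
#' never exactly zero. Positive and negative clusters share one max-|mass|
#' null and are tested at \code{alpha}. Cells that are \code{NA} for any
#' subject are excluded from clustering.
#'
#' @param subjectMaps named list of per-subject freq x time matrices
#'   (\code{\link{pairedDifferenceMaps}}).
#' @param nPerm number of sign-flip permutations (the study used 2000).
#' @param clusterAlpha two-tailed cell-level threshold (0.01).
#' @param alpha cluster-level significance level (0.05).
#' @param seed permutation seed; results are deterministic given it.
#' @return a \code{\link{ClusterResult}}.
#' @export
clusterTest <- function(subjectMaps, nPerm = 2000, clusterAlpha = 0.01,
                        alpha = 0.05, seed) {
  n <- length(subjectMaps)
  if (n < 5) stop("need >= 5 subjects")
  if (nPerm < 100) warning("nPerm < 100 gives a very coarse p resolution")
  dims <- dim(subjectMaps[[1]])
  nr <- dims[1]; nc <- dims[2]
  arr <- vapply(subjectMaps, as.numeric, numeric(nr * nc))  # cells x subj
  ok <- rowSums(!is.finite(arr)) == 0
  arrOk <- arr[ok, , drop = FALSE]
  tcrit <- qt(1 - clusterAlpha / 2, df = n - 1)

  tvFull <- rep(NA_real_, nr * nc)
  tvFull[ok] <- subjectTMap(arrOk)
  tvZ <- ifelse(is.na(tvFull), 0, tvFull)   # NA cells can never exceed tcrit

  clusters <- list()
  for (sgn in c(1, -1)) {
    cells <- which(sgn * tvZ > tcrit)
    for (comp in connectedComponents(cells, nr, nc))
      clusters[[length(clusters) + 1L]] <-
        list(cells = cbind(f = (comp - 1) %% nr + 1,
                           t = (comp - 1) %/% nr + 1),
             idx = comp, mass = sum(tvZ[comp]))
  }

  # null distribution of max |mass| under whole-subject sign flips;
  # sign flips leave per-cell sums of squares unchanged, so only the mean
  # needs recomputing per permutation
  set.seed(deriveSeed(seed, "clusterPerm"))
  sumsq <- rowSums(arrOk^2)
  nullMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    mu <- as.numeric(arrOk %*% s) / n
    s2 <- (sumsq - n * mu^2) / (n - 1)
    tv <- mu / sqrt(s2 / n)
    tv[!is.finite(tv)] <- 0
    tvB <- numeric(nr * nc)
    tvB[ok] <- tv
    nullMax[b] <- maxClusterMass(tvB, tcrit, nr, nc)
  }
  for (k in seq_along(clusters)) {
    obs <- abs(clusters[[k]]$mass)
    clusters[[k]]$p <- (1 + sum(nullMax >= obs)) / (nPerm + 1)
    clusters[[k]]$idx <- NULL
  }
  # order by significance for display
  if (length(clusters))
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "p"))]
  tmap <- matrix(tvFull, nr, nc)
  fr <- attr(subjectMaps, "freqs"); tm <- attr(subjectMaps, "times")
  new("ClusterResult", clusters = clusters, tmap = tmap,
      freqs = if (is.null(fr)) seq_len(nr) else fr,
      times = if (is.null(tm)) seq_len(nc) else tm,
      params = list(nPerm = nPerm, clusterAlpha = clusterAlpha,
                    alpha = alpha, tails = 2),
      seed = seed)
}

#' Integrate significant clusters into one mask
#'
#' Unions the cells of all significant clusters across the given results
#' (e.g. the early-off and late-off contrasts) into a single logical
#' frequency x time mask, recording which contrast contributed which
#' cluster.
#'
#' @param results list of \code{\link{ClusterResult}} objects sharing one
#'   grid; may be named by contrast.
#' @param alpha significance level (default: each result's own alpha).
#' @return list with \code{mask} (logical freq x time matrix) and
#'   \code{provenance} (data.frame of contributing contrast / cluster /
#'   size / p).
#' @export
integrateMasks <- function(results, alpha = NULL) {
  stopifnot(length(results) >= 1)
  dims <- dim(results[[1]]@tmap)
  for (r in results)
    if (!identical(dim(r@tmap), dims)) stop("results must share one grid")
  mask <- matrix(FALSE, dims[1], dims[2])
  prov <- list()
  nms <- names(results)
  for (i in seq_along(results)) {
    r <- results[[i]]
    a <- if (is.null(alpha)) r@params$alpha else alpha
    sig <- significantClusters(r, a)
    for (k in seq_along(sig)) {
      cells <- sig[[k]]$cells
      mask[cells] <- TRUE
      prov[[length(prov) + 1L]] <- data.frame(
        contrast = if (!is.null(nms) && nzchar(nms[i])) nms[i] else
          paste0("result", i),
        cluster = k, size = nrow(cells), p = sig[[k]]$p)
    }
  }
  list(mask = mask,
       provenance = if (length(prov)) do.call(rbind, prov) else
         data.frame(contrast = character(0), cluster = integer(0),
                    size = integer(0), p = numeric(0)))
}

#' Mean map value over a significance mask
#'
#' @param map a \code{\link{TFCoherenceMap}} or numeric freq x time matrix.
#' @param mask logical matrix of the same shape (e.g. from
#'   \code{\link{integrateMasks}}).
#' @return scalar mean of the masked cells.
#' @export
extractMaskedMean <- function(map, mask) {
  m <- if (is(map, "TFCoherenceMap")) map@coh else map
  stopifnot(identical(dim(m), dim(mask)))
  if (!any(mask)) stop("empty mask")
  mean(m[mask], na.rm = TRUE)
}

#' Masked means for a set of coherence maps
#'
#' @param maps list of \code{\link{TFCoherenceMap}} objects.
#' @param mask logical matrix.
#' @return \code{data.frame}: \code{subject}, \code{fnmes}, \code{choice},
#'   \code{roiPair}, \code{coherence}.
#' @export
maskedMeansTable <- function(maps, mask) {
  do.call(rbind, lapply(maps, function(m)
    data.frame(subject = m@subject, fnmes = m@fnmes, choice = m@choice,
               roiPair = m@roiPair,
               coherence = extractMaskedMean(m, mask))))
}

#' Repeated-measures ANOVA on masked coherence means
#'
#' A condition (3: off, early, late) by choice (2: happy, sad) fully
#' within-subject ANOVA with Greenhouse-Geisser sphericity correction
#' (fractional corrected degrees of freedom, as in the published
#' F(1.92, 90.45)), partial eta squared per effect, and
#' Bonferroni-corrected paired-sample t post-hocs comparing the two
#' choices within each condition.
#'
#' @param maskedMeans \code{data.frame} with columns \code{subject},
#'   \code{fnmes}, \code{choice} and a value column.
#' @param value name of the value column.
#' @return list with \code{anova} (term, df, df_gg, F, p, p_gg, epsilon,
#'   eta_p2) and \code{posthoc} (per-condition paired t with adjusted p).
#' @export
maskedAnova <- function(maskedMeans, value = "coherence") {
  d <- maskedMeans
  d$y <- d[[value]]
  d$subject <- factor(d$subject)
  aLev <- intersect(c("off", "early", "late"), unique(d$fnmes))
  bLev <- intersect(c("happy", "sad"), unique(d$choice))
  d$A <- factor(d$fnmes, levels = aLev)
  d$B <- factor(d$choice, levels = bLev)
  tab <- tapply(d$y, list(d$subject, d$A, d$B), mean)
  if (anyNA(tab)) stop("missing subject x condition x choice cells")
  res <- rmAnovaGG(tab)
  # post-hoc: happy vs sad within each condition, Bonferroni over A levels
  ph <- do.call(rbind, lapply(seq_along(aLev), function(ai) {
    x <- tab[, ai, 1]; y <- tab[, ai, 2]
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(fnmes = aLev[ai],
               contrast = paste(bLev[1], "-", bLev[2]),
               estimate = mean(x - y), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  ph$p_adj <- pmin(1, length(aLev) * ph$p)
  list(anova = res, posthoc = ph)
}

# Two-way fully within-subject ANOVA with GG correction.
# tab: subjects x A x B cell means.
rmAnovaGG <- function(tab) {
  n <- dim(tab)[1]; A <- dim(tab)[2]; B <- dim(tab)[3]
  g <- mean(tab)
  mA <- apply(tab, 2, mean); mB <- apply(tab, 3, mean)
  mS <- apply(tab, 1, mean)
  mAB <- apply(tab, c(2, 3), mean)
  mSA <- apply(tab, c(1, 2), mean)
  mSB <- apply(tab, c(1, 3), mean)
  ssA <- n * B * sum((mA - g)^2)
  ssB <- n * A * sum((mB - g)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + g)^2)
  ssSA <- B * sum((sweep(sweep(mSA, 1, mS), 2, mA) + g)^2)
  ssSB <- A * sum((sweep(sweep(mSB, 1, mS), 2, mB) + g)^2)
  resid <- tab
  for (s in seq_len(n)) for (a in seq_len(A)) for (b in seq_len(B))
    resid[s, a, b] <- tab[s, a, b] - mSA[s, a] - mSB[s, b] - mAB[a, b] +
      mS[s] + mA[a] + mB[b] - g
  ssSAB <- sum(resid^2)

  orthContrasts <- function(k) {
    C <- stats::contr.helmert(k)
    qr.Q(qr(C))   # orthonormal columns
  }
  ggEps <- function(scores) {
    # scores: n x q contrast variables; eps = tr(S)^2 / (q * tr(S^2))
    S <- stats::cov(scores)
    q <- ncol(scores)
    sum(diag(S))^2 / (q * sum(S^2))
  }
  # contrast scores per effect
  CA <- orthContrasts(A); CB <- orthContrasts(B)
  matSA <- apply(tab, c(1, 2), mean)          # n x A (avg over B)
  matSB <- apply(tab, c(1, 3), mean)          # n x B
  cellMat <- matrix(aperm(tab, c(1, 2, 3)), n, A * B)
  epsA <- if (A > 2) ggEps(matSA %*% CA) else 1
  epsB <- if (B > 2) ggEps(matSB %*% CB) else 1
  CAB <- kronecker(CB, CA)                    # (A*B) x (A-1)(B-1)
  epsAB <- if ((A - 1) * (B - 1) > 1) ggEps(cellMat %*% CAB) else 1

  row <- function(term, ss, df, ssE, dfE, eps) {
    f <- (ss / df) / (ssE / dfE)
    data.frame(term = term, df1 = df, df2 = dfE,
               df1_gg = eps * df, df2_gg = eps * dfE,
               F = f, p = pf(f, df, dfE, lower.tail = FALSE),
               p_gg = pf(f, eps * df, eps * dfE, lower.tail = FALSE),
               epsilon = eps, eta_p2 = ss / (ss + ssE))
  }
  rbind(row("fnmes", ssA, A - 1, ssSA, (A - 1) * (n - 1), epsA),
        row("choice", ssB, B - 1, ssSB, (B - 1) * (n - 1), epsB),
        row("fnmes:choice", ssAB, (A - 1) * (B - 1), ssSAB,
            (A - 1) * (B - 1) * (n - 1), epsAB))
}
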