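mkSubjectMaps <- function(n, nr = 20, nc = 30, effect = 0,
                          rows = 5:10, cols = 10:20, seed = 1) {
  set.seed(seed)
  maps <- lapply(seq_len(n), function(s) {
    m <- matrix(rnorm(nr * nc), nr, nc)
    m[rows, cols] <- m[rows, cols] + effect
    m
  })
  names(maps) <- seq_len(n)
  maps
}

test_that("all-zero maps yield no clusters and constant maps no crash", {
  maps <- lapply(1:8, function(s) matrix(rnorm(100, sd = 1e-6), 10, 10))
  names(maps) <- 1:8
  cr <- clusterTest(maps, nPerm = 200, seed = 1)
  # pure noise at tiny scale: clusters possible but none with mass ~ 0 maps
  zero <- lapply(1:8, function(s) matrix(0, 10, 10))
  names(zero) <- 1:8
  cr0 <- clusterTest(zero, nPerm = 200, seed = 1)
  expect_equal(length(cr0@clusters), 0)
  expect_error(clusterTest(zero[1:4], nPerm = 200, seed = 1), ">= 5")
  expect_warning(clusterTest(zero, nPerm = 50, seed = 1), "coarse")
})

test_that("planted effect yields a significant overlapping cluster", {
  maps <- mkSubjectMaps(12, effect = 1.3, seed = 42)
  cr <- clusterTest(maps, nPerm = 500, seed = 7)
  sig <- significantClusters(cr)
  expect_gte(length(sig), 1)
  cells <- sig[[1]]$cells
  planted <- paste(rep(5:10, times = 11), rep(10:20, each = 6))
  got <- paste(cells[, 1], cells[, 2])
  # at least half the planted region is recovered
  expect_gte(mean(planted %in% got), 0.5)
  # p respects the plus-one rule
  expect_gte(min(clusterTable(cr)$p), 1 / 501)
})

test_that("cluster test is deterministic given the seed", {
  maps <- mkSubjectMaps(8, effect = 0.8, seed = 3)
  a <- clusterTest(maps, nPerm = 300, seed = 5)
  b <- clusterTest(maps, nPerm = 300, seed = 5)
  expect_equal(clusterTable(a), clusterTable(b))
  # and invariant to subject ordering
  c_ <- clusterTest(maps[sample(names(maps))], nPerm = 300, seed = 5)
  expect_equal(clusterTable(a)$mass, clusterTable(c_)$mass)
})

test_that("connected components are 4-connected and maximal", {
  # two diagonal cells must be separate clusters
  comps <- fnmesEEG:::connectedComponents(c(1, 5), nr = 3, nc = 3)
  expect_equal(length(comps), 2)
  # an L-shaped set is one component
  cellsL <- c(1, 2, 3, 6)   # column-major 3x3: (1,1),(2,1),(3,1),(3,2)
  comps2 <- fnmesEEG:::connectedComponents(cellsL, nr = 3, nc = 3)
  expect_equal(length(comps2), 1)
  expect_equal(sort(comps2[[1]]), cellsL)
})

test_that("paired difference maps form the choice-by-condition interaction", {
  mkMap <- function(s, fn, ch, val)
    new("TFCoherenceMap", coh = matrix(val, 2, 3), freqs = c(10, 20),
        times = c(0, 500, 1000), subject = s, fnmes = fn, choice = ch,
        roiPair = "central.left", nTrials = 20L)
  maps <- list(mkMap("1", "off", "happy", 0.40),
               mkMap("1", "off", "sad", 0.30),
               mkMap("1", "late", "happy", 0.25),
               mkMap("1", "late", "sad", 0.35),
               mkMap("2", "off", "happy", 0.5),
               mkMap("2", "off", "sad", 0.5),
               mkMap("2", "late", "happy", 0.5))  # subject 2 incomplete
  dm <- pairedDifferenceMaps(maps, cond = "late")
  expect_equal(names(dm), "1")
  expect_equal(attr(dm, "excluded"), "2")
  expect_equal(unique(as.numeric(dm[["1"]])), (0.25 - 0.35) - (0.40 - 0.30))
  # identical cells -> zero; swapping choices flips the sign
  dmSwap <- pairedDifferenceMaps(maps, cond = "late",
                                 choices = c("sad", "happy"))
  expect_equal(dm[["1"]], -dmSwap[["1"]])
})

test_that("mask integration equals the brute-force cell-wise union", {
  maps1 <- mkSubjectMaps(10, effect = 1.5, rows = 2:5, cols = 2:6, seed = 9)
  maps2 <- mkSubjectMaps(10, effect = -1.5, rows = 12:16, cols = 20:26,
                         seed = 10)
  r1 <- clusterTest(maps1, nPerm = 300, seed = 1)
  r2 <- clusterTest(maps2, nPerm = 300, seed = 2)
  im <- integrateMasks(list(earlyOff = r1, lateOff = r2))
  manual <- matrix(FALSE, 20, 30)
  for (r in list(r1, r2)) for (cl in significantClusters(r))
    manual[cl$cells] <- TRUE
  expect_equal(im$mask, manual)
  expect_true(all(c("earlyOff", "lateOff") %in% im$provenance$contrast))
  # no significant clusters -> empty mask
  null <- lapply(1:8, function(s) matrix(0, 4, 4))
  names(null) <- 1:8
  im0 <- integrateMasks(list(clusterTest(null, nPerm = 200, seed = 3)))
  expect_false(any(im0$mask))
})

test_that("masked means equal the enumeration oracle and ignore the rest", {
  set.seed(12)
  m <- matrix(runif(50), 5, 10)
  mask <- matrix(FALSE, 5, 10)
  mask[2:3, 4:6] <- TRUE
  expect_equal(extractMaskedMean(m, mask), mean(m[2:3, 4:6]))
  m2 <- m; m2[!mask] <- 99
  expect_equal(extractMaskedMean(m2, mask), extractMaskedMean(m, mask))
  expect_equal(extractMaskedMean(matrix(0.7, 5, 10), mask), 0.7)
  expect_error(extractMaskedMean(m, matrix(FALSE, 5, 10)), "empty mask")
})

test_that("repeated-measures ANOVA matches the anova.mlm oracle", {
  set.seed(7)
  n <- 12
  tab <- array(rnorm(n * 3 * 2), dim = c(n, 3, 2))
  tab[, 3, 1] <- tab[, 3, 1] + 0.8
  res <- fnmesEEG:::rmAnovaGG(tab)
  Y <- matrix(tab, n, 6)
  mlmfit <- lm(Y ~ 1)
  idata <- expand.grid(A = factor(1:3), B = factor(1:2))
  avA <- anova(mlmfit, X = ~B, M = ~A + B, idata = idata,
               test = "Spherical")
  avAB <- anova(mlmfit, X = ~A + B, M = ~A * B + 0, idata = idata,
                test = "Spherical")
  expect_equal(res$F[res$term == "fnmes"], avA$F[1], tolerance = 1e-8)
  expect_equal(res$p[res$term == "fnmes"], avA$`Pr(>F)`[1],
               tolerance = 1e-8)
  expect_equal(res$p_gg[res$term == "fnmes"], avA$`G-G Pr`[1],
               tolerance = 1e-8)
  expect_equal(res$F[res$term == "fnmes:choice"], avAB$F[1],
               tolerance = 1e-8)
  expect_equal(res$p_gg[res$term == "fnmes:choice"], avAB$`G-G Pr`[1],
               tolerance = 1e-8)
})

test_that("maskedAnova detects a planted choice-by-condition reversal", {
  set.seed(31)
  n <- 48
  rows <- list()
  for (s in seq_len(n)) {
    base <- rnorm(1, 0.33, 0.05)
    for (fn in c("off", "early", "late")) for (ch in c("happy", "sad")) {
      eff <- if (fn == "off" && ch == "happy") 0.012 else
        if (fn == "off") -0.012 else
          if (fn == "late" && ch == "happy") -0.007 else
            if (fn == "late") 0.007 else 0
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, fnmes = fn, choice = ch,
        coherence = base + eff + rnorm(1, 0, 0.02))
    }
  }
  mm <- do.call(rbind, rows)
  res <- maskedAnova(mm)
  av <- res$anova
  expect_lt(av$p_gg[av$term == "fnmes:choice"], 0.05)
  expect_gt(av$eta_p2[av$term == "fnmes:choice"],
            av$eta_p2[av$term == "choice"])
  # identical cell means -> F ~ 0
  mm0 <- mm
  mm0$coherence <- ave(mm$coherence, mm$subject)
  res0 <- maskedAnova(mm0)
  expect_lt(max(res0$anova$F[is.finite(res0$anova$F)], 0), 1e-10)
  # posthoc Bonferroni: p_adj = min(1, 3 * p)
  expect_equal(res$posthoc$p_adj, pmin(1, 3 * res$posthoc$p))
})
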