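# hand-checkable toys ---------------------------------------------------------

test_that("single-marker regression matches closed-form OLS on a toy", {
  # dosages (0,0,1,1,2), y = (0,1,1,2,2): hand OLS
  g <- c(0, 0, 1, 1, 2)
  y <- c(0, 1, 1, 2, 2)
  d <- rbind(as.integer(g), c(0L, 1L, 0L, 0L, 0L))
  pan <- toyPanel(d)
  res <- singleMarkerScan(pan, y)
  # closed form: slope = Sxy/Sxx, t = r sqrt(n-2)/sqrt(1-r^2)
  r <- cor(g, y)
  tExp <- r * sqrt(3) / sqrt(1 - r^2)
  pExp <- 2 * pt(-abs(tExp), df = 3)
  expect_equal(res@perVariantP[1], pExp, tolerance = 1e-10)
  expect_equal(res@statistic, abs(tExp), tolerance = 1e-10)
  expect_equal(res@extra$bonferroniThreshold, 0.05 / 2)
})

test_that("monomorphic variants get p = 1 with a warning", {
  d <- rbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  pan <- suppressWarnings(toyPanel(d))
  expect_warning(res <- singleMarkerScan(pan, c(0.1, 0.4, -0.2, 0.9)),
                 "monomorphic")
  expect_equal(res@perVariantP[1], 1)
})

test_that("huge single-variant shifts are detected below Bonferroni", {
  set.seed(1)
  n <- 500
  d <- rbind(c(rep(1L, 20), rep(0L, n - 20)),
             as.integer(rbinom(n, 2, 0.2)))
  pan <- toyPanel(d)
  y <- rnorm(n)
  y[1:20] <- rnorm(20, -10, 0.2)
  res <- singleMarkerScan(pan, y, causal = 1L)
  expect_lt(res@perVariantP[1], 0.05 / 2)
  expect_equal(res@extra$causalDetection, 1)
})

test_that("burden scores are hand-computable weighted allele sums", {
  d <- rbind(c(0L, 1L, 2L), c(1L, 0L, 1L), c(0L, 0L, 1L))
  pan <- toyPanel(d)  # n = 3, all variants rare at threshold 0.5
  w <- c(1, 2, 0.5)
  s <- burdenScore(pan, threshold = 0.5, weights = w)
  expect_equal(s, c(0*1 + 1*2 + 0*0.5, 1*1 + 0 + 0, 2*1 + 1*2 + 1*0.5))
  # individual with zero rare alleles scores 0
  expect_equal(s[1] - 2, 0)
  expect_error(burdenScore(pan, threshold = 1e-6), "untestable")
})

test_that("T5 equals T1 when no variant has MAF in (1%, 5%]", {
  # singletons (MAF 0.25%) plus one clearly common variant (20%)
  n <- 200
  d <- rbind(c(1L, rep(0L, n - 1L)),
             c(0L, 1L, rep(0L, n - 2L)),
             as.integer(rep(c(1L, 0L, 0L, 0L, 0L), n / 5)))
  pan <- toyPanel(d)
  expect_equal(burdenScore(pan, 0.01), burdenScore(pan, 0.05))
  y <- rnorm(n)
  t1 <- collapseTest(pan, y, 0.01, B = 100, seed = 1, adaptive = FALSE)
  t5 <- collapseTest(pan, y, 0.05, B = 100, seed = 1, adaptive = FALSE)
  expect_identical(t1@pValue, t5@pValue)
})

test_that("weighted-sum weights follow the inverse-frequency formula", {
  # m = 1 minor allele among n = 1000 individuals
  d <- rbind(c(1L, rep(0L, 999L)), rep(c(0L, 1L), 500L))
  pan <- toyPanel(d)
  q <- 2 / 2002
  wExp <- 1 / sqrt(1000 * q * (1 - q))
  expect_equal(weWeights(pan)[1], wExp, tolerance = 1e-12)
  expect_equal(wExp, 1.0015, tolerance = 1e-3)
  # equal allele counts -> equal weights
  d2 <- rbind(c(1L, 1L, rep(0L, 98L)), c(0L, 0L, 1L, 1L, rep(0L, 96L)))
  w2 <- weWeights(toyPanel(d2))
  expect_equal(w2[1], w2[2])
  # q(1-q) is increasing on (0, 0.5]: commonest variant has smallest weight
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 500, seed = 3)
  w <- weWeights(p)
  expect_equal(unname(which.min(w)), unname(which.max(mafs(p))))
})

test_that("control-based weights use only control individuals", {
  d <- rbind(c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L))
  pan <- toyPanel(d)
  lab <- factor(c("case", "case", "control", "control"),
                levels = c("case", "control", "excluded"))
  w <- weWeights(pan, labels = lab)
  # variant 1 has 0 minor alleles among the 2 controls: q = 1/6
  q <- 1 / 6
  expect_equal(w[1], 1 / sqrt(2 * q * (1 - q)), tolerance = 1e-12)
})

# permutation machinery --------------------------------------------------------

test_that("permutation p-values are exact against exhaustive enumeration", {
  y <- c(0.5, -1.2, 0.3, 2.1, -0.4, 1.1)
  statFn <- function(v) abs(sum(v[c(1, 3)]) - sum(v[c(2, 4)]))
  res <- permutationP(statFn, y, exhaustive = TRUE)
  # oracle: brute-force enumeration of all 6! orderings
  perms <- RareVarPower:::.allPermsOf(1:6)
  stats <- apply(perms, 1, function(ix) statFn(y[ix]))
  expect_equal(res$p, mean(stats >= res$observed - 1e-12))
  expect_equal(res$B, 720L)
})

test_that("permutation p hits its boundary values", {
  # every permuted statistic at least matches the observed one -> p = 1
  y <- c(1, 2, 3, 4, 5, 6)
  pLow <- permutationP(function(v) -abs(v[1] - 3.5), y, B = 999, seed = 1,
                       adaptive = FALSE)
  expect_equal(pLow$p, 1)
  # identity uniquely maximizes sum(v * rank weights) for distinct sorted y
  # (rearrangement inequality): no permuted draw can match it -> p = 1/1000
  yy <- seq_len(20) / 2
  pHigh <- permutationP(function(v) sum(v * seq_len(20)), yy, B = 999,
                        seed = 2, adaptive = FALSE)
  expect_equal(pHigh$p, 1 / 1000)
  expect_error(permutationP(function(v) NaN, y, B = 10), "finite")
})

test_that("same seed gives bit-identical permutation p-values", {
  p <- smallGene3Panel()
  y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 7)
  r1 <- collapseTest(p, y, 0.01, B = 300, seed = 5, adaptive = FALSE)
  r2 <- collapseTest(p, y, 0.01, B = 300, seed = 5, adaptive = FALSE)
  expect_identical(r1@pValue, r2@pValue)
  s1 <- skatTest(p, y, B = 200, seed = 9, adaptive = FALSE)
  s2 <- skatTest(p, y, B = 200, seed = 9, adaptive = FALSE)
  expect_identical(s1@pValue, s2@pValue)
})

test_that("collapse test p matches exhaustive enumeration on 6 individuals", {
  d <- rbind(c(1L, 0L, 0L, 1L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L))
  pan <- toyPanel(d)
  y <- c(1.8, 0.4, -0.2, 2.2, 0.1, -0.5)
  res <- collapseTest(pan, y, threshold = 0.5, exhaustive = TRUE)
  # oracle: enumerate relabelings, statistic |centered score . y|
  s <- colSums(d)
  sc <- s - mean(s)
  perms <- RareVarPower:::.allPermsOf(1:6)
  stats <- apply(perms, 1, function(ix) abs(sum(sc * y[ix])))
  obs <- abs(sum(sc * y))
  expect_equal(res@pValue, mean(stats >= obs - 1e-9))
})

test_that("WE with unit weights reproduces T1 at the same seed", {
  p <- smallGene3Panel()
  y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 3)
  t1 <- collapseTest(p, y, 0.01, B = 300, seed = 4, adaptive = FALSE)
  weUnit <- collapseTest(p, y, 0.01, weights = rep(1, nrow(p)),
                         B = 300, seed = 4, adaptive = FALSE)
  expect_identical(t1@pValue, weUnit@pValue)
  expect_equal(t1@statistic, weUnit@statistic)
})

test_that("VT reduces to the single-threshold test and dominates fixed
           thresholds", {
  # one distinct MAF only
  d <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  pan <- toyPanel(d)
  y <- c(2.5, 0.1, 1.9, 0.2, -0.3, 0.4, -0.1, 0)
  v <- vtTest(pan, y, exhaustive = TRUE)
  s <- colSums(d)
  sc <- (s - mean(s))
  zSingle <- abs(sum(sc / sqrt(sum(sc^2)) * y))
  expect_equal(v@statistic, zSingle, tolerance = 1e-12)
  # VT statistic >= |z| at the 1% threshold on a real panel
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 4)
  yy <- phenotypes(simulateContinuous(p, selectCausal(p, scenarioSpec(1), 2),
                                      11))
  s1 <- burdenScore(p, 0.01)
  sc1 <- s1 - mean(s1)
  z1 <- abs(sum(sc1 / sqrt(sum(sc1^2)) * yy))
  vv <- vtTest(p, yy, B = 50, seed = 1)
  expect_gte(vv@statistic, z1 - 1e-12)
})

test_that("VT permutation p matches brute force with re-maximization", {
  d <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),      # singleton
             c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),      # doubleton
             c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L))      # commoner
  pan <- toyPanel(d)
  y <- c(2.1, 1.5, 1.2, -0.4, 0.3, -0.8, 0.2, -0.6)
  v <- vtTest(pan, y, exhaustive = TRUE)
  # oracle: brute force per-permutation maximization over the 3 thresholds
  mafv <- mafs(pan)
  thr <- sort(unique(mafv))
  S <- t(vapply(thr, function(t0) colSums(d[mafv <= t0, , drop = FALSE]),
                numeric(8)))
  Sc <- S - rowMeans(S)
  Z <- Sc / sqrt(rowSums(Sc^2))
  vtStat <- function(v0) max(abs(as.vector(Z %*% v0)))
  perms <- RareVarPower:::.allPermsOf(1:8)
  stats <- apply(perms, 1, function(ix) vtStat(y[ix]))
  expect_equal(v@statistic, vtStat(y), tolerance = 1e-12)
  expect_equal(v@pValue, mean(stats >= vtStat(y) - 1e-9))
})

test_that("SKAT Q equals the brute-force quadratic form", {
  # random instances, unit weights via Beta(1,1)
  for (s in 1:5) {
    set.seed(s)
    d <- matrix(rbinom(200, 2, runif(1, 0.05, 0.3)), 10, 20)
    d[1, ] <- c(1L, rep(0L, 19L))  # keep at least one polymorphic rare row
    pan <- toyPanel(d)
    y <- rnorm(20)
    res <- skatTest(pan, y, weightsBeta = c(1, 1), B = 10, seed = 1)
    G <- RareVarPower:::.minorDosages(pan)
    expect_equal(res@statistic,
                 sum((G %*% (y - mean(y)))^2), tolerance = 1e-8)
  }
  # weighted case: W = Beta(1,25) density of the MAFs
  p <- smallGene3Panel()
  y <- rnorm(ncol(p))
  res <- skatTest(p, y, B = 10, seed = 1)
  G <- RareVarPower:::.minorDosages(p)
  w <- dbeta(pmin(pmax(mafs(p), 1e-12), 1), 1, 25)
  Q <- sum((w * as.vector(G %*% (y - mean(y))))^2)
  expect_equal(res@statistic, Q, tolerance = 1e-6)
  # Q >= 0 and Q = 0 for a constant-fitted phenotype is impossible to test
  # directly (zero variance errors), so check near-zero residuals
  expect_gte(res@statistic, 0)
  expect_error(skatTest(p, rep(1, ncol(p)), B = 10), "zero-variance")
})

test_that("SKAT analytic moment-matched p tracks the permutation p", {
  p <- smallGene3Panel(n = 600, seed = 5)
  pvals <- vapply(1:30, function(s) {
    y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), s)
    r <- skatTest(p, y, B = 400, seed = s, adaptive = FALSE)
    c(r@pValue, r@extra$analyticP)
  }, numeric(2))
  # same rejection pattern at alpha = 0.2 in most null replicates
  agree <- mean((pvals[1, ] <= 0.2) == (pvals[2, ] <= 0.2))
  expect_gte(agree, 0.8)
  expect_lt(abs(mean(pvals[1, ]) - mean(pvals[2, ])), 0.12)
})

test_that("WOD statistic is invariant under phenotype negation and flags
           bidirectional outlier carriers that T1 misses", {
  p <- smallGene3Panel(n = 500, seed = 3)
  set.seed(8)
  yv <- rnorm(500)
  w1 <- wodTest(p, yv, B = 100, seed = 2, adaptive = FALSE)
  w2 <- wodTest(p, -yv, B = 100, seed = 2, adaptive = FALSE)
  expect_equal(w1@statistic, w2@statistic, tolerance = 1e-8)
  expect_identical(w1@pValue, w2@pValue)

  # 50-individual toy: carriers pushed into both tails
  set.seed(10)
  n <- 50
  d <- rbind(as.integer(seq_len(n) <= 10), c(rep(0L, 40), rep(1L, 10)))
  pan <- toyPanel(d)
  y <- rnorm(n)
  y[1:5] <- rnorm(5, -1.64, 0.2)
  y[6:10] <- rnorm(5, 1.64, 0.2)
  wod <- wodTest(pan, y, threshold = 0.25, B = 500, seed = 3,
                 adaptive = FALSE)
  t1 <- collapseTest(pan, y, threshold = 0.25, B = 500, seed = 3,
                     adaptive = FALSE)
  expect_lt(wod@pValue, 0.05)
  expect_gt(t1@pValue, 0.2)   # burden cancels out across directions

  # all carriers at the non-carrier median: no outliers, p not small
  y2 <- rnorm(n)
  med <- median(y2[11:50])
  y2[1:10] <- med + rnorm(10, 0, 0.01)
  wod2 <- wodTest(pan, y2, threshold = 0.25, B = 300, seed = 4,
                  adaptive = FALSE)
  expect_gt(wod2@pValue, 0.2)
})

test_that("WOD rejects dichotomous traits and degenerate carrier sets", {
  p <- smallGene3Panel()
  y <- dichotomizeExtremes(simulateContinuous(
    p, selectCausal(p, scenarioSpec(1), 1), 2), 100, 100)
  expect_error(wodTest(p, y), "continuous")
  dAll <- rbind(rep(1L, 6), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_error(wodTest(suppressWarnings(toyPanel(dAll)),
                       rnorm(6), threshold = 0.6), "all individuals")
})

test_that("statistics are invariant to variant order and to monomorphic
           padding", {
  p <- smallGene3Panel()
  y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 13)
  d <- dosages(p)
  set.seed(3)
  perm <- sample(nrow(d))
  pShuf <- GenotypePanel(d[perm, ], geneId(p))
  for (fn in list(
    function(pp) collapseTest(pp, y, 0.01, B = 100, seed = 1,
                              adaptive = FALSE)@pValue,
    function(pp) vtTest(pp, y, B = 100, seed = 1, adaptive = FALSE)@pValue,
    function(pp) skatTest(pp, y, B = 100, seed = 1, adaptive = FALSE)@pValue))
    expect_identical(fn(p), fn(pShuf))
  # a monomorphic extra column leaves burden and VT untouched
  dPad <- rbind(d, 0L)
  pPad <- suppressWarnings(GenotypePanel(dPad, geneId(p)))
  expect_equal(collapseTest(pPad, y, 0.01, B = 100, seed = 1,
                            adaptive = FALSE)@pValue,
               collapseTest(p, y, 0.01, B = 100, seed = 1,
                            adaptive = FALSE)@pValue)
})

test_that("null p-values are uniform for every method", {
  p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 1998, seed = 21)
  a0 <- selectCausal(p, scenarioSpec(1), 1)
  R <- 400
  pv <- matrix(NA_real_, R, 7,
               dimnames = list(NULL, c("T1", "T5", "WE", "VT",
                                       "WOD1", "WOD5", "SKAT")))
  for (r in seq_len(R)) {
    y <- simulateContinuous(p, a0, seed = deriveSeed(77, "null", r))
    res <- runAssocMethods(p, y, B = 200, seed = deriveSeed(78, "perm", r),
                           adaptive = FALSE)
    pv[r, ] <- vapply(res, function(x) x@pValue, 1)
  }
  for (m in colnames(pv)) {
    # KS distance to U(0,1); crit ~ 1.95/sqrt(R) at alpha 0.001, plus the
    # 1/(2B) discreteness of permutation p-values
    D <- suppressWarnings(stats::ks.test(pv[, m], "punif")$statistic)
    expect_lt(unname(D), 1.95 / sqrt(R) + 1 / 400)
    rej <- mean(pv[, m] <= 0.05)
    expect_lt(abs(rej - 0.05), 2.807 * sqrt(0.05 * 0.95 / R))  # 99.5% CI
  }
})
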