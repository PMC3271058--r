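## Gene-level association tests, all calibrated by phenotype permutation.
##
## The permutation engine exploits two reductions: (i) for burden-type
## statistics the OLS t (continuous) and the case/control mean-score
## difference (dichotomous) are monotone in |centered-score . y| under
## phenotype permutation (the total sum of squares of y is permutation
## invariant), so permuted statistics are inner products; (ii) all methods
## of one replicate share the same permutation stream, which is both cheaper
## and makes cross-method power comparisons use identical permutations.

.allPermsOf <- function(v) {
  if (length(v) == 1L) return(matrix(v))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], .allPermsOf(v[-i]))))
}

# core permutation loop; batchFn(idx) maps an n x b matrix of permutation
# indices to b permuted statistics, compared against obs on the engine scale
.permEngine <- function(obs, batchFn, n, B, seed, adaptive = TRUE,
                        alpha = 0.05, exhaustive = FALSE,
                        batchSize = 100L) {
  tol <- 1e-9 * (1 + abs(obs))
  if (exhaustive) {
    if (n > 9L) stop("exhaustive enumeration is limited to n <= 9")
    idx <- t(.allPermsOf(seq_len(n)))
    stats <- batchFn(idx)
    return(list(p = mean(stats >= obs - tol), B = ncol(idx),
                exhaustive = TRUE))
  }
  withSeed(seed, {
    done <- 0L
    b <- 0L
    repeat {
      nb <- min(batchSize, B - done)
      idx <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))
      b <- b + sum(batchFn(idx) >= obs - tol)
      done <- done + nb
      if (done >= B) break
      if (adaptive) {
        p <- (b + 1) / (done + 1)
        se <- sqrt(p * (1 - p) / (done + 1))
        if (p - 2.576 * se > alpha || p + 2.576 * se < alpha) break
      }
    }
    list(p = (b + 1) / (done + 1), B = done, exhaustive = FALSE)
  })
}

#' Permutation p-value of an arbitrary statistic
#'
#' Permutes the phenotype values over individuals and returns
#' p = (b + 1) / (B + 1), where b counts permuted statistics at least as
#' large as the observed one. In adaptive mode permutation stops early once
#' the rejection decision at alpha = 0.05 is settled at 99\% confidence.
#' With \code{exhaustive = TRUE} all n! orderings are enumerated (n <= 9)
#' and p is the exact fraction of orderings, the identity included, whose
#' statistic is at least the observed one.
#'
#' @param statFn function mapping a phenotype vector to a single finite
#'   statistic (larger = more extreme).
#' @param pheno a \code{\linkS4class{PhenotypeSet}} or numeric vector. When
#'   case/control labels are present, the labels of the non-excluded
#'   individuals are permuted (their case indicator is the permuted value).
#' @param B maximum number of permutations (>= 1).
#' @param seed integer seed; the stream is bit-reproducible.
#' @param adaptive early stopping flag.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with \code{p}, \code{observed}, and \code{B} (permutations
#'   actually used).
#' @examples
#' y <- c(0.1, 0.3, 2.5, 2.8, 0.2, 0.4)
#' permutationP(function(v) sum(v[3:4]), y, B = 200, seed = 1)$p
#' @export
permutationP <- function(statFn, pheno, B = 1000L, seed = 1L,
                         adaptive = TRUE, exhaustive = FALSE) {
  if (B < 1L) stop("B must be >= 1")
  y <- if (is(pheno, "PhenotypeSet")) {
    lab <- caseLabels(pheno)
    if (length(lab)) as.numeric(lab[lab != "excluded"] == "case")
    else phenotypes(pheno)
  } else as.numeric(pheno)
  obs <- statFn(y)
  if (!is.finite(obs)) stop("observed statistic is not finite")
  res <- .permEngine(obs,
                     function(idx) apply(idx, 2, function(i) statFn(y[i])),
                     length(y), B, seed, adaptive = adaptive,
                     exhaustive = exhaustive)
  list(p = res$p, observed = obs, B = res$B)
}

# --- shared context ---------------------------------------------------------

# resolves phenotype/labels, the analysis dosage matrix and the MAF vector
# used for thresholds and weights (full sample for continuous traits,
# controls for dichotomous, following the weighted-sum convention of
# estimating allele frequencies among unaffected individuals)
.assocContext <- function(panel, pheno) {
  stopifnot(is(panel, "GenotypePanel"))
  y <- if (is(pheno, "PhenotypeSet")) pheno else
    new("PhenotypeSet", y = as.numeric(pheno))
  lab <- caseLabels(y)
  G <- .minorDosages(panel)
  if (anyNA(G)) stop("panel must be imputed before testing")
  if (length(lab)) {
    include <- which(lab != "excluded")
    ctrl <- which(lab == "control")
    mafv <- .foldedMafs(G[, ctrl, drop = FALSE])
    list(G = G[, include, drop = FALSE],
         y = as.numeric(lab[include] == "case"),
         maf = mafv, dichotomous = TRUE,
         nMafSample = length(ctrl))
  } else {
    if (length(phenotypes(y)) != ncol(G))
      stop("phenotype length does not match panel individuals")
    list(G = G, y = phenotypes(y), maf = .foldedMafs(G),
         dichotomous = FALSE, nMafSample = ncol(G))
  }
}

# --- per-method preparations ------------------------------------------------
# each returns: statistic (reported), obs (engine scale), batchFn, extra;
# or fixed = p for degenerate cases that bypass permutation

.prepBurden <- function(ctx, threshold, weights = NULL) {
  sel <- which(!is.na(ctx$maf) & ctx$maf <= threshold + 1e-12)
  if (!length(sel))
    stop("no variant at or below MAF threshold ", threshold,
         ": gene untestable")
  w <- if (is.null(weights)) rep(1, length(sel)) else {
    stopifnot(length(weights) %in% c(length(ctx$maf), length(sel)))
    if (length(weights) == length(ctx$maf)) weights[sel] else weights
  }
  if (any(w <= 0)) stop("weights must be positive")
  score <- as.vector(crossprod(ctx$G[sel, , drop = FALSE], w))
  sc <- score - mean(score)
  n <- length(score)
  if (all(abs(sc) < 1e-12))
    return(list(fixed = 1, statistic = 0, extra = list()))
  obs <- abs(sum(sc * ctx$y))
  stat <- if (ctx$dichotomous) {
    mean(score[ctx$y == 1]) - mean(score[ctx$y == 0])
  } else {
    r <- cor(score, ctx$y)
    r * sqrt(n - 2) / sqrt(max(1 - r^2, 1e-12))
  }
  list(obs = obs, statistic = stat,
       batchFn = function(idx)
         abs(as.vector(crossprod(sc, matrix(ctx$y[idx], nrow(idx))))),
       extra = list(threshold = threshold, nVariantsUsed = length(sel)))
}

.prepVT <- function(ctx) {
  ok <- which(!is.na(ctx$maf))
  if (!length(ok)) stop("no variant with a defined MAF")
  ordv <- ok[order(ctx$maf[ok])]
  sortedM <- ctx$maf[ordv]
  Gm <- ctx$G[ordv, , drop = FALSE]
  cum <- apply(Gm, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  keep <- which(diff(c(sortedM, Inf)) > 1e-12)
  S <- cum[keep, , drop = FALSE]
  Sc <- S - rowMeans(S)
  norms <- sqrt(rowSums(Sc^2))
  use <- norms > 1e-12
  if (!any(use))
    return(list(fixed = 1, statistic = 0, extra = list()))
  Z <- Sc[use, , drop = FALSE] / norms[use]
  zObs <- as.vector(Z %*% ctx$y)
  stat <- max(abs(zObs))
  list(obs = stat, statistic = stat,
       batchFn = function(idx) {
         A <- abs(Z %*% matrix(ctx$y[idx], nrow(idx)))
         apply(A, 2, max)
       },
       extra = list(threshold = sortedM[keep][use][which.max(abs(zObs))],
                    nThresholds = sum(use)))
}

# kernel-smoothed two-sided tail scores of the phenotypes; the reference
# CDF is estimated once from all phenotypes so that permuting carrier
# labels against fixed per-individual scores is an exact exchangeable test
.wodTailScores <- function(y) {
  n <- length(y)
  dens <- density(y, n = 512L)
  dx <- dens$x[2L] - dens$x[1L]
  Fg <- (cumsum(dens$y) - dens$y / 2) * dx
  tot <- sum(dens$y) * dx
  Fi <- approx(dens$x, Fg, xout = y, rule = 2)$y / tot
  lo <- 1 / (2 * n)                    # clip at the ECDF resolution
  Fi <- pmin(pmax(Fi, lo), 1 - lo)
  -log(2 * pmin(Fi, 1 - Fi))
}

.prepWOD <- function(ctx, threshold) {
  if (ctx$dichotomous)
    stop("WOD is defined for continuous traits only")
  sel <- which(!is.na(ctx$maf) & ctx$maf <= threshold + 1e-12)
  if (!length(sel))
    stop("no variant at or below MAF threshold ", threshold,
         ": gene untestable")
  carriers <- which(colSums(ctx$G[sel, , drop = FALSE] > 0) > 0)
  if (length(carriers) == length(ctx$y))
    stop("all individuals carry a rare allele: WOD reference undefined")
  if (!length(carriers))
    return(list(fixed = 1, statistic = 0,
                extra = list(threshold = threshold, nCarriers = 0L)))
  s <- .wodTailScores(ctx$y)
  obs <- sum(s[carriers])
  list(obs = obs, statistic = obs,
       batchFn = function(idx) {
         S <- matrix(s[idx], nrow(idx))
         colSums(S[carriers, , drop = FALSE])
       },
       extra = list(threshold = threshold, nCarriers = length(carriers)))
}

.prepSKAT <- function(ctx, weightsBeta = c(1, 25)) {
  y <- ctx$y
  if (sd(y) < 1e-12) stop("zero-variance phenotype")
  w <- dbeta(pmin(pmax(ctx$maf, 1e-12), 1), weightsBeta[1], weightsBeta[2])
  w[is.na(ctx$maf)] <- 0
  mu <- mean(y)                        # intercept-only fit, both trait types
  yc <- y - mu
  Gw <- w * ctx$G
  r <- as.vector(Gw %*% yc)
  Q <- sum(r^2)
  # moment-matched (Satterthwaite) chi-square reference, reported alongside
  sigma2 <- mean(yc^2)
  Mc <- Gw - rowMeans(Gw)
  K2 <- Mc %*% t(Mc)
  trA <- sigma2 * sum(diag(K2))
  trA2 <- sigma2^2 * sum(K2^2)
  pAnalytic <- if (trA > 0 && trA2 > 0) {
    kap <- 2 * trA2 / (2 * trA)
    nu <- 2 * trA^2 / (2 * trA2)
    pchisq(Q / kap, df = nu, lower.tail = FALSE)
  } else 1
  list(obs = Q, statistic = Q,
       batchFn = function(idx) {
         Yc <- matrix(y[idx], nrow(idx)) - mu
         colSums((Gw %*% Yc)^2)
       },
       extra = list(analyticP = pAnalytic, weightsBeta = weightsBeta))
}

.finishTest <- function(method, prep, engineArgs) {
  if (!is.null(prep$fixed)) {
    return(new("RareTestResult", method = method,
               statistic = prep$statistic, pValue = prep$fixed,
               nPermutations = 0L, extra = prep$extra))
  }
  res <- do.call(.permEngine,
                 c(list(obs = prep$obs, batchFn = prep$batchFn), engineArgs))
  new("RareTestResult", method = method, statistic = prep$statistic,
      pValue = res$p, nPermutations = as.integer(res$B), extra = prep$extra)
}

setMethod("show", "RareTestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (B = %d)\n", object@method,
              object@statistic, object@pValue, object@nPermutations))
})

# --- exported tests ---------------------------------------------------------

#' Per-individual burden score
#'
#' Weighted sum of minor-allele dosages over variants at or below a MAF
#' threshold: score_i = sum_j w_j d_ij. Unit weights give the plain
#' collapsing score (T1 at 1\%, T5 at 5\%); the weighted-sum test passes
#' inverse-frequency weights from \code{\link{weWeights}}.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param threshold MAF threshold for inclusion.
#' @param weights optional positive per-variant weights (full-length or one
#'   per selected variant); unit weights when NULL.
#' @return numeric vector, one score per individual.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 300, 1)
#' head(burdenScore(p, 0.01))
#' @export
burdenScore <- function(panel, threshold = 0.01, weights = NULL) {
  mafv <- mafs(panel)
  sel <- which(!is.na(mafv) & mafv <= threshold + 1e-12)
  if (!length(sel))
    stop("no variant at or below MAF threshold ", threshold,
         ": gene untestable")
  w <- if (is.null(weights)) rep(1, length(sel)) else {
    stopifnot(length(weights) %in% c(length(mafv), length(sel)))
    if (length(weights) == length(mafv)) weights[sel] else weights
  }
  if (any(w <= 0)) stop("weights must be positive")
  G <- .minorDosages(panel)
  as.vector(crossprod(G[sel, , drop = FALSE], w))
}

#' Inverse-frequency (weighted-sum) variant weights
#'
#' The weighted-sum weights: with m_j the minor-allele count and n_j the
#' number of individuals used (controls when case/control labels are given,
#' the full sample for continuous traits), q_j = (m_j + 1) / (2 n_j + 2)
#' and w_j = sqrt(n_j q_j (1 - q_j)); the returned weight is 1 / w_j, so
#' rarer variants weigh more. Weights are computed from genotypes only,
#' never from the phenotype values.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param labels optional factor of case/control(/excluded) labels.
#' @return numeric vector of positive per-variant weights.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 300, 1)
#' head(weWeights(p))
#' @export
weWeights <- function(panel, labels = NULL) {
  G <- .minorDosages(panel)
  if (!is.null(labels) && length(labels)) {
    ctrl <- which(as.character(labels) == "control")
    if (!length(ctrl)) stop("no control individuals to estimate weights")
    G <- G[, ctrl, drop = FALSE]
  }
  n <- ncol(G)
  if (n == 0L) stop("no individuals to estimate weights")
  mj <- rowSums(G)
  q <- (mj + 1) / (2 * n + 2)
  unname(1 / sqrt(n * q * (1 - q)))
}

#' Collapsing / weighted-sum burden test (T1, T5, WE)
#'
#' Associates the per-individual burden score with the phenotype: for a
#' continuous trait the statistic is the OLS slope t of phenotype on score;
#' for an extreme-sampled dichotomous trait it is the case-minus-control
#' mean score difference. Significance comes from phenotype (or label)
#' permutation, p = (b + 1)/(B + 1).
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param pheno a \code{\linkS4class{PhenotypeSet}} or numeric vector.
#' @param threshold MAF threshold (0.01 for T1, 0.05 for T5; 0.5 with
#'   weights for WE).
#' @param weights optional positive weights (see \code{\link{weWeights}}).
#' @param method label stored in the result.
#' @param B,seed,adaptive,exhaustive permutation controls (see
#'   \code{\link{permutationP}}).
#' @return a \code{\linkS4class{RareTestResult}}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' collapseTest(p, y, threshold = 0.01, B = 99, seed = 3)
#' @export
collapseTest <- function(panel, pheno, threshold = 0.01, weights = NULL,
                         method = NULL, B = 1000L, seed = 1L,
                         adaptive = TRUE, exhaustive = FALSE) {
  ctx <- .assocContext(panel, pheno)
  if (is.null(method))
    method <- if (!is.null(weights)) "WE" else
      sprintf("T%g", round(threshold * 100))
  prep <- .prepBurden(ctx, threshold, weights)
  .finishTest(method, prep,
              list(n = length(ctx$y), B = B, seed = seed,
                   adaptive = adaptive, exhaustive = exhaustive))
}

#' Variable-threshold burden test (VT)
#'
#' Computes the standardized burden-phenotype association z(t) at every
#' candidate threshold t (the distinct observed MAFs) and takes the maximum
#' of |z(t)|. The permutation re-maximizes over thresholds for every
#' permuted phenotype, so the p-value accounts for the threshold search.
#'
#' @inheritParams collapseTest
#' @return a \code{\linkS4class{RareTestResult}}; \code{extra$threshold}
#'   is the maximizing MAF threshold.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' vtTest(p, y, B = 99, seed = 3)
#' @export
vtTest <- function(panel, pheno, B = 1000L, seed = 1L, adaptive = TRUE,
                   exhaustive = FALSE) {
  ctx <- .assocContext(panel, pheno)
  prep <- .prepVT(ctx)
  .finishTest("VT", prep,
              list(n = length(ctx$y), B = B, seed = seed,
                   adaptive = adaptive, exhaustive = exhaustive))
}

#' Weighted outlier detection test (WOD1 / WOD5)
#'
#' A distribution-based test for continuous traits, sensitive to carriers
#' lying in either phenotype tail. Each individual gets a two-sided tail
#' score s_i = -log(2 min(F(y_i), 1 - F(y_i))), with F a Gaussian-kernel
#' smoothed CDF of the phenotypes, clipped at the empirical resolution; the
#' statistic sums the scores of the individuals carrying at least one
#' allele at or below the MAF threshold, and significance comes from
#' permuting the carrier labels. The statistic is invariant under negating
#' the phenotypes (two-sided by construction). This is a reconstruction of
#' the outlier-detection approach: it is designed to have power when causal
#' variants push carriers into either tail (large bidirectional effects)
#' and little power under small unidirectional shifts.
#'
#' @inheritParams collapseTest
#' @param threshold MAF threshold: 0.01 for WOD1, 0.05 for WOD5.
#' @return a \code{\linkS4class{RareTestResult}}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' wodTest(p, y, threshold = 0.01, B = 99, seed = 3)
#' @export
wodTest <- function(panel, pheno, threshold = 0.01, B = 1000L, seed = 1L,
                    adaptive = TRUE, exhaustive = FALSE) {
  ctx <- .assocContext(panel, pheno)
  prep <- .prepWOD(ctx, threshold)
  .finishTest(sprintf("WOD%g", round(threshold * 100)), prep,
              list(n = length(ctx$y), B = B, seed = seed,
                   adaptive = adaptive, exhaustive = exhaustive))
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score statistic Q = (y - mu)' G' W^2 G (y - mu), with
#' mu the intercept-only fit (the phenotype mean for continuous traits, the
#' case fraction for dichotomous ones), G the full dosage matrix (rare and
#' common variants) and W the diagonal of Beta(MAF; a1, a2) density
#' weights. The primary p-value is by phenotype permutation, for
#' comparability with the other methods; a moment-matched chi-square
#' p-value (Satterthwaite) is reported in \code{extra$analyticP} for
#' validation.
#'
#' @inheritParams collapseTest
#' @param weightsBeta Beta density parameters (a1, a2); default c(1, 25).
#' @return a \code{\linkS4class{RareTestResult}}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' skatTest(p, y, B = 99, seed = 3)
#' @export
skatTest <- function(panel, pheno, weightsBeta = c(1, 25), B = 1000L,
                     seed = 1L, adaptive = TRUE, exhaustive = FALSE) {
  ctx <- .assocContext(panel, pheno)
  prep <- .prepSKAT(ctx, weightsBeta)
  .finishTest("SKAT", prep,
              list(n = length(ctx$y), B = B, seed = seed,
                   adaptive = adaptive, exhaustive = exhaustive))
}

#' Per-variant single-marker scan
#'
#' Simple linear regression of the continuous phenotype on each variant's
#' dosage; per-variant two-sided t-test p-values with a gene-level
#' Bonferroni threshold of alpha / m. Monomorphic variants get p = 1 with a
#' warning. When a causal assignment is supplied, the proportion of causal
#' variants reaching Bonferroni-corrected significance is reported in
#' \code{extra$causalDetection}.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param pheno a continuous \code{\linkS4class{PhenotypeSet}} or numeric
#'   vector.
#' @param causal optional \code{\linkS4class{CausalAssignment}} or integer
#'   indices of causal variants.
#' @param alpha gene-level significance level before Bonferroni division.
#' @return a \code{\linkS4class{RareTestResult}} with method "SM":
#'   \code{statistic} is the largest |t|, \code{pValue} the smallest
#'   Bonferroni-adjusted per-variant p, \code{perVariantP} the raw
#'   per-variant p-values.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' singleMarkerScan(p, y)
#' @export
singleMarkerScan <- function(panel, pheno, causal = NULL, alpha = 0.05) {
  ctx <- .assocContext(panel, pheno)
  if (ctx$dichotomous)
    stop("singleMarkerScan expects a continuous phenotype")
  G <- ctx$G
  y <- ctx$y
  n <- length(y)
  m <- nrow(G)
  sds <- apply(G, 1, sd)
  mono <- sds < 1e-12
  if (any(mono))
    warning(sum(mono), " monomorphic variant(s): p set to 1")
  tv <- rep(0, m)
  pv <- rep(1, m)
  ok <- which(!mono)
  if (length(ok)) {
    r <- as.vector(cor(t(G[ok, , drop = FALSE]), y))
    r <- pmin(pmax(r, -1), 1)
    tv[ok] <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-12))
    pv[ok] <- 2 * pt(-abs(tv[ok]), df = n - 2)
  }
  thr <- alpha / m
  cidx <- if (is(causal, "CausalAssignment")) causalIndex(causal) else
    as.integer(causal)
  detection <- if (length(cidx)) mean(pv[cidx] <= thr) else NA_real_
  new("RareTestResult", method = "SM", statistic = max(abs(tv)),
      pValue = min(1, min(pv) * m), nPermutations = 0L, perVariantP = pv,
      extra = list(bonferroniThreshold = thr, nSignificant = sum(pv <= thr),
                   causalDetection = detection))
}

#' Run several gene-level tests on one phenotype replicate
#'
#' Prepares every requested method once and pushes the same permutation
#' stream through all of them (batching, with per-method adaptive early
#' stopping), so method comparisons use identical permutations and the
#' dosage matrix is traversed once per batch.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param pheno a \code{\linkS4class{PhenotypeSet}}; label presence selects
#'   the dichotomous analysis path (MAFs and weights then come from
#'   controls).
#' @param methods subset of c("T1","T5","WE","VT","WOD1","WOD5","SKAT").
#' @param B permutation cap.
#' @param seed integer seed.
#' @param adaptive early stopping flag.
#' @param alpha level used by the adaptive rule.
#' @param onError "stop" to propagate method errors, "keep" to return the
#'   condition object in that method's slot of the result list.
#' @return named list of \code{\linkS4class{RareTestResult}} (or, under
#'   \code{onError = "keep"}, condition objects for failing methods).
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 300, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 2)
#' res <- runAssocMethods(p, y, methods = c("T1", "SKAT"), B = 99, seed = 3)
#' vapply(res, function(r) r@pValue, 1)
#' @export
runAssocMethods <- function(panel, pheno,
                            methods = c("T1", "T5", "WE", "VT",
                                        "WOD1", "WOD5", "SKAT"),
                            B = 1000L, seed = 1L, adaptive = TRUE,
                            alpha = 0.05, onError = c("stop", "keep")) {
  onError <- match.arg(onError)
  ctx <- .assocContext(panel, pheno)
  prepOne <- function(m) {
    switch(m,
      T1 = .prepBurden(ctx, 0.01),
      T5 = .prepBurden(ctx, 0.05),
      WE = .prepBurden(ctx, 0.5, weights = .weWeightsFromG(ctx)),
      VT = .prepVT(ctx),
      WOD1 = .prepWOD(ctx, 0.01),
      WOD5 = .prepWOD(ctx, 0.05),
      SKAT = .prepSKAT(ctx),
      stop("unknown method: ", m))
  }
  preps <- setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    preps[[m]] <- if (onError == "stop") prepOne(m) else
      tryCatch(prepOne(m), error = function(e) e)
  }
  n <- length(ctx$y)
  out <- setNames(vector("list", length(methods)), methods)
  active <- character(0)
  counts <- dones <- setNames(integer(length(methods)), methods)
  for (m in methods) {
    p <- preps[[m]]
    if (inherits(p, "condition")) out[[m]] <- p
    else if (!is.null(p$fixed))
      out[[m]] <- new("RareTestResult", method = m, statistic = p$statistic,
                      pValue = p$fixed, nPermutations = 0L, extra = p$extra)
    else active <- c(active, m)
  }
  if (length(active)) {
    withSeed(seed, {
      done <- 0L
      while (done < B && length(active)) {
        nb <- min(100L, B - done)
        idx <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))
        done <- done + nb
        for (m in active) {
          p <- preps[[m]]
          tol <- 1e-9 * (1 + abs(p$obs))
          counts[m] <- counts[m] + sum(p$batchFn(idx) >= p$obs - tol)
          dones[m] <- done
        }
        if (adaptive && done < B) {
          settled <- vapply(active, function(m) {
            pv <- (counts[m] + 1) / (done + 1)
            se <- sqrt(pv * (1 - pv) / (done + 1))
            pv - 2.576 * se > alpha || pv + 2.576 * se < alpha
          }, TRUE)
          for (m in active[settled]) {
            out[[m]] <- new("RareTestResult", method = m,
                            statistic = preps[[m]]$statistic,
                            pValue = (counts[m] + 1) / (dones[m] + 1),
                            nPermutations = as.integer(dones[m]),
                            extra = preps[[m]]$extra)
          }
          active <- active[!settled]
        }
      }
      for (m in active) {
        out[[m]] <- new("RareTestResult", method = m,
                        statistic = preps[[m]]$statistic,
                        pValue = (counts[m] + 1) / (dones[m] + 1),
                        nPermutations = as.integer(dones[m]),
                        extra = preps[[m]]$extra)
      }
    })
  }
  out
}

# weighted-sum weights from a prepared context (controls already selected
# for dichotomous traits)
.weWeightsFromG <- function(ctx) {
  G <- if (ctx$dichotomous) ctx$G[, ctx$y == 0, drop = FALSE] else ctx$G
  n <- ncol(G)
  mj <- rowSums(G)
  q <- (mj + 1) / (2 * n + 2)
  unname(1 / sqrt(n * q * (1 - q)))
}
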