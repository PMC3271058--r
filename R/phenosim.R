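#' Control-scenario specifications
#'
#' Returns the specification of one of the six control scenarios:
#' \enumerate{
#'   \item null model, no causal variants;
#'   \item every rare variant (MAF < 1\%) causal, deleterious (-1.64 SD) --
#'     positive control for collapsing tests;
#'   \item 4 rare (-1.64) plus 4 common (-0.07) causal variants;
#'   \item 15\% of rare variants causal, half deleterious (-1.64), half
#'     protective (+1.64);
#'   \item causal variants sampled with probability proportional to 1/MAF
#'     from all variants, count = 10\% of the rare variants, effects
#'     proportional to 1/MAF with largest effect -2.5;
#'   \item as 5 but uniform sampling, count = 10\% of all variants.
#' }
#'
#' @param id scenario number 1..6.
#' @return a \code{\linkS4class{ScenarioSpec}}.
#' @examples
#' scenarioSpec(4)
#' @export
scenarioSpec <- function(id) {
  id <- as.integer(id)
  stopifnot(length(id) == 1L, id %in% 1:6)
  switch(id,
    new("ScenarioSpec", scenarioId = "1", causalMafRule = "none"),
    new("ScenarioSpec", scenarioId = "2", causalMafRule = "rare_only",
        causalFraction = 1, meanEffectSd = 1.64),
    new("ScenarioSpec", scenarioId = "3", causalMafRule = "rare_only",
        fixedRare = 4L, fixedCommon = 4L, meanEffectSd = 1.64),
    new("ScenarioSpec", scenarioId = "4", causalMafRule = "rare_only",
        causalFraction = 0.15, directionMix = 0.5, meanEffectSd = 1.64),
    new("ScenarioSpec", scenarioId = "5", causalMafRule = "unrestricted",
        causalFraction = 0.10, effectModel = "inverse_maf",
        samplingRule = "inverse_maf_probability"),
    new("ScenarioSpec", scenarioId = "6", causalMafRule = "unrestricted",
        causalFraction = 0.10, effectModel = "inverse_maf")
  )
}

#' Grid-cell scenario specification
#'
#' One cell of the systematic simulation grid: a fraction of the rare
#' variants is causal, carriers shift by a fixed mean effect; optionally a
#' mixture of deleterious and protective directions.
#'
#' @param effectSd carrier mean-shift magnitude in SD units.
#' @param causalFraction fraction of rare variants made causal.
#' @param directionMix fraction of causal variants that are deleterious
#'   (1 = all deleterious, 0.5 = half/half).
#' @return a \code{\linkS4class{ScenarioSpec}} with id "grid".
#' @examples
#' gridScenario(1.5, 0.20)
#' @export
gridScenario <- function(effectSd, causalFraction, directionMix = 1) {
  new("ScenarioSpec", scenarioId = "grid", causalMafRule = "rare_only",
      causalFraction = causalFraction, directionMix = directionMix,
      meanEffectSd = effectSd)
}

# round-half-up causal counts (deterministic)
.roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' @describeIn causalIndex causal indices of an assignment
#' @export
setMethod("causalIndex", "CausalAssignment", function(x) x@causalIndex)

#' @describeIn effectMeans effects of an assignment
#' @export
setMethod("effectMeans", "CausalAssignment", function(x) x@effectMean)

setMethod("show", "CausalAssignment", function(object) {
  cat("CausalAssignment:", length(object@causalIndex), "causal variants (",
      sum(object@isRare), "rare )\n")
  if (length(object@causalIndex))
    cat(" effects:", paste(format(object@effectMean, digits = 3),
                           collapse = " "), "\n")
})

#' Select causal variants for one replicate
#'
#' Applies the scenario's sampling rule to the panel: nothing for the null
#' scenario, all rare variants for scenario 2, fixed rare/common counts for
#' scenario 3, a deterministic round-half-up fraction of the rare pool for
#' scenario 4 and the grid, and 1/MAF-weighted or uniform sampling from all
#' variants for scenarios 5 and 6 (counts anchored to the rare or total
#' variant pool as each scenario prescribes). Effects are left unassigned;
#' see \code{\link{assignEffects}}.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param spec a \code{\linkS4class{ScenarioSpec}}.
#' @param seed integer seed for this replicate's selection substream.
#' @return a \code{\linkS4class{CausalAssignment}} (effects NA).
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 500, 1)
#' length(causalIndex(selectCausal(p, scenarioSpec(3), 1)))  # 8
#' @export
selectCausal <- function(panel, spec, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"), is(spec, "ScenarioSpec"))
  if (any(is.na(dosages(panel))))
    stop("panel must be imputed before causal selection")
  m <- mafs(panel)
  rare <- isRare(panel)
  pick <- withSeed(seed, {
    switch(spec@scenarioId,
      "1" = integer(0),
      "2" = which(rare),
      "3" = {
        if (sum(rare) < spec@fixedRare || sum(!rare) < spec@fixedCommon)
          stop("not enough eligible variants for fixed rare/common counts")
        c(sample(which(rare), spec@fixedRare),
          sample(which(!rare), spec@fixedCommon))
      },
      "4" = ,
      "grid" = {
        pool <- which(rare)
        k <- .roundHalfUp(spec@causalFraction * length(pool))
        if (k > length(pool))
          stop("requested causal count exceeds eligible variants")
        sample(pool, k)
      },
      "5" = {
        k <- .roundHalfUp(spec@causalFraction * sum(rare))
        if (k > length(m))
          stop("requested causal count exceeds eligible variants")
        sample(seq_along(m), k, prob = 1 / pmax(m, 1e-12))
      },
      "6" = {
        k <- .roundHalfUp(spec@causalFraction * length(m))
        if (k > length(m))
          stop("requested causal count exceeds eligible variants")
        sample(seq_along(m), k)
      },
      stop("unknown scenario id")
    )
  })
  pick <- sort(as.integer(pick))
  new("CausalAssignment", causalIndex = pick,
      effectMean = rep(NA_real_, length(pick)),
      isRare = rare[pick])
}

#' Assign per-variant effect means
#'
#' Under the fixed-mean model every rare causal variant receives a shift of
#' magnitude \code{spec@meanEffectSd}; the sign split follows
#' \code{spec@directionMix} (deleterious = negative; with an odd causal
#' count the extra variant goes to the deleterious side). Common causal
#' variants receive the GWAS-scale shift -0.07. Under the inverse-MAF model
#' the effect of causal variant j is -2.5 * w_min / w_j, where
#' w_j = sqrt(n * q_j * (1 - q_j)) and q_j = (m_j + 1) / (2n + 2) with m_j
#' the minor-allele count, so the rarest causal variant attains exactly
#' -2.5.
#'
#' @param assignment a \code{\linkS4class{CausalAssignment}} from
#'   \code{\link{selectCausal}}.
#' @param spec the \code{\linkS4class{ScenarioSpec}}.
#' @param panel the panel the assignment refers to.
#' @return the assignment with \code{effectMean} filled in.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 500, 1)
#' a <- assignEffects(selectCausal(p, scenarioSpec(2), 1), scenarioSpec(2), p)
#' unique(effectMeans(a))  # -1.64
#' @export
assignEffects <- function(assignment, spec, panel) {
  stopifnot(is(assignment, "CausalAssignment"), is(spec, "ScenarioSpec"))
  k <- length(assignment@causalIndex)
  if (k == 0L) {
    if (spec@scenarioId != "1")
      stop("causal set is empty for a non-null scenario")
    return(assignment)
  }
  eff <- numeric(k)
  if (spec@effectModel == "fixed_mean") {
    rare <- assignment@isRare
    nDel <- as.integer(ceiling(sum(rare) * spec@directionMix))
    sgn <- rep(1, sum(rare))
    if (nDel > 0) sgn[seq_len(nDel)] <- -1
    eff[rare] <- sgn * spec@meanEffectSd
    eff[!rare] <- -0.07
  } else {
    d <- .minorDosages(panel)[assignment@causalIndex, , drop = FALSE]
    n <- ncol(d)
    mj <- rowSums(d)
    q <- (mj + 1) / (2 * n + 2)
    w <- sqrt(n * q * (1 - q))
    eff <- -2.5 * min(w) / w
  }
  assignment@effectMean <- unname(eff)
  validObject(assignment)
  assignment
}

#' Simulate a continuous phenotype replicate
#'
#' Every non-carrier of a causal allele draws N(0, 1). A carrier of at
#' least one rare causal allele draws a single N(mu, 0.2^2) value, where mu
#' is the effect of the carried rare causal variant with the smallest MAF
#' (ties broken by lowest variant index) -- effects are not additive across
#' carried variants, and rare effects take precedence over common ones. An
#' individual carrying only common causal alleles draws N(mu_c, 1.01^2)
#' with mu_c the effect of the carried common causal variant chosen by the
#' same smallest-MAF rule (-0.07 under the fixed-mean model).
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param assignment a \code{\linkS4class{CausalAssignment}} with effects.
#' @param seed integer seed.
#' @param replicateId integer stored in the result.
#' @return a \code{\linkS4class{PhenotypeSet}}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 500, 1)
#' y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), seed = 9)
#' length(phenotypes(y))
#' @export
simulateContinuous <- function(panel, assignment, seed = 1L,
                               replicateId = 1L) {
  stopifnot(is(panel, "GenotypePanel"), is(assignment, "CausalAssignment"))
  d <- dosages(panel)
  if (any(is.na(d))) stop("panel must be imputed before phenotype simulation")
  n <- ncol(d)
  mu <- rep(0, n)
  sdv <- rep(1, n)
  k <- length(assignment@causalIndex)
  if (k && anyNA(assignment@effectMean))
    stop("assignment has unassigned effects; run assignEffects() first")
  if (k) {
    dm <- .minorDosages(panel)
    m <- mafs(panel)
    pickGroup <- function(idx, sdCarrier) {
      # per individual: effect of carried variant with smallest MAF,
      # ties by lowest variant index
      o <- order(m[idx], idx)
      idx <- idx[o]
      effs <- assignment@effectMean[match(idx, assignment@causalIndex)]
      sub <- dm[idx, , drop = FALSE] > 0
      carrier <- colSums(sub) > 0
      first <- apply(sub[, carrier, drop = FALSE], 2, which.max)
      list(carrier = which(carrier), mu = effs[first], sd = sdCarrier)
    }
    rareIdx <- assignment@causalIndex[assignment@isRare]
    commonIdx <- assignment@causalIndex[!assignment@isRare]
    if (length(commonIdx)) {
      g <- pickGroup(commonIdx, 1.01)
      mu[g$carrier] <- g$mu
      sdv[g$carrier] <- g$sd
    }
    if (length(rareIdx)) {  # rare effects take precedence over common
      g <- pickGroup(rareIdx, 0.2)
      mu[g$carrier] <- g$mu
      sdv[g$carrier] <- g$sd
    }
  }
  y <- withSeed(seed, rnorm(n, mean = mu, sd = sdv))
  names(y) <- colnames(d)
  new("PhenotypeSet", y = y, replicateId = as.integer(replicateId))
}

#' @describeIn phenotypes continuous values of a phenotype set
#' @export
setMethod("phenotypes", "PhenotypeSet", function(x) x@y)

#' @describeIn caseLabels labels of a phenotype set
#' @export
setMethod("caseLabels", "PhenotypeSet", function(x) x@labels)

setMethod("show", "PhenotypeSet", function(object) {
  cat("PhenotypeSet:", length(object@y), "individuals, replicate",
      object@replicateId, "\n")
  if (length(object@labels))
    print(table(object@labels))
})

#' Dichotomize by sampling the phenotype extremes
#'
#' Labels the \code{nCases} individuals with the lowest continuous
#' phenotypes as cases and the \code{nControls} with the highest as
#' controls; everyone else is excluded. Ties are broken by individual index
#' (stable order), so label counts are always exact.
#'
#' @param pheno a \code{\linkS4class{PhenotypeSet}}.
#' @param nCases,nControls extreme-group sizes (defaults 500/500, the
#'   extreme quarters of a cohort of 1,998).
#' @return the phenotype set with labels attached.
#' @examples
#' ph <- new("PhenotypeSet", y = c(3, 1, 2, 6, 5, 4))
#' caseLabels(dichotomizeExtremes(ph, 2, 2))
#' @export
dichotomizeExtremes <- function(pheno, nCases = 500L, nControls = 500L) {
  stopifnot(is(pheno, "PhenotypeSet"))
  n <- length(pheno@y)
  if (nCases + nControls > n)
    stop("nCases + nControls exceeds the number of individuals")
  o <- order(pheno@y, seq_len(n))      # stable: ties by individual index
  lab <- rep("excluded", n)
  lab[o[seq_len(nCases)]] <- "case"
  lab[o[(n - nControls + 1L):n]] <- "control"
  pheno@labels <- factor(lab, levels = c("case", "control", "excluded"))
  pheno
}

#' Phenotypic variance explained by the causal assignment
#'
#' Estimates Var(E[y | carrier status]) / Var(y) by Monte-Carlo: phenotypes
#' are simulated \code{nMC} times on the fixed panel/assignment, each
#' individual's conditional mean is estimated by averaging across
#' replicates (with the within-individual sampling noise removed), and the
#' between-individual variance of those means is compared with the total
#' phenotypic variance. Because the normalization of the printed
#' variance-explained table is not fully determined, the unnormalized
#' between-group variance is returned alongside the ratio.
#'
#' @param panel an imputed \code{\linkS4class{GenotypePanel}}.
#' @param assignment a \code{\linkS4class{CausalAssignment}} with effects
#'   (fixed-mean model).
#' @param nMC number of Monte-Carlo phenotype replicates (>= 2).
#' @param seed integer seed.
#' @return list with \code{proportion} (normalized), \code{betweenVar}
#'   (unnormalized Var(E[y|.])) and \code{totalVar}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 500, 1)
#' a <- assignEffects(selectCausal(p, scenarioSpec(2), 1), scenarioSpec(2), p)
#' varianceExplained(p, a, nMC = 50, seed = 2)$proportion
#' @export
varianceExplained <- function(panel, assignment, nMC = 200L, seed = 1L) {
  if (nMC < 2L) stop("nMC must be >= 2")
  n <- ncol(panel)
  Y <- matrix(0, n, nMC)
  for (r in seq_len(nMC))
    Y[, r] <- phenotypes(simulateContinuous(panel, assignment,
                                            seed = deriveSeed(seed, "ve", r),
                                            replicateId = r))
  mi <- rowMeans(Y)
  vi <- apply(Y, 1, var)
  between <- max(0, var(mi) - mean(vi) / nMC)  # remove MC noise in means
  total <- var(as.vector(Y))
  list(proportion = if (total > 0) between / total else 0,
       betweenVar = between, totalVar = total)
}
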