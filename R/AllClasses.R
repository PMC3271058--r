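#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm rbinom runif dbeta pnorm pchisq pt qnorm sd var
#'   density approx cor uniroot median quantile setNames aggregate reshape
#' @importFrom utils head read.table write.table
NULL

#' Summary profile of a sequenced gene
#'
#' A \code{GeneProfile} holds the printed summary statistics of one
#' Sanger-sequenced gene and is the calibration target for
#' \code{\link{generateGenePanel}}: variant counts, the number of rare
#' variants (MAF < 1\%), the median MAF across variants, the mean per-variant
#' missing-genotype rate, the coding length, the fraction of variants that
#' are singletons, and the histogram of individuals by the number of rare
#' variants they carry.
#'
#' @slot geneId single character label.
#' @slot nVariants total number of polymorphic variants in the gene.
#' @slot nRare number of variants with MAF < 1\%.
#' @slot medianMAF median minor-allele frequency across all variants.
#' @slot missingRate mean fraction of missing genotypes per variant, in [0,1).
#' @slot codingLength coding length in base pairs.
#' @slot singletonFraction fraction of all variants whose minor allele is
#'   observed exactly once in the cohort.
#' @slot carrierCountDist named integer vector; entry \code{"k"} is the
#'   number of individuals carrying exactly \code{k} rare variants. Sums to
#'   the cohort size.
#'
#' @seealso \code{\link{defaultGeneProfiles}}, \code{\link{generateGenePanel}}
#' @exportClass GeneProfile
setClass("GeneProfile",
  representation(
    geneId = "character",
    nVariants = "integer",
    nRare = "integer",
    medianMAF = "numeric",
    missingRate = "numeric",
    codingLength = "integer",
    singletonFraction = "numeric",
    carrierCountDist = "integer"
  )
)

setValidity("GeneProfile", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (object@nRare > object@nVariants)
    msg <- c(msg, "nRare must not exceed nVariants")
  if (object@nVariants < 1L)
    msg <- c(msg, "nVariants must be >= 1")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@medianMAF <= 0 || object@medianMAF > 0.5)
    msg <- c(msg, "medianMAF must lie in (0, 0.5]")
  if (object@singletonFraction < 0 || object@singletonFraction > 1)
    msg <- c(msg, "singletonFraction must lie in [0, 1]")
  if (length(object@carrierCountDist) &&
      is.null(names(object@carrierCountDist)))
    msg <- c(msg, "carrierCountDist must be named by carried-variant count")
  if (length(msg)) msg else TRUE
})

#' Genotype panel for one gene
#'
#' \code{GenotypePanel} extends \code{SummarizedExperiment}. The single assay
#' \code{"dosage"} is a variants x individuals integer matrix of minor-allele
#' dosages in \{0, 1, 2\} with \code{NA} for missing genotypes.
#' \code{rowData} carries per-variant minor-allele frequency (\code{maf},
#' computed on non-missing entries), minor-allele count (\code{alleleCount})
#' and the rare flag at the active threshold (\code{isRare}). The gene label
#' and the rare-MAF threshold live in \code{metadata}.
#'
#' @seealso \code{\link{generateGenePanel}}, \code{\link{dosages}},
#'   \code{\link{mafs}}
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character(0)
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d[!is.na(d)] %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (is.null(S4Vectors::metadata(object)$geneId))
    msg <- c(msg, "metadata geneId is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("maf", "isRare") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'maf' and 'isRare'")
  else if (any(!is.na(rd$maf) & (rd$maf < 0 | rd$maf > 0.5)))
    msg <- c(msg, "maf must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Causal-variant assignment
#'
#' Indices of the variants chosen as causal for one simulated phenotype
#' replicate, with their signed per-carrier mean phenotype shifts (in
#' phenotype standard-deviation units) and rare flags.
#'
#' @slot causalIndex integer indices into the panel's variants.
#' @slot effectMean signed per-variant mean shift for carriers (SD units);
#'   filled by \code{\link{assignEffects}} (NA before that).
#' @slot isRare logical, per causal variant.
#'
#' @seealso \code{\link{selectCausal}}, \code{\link{assignEffects}}
#' @exportClass CausalAssignment
setClass("CausalAssignment",
  representation(
    causalIndex = "integer",
    effectMean = "numeric",
    isRare = "logical"
  )
)

setValidity("CausalAssignment", function(object) {
  k <- length(object@causalIndex)
  if (length(object@effectMean) != k || length(object@isRare) != k)
    return("causalIndex, effectMean and isRare must have equal length")
  if (k && any(duplicated(object@causalIndex)))
    return("causalIndex must not contain duplicates")
  TRUE
})

#' Simulated phenotypes for one replicate
#'
#' Continuous trait values for every individual, optionally with extreme
#' case/control labels attached by \code{\link{dichotomizeExtremes}}.
#'
#' @slot y numeric phenotype vector, one value per individual.
#' @slot labels factor with levels case/control/excluded, or length zero
#'   when the trait is analysed as continuous.
#' @slot replicateId integer replicate index.
#'
#' @exportClass PhenotypeSet
setClass("PhenotypeSet",
  representation(
    y = "numeric",
    labels = "factor",
    replicateId = "integer"
  ),
  prototype(labels = factor(character(0),
                            levels = c("case", "control", "excluded")),
            replicateId = 1L)
)

setValidity("PhenotypeSet", function(object) {
  if (length(object@labels) &&
      length(object@labels) != length(object@y))
    return("labels, when present, must have one entry per individual")
  if (length(object@labels) &&
      !all(levels(object@labels) %in% c("case", "control", "excluded")))
    return("labels levels must be case/control/excluded")
  TRUE
})

#' Scenario specification for phenotype simulation
#'
#' Declares how causal variants are picked and what effects they carry for
#' one simulation scenario: the six control scenarios (ids "1".."6") or one
#' cell of the systematic grid (id "grid").
#'
#' @slot scenarioId "1".."6" or "grid".
#' @slot causalMafRule "rare_only", "none" or "unrestricted".
#' @slot causalFraction fraction of the eligible pool made causal (NA when
#'   fixed counts are used).
#' @slot fixedRare,fixedCommon explicit causal counts (scenario 3).
#' @slot directionMix fraction of causal variants that are deleterious
#'   (negative shift); the remainder are protective.
#' @slot effectModel "fixed_mean" (all rare causal share one magnitude) or
#'   "inverse_maf" (magnitude scaled so the rarest causal variant has shift
#'   -2.5 SD).
#' @slot meanEffectSd effect magnitude in SD units under "fixed_mean".
#' @slot samplingRule "uniform" or "inverse_maf_probability".
#'
#' @seealso \code{\link{scenarioSpec}}, \code{\link{gridScenario}}
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    scenarioId = "character",
    causalMafRule = "character",
    causalFraction = "numeric",
    fixedRare = "integer",
    fixedCommon = "integer",
    directionMix = "numeric",
    effectModel = "character",
    meanEffectSd = "numeric",
    samplingRule = "character"
  ),
  prototype(fixedRare = NA_integer_, fixedCommon = NA_integer_,
            causalFraction = NA_real_, directionMix = 1,
            effectModel = "fixed_mean", meanEffectSd = 1.64,
            samplingRule = "uniform")
)

setValidity("ScenarioSpec", function(object) {
  msg <- character(0)
  if (!object@scenarioId %in% c(as.character(1:6), "grid"))
    msg <- c(msg, "scenarioId must be '1'..'6' or 'grid'")
  if (!object@causalMafRule %in% c("rare_only", "none", "unrestricted"))
    msg <- c(msg, "unknown causalMafRule")
  if (!is.na(object@causalFraction) &&
      (object@causalFraction <= 0 || object@causalFraction > 1))
    msg <- c(msg, "causalFraction must lie in (0, 1]")
  if (object@directionMix < 0 || object@directionMix > 1)
    msg <- c(msg, "directionMix must lie in [0, 1]")
  if (!object@effectModel %in% c("fixed_mean", "inverse_maf"))
    msg <- c(msg, "unknown effectModel")
  if (!object@samplingRule %in% c("uniform", "inverse_maf_probability"))
    msg <- c(msg, "unknown samplingRule")
  if (length(msg)) msg else TRUE
})

#' Result of one gene-level association test
#'
#' @slot method one of SM, T1, T5, WE, VT, WOD1, WOD5, SKAT.
#' @slot statistic observed test statistic.
#' @slot pValue permutation p-value, (b+1)/(B+1), hence strictly positive
#'   (for SM, the smallest Bonferroni-adjusted per-variant p).
#' @slot nPermutations permutations actually used (0 for analytic SM).
#' @slot perVariantP per-variant p-values (SM only; empty otherwise).
#' @slot extra list of method-specific extras (e.g. SKAT's moment-matched
#'   analytic p, VT's chosen threshold, SM's causal detection proportion).
#'
#' @exportClass RareTestResult
setClass("RareTestResult",
  representation(
    method = "character",
    statistic = "numeric",
    pValue = "numeric",
    nPermutations = "integer",
    perVariantP = "numeric",
    extra = "list"
  ),
  prototype(perVariantP = numeric(0), extra = list())
)

setValidity("RareTestResult", function(object) {
  msg <- character(0)
  if (!is.finite(object@statistic))
    msg <- c(msg, "statistic must be finite")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Plan for a power experiment
#'
#' Bundles gene profiles, the scenario list (control scenarios and/or grid
#' cells), replicate and permutation counts, trait type and the master seed.
#' With the default profiles, the full grid (7 effects x 4 causal fractions)
#' over seven genes gives 196 gene-by-cell combinations.
#'
#' @slot profiles list of \code{GeneProfile}.
#' @slot scenarios list of \code{ScenarioSpec}.
#' @slot nReplicates phenotype replicates per (gene, scenario).
#' @slot nPermutations permutation cap per test.
#' @slot alpha rejection level (default 0.05).
#' @slot traitType "continuous" or "dichotomous".
#' @slot methods character vector of gene-level methods to run.
#' @slot nIndividuals cohort size (default 1998).
#' @slot seed master seed; all randomness derives from it.
#' @slot adaptive logical; early-stop permutations once the alpha decision
#'   is settled at 99\% confidence.
#'
#' @seealso \code{\link{experimentPlan}}, \code{\link{estimatePower}}
#' @exportClass ExperimentPlan
setClass("ExperimentPlan",
  representation(
    profiles = "list",
    scenarios = "list",
    nReplicates = "integer",
    nPermutations = "integer",
    alpha = "numeric",
    traitType = "character",
    methods = "character",
    nIndividuals = "integer",
    seed = "integer",
    adaptive = "logical"
  )
)

setValidity("ExperimentPlan", function(object) {
  msg <- character(0)
  if (!length(object@profiles) ||
      !all(vapply(object@profiles, is, TRUE, "GeneProfile")))
    msg <- c(msg, "profiles must be a non-empty list of GeneProfile")
  if (!length(object@scenarios) ||
      !all(vapply(object@scenarios, is, TRUE, "ScenarioSpec")))
    msg <- c(msg, "scenarios must be a non-empty list of ScenarioSpec")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (object@nPermutations < 1L)
    msg <- c(msg, "nPermutations must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (!object@traitType %in% c("continuous", "dichotomous"))
    msg <- c(msg, "traitType must be 'continuous' or 'dichotomous'")
  if (object@nIndividuals < 2L)
    msg <- c(msg, "nIndividuals must be >= 2")
  if (length(msg)) msg else TRUE
})
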