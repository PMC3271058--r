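#' The six control scenarios
#'
#' @return list of \code{\linkS4class{ScenarioSpec}} for scenarios 1..6.
#' @examples
#' length(controlScenarios())
#' @export
controlScenarios <- function() lapply(1:6, scenarioSpec)

#' The systematic grid of scenario cells
#'
#' The full crossing of carrier mean effects and causal fractions of rare
#' variants (defaults: 7 effects x 4 fractions; combined with seven genes
#' this is the 196-cell systematic design).
#'
#' @param effects carrier mean-shift magnitudes (SD units).
#' @param fractions causal fractions of the rare-variant pool.
#' @param directionMix fraction of causal variants deleterious (1 = all
#'   deleterious, 0.5 = bidirectional).
#' @return list of \code{\linkS4class{ScenarioSpec}} grid cells.
#' @examples
#' length(fullGrid())  # 28
#' @export
fullGrid <- function(effects = c(0.5, 0.75, 1, 1.25, 1.5, 2, 2.5),
                     fractions = c(0.10, 0.15, 0.20, 0.30),
                     directionMix = 1) {
  cells <- expand.grid(effect = effects, fraction = fractions)
  mapply(function(e, f) gridScenario(e, f, directionMix),
         cells$effect, cells$fraction, SIMPLIFY = FALSE)
}

#' Construct an experiment plan
#'
#' @param profiles list of \code{\linkS4class{GeneProfile}} (default: the
#'   seven packaged profiles).
#' @param scenarios list of \code{\linkS4class{ScenarioSpec}}, e.g.
#'   \code{\link{controlScenarios}()} or \code{\link{fullGrid}()}.
#' @param nReplicates phenotype replicates per gene and scenario
#'   (default 250).
#' @param nPermutations permutation cap per test (default 1000).
#' @param alpha rejection level (default 0.05).
#' @param traitType "continuous" or "dichotomous" (extreme-quarter
#'   case/control sampling).
#' @param methods gene-level methods to run.
#' @param nIndividuals cohort size (default 1998).
#' @param seed master seed.
#' @param adaptive permutation early stopping.
#' @return a validated \code{\linkS4class{ExperimentPlan}}.
#' @examples
#' experimentPlan(scenarios = controlScenarios()[1:2], nReplicates = 5,
#'                nPermutations = 50)
#' @export
experimentPlan <- function(profiles = defaultGeneProfiles(),
                           scenarios = controlScenarios(),
                           nReplicates = 250L, nPermutations = 1000L,
                           alpha = 0.05, traitType = "continuous",
                           methods = c("T1", "T5", "WE", "VT",
                                       "WOD1", "WOD5", "SKAT"),
                           nIndividuals = 1998L, seed = 1L,
                           adaptive = TRUE) {
  if (traitType == "dichotomous")
    methods <- setdiff(methods, c("WOD1", "WOD5"))
  new("ExperimentPlan", profiles = unname(profiles), scenarios = scenarios,
      nReplicates = as.integer(nReplicates),
      nPermutations = as.integer(nPermutations), alpha = alpha,
      traitType = traitType, methods = methods,
      nIndividuals = as.integer(nIndividuals), seed = as.integer(seed),
      adaptive = adaptive)
}

.scenarioLabel <- function(sc) {
  if (sc@scenarioId == "grid")
    sprintf("grid_e%g_f%g_d%g", sc@meanEffectSd, sc@causalFraction,
            sc@directionMix)
  else paste0("S", sc@scenarioId)
}

# one (gene, scenario) power cell: fresh causal set and phenotype draw per
# replicate; method errors count as non-rejections, reported via one
# summarizing warning per cell
.powerCell <- function(panel, sc, plan, gene, label) {
  R <- plan@nReplicates
  nCase <- as.integer(round(plan@nIndividuals * 0.25))
  rejects <- setNames(numeric(length(plan@methods)), plan@methods)
  errCount <- setNames(integer(length(plan@methods)), plan@methods)
  for (r in seq_len(R)) {
    base <- deriveSeed(plan@seed, gene, label, r)
    a <- selectCausal(panel, sc, deriveSeed(base, "sel"))
    if (length(causalIndex(a))) a <- assignEffects(a, sc, panel)
    ph <- simulateContinuous(panel, a, deriveSeed(base, "phen"), r)
    if (plan@traitType == "dichotomous")
      ph <- dichotomizeExtremes(ph, nCase, nCase)
    res <- runAssocMethods(panel, ph, methods = plan@methods,
                           B = plan@nPermutations,
                           seed = deriveSeed(base, "perm"),
                           adaptive = plan@adaptive, alpha = plan@alpha,
                           onError = "keep")
    for (m in plan@methods) {
      if (inherits(res[[m]], "condition")) errCount[m] <- errCount[m] + 1L
      else if (res[[m]]@pValue <= plan@alpha)
        rejects[m] <- rejects[m] + 1
    }
  }
  for (m in plan@methods[errCount > 0]) {
    warning(sprintf("%s/%s: %s failed on %d of %d replicates (counted as %s)",
                    gene, label, m, errCount[m], R, "non-rejections"),
            call. = FALSE)
  }
  data.frame(method = plan@methods, scenario = label,
             effectSd = if (sc@scenarioId == "grid") sc@meanEffectSd else NA,
             causalFraction = if (sc@scenarioId == "grid")
               sc@causalFraction else NA,
             directionMix = sc@directionMix,
             gene = gene, power = rejects / R, nReplicates = R,
             mcSE = sqrt(pmax(rejects / R * (1 - rejects / R), 0) / R),
             row.names = NULL)
}

#' Estimate empirical power across genes and scenarios
#'
#' For every (gene, scenario, replicate) a fresh causal assignment and
#' phenotype are drawn, every method's permutation p-value is computed
#' (shared permutation stream per replicate), and power is the fraction of
#' replicates with p <= alpha. A method erroring on a replicate (e.g. an
#' untestable gene) is counted as a non-rejection and reported through a
#' warning, never silently dropped. Unweighted gene-averaged rows
#' (\code{gene = "average"}) are appended per method and scenario.
#'
#' @param plan an \code{\linkS4class{ExperimentPlan}}.
#' @return data.frame with columns method, scenario, effectSd,
#'   causalFraction, directionMix, gene, power, nReplicates, mcSE.
#' @examples
#' plan <- experimentPlan(profiles = defaultGeneProfiles()[1],
#'                        scenarios = controlScenarios()[1],
#'                        nReplicates = 4, nPermutations = 60,
#'                        methods = c("T1", "SKAT"), nIndividuals = 300)
#' estimatePower(plan)
#' @export
estimatePower <- function(plan) {
  stopifnot(is(plan, "ExperimentPlan"))
  validObject(plan)
  rows <- list()
  for (prof in plan@profiles) {
    gene <- geneId(prof)
    panel <- generateGenePanel(prof, plan@nIndividuals,
                               seed = deriveSeed(plan@seed, "panel", gene))
    for (sc in plan@scenarios) {
      label <- .scenarioLabel(sc)
      rows[[length(rows) + 1L]] <- .powerCell(panel, sc, plan, gene, label)
    }
  }
  out <- do.call(rbind, rows)
  avg <- aggregate(power ~ method + scenario, data = out, FUN = mean)
  avg$effectSd <- out$effectSd[match(avg$scenario, out$scenario)]
  avg$causalFraction <- out$causalFraction[match(avg$scenario, out$scenario)]
  avg$directionMix <- out$directionMix[match(avg$scenario, out$scenario)]
  avg$gene <- "average"
  avg$nReplicates <- plan@nReplicates * length(plan@profiles)
  avg$mcSE <- sqrt(pmax(avg$power * (1 - avg$power), 0) / avg$nReplicates)
  rbind(out, avg[, colnames(out)])
}

#' Proportion of causal variants reaching single-marker significance
#'
#' For every grid cell, simulates continuous phenotypes, runs the
#' per-variant single-marker regression restricted to the assigned causal
#' variants, applies the gene's Bonferroni threshold, and averages the
#' proportion of causal variants reaching significance over replicates and
#' genes. Replicates with an empty causal set are skipped with a warning.
#'
#' @param plan an \code{\linkS4class{ExperimentPlan}} whose scenarios are
#'   grid cells (continuous traits).
#' @return data.frame with columns scenario, effectSd, causalFraction,
#'   gene, detection, nReplicates; gene-averaged rows appended.
#' @examples
#' plan <- experimentPlan(profiles = defaultGeneProfiles()[3],
#'                        scenarios = list(gridScenario(2.5, 0.3)),
#'                        nReplicates = 5, nIndividuals = 400)
#' causalDetectionProportion(plan)
#' @export
causalDetectionProportion <- function(plan) {
  stopifnot(is(plan, "ExperimentPlan"))
  validObject(plan)
  if (plan@traitType != "continuous")
    stop("single-marker detection is defined for continuous traits")
  rows <- list()
  for (prof in plan@profiles) {
    gene <- geneId(prof)
    panel <- generateGenePanel(prof, plan@nIndividuals,
                               seed = deriveSeed(plan@seed, "panel", gene))
    for (sc in plan@scenarios) {
      label <- .scenarioLabel(sc)
      det <- numeric(0)
      for (r in seq_len(plan@nReplicates)) {
        base <- deriveSeed(plan@seed, gene, label, r, "sm")
        a <- selectCausal(panel, sc, deriveSeed(base, "sel"))
        if (!length(causalIndex(a))) {
          warning(gene, "/", label, ": empty causal set, replicate skipped",
                  call. = FALSE)
          next
        }
        a <- assignEffects(a, sc, panel)
        ph <- simulateContinuous(panel, a, deriveSeed(base, "phen"), r)
        sm <- singleMarkerScan(panel, ph, causal = a, alpha = plan@alpha)
        det <- c(det, sm@extra$causalDetection)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = label, effectSd = sc@meanEffectSd,
        causalFraction = sc@causalFraction, gene = gene,
        detection = mean(det), nReplicates = length(det))
    }
  }
  out <- do.call(rbind, rows)
  avg <- aggregate(detection ~ scenario, data = out, FUN = mean)
  avg$effectSd <- out$effectSd[match(avg$scenario, out$scenario)]
  avg$causalFraction <- out$causalFraction[match(avg$scenario, out$scenario)]
  avg$gene <- "average"
  avg$nReplicates <- vapply(avg$scenario, function(s)
    sum(out$nReplicates[out$scenario == s]), numeric(1))
  rbind(out, avg[, colnames(out)])
}

#' Probability that a causal-allele carrier is sampled as a case
#'
#' Under the extreme-sampling design, cases are the lowest quarter of the
#' phenotype mixture. Carriers of a deleterious causal allele have
#' phenotype N(-effectSd, 0.2^2) and non-carriers N(0, 1); the case
#' threshold is the \code{caseFraction} quantile of the mixture (found
#' numerically), and the returned value is the carrier CDF at that
#' threshold. With \code{effectSd = 0} there are no causal effects, so
#' carriers draw from the same N(0, 1) background as everyone else and the
#' probability equals \code{caseFraction} exactly.
#'
#' @param effectSd carrier mean shift (SD units, magnitude).
#' @param caseFraction fraction of the cohort sampled as cases (0.25 for
#'   extreme quarters).
#' @param carrierPrevalence fraction of individuals carrying a causal
#'   allele.
#' @return probability in [0, 1].
#' @examples
#' carrierCaseProbability(1.0, 0.25, 0.02)  # > 0.9
#' @export
carrierCaseProbability <- function(effectSd, caseFraction,
                                   carrierPrevalence) {
  stopifnot(caseFraction > 0, caseFraction < 1,
            carrierPrevalence > 0, carrierPrevalence < 1)
  if (effectSd == 0) return(caseFraction)
  mixCDF <- function(x)
    carrierPrevalence * pnorm(x, mean = -effectSd, sd = 0.2) +
      (1 - carrierPrevalence) * pnorm(x)
  lower <- -effectSd - 10
  upper <- 10
  thr <- uniroot(function(x) mixCDF(x) - caseFraction, c(lower, upper),
                 tol = 1e-10)$root
  pnorm(thr, mean = -effectSd, sd = 0.2)
}
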