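#' Construct a GenotypePanel from a dosage matrix
#'
#' @param dosages integer matrix, variants in rows, individuals in columns;
#'   minor-allele dosages 0/1/2, NA for missing.
#' @param geneId gene label.
#' @param mafThreshold active rare-MAF threshold (default 0.01).
#' @param positions optional integer vector of synthetic base-pair positions.
#' @return a \code{\linkS4class{GenotypePanel}}.
#' @examples
#' d <- rbind(V1 = c(0L, 1L, 0L, 0L), V2 = c(1L, 0L, 2L, 0L))
#' GenotypePanel(d, "toy")
#' @export
GenotypePanel <- function(dosages, geneId, mafThreshold = 0.01,
                          positions = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("%s_V%03d", geneId, seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("I%04d", seq_len(ncol(dosages)))
  if (is.null(positions)) positions <- seq_len(nrow(dosages))
  maf <- .foldedMafs(dosages)
  rd <- S4Vectors::DataFrame(
    position = as.integer(positions),
    maf = maf,
    alleleCount = .minorAlleleCounts(dosages),
    isRare = !is.na(maf) & maf <= mafThreshold + 1e-12
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages), rowData = rd,
    metadata = list(geneId = as.character(geneId),
                    mafThreshold = mafThreshold))
  new("GenotypePanel", se)
}

# alt-allele frequency on non-missing entries (not folded)
.altFreqs <- function(d) {
  nObs <- rowSums(!is.na(d))
  rowSums(d, na.rm = TRUE) / (2 * nObs)
}

.foldedMafs <- function(d) {
  f <- .altFreqs(d)
  pmin(f, 1 - f)
}

.minorAlleleCounts <- function(d) {
  ac <- rowSums(d, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(d))
  as.integer(pmin(ac, tot - ac))
}

# refresh rowData MAF/AC/isRare after the dosage matrix changed
.refreshPanelStats <- function(panel) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  thr <- S4Vectors::metadata(panel)$mafThreshold
  maf <- .foldedMafs(d)
  rd <- SummarizedExperiment::rowData(panel)
  rd$maf <- maf
  rd$alleleCount <- .minorAlleleCounts(d)
  rd$isRare <- !is.na(maf) & maf <= thr + 1e-12
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' @describeIn dosages dosage assay of a panel
#' @export
setMethod("dosages", "GenotypePanel", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn mafs stored per-variant MAFs
#' @export
setMethod("mafs", "GenotypePanel", function(x)
  SummarizedExperiment::rowData(x)$maf)

#' @describeIn geneId gene label of a panel
#' @export
setMethod("geneId", "GenotypePanel", function(x)
  S4Vectors::metadata(x)$geneId)

#' @describeIn isRare rare flags of a panel at a MAF threshold
#' @export
setMethod("isRare", "GenotypePanel", function(x, threshold = NULL) {
  if (is.null(threshold))
    return(SummarizedExperiment::rowData(x)$isRare)
  m <- mafs(x)
  !is.na(m) & m <= threshold + 1e-12
})

#' @describeIn nIndividuals number of individuals (columns) in a panel
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) ncol(x))

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel", geneId(object), "\n",
      "", nrow(object), "variants x", ncol(object), "individuals\n",
      " rare (MAF <=", paste0(S4Vectors::metadata(object)$mafThreshold, "):"),
      sum(isRare(object)), "  missing entries:",
      sum(is.na(dosages(object))), "\n")
})

# dosages with rows counting the minor allele (flips rows whose alt
# frequency drifted above 0.5)
.minorDosages <- function(panel) {
  d <- dosages(panel)
  f <- .altFreqs(d)
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) d[flip, ] <- 2L - d[flip, ]
  d
}

# expected carrier-count distribution (bins 0..length(target)-1, last bin
# absorbing) when individual i carries variant v independently w.p. ac_v/n
.carrierCountPMF <- function(ac, n, nBins) {
  p <- ac / n
  dist <- c(1, rep(0, nBins - 1L))
  for (pv in p) {
    shifted <- c(0, dist[-nBins] * pv)
    shifted[nBins] <- shifted[nBins] + dist[nBins] * pv
    dist <- dist * (1 - pv) + shifted
  }
  dist
}

# chi-square distance between expected carrier histogram and target, with
# top bins pooled so that every compared cell has a non-trivial expectation
.carrierHistChisq <- function(ac, profile) {
  target <- profile@carrierCountDist
  n <- .cohortSize(profile)
  nBins <- length(target)
  expd <- .carrierCountPMF(ac, n, nBins) * n
  keep <- max(2L, max(which(expd >= 1)))
  pool <- function(v, k) c(v[seq_len(k - 1L)], sum(v[k:length(v)]))
  e <- pool(expd, keep)
  o <- pool(as.numeric(target), keep)
  sum((e - o)^2 / pmax(e, 0.5))
}

#' Generate a synthetic genotype panel matching a gene profile
#'
#' Builds an n x m dosage panel whose summary statistics reproduce the
#' profile's calibration targets. Rare variants get minor-allele counts from
#' a heavy-tailed neutral-like spectrum: the profile's singleton count is
#' placed exactly (allele count 1), and the remaining rare counts are drawn
#' from P(AC = k) proportional to 1/k on 2..ACmax (ACmax = largest count
#' still below the 1\% MAF threshold), then rescaled by a factor chosen to
#' minimize the chi-square distance between the expected carrier-count
#' histogram and the profile's histogram. Minor alleles are placed in
#' carriers sampled without replacement (exchangeable across individuals, no
#' linkage structure). Common variants draw their allele frequency
#' log-uniformly in (0.01, 0.5) and genotypes under Hardy-Weinberg,
#' redrawing until the realized MAF stays above the rare threshold so the
#' panel holds exactly \code{profile@nRare} rare variants.
#'
#' @param profile a \code{\linkS4class{GeneProfile}}.
#' @param nIndividuals cohort size (>= 2); default 1998.
#' @param seed integer seed for this panel's substream.
#' @return an imputation-free (no missing entries)
#'   \code{\linkS4class{GenotypePanel}}.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 1)
#' sum(isRare(p))  # 42
#' @export
generateGenePanel <- function(profile, nIndividuals = 1998L, seed = 1L) {
  stopifnot(is(profile, "GeneProfile"))
  validObject(profile)
  n <- as.integer(nIndividuals)
  if (n < 2L) stop("nIndividuals must be >= 2")
  m <- profile@nVariants
  nRare <- profile@nRare
  acMax <- {
    lim <- 0.02 * n
    if (abs(lim - round(lim)) < 1e-9) as.integer(lim) - 1L
    else as.integer(floor(lim))
  }
  if (acMax < 1L) stop("cohort too small for any rare variant")

  withSeed(seed, {
    nSingle <- min(nRare, as.integer(floor(profile@singletonFraction * m + 0.5)))
    nHeavy <- nRare - nSingle
    heavyAC <- integer(0)
    if (nHeavy > 0L) {
      if (acMax >= 2L) {
        kk <- 2:acMax
        heavyAC <- if (length(kk) == 1L) rep(kk, nHeavy) else
          sample(kk, nHeavy, replace = TRUE, prob = 1 / kk)
        # rescale the non-singleton counts toward the profile's carrier
        # histogram (chi-square distance, expected Poisson-binomial counts)
        grid <- seq(0.25, 4, by = 0.05)
        scaled <- lapply(grid, function(cc)
          pmin(acMax, pmax(2L, as.integer(round(cc * heavyAC)))))
        fit <- vapply(scaled, function(a)
          .carrierHistChisq(c(rep(1L, nSingle), a), profile), 0)
        heavyAC <- scaled[[which.min(fit)]]
      } else heavyAC <- rep(1L, nHeavy)
    }
    rareAC <- c(rep(1L, nSingle), heavyAC)

    d <- matrix(0L, nrow = m, ncol = n)
    ord <- sample.int(m)                    # interleave rare/common positions
    rareRows <- ord[seq_len(nRare)]
    commonRows <- if (nRare < m) ord[(nRare + 1L):m] else integer(0)
    for (i in seq_along(rareRows)) {
      carriers <- sample.int(n, rareAC[i])
      d[rareRows[i], carriers] <- 1L
    }
    for (r in commonRows) {
      for (try in seq_len(200L)) {
        p <- exp(runif(1, log(0.01), log(0.5)))
        g <- rbinom(n, 2L, p)
        ac <- sum(g)
        if (min(ac, 2L * n - ac) > acMax) break
      }
      d[r, ] <- as.integer(g)
    }
    pos <- sort(sample.int(max(profile@codingLength, m), m))
    panel <- GenotypePanel(d, geneId(profile), positions = pos)
    drawn <- integer(m)
    drawn[rareRows] <- rareAC
    rd <- SummarizedExperiment::rowData(panel)
    rd$drawnAC <- drawn
    SummarizedExperiment::rowData(panel) <- rd
    panel
  })
}

#' Degrade a panel with random missingness
#'
#' Sets each dosage entry to missing independently with the given
#' probability, emulating per-variant missing-genotype rates of the original
#' Sanger calls. Per-variant MAFs are recomputed on the remaining observed
#' entries.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed.
#' @return the degraded panel.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 400, seed = 2)
#' pm <- applyMissingness(p, 0.112, seed = 3)
#' mean(is.na(dosages(pm)))
#' @export
applyMissingness <- function(panel, rate, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  if (rate == 0) return(panel)
  d <- dosages(panel)
  withSeed(seed, {
    mask <- runif(length(d)) < rate
    d[mask] <- NA_integer_
  })
  SummarizedExperiment::assay(panel, "dosage") <- d
  .refreshPanelStats(panel)
}

#' Impute missing genotypes from observed allele frequencies
#'
#' Each rare variant was imputed independently of the others: every missing
#' dosage is replaced by a draw from Binomial(2, f-hat), where f-hat is the
#' variant's allele frequency computed on its observed entries. Observed
#' entries are untouched. Imputed values are sampled genotypes, not dosage
#' expectations, so the allele frequency itself enters the imputed calls
#' (a best-guess rule would always impute 0 for rare variants).
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}, possibly with missing
#'   entries.
#' @param seed integer seed.
#' @return a panel with no missing entries and refreshed MAFs.
#' @examples
#' p <- generateGenePanel(defaultGeneProfiles()[["Gene3"]], 400, seed = 2)
#' pm <- applyMissingness(p, 0.05, seed = 3)
#' pi <- imputeByMAF(pm, seed = 4)
#' any(is.na(dosages(pi)))  # FALSE
#' @export
imputeByMAF <- function(panel, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  miss <- is.na(d)
  if (!any(miss)) return(panel)
  nObs <- rowSums(!miss)
  if (any(nObs == 0L))
    stop("variant with all entries missing: allele frequency undefined")
  f <- rowSums(d, na.rm = TRUE) / (2 * nObs)
  withSeed(seed, {
    idx <- which(miss, arr.ind = TRUE)
    d[miss] <- rbinom(nrow(idx), 2L, f[idx[, 1L]])
  })
  SummarizedExperiment::assay(panel, "dosage") <- d
  .refreshPanelStats(panel)
}

#' Compare a panel's realized summaries against a gene profile
#'
#' Reports realized versus target values for the rare-variant count, median
#' MAF, singleton fraction and the carrier-count histogram, with absolute
#' deviations and a chi-square distance for the histogram. Mismatches are
#' reported, never raised as errors.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param profile the \code{\linkS4class{GeneProfile}} it should match
#'   (same \code{geneId}).
#' @return a list with components \code{nRare}, \code{medianMAF},
#'   \code{singletonFraction} (each holding \code{target}, \code{realized},
#'   \code{deviation}) and \code{carrierHist} (\code{target},
#'   \code{realized}, \code{absDeviation}, \code{chisq}).
#' @examples
#' prof <- defaultGeneProfiles()[["Gene1"]]
#' rep <- panelFidelityReport(generateGenePanel(prof, 1998, 5), prof)
#' rep$nRare$deviation  # 0
#' @export
panelFidelityReport <- function(panel, profile) {
  stopifnot(is(panel, "GenotypePanel"), is(profile, "GeneProfile"))
  if (!identical(geneId(panel), geneId(profile)))
    stop("panel and profile gene ids differ")
  m <- mafs(panel)
  ac <- SummarizedExperiment::rowData(panel)$alleleCount
  rlNRare <- sum(isRare(panel))
  rlMed <- median(m, na.rm = TRUE)
  rlSing <- mean(ac == 1L)
  d <- .minorDosages(panel)
  rareCnt <- colSums(d[isRare(panel), , drop = FALSE] > 0, na.rm = TRUE)
  nBins <- length(profile@carrierCountDist)
  rlHist <- tabulate(pmin(rareCnt, nBins - 1L) + 1L, nbins = nBins)
  names(rlHist) <- names(profile@carrierCountDist)
  tgt <- as.numeric(profile@carrierCountDist)
  list(
    geneId = geneId(panel),
    nRare = list(target = profile@nRare, realized = rlNRare,
                 deviation = abs(rlNRare - profile@nRare)),
    medianMAF = list(target = profile@medianMAF, realized = rlMed,
                     deviation = abs(rlMed - profile@medianMAF)),
    singletonFraction = list(target = profile@singletonFraction,
                             realized = rlSing,
                             deviation = abs(rlSing -
                                             profile@singletonFraction)),
    carrierHist = list(target = profile@carrierCountDist,
                       realized = rlHist,
                       absDeviation = sum(abs(rlHist - tgt)),
                       chisq = sum((rlHist - tgt)^2 / pmax(tgt, 0.5)))
  )
}
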