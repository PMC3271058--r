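# shared fixtures, all built in code

# tiny hand-checkable panel: variants x individuals
toyPanel <- function(d, geneId = "toy") {
  storage.mode(d) <- "integer"
  GenotypePanel(d, geneId)
}

# a small but realistic panel for distribution-level tests
smallGene3Panel <- function(n = 400, seed = 2) {
  generateGenePanel(defaultGeneProfiles()[["Gene3"]], n, seed = seed)
}

# profile for quick generator tests: 10 variants, 8 rare, mostly singletons
miniProfile <- function() {
  GeneProfile("Mini", nVariants = 10L, nRare = 8L, medianMAF = 1 / 400,
              missingRate = 0.05, codingLength = 600L,
              singletonFraction = 0.6,
              carrierCountDist = c(`0` = 180L, `1` = 18L, `2` = 2L))
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
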