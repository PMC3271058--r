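test_that("scenario rules pick the prescribed causal sets", {
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 1)
  # null: empty; scenario 2: every rare variant
  expect_length(causalIndex(selectCausal(p, scenarioSpec(1), 1)), 0)
  a2 <- selectCausal(p, scenarioSpec(2), 1)
  expect_equal(causalIndex(a2), unname(which(isRare(p))))
  # scenario 3: exactly 4 rare + 4 common
  a3 <- selectCausal(p, scenarioSpec(3), 1)
  expect_length(causalIndex(a3), 8)
  expect_equal(sum(a3@isRare), 4)
  expect_equal(sum(!a3@isRare), 4)
  # scenario 4: round-half-up of 15% of the rare pool
  a4 <- selectCausal(p, scenarioSpec(4), 1)
  expect_length(causalIndex(a4), floor(0.15 * sum(isRare(p)) + 0.5))
  # grid: fraction of rare pool
  ag <- selectCausal(p, gridScenario(1, 0.30), 2)
  expect_length(causalIndex(ag), floor(0.30 * sum(isRare(p)) + 0.5))
  expect_true(all(ag@isRare))
  # scenario 6: 10% of all variants, any frequency
  a6 <- selectCausal(p, scenarioSpec(6), 3)
  expect_length(causalIndex(a6), floor(0.10 * nrow(p) + 0.5))
})

test_that("inverse-MAF sampling frequencies follow normalized 1/MAF", {
  # 3-variant toy with MAFs (0.001, 0.01, 0.1); exact oracle probabilities
  n <- 500
  d <- matrix(0L, 3, n)
  d[1, 1] <- 1L                       # maf 1/1000
  d[2, 1:10] <- 1L                    # maf 10/1000
  d[3, 1:100] <- 1L                   # maf 100/1000
  pan <- toyPanel(d)
  spec <- scenarioSpec(5)
  spec@causalFraction <- 1 / 3        # one of three (rare pool count anchor)
  counts <- integer(3)
  for (s in 1:4000) {
    i <- causalIndex(selectCausal(pan, spec, s))
    counts[i] <- counts[i] + 1L
  }
  pexp <- (1 / c(0.001, 0.01, 0.1)) / sum(1 / c(0.001, 0.01, 0.1))
  expect_lt(max(abs(counts / 4000 - pexp)), 0.02)
})

test_that("fixed-mean effects honor magnitude, direction split and the
           common-variant shift", {
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 1)
  a2 <- assignEffects(selectCausal(p, scenarioSpec(2), 1), scenarioSpec(2), p)
  expect_true(all(effectMeans(a2) == -1.64))
  a3 <- assignEffects(selectCausal(p, scenarioSpec(3), 1), scenarioSpec(3), p)
  expect_equal(sort(unique(effectMeans(a3))), c(-1.64, -0.07))
  expect_true(all(effectMeans(a3)[!a3@isRare] == -0.07))
  a4 <- assignEffects(selectCausal(p, scenarioSpec(4), 1), scenarioSpec(4), p)
  k <- length(causalIndex(a4))
  expect_equal(sum(effectMeans(a4) == -1.64), ceiling(k / 2))
  expect_equal(sum(effectMeans(a4) == +1.64), floor(k / 2))
})

test_that("inverse-MAF effects give the rarest causal variant exactly -2.5", {
  # two causal variants with equal MAF -> both -2.5
  d <- matrix(0L, 2, 100)
  d[1, 1:2] <- 1L
  d[2, 3:4] <- 1L
  pan <- toyPanel(d)
  spec <- scenarioSpec(6)
  a <- new("CausalAssignment", causalIndex = c(1L, 2L),
           effectMean = c(NA_real_, NA_real_), isRare = c(TRUE, TRUE))
  a <- assignEffects(a, spec, pan)
  expect_equal(effectMeans(a), c(-2.5, -2.5))
  # unequal MAFs: rarest gets -2.5, others shrink toward zero
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 1)
  a5 <- assignEffects(selectCausal(p, scenarioSpec(5), 2), scenarioSpec(5), p)
  expect_equal(min(effectMeans(a5)), -2.5)
  expect_true(all(effectMeans(a5) >= -2.5 & effectMeans(a5) < 0))
  mafsel <- mafs(p)[causalIndex(a5)]
  expect_equal(which.min(effectMeans(a5)), unname(which.min(mafsel)))
})

test_that("null phenotypes are standard normal and reproducible", {
  p <- generateGenePanel(defaultGeneProfiles()[["Gene2"]], 1998, seed = 1)
  a0 <- selectCausal(p, scenarioSpec(1), 1)
  y1 <- phenotypes(simulateContinuous(p, a0, seed = 5))
  y2 <- phenotypes(simulateContinuous(p, a0, seed = 5))
  expect_identical(y1, y2)
  ks <- suppressWarnings(stats::ks.test(y1, "pnorm"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(y1)), 0.1)
  expect_lt(abs(sd(y1) - 1), 0.06)
})

test_that("carrier phenotypes center on the causal mean with SD 0.2 and rare
           effects take precedence over common ones", {
  # individual 1 carries both a rare causal (-1.64) and a common causal
  n <- 3000
  d <- matrix(0L, 2, n)
  d[1, 1:30] <- 1L                       # rare-ish causal
  d[2, ] <- rep(c(1L, 0L), length.out = n)  # common causal, individual 1 too
  d[2, 1] <- 1L
  pan <- toyPanel(d)
  a <- new("CausalAssignment", causalIndex = c(1L, 2L),
           effectMean = c(-1.64, -0.07), isRare = c(TRUE, FALSE))
  ys <- vapply(1:400, function(s)
    phenotypes(simulateContinuous(pan, a, seed = s))[1], numeric(1))
  expect_lt(abs(mean(ys) + 1.64), 0.05)       # rare wins over common
  expect_lt(abs(sd(ys) - 0.2), 0.03)
  # carriers of the common causal only: mean -0.07, sd 1.01
  y <- phenotypes(simulateContinuous(pan, a, seed = 9))
  commonOnly <- which(dosages(pan)[2, ] > 0 & dosages(pan)[1, ] == 0)
  expect_lt(abs(mean(y[commonOnly]) + 0.07), 0.1)
  expect_lt(abs(sd(y[commonOnly]) - 1.01), 0.1)
})

test_that("conflicting rare effects resolve by smallest MAF then index", {
  n <- 200
  d <- matrix(0L, 3, n)
  d[1, 1] <- 1L            # rarest, effect +1.64
  d[2, c(1, 2, 3)] <- 1L   # commoner rare, effect -1.64
  d[3, c(1, 4, 5)] <- 1L   # same MAF as variant 2, effect -0.5
  pan <- toyPanel(d)
  a <- new("CausalAssignment", causalIndex = c(1L, 2L, 3L),
           effectMean = c(1.64, -1.64, -0.5), isRare = rep(TRUE, 3))
  ys <- vapply(1:300, function(s)
    phenotypes(simulateContinuous(pan, a, seed = s))[1], numeric(1))
  expect_lt(abs(mean(ys) - 1.64), 0.05)  # smallest MAF wins
  # individuals 2,3 carry only variant 2; 4,5 only variant 3 (index tie-break
  # plays no role for them, values confirm per-variant means)
  y <- rowMeans(vapply(1:300, function(s)
    phenotypes(simulateContinuous(pan, a, seed = s)), numeric(n)))
  expect_lt(abs(y[2] + 1.64), 0.05)
  expect_lt(abs(y[4] + 0.5), 0.05)
})

test_that("extreme dichotomization labels exact counts with stable ties", {
  ph <- new("PhenotypeSet", y = c(3, 1, 2, 6, 5, 4))
  d <- dichotomizeExtremes(ph, 2, 2)
  lab <- caseLabels(d)
  expect_equal(which(lab == "case"), c(2L, 3L))
  expect_equal(which(lab == "control"), c(4L, 5L))
  expect_true(max(phenotypes(d)[lab == "case"]) <
              min(phenotypes(d)[lab == "control"]))
  # all-equal phenotypes: labels by index, counts exact
  ph2 <- new("PhenotypeSet", y = rep(1, 10))
  lab2 <- caseLabels(dichotomizeExtremes(ph2, 3, 3))
  expect_equal(which(lab2 == "case"), 1:3)
  expect_equal(which(lab2 == "control"), 8:10)
  expect_error(dichotomizeExtremes(ph2, 6, 6), "exceeds")
  # cohort-scale: 1998 -> 500/500/998
  p <- generateGenePanel(defaultGeneProfiles()[["Gene1"]], 1998, seed = 1)
  y <- simulateContinuous(p, selectCausal(p, scenarioSpec(1), 1), 3)
  t3 <- table(caseLabels(dichotomizeExtremes(y)))
  expect_equal(unname(as.vector(t3)), c(500L, 500L, 998L))
})

test_that("variance explained matches the mixture decomposition and is
           monotone in effect and carrier fraction", {
  n <- 5000
  d <- rbind(c(rep(1L, 100), rep(0L, n - 100)),
             rep(c(0L, 1L), length.out = n))
  pan <- toyPanel(d)
  a <- new("CausalAssignment", causalIndex = 1L, effectMean = -0.5,
           isRare = TRUE)
  ve <- varianceExplained(pan, a, nMC = 300, seed = 5)
  expect_lt(abs(ve$betweenVar - 0.02 * 0.98 * 0.25), 0.0015)
  expect_error(varianceExplained(pan, a, nMC = 1, seed = 1), "nMC")
  # empty causal set explains nothing
  a0 <- new("CausalAssignment", causalIndex = integer(0),
            effectMean = numeric(0), isRare = logical(0))
  expect_lt(varianceExplained(pan, a0, nMC = 100, seed = 2)$proportion, 0.002)
  # monotone in |effect|
  a2 <- a; a2@effectMean <- -1.0
  expect_gt(varianceExplained(pan, a2, nMC = 300, seed = 5)$betweenVar,
            ve$betweenVar)
  # monotone in carrier fraction (p < 1/2)
  d3 <- rbind(c(rep(1L, 400), rep(0L, n - 400)),
              rep(c(0L, 1L), length.out = n))
  a3 <- a
  expect_gt(varianceExplained(toyPanel(d3), a3, nMC = 300, seed = 5)$betweenVar,
            ve$betweenVar)
})
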