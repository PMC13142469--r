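test_that("Balding-Nichols frequencies collapse to the ancestral at tiny Fst", {
  cfg <- simulationConfig(nChrom = 1, sitesPerChrom = 10000, Fst = 1e-6, seed = 5)
  set.seed(cfg$seed)
  fr <- simulateSourceFrequencies(cfg)
  expect_lt(max(abs(fr$fHG - fr$ancestral)), 0.01)
  expect_lt(max(abs(fr$fF - fr$ancestral)), 0.01)
})

test_that("simulated divergence matches the target Fst (Hudson estimator)", {
  cfg <- simulationConfig(nChrom = 1, sitesPerChrom = 100000, Fst = 0.1, seed = 6)
  set.seed(cfg$seed)
  fr <- simulateSourceFrequencies(cfg)
  expect_true(all(fr$fHG >= 0 & fr$fHG <= 1))
  expect_true(all(fr$fF >= 0 & fr$fF <= 1))
  expect_lt(abs(hudsonFst(fr$fHG, fr$fF) - 0.1), 0.02)
})

test_that("interior tract lengths are exponential with the single-pulse rate", {
  # T = 35, p = 0.2: hunter-gatherer tracts ~ Exp(0.28 per cM)
  # long chromosome so that interior-tract length bias (longer tracts
  # are likelier to touch an end) is negligible next to 3 SE
  cfg <- simulationConfig(
    nAdmixed = 90, nChrom = 1, sitesPerChrom = 10,
    chromLengthCM = 1000, seed = 7
  )
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  interior <- truth[truth$state == 1L & truth$startCM > 0 &
    truth$endCM < cfg$chromLengthCM, ]
  len <- interior$endCM - interior$startCM
  expect_gt(length(len), 4000)
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 1 / 0.28), 3 * se)
})

test_that("degenerate proportion p = 1 gives one full-chromosome HG tract", {
  cfg <- simulationConfig(nAdmixed = 3, nChrom = 1, sitesPerChrom = 10, seed = 8)
  cfg$p <- 1
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  expect_equal(nrow(truth), 6L) # one tract per haplotype
  expect_true(all(truth$state == 1L))
  expect_true(all(truth$startCM == 0 & truth$endCM == cfg$chromLengthCM))
})

test_that("genome-wide HG fraction matches p and tracts tile chromosomes", {
  cfg <- simulationConfig(
    nAdmixed = 50, nChrom = 35, sitesPerChrom = 10,
    chromLengthCM = 150, seed = 9
  )
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  len <- truth$endCM - truth$startCM
  hapChrom <- paste(truth$haplotype, truth$chrom)
  # conservation: lengths sum to the chromosome length on every haplotype
  sums <- tapply(len, hapChrom, sum)
  expect_true(all(abs(sums - cfg$chromLengthCM) < 1e-9))
  # no gaps/overlaps: next start equals previous end within a haplotype
  ord <- order(truth$haplotype, truth$chrom, truth$startCM)
  tr <- truth[ord, ]
  same <- hapChrom[ord][-1L] == hapChrom[ord][-nrow(tr)]
  expect_true(all(abs(tr$startCM[-1L][same] - tr$endCM[-nrow(tr)][same]) < 1e-12))
  # HG fraction across 100 haplotypes x 35 chromosomes within 3 SE of 0.2
  fracByHap <- tapply(len * (truth$state == 1L), hapChrom, sum) / cfg$chromLengthCM
  se <- sd(fracByHap) / sqrt(length(fracByHap))
  expect_lt(abs(mean(fracByHap) - 0.2), 3 * se)
})

test_that("interior tracts pass an exponential goodness-of-fit across seeds", {
  lambda <- 35 * (1 - 0.2) / 100
  edges <- c(qexp(seq(0, 0.9, 0.1), lambda), Inf)
  pass <- 0L
  for (seed in 1:100) {
    cfg <- simulationConfig(
      nAdmixed = 60, nChrom = 1, sitesPerChrom = 10,
      chromLengthCM = 150, seed = seed
    )
    set.seed(seed)
    truth <- layTracts(cfg)
    keep <- truth$state == 1L & truth$startCM > 0 & truth$endCM < 150
    len <- truth$endCM[keep] - truth$startCM[keep]
    obs <- table(cut(len, edges))
    p <- suppressWarnings(chisq.test(obs, p = diff(pexp(edges, lambda)))$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("ancestry state sequences match the two-state Markov chain", {
  # 3 sites on one chromosome; compare the empirical distribution of the
  # 8 state sequences against exact transition-matrix enumeration
  cfg <- simulationConfig(
    nAdmixed = 50000, nChrom = 1, sitesPerChrom = 3,
    chromLengthCM = 6, phaseSwitchRate = 0, genotypeErrorRate = 0, seed = 10
  )
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  panel <- laiscan:::simSitePanel(cfg)
  lab <- laiscan:::labelsFromTracts(truth, panel, unique(truth$haplotype))
  seqs <- paste(lab[, 1L], lab[, 2L], lab[, 3L])
  emp <- table(factor(seqs, levels = apply(
    expand.grid(0:1, 0:1, 0:1), 1L, paste,
    collapse = " "
  ))) / nrow(lab)

  a <- cfg$generations * (1 - cfg$p) / 100 # rate out of HG
  b <- cfg$generations * cfg$p / 100 # rate out of farmer
  piH <- b / (a + b) # stationary HG probability = p
  piF <- a / (a + b)
  trans <- function(d) {
    decay <- exp(-(a + b) * d)
    rbind(
      c(piF + piH * decay, piH * (1 - decay)), # from farmer: (to F, to HG)
      c(piF * (1 - decay), piH + piF * decay) # from HG
    )
  }
  d <- diff(siteCM(panel))
  P1 <- trans(d[1L])
  P2 <- trans(d[2L])
  theo <- numeric(8L)
  k <- 0L
  for (s3 in 0:1) {
    for (s2 in 0:1) {
      for (s1 in 0:1) {
        k <- k + 1L
        init <- if (s1 == 1L) cfg$p else 1 - cfg$p
        theo[k] <- init * P1[s1 + 1L, s2 + 1L] * P2[s2 + 1L, s3 + 1L]
      }
    }
  }
  names(theo) <- apply(expand.grid(0:1, 0:1, 0:1), 1L, paste, collapse = " ")
  tv <- sum(abs(emp[names(theo)] - theo)) / 2
  expect_lt(tv, 0.02)
})

test_that("selection injection shifts the focal ancestry by delta with a taper", {
  loci <- data.frame(chrom = "1", posCM = 10, delta = 0.15, radiusCM = 4)
  cfg <- simulationConfig(
    nAdmixed = 5000, nChrom = 1, sitesPerChrom = 41, chromLengthCM = 20.5,
    selectionLoci = loci, phaseSwitchRate = 0, genotypeErrorRate = 0, seed = 11
  )
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  injected <- injectSelection(truth, loci, cfg$p)
  panel <- laiscan:::simSitePanel(cfg)
  lab <- laiscan:::labelsFromTracts(injected, panel, unique(injected$haplotype))
  cm <- siteCM(panel)
  n <- nrow(lab)
  se <- sqrt(0.35 * 0.65 / n)
  focal <- which.min(abs(cm - 10))
  expect_lt(abs(mean(lab[, focal]) - 0.35), 3 * se)
  # linear taper: expected deviation delta * (1 - d/r)
  for (d in c(1, 2, 3)) {
    at <- which.min(abs(cm - (10 + d)))
    expmean <- 0.2 + 0.15 * (1 - d / 4)
    expect_lt(abs(mean(lab[, at]) - expmean), 4 * sqrt(expmean * (1 - expmean) / n))
  }
  # outside the radius the process is untouched
  far <- which.min(abs(cm - 17))
  expect_lt(abs(mean(lab[, far]) - 0.2), 4 * sqrt(0.2 * 0.8 / n))
})

test_that("zero-delta injection is the identity", {
  cfg <- simulationConfig(nAdmixed = 5, nChrom = 1, sitesPerChrom = 10, seed = 12)
  set.seed(cfg$seed)
  truth <- layTracts(cfg)
  loci <- data.frame(chrom = "1", posCM = 50, delta = 0, radiusCM = 5)
  expect_identical(injectSelection(truth, loci, cfg$p), truth)
  bad <- data.frame(chrom = "1", posCM = 50, delta = 0.9, radiusCM = 5)
  expect_error(simulationConfig(selectionLoci = bad), "delta")
})

test_that("cohort simulation is seed-deterministic", {
  co1 <- smallCohort(42, nAdmixed = 5, sitesPerChrom = 200)
  co2 <- smallCohort(42, nAdmixed = 5, sitesPerChrom = 200)
  expect_identical(alleles(co1$genotypes), alleles(co2$genotypes))
  expect_identical(callLabels(co1$truthCalls), callLabels(co2$truthCalls))
  expect_identical(alleles(co1$sourceHG), alleles(co2$sourceHG))
  co3 <- smallCohort(43, nAdmixed = 5, sitesPerChrom = 200)
  expect_false(identical(alleles(co1$genotypes), alleles(co3$genotypes)))
})

test_that("noise-free emission reproduces the tract-conditional draws", {
  co <- smallCohort(13,
    nAdmixed = 6, sitesPerChrom = 500,
    genotypeErrorRate = 0, phaseSwitchRate = 0
  )
  # truth calls then equal the raw tract labels (no swaps applied)
  lab <- laiscan:::labelsFromTracts(
    co$truth, co$panel, unique(co$truth$haplotype)
  )
  expect_identical(unname(callLabels(co$truthCalls)), unname(lab))
})

test_that("phase-switch points occur at the configured Poisson rate", {
  cfg <- simulationConfig(
    nAdmixed = 200, nChrom = 2, sitesPerChrom = 100,
    chromLengthCM = 100, phaseSwitchRate = 0.02, seed = 14
  )
  co <- simulateCohort(cfg)
  observed <- attr(co$genotypes, "phaseSwitchCount")
  expected <- 200 * 2 * 100 * 0.02 # individuals x chromosomes x r L
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("pseudohaploid mode emits one allele per individual per site", {
  co <- smallCohort(15, nAdmixed = 8, sitesPerChrom = 300, pseudohaploid = TRUE)
  expect_equal(nHaplotypes(co$genotypes), 8L)
  expect_true(all(ploidy(co$genotypes) == 1L))
  expect_false(anyNA(alleles(co$genotypes)))
})

test_that("haploid individuals carry a single haplotype (X-style simulation)", {
  co <- smallCohort(16, nAdmixed = 6, sitesPerChrom = 100, haploidIndividuals = c(2L, 5L))
  expect_equal(sum(ploidy(co$genotypes) == 1L), 2L)
  expect_equal(nHaplotypes(co$genotypes), 10L)
})
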