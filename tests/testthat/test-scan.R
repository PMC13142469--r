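mkWindows <- function(Z, chrom = "1", bp = NULL) {
  if (is.null(bp)) bp <- seq_along(Z) * 10000L
  data.frame(chrom = chrom, leadBp = bp, Z = Z, stringsAsFactors = FALSE)
}

test_that("per-SNP mean ancestry handles missingness and call-rate masking", {
  lab <- rbind(
    c(1L, 1L, -1L, -1L),
    c(0L, 1L, 1L, -1L),
    c(0L, 0L, -1L, -1L),
    c(0L, 1L, 0L, -1L)
  )
  rownames(lab) <- c("a.0", "a.1", "b.0", "b.1")
  calls <- AncestryCalls(lab)
  expect_message(m <- snpMeanAncestry(calls, minCallRate = 0.5), "below 0.5")
  expect_equal(m[1:3], c(1 / 4, 3 / 4, 1 / 2))
  expect_true(is.na(m[4L]))
  allHG <- AncestryCalls(matrix(1L, 2L, 3L, dimnames = list(c("a.0", "a.1"), NULL)))
  expect_equal(snpMeanAncestry(allHG), rep(1, 3L))
})

test_that("window Z is self-standardized with outliers at the extreme window", {
  set.seed(91)
  S <- 3000L
  panel <- tinyPanel(cM = (1:S) / 100, pos = (1:S) * 10000L)
  m <- rnorm(S, 0.2, 0.02)
  spike <- 1400:1480
  m[spike] <- m[spike] + 0.2
  w <- windowZ(m, panel, scanConfig())
  best <- w[which.max(abs(w$Z)), ]
  expect_true(best$leadIdx %in% spike)
  expect_equal(sd(w$Z[!w$masked]), 1, tolerance = 1e-9)

  # constant track: no usable SD, everything masked with a warning
  expect_warning(wc <- windowZ(rep(0.2, S), panel, scanConfig()), "constant")
  expect_true(all(wc$masked))

  # short chromosomes cannot host a full window
  shortPanel <- tinyPanel(cM = 1:10)
  expect_warning(windowZ(rep(0.2, 10L), shortPanel, scanConfig()), "fewer than")
})

test_that("windows overlapping masks are excluded and never become leads", {
  set.seed(92)
  S <- 2000L
  panel <- tinyPanel(cM = (1:S) / 100, pos = (1:S) * 10000L)
  m <- rnorm(S, 0.2, 0.02)
  mask <- GenomicRanges::GRanges("1", IRanges::IRanges(5e6, 6e6))
  cfg <- scanConfig(masks = mask, discoveryZ = 2)
  w <- windowZ(m, panel, cfg)
  inMask <- w$leadBp >= 5e6 & w$leadBp <= 6e6
  expect_true(all(w$masked[inMask]))
  regions <- callCandidateRegions(w, cfg)
  if (nrow(regions) > 0L) {
    expect_true(all(regions$leadBp < 5e6 | regions$leadBp > 6e6))
  }
})

test_that("combined Z reproduces Stouffer, perfect correlation, and r = 0.5", {
  z1 <- matrix(1, 10L, 5L)
  expect_equal(combineZ(z1, Sigma = diag(5L)), rep(sqrt(5), 10L), tolerance = 1e-9)
  ones <- matrix(1, 5L, 5L)
  z2 <- matrix(rnorm(10L), 10L, 5L)[, rep(1L, 5L)]
  expect_equal(combineZ(z2, Sigma = ones), z2[, 1L], tolerance = 1e-9)
  S2 <- rbind(c(1, 0.5), c(0.5, 1))
  z3 <- matrix(2, 1L, 2L)
  expect_equal(combineZ(z3, Sigma = S2), 4 / sqrt(3), tolerance = 1e-9)
})

test_that("estimated covariance makes the combined track unit scale", {
  set.seed(93)
  shared <- rnorm(5000L)
  z <- sapply(1:3, function(i) 0.6 * shared + 0.8 * rnorm(5000L))
  cz <- combineZ(z)
  expect_lt(abs(sd(cz) - 1), 0.03)
  # identical (unit-scale) tracks: combined equals the single track
  zs <- as.vector(scale(z[, 1L]))
  expect_equal(combineZ(cbind(zs, zs)), zs, tolerance = 1e-9)
  # masked windows propagate unless renormalization is requested
  zNA <- z
  zNA[1L, 2L] <- NA
  expect_true(is.na(combineZ(zNA)[1L]))
  S3 <- estimateMethodCovariance(zNA)
  renorm <- combineZ(zNA, Sigma = S3, renormalize = TRUE)
  expect_equal(
    renorm[1L],
    sum(zNA[1L, -2L]) / sqrt(sum(S3[-2L, -2L]))
  )
})

test_that("Z/p conversions reproduce the published arithmetic", {
  expect_equal(round(zToP(3.07), 3), 0.002)
  expect_equal(zToP(0), 1)
  expect_equal(signif(zToP(4.72), 3), 2.36e-6)
  expect_equal(zToP(1.5, sided = "one.sided"), 1 - pnorm(1.5), tolerance = 1e-12)
  expect_equal(pToZThreshold(0.05, 2, "one.sided"), 1.96, tolerance = 5e-3)
  expect_equal(pToZThreshold(1, 1, "two.sided"), 0)
  # numerical-inversion oracle for the two-sided threshold
  inv <- uniroot(function(z) 2 * (1 - pnorm(z)) - 0.05, c(0, 10), tol = 1e-12)$root
  expect_equal(pToZThreshold(0.05, 1, "two.sided"), inv, tolerance = 1e-9)
  # conversions are mutual inverses at matched sidedness
  for (z in c(0.5, 1.96, 3.2, 4.7)) {
    expect_lt(abs(pToZThreshold(zToP(z), 1, "two.sided") - z), 1e-9)
    expect_lt(abs(pToZThreshold(zToP(z, "one.sided"), 1, "one.sided") - z), 1e-9)
  }
})

test_that("candidate regions merge within 1 Mb and split across gaps", {
  Z <- rep(0, 3000L)
  Z[100:110] <- 4 # one cluster
  Z[1200:1210] <- -3.5 # 10.9 Mb away: separate region, negative sign
  w <- mkWindows(Z)
  reg <- callCandidateRegions(w, scanConfig())
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$sign, c(1, -1))
  expect_equal(reg$leadBp[1L], which.max(Z) * 10000L)
  # single supra-threshold window is its own region
  Z2 <- rep(0, 100L)
  Z2[50L] <- 3.5
  reg2 <- callCandidateRegions(mkWindows(Z2), scanConfig())
  expect_equal(nrow(reg2), 1L)
  expect_equal(reg2$nWindows, 1L)
  expect_equal(reg2$p, zToP(3.5))
})

test_that("replication demands matching sign above threshold within the radius", {
  Z <- rep(0, 1000L)
  Z[500:520] <- 4
  w <- mkWindows(Z)
  reg <- callCandidateRegions(w, scanConfig())
  # the discovery track replicates itself at any lower threshold
  repSelf <- replicateRegions(reg, w, scanConfig(replicationZ = 2.84))
  expect_true(all(repSelf$replicated))
  # a sign-flipped replication track never replicates
  flip <- w
  flip$Z <- -w$Z
  repFlip <- replicateRegions(reg, flip, scanConfig())
  expect_false(any(repFlip$replicated))
  # outside the 2 Mb radius the evidence does not count
  far <- w
  far$Z <- rep(0, 1000L)
  far$Z[900L] <- 5
  repFar <- replicateRegions(reg, far, scanConfig())
  expect_false(any(repFar$replicated))
})

test_that("low-ancestry diagnostic separates selection from misclassification", {
  # synthetic cohort: 30 individuals, 10 with low reference ancestry.
  # region A: deviation present in the full cohort, absent in the subset
  # (selection-like). region B: deviation equally present in the subset
  # (misclassification-like).
  set.seed(94)
  S <- 600L
  panel <- tinyPanel(cM = (1:S) / 10, pos = (1:S) * 100000L)
  nInd <- 30L
  lowInd <- sprintf("i%02d", 1:10)
  allInd <- sprintf("i%02d", 1:30)
  lab <- matrix(0L, 2L * nInd, S)
  rownames(lab) <- paste0(rep(allInd, each = 2L), ".", 0:1)
  base <- ifelse(rep(allInd, each = 2L) %in% lowInd, 0.05, 0.25)
  for (h in seq_len(nrow(lab))) {
    lab[h, ] <- rbinom(S, 1L, base[h])
  }
  regA <- 200:250
  regB <- 400:450
  high <- !(rep(allInd, each = 2L) %in% lowInd)
  lab[high, regA] <- rbinom(sum(high) * length(regA), 1L, 0.6)
  lab[, regB] <- rbinom(nrow(lab) * length(regB), 1L, pmin(base + 0.35, 1))
  calls <- AncestryCalls(lab)
  regions <- data.frame(
    chrom = "1", leadBp = c(225L, 425L) * 100000L,
    Z = c(4, 4), sign = c(1, 1)
  )
  ref <- setNames(ifelse(allInd %in% lowInd, 0.05, 0.25), allInd)
  d <- lowAncestryDiagnostic(calls, regions, panel, ref, cutoff = 0.1)
  expect_equal(d$verdict, c("selection-consistent", "misclassification-suspect"))
  expect_true(all(d$nSubset == 10L))
  # the stated rule itself: equal deviations are suspect, zero subset is clean
  expect_true(abs(d$devSubset[2L]) >= 0.5 * abs(d$devFull[2L]))
  expect_lt(abs(d$devSubset[1L]), 0.5 * abs(d$devFull[1L]))
})

test_that("the full scan pipeline flags an injected locus with matching sign", {
  loci <- data.frame(chrom = "1", posCM = 50, delta = 0.15, radiusCM = 2)
  co <- smallCohort(95,
    nAdmixed = 60, nChrom = 1, sitesPerChrom = 8000,
    chromLengthCM = 100, selectionLoci = loci
  )
  calls <- suppressMessages(cohortMethodCalls(co, nSourceHG = 7, seed = 95))
  sc <- suppressMessages(scanDeviation(calls, co$panel))
  expect_equal(colnames(sc$Sigma), c("hmm", "mismatch"))
  expect_true(nrow(sc$regions) >= 1L)
  d <- abs(sc$regions$leadBp - 50e6)
  hit <- which.min(d)
  expect_lt(d[hit], 2e6)
  expect_equal(sc$regions$sign[hit], 1)
})
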