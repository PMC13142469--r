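## In-package LAI engines and the shared post-processing steps: a
## minimum-mismatch sliding-window classifier, a two-state haplotype
## HMM with posterior decoding, path-code recoding, per-chromosome bias
## correction, TRACTOR-style unkink rephasing and male-X de-duplication.

#' Parameters of the minimum-mismatch window caller
#'
#' Defaults follow the recommended settings of the mismatch-counting
#' caller the engine emulates (window span 1e6 bp, step 5e5 bp, at most
#' 2000 and at least 1000 sites per window, decision-ratio 5). For dense
#' or sparse simulated panels, scale `minSites` to the site density.
#'
#' @param span window span in bp.
#' @param step window step in bp.
#' @param maxSites windows are thinned to at most this many sites.
#' @param minSites windows with fewer sites are not called.
#' @param threshold mismatch-ratio below which a window is flagged
#'   low-confidence (the call is kept; the flag is reported).
#' @return Parameter list.
#' @export
mismatchParams <- function(span = 1e6, step = 5e5, maxSites = 2000,
                           minSites = 1000, threshold = 5) {
  stopifnot(step <= span, minSites <= maxSites, minSites >= 1)
  list(
    span = span, step = step, maxSites = as.integer(maxSites),
    minSites = as.integer(minSites), threshold = threshold
  )
}

#' Parameters of the two-state ancestry HMM
#'
#' `Ne` is accepted for interface parity with drift-aware HMM callers
#' but does not enter the two-state per-haplotype model, which has no
#' drift term; transitions depend only on `generations`, `p` and the
#' genetic distance.
#'
#' @param generations generations since admixture (transition scale).
#' @param Ne effective population size (documented, unused).
#' @param p prior hunter-gatherer proportion, in (0, 1).
#' @param errorRate allele observation error; emissions use
#'   `f * (1 - errorRate) + (1 - f) * errorRate`.
#' @param panelWeightHG,panelWeightF pseudo-count weights (source-panel
#'   haplotype counts) used when `callHmm` refines frequencies.
#' @return Parameter list.
#' @export
hmmParams <- function(generations = 35, Ne = 10000, p = 0.2,
                      errorRate = 1e-3,
                      panelWeightHG = 20, panelWeightF = 20) {
  stopifnot(generations >= 1, p > 0, p < 1, errorRate >= 0, errorRate < 0.5)
  list(
    generations = generations, Ne = Ne, p = p, errorRate = errorRate,
    panelWeightHG = panelWeightHG, panelWeightF = panelWeightF
  )
}

## internal: row minima of a numeric matrix
rowMin <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

#' Minimum-mismatch sliding-window LAI caller
#'
#' For each haplotype and window, counts Hamming mismatches against
#' every source haplotype (pairs with a missing allele are skipped) and
#' assigns the ancestry of the source panel attaining the smaller
#' minimum. Exact ties go to the farmer (majority) ancestry and are
#' counted in the `tieCount` attribute. Each SNP receives the label of
#' the window whose center is nearest; windows with fewer than
#' `minSites` sites stay missing. The pseudo-posterior is
#' `bestOther / (best + bestOther)`, clipped to \[0.5, 1\].
#'
#' @param panel a [SitePanel-class].
#' @param genotypes admixed [GenotypeMatrix-class].
#' @param sourceHG,sourceF source panels ([GenotypeMatrix-class]) on the
#'   same site grid.
#' @param params a [mismatchParams()] list.
#' @return An [AncestryCalls-class] with attributes `tieCount` and
#'   `lowConfidenceCount`.
#' @export
callMismatch <- function(panel, genotypes, sourceHG, sourceF,
                         params = mismatchParams()) {
  if (nHaplotypes(sourceHG) == 0L || nHaplotypes(sourceF) == 0L) {
    stop("empty source panel")
  }
  stopifnot(
    ncol(genotypes@alleles) == nSites(panel),
    ncol(sourceHG@alleles) == nSites(panel),
    ncol(sourceF@alleles) == nSites(panel)
  )
  X <- genotypes@alleles
  Ht <- nrow(X)
  lab <- matrix(LBL_MISSING, Ht, nSites(panel), dimnames = list(rownames(X), NULL))
  post <- matrix(NA_real_, Ht, nSites(panel), dimnames = list(rownames(X), NULL))
  ties <- 0L
  lowConf <- 0L
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)

  zeroNA <- function(m) {
    m[is.na(m)] <- 0L
    storage.mode(m) <- "double" # one conversion, not one per window
    m
  }
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    bp <- pos[sel]
    A1 <- zeroNA(X[, sel, drop = FALSE])
    A0 <- zeroNA(1L - X[, sel, drop = FALSE])
    H1 <- zeroNA(sourceHG@alleles[, sel, drop = FALSE])
    H0 <- zeroNA(1L - sourceHG@alleles[, sel, drop = FALSE])
    F1 <- zeroNA(sourceF@alleles[, sel, drop = FALSE])
    F0 <- zeroNA(1L - sourceF@alleles[, sel, drop = FALSE])

    starts <- seq(1, max(bp), by = params$step)
    nWin <- length(starts)
    centers <- starts + params$span / 2
    winLab <- rep(LBL_MISSING, nWin)
    winLabs <- matrix(LBL_MISSING, nWin, Ht)
    winPost <- matrix(NA_real_, nWin, Ht)
    lo <- findInterval(starts - 1, bp) + 1L
    hi <- findInterval(starts + params$span - 1, bp)
    for (w in seq_len(nWin)) {
      if (hi[w] - lo[w] + 1L < params$minSites) next
      J <- lo[w]:hi[w]
      if (length(J) > params$maxSites) {
        J <- J[unique(round(seq(1L, length(J), length.out = params$maxSites)))]
      }
      mH <- A1[, J, drop = FALSE] %*% t(H0[, J, drop = FALSE]) +
        A0[, J, drop = FALSE] %*% t(H1[, J, drop = FALSE])
      mF <- A1[, J, drop = FALSE] %*% t(F0[, J, drop = FALSE]) +
        A0[, J, drop = FALSE] %*% t(F1[, J, drop = FALSE])
      bestH <- rowMin(mH)
      bestF <- rowMin(mF)
      l <- ifelse(bestH < bestF, LBL_HG, LBL_FARMER)
      ties <- ties + sum(bestH == bestF)
      best <- pmin(bestH, bestF)
      other <- pmax(bestH, bestF)
      pp <- ifelse(best + other == 0, 0.5, other / (best + other))
      lowConf <- lowConf + sum((other + 1) / (best + 1) < params$threshold)
      winLabs[w, ] <- l
      winPost[w, ] <- pmin(pmax(pp, 0.5), 1)
    }
    ## nearest window center decides the per-SNP label
    wIdx <- pmin(pmax(round((bp - centers[1L]) / params$step) + 1L, 1L), nWin)
    lab[, sel] <- t(winLabs[wIdx, , drop = FALSE])
    post[, sel] <- t(winPost[wIdx, , drop = FALSE])
  }
  out <- AncestryCalls(lab,
    posterior = post, method = "mismatch",
    individual = genotypes@individual, ploidy = genotypes@ploidy
  )
  attr(out, "tieCount") <- ties
  attr(out, "lowConfidenceCount") <- lowConf
  out
}

#' Two-state haplotype HMM LAI caller
#'
#' Per haplotype, a hidden two-state chain (farmer / hunter-gatherer)
#' with switch probability `1 - exp(-T * (1 - p_a) * d / 100)` out of
#' ancestry `a` across a gap of `d` cM -- the same rate structure as the
#' single-pulse tract model -- and Bernoulli emissions at the source
#' allele frequencies. Posterior decoding (forward-backward) gives
#' per-site posteriors; the label is the argmax, with 0.5 ties going to
#' the farmer (majority) state. Frequencies at 0 or 1 are clamped to
#' \[1e-3, 1 - 1e-3\] with a message.
#'
#' @param panel a [SitePanel-class].
#' @param genotypes admixed [GenotypeMatrix-class] (one row per
#'   haplotype; pseudohaploid rows are handled as single-read samples).
#' @param freqHG,freqF per-site source allele-frequency estimates.
#' @param params an [hmmParams()] list.
#' @param altCount,totCount optional read-count matrices (haplotypes x
#'   sites) for read-count emissions; when supplied, `genotypes` only
#'   provides the sample bookkeeping.
#' @param refineIterations number of EM-style refinements of the source
#'   allele frequencies: after each decoding pass, frequencies are
#'   re-estimated from the posterior-weighted admixed alleles pooled
#'   with the source-panel counts (panel estimates act as pseudo-counts
#'   weighted by their haplotype number). With the very small source
#'   panels typical of ancient DNA, panel-only frequency estimates carry
#'   large sampling noise that all haplotypes share; one refinement
#'   pass removes most of the resulting method-systematic error.
#'   Genotype-emission mode only. Default 0 (panel frequencies as
#'   given).
#' @return An [AncestryCalls-class] with posteriors; attribute `loglik`
#'   holds per-haplotype log-likelihoods.
#' @export
callHmm <- function(panel, genotypes, freqHG, freqF, params = hmmParams(),
                    altCount = NULL, totCount = NULL, refineIterations = 0L) {
  stopifnot(
    length(freqHG) == nSites(panel), length(freqF) == nSites(panel),
    ncol(genotypes@alleles) == nSites(panel)
  )
  if (refineIterations > 0L && !is.null(altCount)) {
    stop("frequency refinement is available in genotype-emission mode only")
  }
  eps <- 1e-3
  nClamp <- sum(freqHG < eps | freqHG > 1 - eps | freqF < eps | freqF > 1 - eps)
  if (nClamp > 0L) {
    message("callHmm: clamping ", nClamp, " boundary allele frequencies to [",
      eps, ", ", 1 - eps, "]")
  }
  X <- genotypes@alleles
  Ht <- nrow(X)
  chrom <- siteChrom(panel)
  cm <- siteCM(panel)
  Tg <- params$generations
  p <- params$p
  e <- params$errorRate

  decode <- function(fHraw, fFraw) {
    fH <- pmin(pmax(fHraw, eps), 1 - eps)
    fF <- pmin(pmax(fFraw, eps), 1 - eps)
    fH <- fH * (1 - e) + (1 - fH) * e
    fF <- fF * (1 - e) + (1 - fF) * e
    postH <- matrix(NA_real_, Ht, nSites(panel), dimnames = list(rownames(X), NULL))
    ll <- numeric(Ht)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      d <- diff(cm[sel])
      stayH <- exp(-Tg * (1 - p) * d / 100)
      stayF <- exp(-Tg * p * d / 100)
      if (is.null(altCount)) {
        r <- hmm_fb_genotype(t(X[, sel, drop = FALSE]), fH[sel], fF[sel],
          stayF, stayH, p)
      } else {
        a <- t(altCount[, sel, drop = FALSE]) # sites x haplotypes
        n <- t(totCount[, sel, drop = FALSE])
        eH <- stats::dbinom(a, n, fH[sel])
        eF <- stats::dbinom(a, n, fF[sel])
        eH[n == 0L] <- 1
        eF[n == 0L] <- 1
        r <- hmm_fb_emission(eF, eH, stayF, stayH, p)
      }
      postH[, sel] <- t(r$posterior)
      ll <- ll + r$loglik
    }
    list(postH = postH, ll = ll)
  }

  res <- decode(freqHG, freqF)
  if (refineIterations > 0L) {
    ## pool the panel estimates (as pseudo-counts at their haplotype
    ## weight) with posterior-weighted admixed allele counts
    wH <- max(params$panelWeightHG %||% 20, 1)
    wF <- max(params$panelWeightF %||% 20, 1)
    obs <- !is.na(X)
    X0 <- X
    X0[!obs] <- 0L
    for (it in seq_len(refineIterations)) {
      pH <- res$postH
      sH <- colSums(pH * X0)
      tH <- colSums(pH * obs)
      sF <- colSums((1 - pH) * X0)
      tF <- colSums((1 - pH) * obs)
      fH2 <- (sH + wH * freqHG) / (tH + wH)
      fF2 <- (sF + wF * freqF) / (tF + wF)
      res <- decode(fH2, fF2)
    }
  }
  postH <- res$postH
  ll <- res$ll
  lab <- (postH > 0.5) + 0L # 0.5 ties go to the farmer (majority) state
  out <- AncestryCalls(lab,
    posterior = pmax(postH, 1 - postH), method = "hmm",
    individual = genotypes@individual, ploidy = genotypes@ploidy
  )
  attr(out, "loglik") <- ll
  out
}

#' Default path-code recode map
#'
#' Integer path codes 1-6 collapse onto the two sources: codes 3 and 4
#' are hunter-gatherer, codes 1, 2, 5 and 6 are farmer.
#'
#' @return named integer vector mapping code to label.
#' @export
defaultPathRecodeMap <- function() {
  c(`1` = LBL_FARMER, `2` = LBL_FARMER, `3` = LBL_HG, `4` = LBL_HG,
    `5` = LBL_FARMER, `6` = LBL_FARMER)
}

#' Recode integer path calls onto the two source labels
#'
#' @param paths integer vector or matrix of path codes; `NA` (missing)
#'   passes through as missing.
#' @param map named code-to-label map; must cover every code present.
#' @return Same shape as `paths`, with labels 0/1/-1.
#' @export
recodePaths <- function(paths, map = defaultPathRecodeMap()) {
  v <- as.vector(paths)
  known <- is.na(v) | v == LBL_MISSING | as.character(v) %in% names(map)
  if (!all(known)) {
    stop(
      "unknown path code(s): ",
      paste(unique(v[!known]), collapse = ", ")
    )
  }
  out <- rep(LBL_MISSING, length(v))
  hit <- !is.na(v) & as.character(v) %in% names(map)
  out[hit] <- map[as.character(v[hit])]
  out <- as.integer(out)
  if (is.matrix(paths)) {
    out <- matrix(out, nrow(paths), ncol(paths), dimnames = dimnames(paths))
  }
  out
}

#' Per-chromosome bias correction of a mean-ancestry track
#'
#' Shifts each chromosome's per-SNP population mean by the difference
#' between the chromosome mean and the genome-wide mean, so that after
#' adjustment every chromosome's mean equals the genome-wide mean
#' exactly.
#'
#' @param means per-SNP population mean hunter-gatherer ancestry.
#' @param chrom chromosome id per SNP.
#' @return Adjusted numeric vector.
#' @export
correctChromosomeBias <- function(means, chrom) {
  genome <- mean(means, na.rm = TRUE)
  chromMean <- tapply(means, chrom, mean, na.rm = TRUE)
  as.vector(means - (chromMean[as.character(chrom)] - genome))
}

#' TRACTOR-style unkink rephasing
#'
#' For each diploid individual and chromosome, positions where both
#' haplotypes switch ancestry simultaneously in opposite directions
#' ("kinks", the signature of a phase-switch error) trigger a swap of
#' the two haplotypes' label assignments from that point on. The total
#' number of ancestry switches never increases. Ploidy-1 individuals
#' pass through unchanged.
#'
#' @param calls an [AncestryCalls-class].
#' @param panel the matching [SitePanel-class] (chromosome boundaries
#'   delimit the rephasing).
#' @return Rephased [AncestryCalls-class].
#' @export
unkink <- function(calls, panel) {
  lab <- calls@labels
  post <- if (length(calls@posterior) > 0L) calls@posterior else NULL
  chrom <- siteChrom(panel)
  ind <- calls@individual
  for (id in names(calls@ploidy)[calls@ploidy == 2L]) {
    rows <- which(ind == id)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      h1 <- lab[rows[1L], sel]
      h2 <- lab[rows[2L], sel]
      n <- length(sel)
      if (n < 2L) next
      obs <- h1 != LBL_MISSING & h2 != LBL_MISSING
      prevOk <- obs[-n] & obs[-1L]
      kink <- prevOk &
        h1[-n] != h1[-1L] & h2[-n] != h2[-1L] &
        h1[-n] != h2[-n]
      if (!any(kink)) next
      swap <- cumsum(c(FALSE, kink)) %% 2L == 1L
      w <- sel[swap]
      tmp <- lab[rows[1L], w]
      lab[rows[1L], w] <- lab[rows[2L], w]
      lab[rows[2L], w] <- tmp
      if (!is.null(post)) {
        tmp <- post[rows[1L], w]
        post[rows[1L], w] <- post[rows[2L], w]
        post[rows[2L], w] <- tmp
      }
    }
  }
  AncestryCalls(lab,
    posterior = post, method = calls@method,
    individual = ind, ploidy = calls@ploidy
  )
}

#' Drop the duplicated haplotype of haploid (male X) samples
#'
#' After running a diploid-only caller on pseudo-diploid males, exactly
#' one haplotype per ploidy-1 individual is retained to avoid double
#' counting. Idempotent.
#'
#' @param calls an [AncestryCalls-class].
#' @param truePloidy named per-individual ploidy; defaults to the
#'   ploidy recorded in `calls`.
#' @return [AncestryCalls-class] with one haplotype per haploid sample.
#' @export
dedupMaleX <- function(calls, truePloidy = NULL) {
  pl <- truePloidy %||% calls@ploidy
  ind <- calls@individual
  keep <- rep(TRUE, nrow(calls@labels))
  for (id in names(pl)[pl == 1L]) {
    rows <- which(ind == id)
    if (length(rows) > 1L) keep[rows[-1L]] <- FALSE
  }
  out <- subsetCallsHaps(calls, keep)
  newPl <- out@ploidy
  newPl[names(pl)[pl == 1L & names(pl) %in% names(newPl)]] <- 1L
  out@ploidy <- newPl
  validObject(out)
  out
}
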