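## Synthetic two-way admixture with known truth tracts. Ancestry along a
## haplotype is a two-state Markov jump process in cM: the switch rate
## out of an ancestry with genome-wide proportion p_a is
## T * (1 - p_a) / 100 per cM, the stationary approximation to a
## T-generation pedigree. Interior tract lengths are then exactly
## exponential with the single-pulse rate lambda = T * (1 - p_a) / 100,
## so the simulator realizes the same tract-length theory the fitting
## code assumes.

#' Simulation configuration
#'
#' Defaults mirror the admixed Neolithic study conditions: 48
#' hunter-gatherer and 7 farmer source diploids, a single admixture
#' pulse 35 generations ago contributing 20% hunter-gatherer ancestry,
#' and ancient-DNA-style noise (genotype error, phase-switch error,
#' optional pseudohaploid sampling).
#'
#' @param nAdmixed number of admixed diploid individuals.
#' @param nSourceHG,nSourceF source panel sizes (diploids).
#' @param generations generations since the admixture pulse (T).
#' @param p genome-wide hunter-gatherer proportion, in (0, 1).
#' @param nChrom,sitesPerChrom,chromLengthCM genome geometry; sites are
#'   evenly spaced, with 1 cM = 1 Mb physical scaling.
#' @param Fst divergence of the two source populations, in (0, 1);
#'   source allele frequencies follow the Balding-Nichols model around
#'   an ancestral frequency drawn Uniform(0.05, 0.95).
#' @param selectionLoci optional `data.frame(chrom, posCM, delta,
#'   radiusCM)` of injected ancestry deviations: at each locus the local
#'   hunter-gatherer probability is shifted to `p + delta`, tapering
#'   linearly to `p` at `radiusCM`.
#' @param genotypeErrorRate per-allele flip probability.
#' @param phaseSwitchRate per-cM rate of phase-switch points per diploid.
#' @param pseudohaploid emit one random allele per individual per site.
#' @param haploidIndividuals indices (1-based, into the admixed cohort)
#'   of ploidy-1 individuals, e.g. males on the X chromosome.
#' @param seed RNG seed used by [simulateCohort()].
#' @return A validated configuration list.
#' @export
simulationConfig <- function(nAdmixed = 20, nSourceHG = 48, nSourceF = 7,
                             generations = 35, p = 0.2,
                             nChrom = 3, sitesPerChrom = 16500,
                             chromLengthCM = 110, Fst = 0.1,
                             selectionLoci = NULL,
                             genotypeErrorRate = 0.005,
                             phaseSwitchRate = 0.01,
                             pseudohaploid = FALSE,
                             haploidIndividuals = integer(0),
                             seed = 1L) {
  stopifnot(
    nAdmixed >= 1, nSourceHG >= 1, nSourceF >= 1,
    generations >= 1, p > 0, p < 1,
    nChrom >= 1, sitesPerChrom >= 2, chromLengthCM > 0,
    Fst > 0, Fst < 1,
    genotypeErrorRate >= 0, genotypeErrorRate < 1,
    phaseSwitchRate >= 0
  )
  if (!is.null(selectionLoci)) {
    stopifnot(all(c("chrom", "posCM", "delta", "radiusCM") %in% names(selectionLoci)))
    if (any(abs(selectionLoci$delta) > pmin(p, 1 - p))) {
      stop("|delta| must not exceed min(p, 1 - p) at any selection locus")
    }
    stopifnot(all(selectionLoci$radiusCM > 0))
  }
  list(
    nAdmixed = as.integer(nAdmixed), nSourceHG = as.integer(nSourceHG),
    nSourceF = as.integer(nSourceF), generations = generations, p = p,
    nChrom = as.integer(nChrom), sitesPerChrom = as.integer(sitesPerChrom),
    chromLengthCM = chromLengthCM, Fst = Fst,
    selectionLoci = selectionLoci,
    genotypeErrorRate = genotypeErrorRate,
    phaseSwitchRate = phaseSwitchRate,
    pseudohaploid = isTRUE(pseudohaploid),
    haploidIndividuals = as.integer(haploidIndividuals),
    seed = as.integer(seed)
  )
}

## internal: the simulated site grid (1 cM = 1 Mb)
simSitePanel <- function(config) {
  S <- config$sitesPerChrom
  L <- config$chromLengthCM
  cmOne <- (seq_len(S) - 0.5) * L / S
  SitePanel(
    chrom = rep(as.character(seq_len(config$nChrom)), each = S),
    pos = rep(as.integer(round(cmOne * 1e6)), config$nChrom),
    cM = rep(cmOne, config$nChrom),
    info = rep(1, S * config$nChrom)
  )
}

#' Draw diverged source-population allele frequencies
#'
#' Per site, an ancestral frequency f ~ Uniform(0.05, 0.95) and two
#' population frequencies from the Balding-Nichols distribution
#' Beta(f(1-F)/F, (1-f)(1-F)/F) with F = `Fst`.
#'
#' @param config a [simulationConfig()].
#' @return `list(ancestral, fHG, fF)`, numeric vectors over all sites in
#'   panel order.
#' @export
simulateSourceFrequencies <- function(config) {
  S <- config$nChrom * config$sitesPerChrom
  anc <- runif(S, 0.05, 0.95)
  F <- config$Fst
  a <- anc * (1 - F) / F
  b <- (1 - anc) * (1 - F) / F
  list(
    ancestral = anc,
    fHG = stats::rbeta(S, a, b),
    fF = stats::rbeta(S, a, b)
  )
}

## internal: batch-simulate the two-state tract process for n haplotypes
## on one chromosome of length L cM. Returns a data.frame with columns
## hap (1..n), startCM, endCM, state (1 = HG, 0 = farmer).
simTractBatch <- function(n, L, generations, p) {
  rateHG <- max(generations * (1 - p) / 100, 1e-300)
  rateF <- max(generations * p / 100, 1e-300)
  s0 <- rbinom(n, 1L, p)
  cycles <- L * (rateHG * rateF) / (rateHG + rateF) # expected full cycles
  K <- max(4L, ceiling(2 * cycles + 6 * sqrt(2 * cycles) + 8))
  draw <- function(nh, s0h) {
    odd <- matrix(rep(c(TRUE, FALSE), length.out = K), nh, K, byrow = TRUE)
    stHG <- (odd & s0h == 1L) | (!odd & s0h == 0L)
    rates <- ifelse(stHG, rateHG, rateF)
    jumps <- matrix(rexp(nh * K, rate = as.vector(rates)), nh, K)
    t(apply(jumps, 1L, cumsum))
  }
  cs <- draw(n, s0)
  ## rare haplotypes with more than K switches: extend by resimulation
  while (any(short <- cs[, K] < L)) {
    K2 <- 2L * K
    idx <- which(short)
    odd <- matrix(rep(c(TRUE, FALSE), length.out = K2), length(idx), K2, byrow = TRUE)
    stHG <- (odd & s0[idx] == 1L) | (!odd & s0[idx] == 0L)
    jumps <- matrix(rexp(length(idx) * K2, rate = as.vector(ifelse(stHG, rateHG, rateF))),
      length(idx), K2
    )
    cs2 <- t(apply(jumps, 1L, cumsum))
    cs <- cbind(cs, matrix(Inf, n, K2 - K))
    cs[idx, ] <- cs2
    K <- K2
  }
  ntr <- rowSums(cs < L) + 1L
  hap <- rep(seq_len(n), ntr)
  k <- sequence(ntr)
  ends <- cs[cbind(hap, k)]
  ends[k == ntr[hap]] <- L
  starts <- c(0, ends[-length(ends)])
  starts[k == 1L] <- 0
  state <- ifelse(k %% 2L == 1L, s0[hap], 1L - s0[hap])
  data.frame(hap = hap, startCM = starts, endCM = ends, state = as.integer(state))
}

#' Lay down truth ancestry tracts
#'
#' Simulates the two-state ancestry process along every admixed
#' haplotype and chromosome. Tracts tile each chromosome exactly.
#'
#' @param config a [simulationConfig()] (or compatible list).
#' @return data.frame with columns `individual`, `haplotype`, `chrom`,
#'   `startCM`, `endCM`, `state` (1 = hunter-gatherer, 0 = farmer).
#' @export
layTracts <- function(config) {
  pl <- rep(2L, config$nAdmixed)
  pl[config$haploidIndividuals] <- 1L
  ind <- rep(sprintf("adm%03d", seq_len(config$nAdmixed)), pl)
  hapNo <- unlist(lapply(pl, seq_len)) - 1L
  haps <- paste0(ind, ".", hapNo)
  out <- vector("list", config$nChrom)
  for (c in seq_len(config$nChrom)) {
    tr <- simTractBatch(
      length(haps), config$chromLengthCM, config$generations, config$p
    )
    out[[c]] <- data.frame(
      individual = ind[tr$hap], haplotype = haps[tr$hap],
      chrom = as.character(c), startCM = tr$startCM, endCM = tr$endCM,
      state = tr$state, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

## internal: replace [a, b] of one haplotype's tract list by a forced
## state, merging adjacent same-state tracts afterwards
spliceInterval <- function(tr, a, b, state) {
  keepL <- tr[tr$startCM < a, , drop = FALSE]
  if (nrow(keepL) > 0L) keepL$endCM <- pmin(keepL$endCM, a)
  keepR <- tr[tr$endCM > b, , drop = FALSE]
  if (nrow(keepR) > 0L) keepR$startCM <- pmax(keepR$startCM, b)
  mid <- tr[1L, , drop = FALSE]
  mid$startCM <- a
  mid$endCM <- b
  mid$state <- state
  out <- rbind(keepL, mid, keepR)
  out <- out[out$endCM > out$startCM, , drop = FALSE]
  out <- out[order(out$startCM), , drop = FALSE]
  same <- c(FALSE, out$state[-1L] == out$state[-nrow(out)])
  grp <- cumsum(!same)
  if (any(same)) {
    first <- !duplicated(grp)
    merged <- out[first, , drop = FALSE]
    merged$endCM <- tapply(out$endCM, grp, max)
    out <- merged
  }
  out
}

#' Inject local ancestry deviations into truth tracts
#'
#' Within `radiusCM` of each locus, haplotypes are resampled so that the
#' local hunter-gatherer probability equals `p + delta` at the locus,
#' tapering linearly to `p` at the radius edge. Each affected haplotype
#' is overridden on one contiguous interval, so tract structure stays
#' blocky. Outside all loci the truth is unchanged; `delta = 0` is the
#' identity.
#'
#' @param truth tract data.frame from [layTracts()].
#' @param selectionLoci `data.frame(chrom, posCM, delta, radiusCM)`.
#' @param p genome-wide hunter-gatherer proportion.
#' @return Modified tract data.frame.
#' @export
injectSelection <- function(truth, selectionLoci, p) {
  if (is.null(selectionLoci) || nrow(selectionLoci) == 0L) {
    return(truth)
  }
  if (any(p + selectionLoci$delta <= 0 | p + selectionLoci$delta >= 1)) {
    stop("p + delta must stay inside (0, 1) at every selection locus")
  }
  for (i in seq_len(nrow(selectionLoci))) {
    delta <- selectionLoci$delta[i]
    if (delta == 0) next
    ch <- as.character(selectionLoci$chrom[i])
    x0 <- selectionLoci$posCM[i]
    r <- selectionLoci$radiusCM[i]
    onChrom <- truth$chrom == ch
    haps <- unique(truth$haplotype[onChrom])
    q <- if (delta > 0) delta / (1 - p) else -delta / p
    force <- if (delta > 0) 1L else 0L
    V <- runif(length(haps))
    hit <- which(V < q)
    if (length(hit) == 0L) next
    w <- r * (1 - V[hit] / q)
    pieces <- split(
      which(onChrom),
      factor(truth$haplotype[onChrom], levels = haps)
    )
    repl <- vector("list", length(hit))
    dropIdx <- integer(0)
    for (k in seq_along(hit)) {
      idx <- pieces[[hit[k]]]
      a <- max(0, x0 - w[k])
      b <- min(max(truth$endCM[idx]), x0 + w[k])
      repl[[k]] <- spliceInterval(truth[idx, , drop = FALSE], a, b, force)
      dropIdx <- c(dropIdx, idx)
    }
    truth <- rbind(truth[-dropIdx, , drop = FALSE], do.call(rbind, repl))
  }
  ord <- order(truth$haplotype, truth$chrom, truth$startCM)
  rownames(truth) <- NULL
  truth[ord, , drop = FALSE]
}

## internal: per-site truth labels from tracts, sites x haplotypes
## (column-major so that per-haplotype writes are contiguous)
labelsFromTractsT <- function(truth, panel, hapIds) {
  S <- nSites(panel)
  lab <- matrix(LBL_MISSING, S, length(hapIds))
  chrom <- siteChrom(panel)
  cm <- siteCM(panel)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- truth[truth$chrom == ch, , drop = FALSE]
    idxByHap <- split(seq_len(nrow(sub)), factor(sub$haplotype, levels = hapIds))
    for (h in seq_along(hapIds)) {
      tr <- sub[idxByHap[[h]], , drop = FALSE]
      if (nrow(tr) == 0L) next
      tr <- tr[order(tr$startCM), , drop = FALSE]
      lab[sel, h] <- tr$state[findInterval(cm[sel], tr$startCM)]
    }
  }
  lab
}

## internal: haplotypes x sites view used by tests and callers
labelsFromTracts <- function(truth, panel, hapIds) {
  out <- t(labelsFromTractsT(truth, panel, hapIds))
  rownames(out) <- hapIds
  out
}

#' Emit genotypes (and matched truth calls) from truth tracts
#'
#' Each haplotype allele is drawn from its tract's source-population
#' frequency; genotype errors flip alleles; phase-switch points (Poisson
#' along the chromosome) swap the two haplotypes of a diploid downstream
#' of each point, in both the emitted alleles and the returned truth
#' labels (so the truth matches the emitted phasing); pseudohaploid mode
#' collapses each diploid to one random allele per site.
#'
#' @param truth tract data.frame ([layTracts()], possibly after
#'   [injectSelection()]).
#' @param freqs source frequencies from [simulateSourceFrequencies()].
#' @param config the [simulationConfig()].
#' @return `list(panel, genotypes, truthCalls)`; `truthCalls` is an
#'   [AncestryCalls-class] aligned with the emitted haplotypes.
#' @export
emitGenotypes <- function(truth, freqs, config) {
  panel <- simSitePanel(config)
  hapIds <- unique(truth$haplotype)
  ind <- sub("\\.[0-9]+$", "", hapIds)
  ## sites x haplotypes internally: column-major R storage makes the
  ## per-site frequency recycling and per-haplotype swaps contiguous
  labT <- labelsFromTractsT(truth, panel, hapIds)
  S <- nrow(labT)
  H <- ncol(labT)
  pmat <- matrix(freqs$fF, S, H)
  selHG <- labT == 1L
  pmat[selHG] <- matrix(freqs$fHG, S, H)[selHG]
  allT <- (runif(S * H) < pmat) + 0L
  dim(allT) <- c(S, H)
  if (config$genotypeErrorRate > 0) {
    flip <- runif(S * H) < config$genotypeErrorRate
    allT[flip] <- 1L - allT[flip]
  }

  ## phase-switch error: swap the diploid's haplotype labels downstream
  ## of Poisson points (applies to alleles and to the aligned truth)
  chrom <- siteChrom(panel)
  cm <- siteCM(panel)
  tabInd <- table(ind)[unique(ind)]
  nSwitchPts <- 0L
  if (config$phaseSwitchRate > 0) {
    for (id in names(tabInd)[tabInd == 2L]) {
      cols <- which(ind == id)
      for (ch in unique(chrom)) {
        sel <- which(chrom == ch)
        L <- max(cm[sel])
        npt <- rpois(1L, config$phaseSwitchRate * L)
        nSwitchPts <- nSwitchPts + npt
        if (npt == 0L) next
        pts <- sort(runif(npt, 0, L))
        swap <- sel[findInterval(cm[sel], pts) %% 2L == 1L]
        if (length(swap) == 0L) next
        tmp <- allT[swap, cols[1L]]
        allT[swap, cols[1L]] <- allT[swap, cols[2L]]
        allT[swap, cols[2L]] <- tmp
        tmp <- labT[swap, cols[1L]]
        labT[swap, cols[1L]] <- labT[swap, cols[2L]]
        labT[swap, cols[2L]] <- tmp
      }
    }
  }

  if (config$pseudohaploid) {
    inds <- unique(ind)
    outA <- matrix(NA_integer_, S, length(inds))
    outL <- matrix(LBL_MISSING, S, length(inds))
    for (k in seq_along(inds)) {
      cols <- which(ind == inds[k])
      if (length(cols) == 1L) {
        outA[, k] <- allT[, cols]
        outL[, k] <- labT[, cols]
      } else {
        pick <- cols[(runif(S) < 0.5) + 1L]
        idx <- cbind(seq_len(S), pick)
        outA[, k] <- allT[idx]
        outL[, k] <- labT[idx]
      }
    }
    allT <- outA
    labT <- outL
    hapIds <- paste0(inds, ".0")
    ind <- inds
    pl <- setNames(rep(1L, length(inds)), inds)
  } else {
    pl <- setNames(as.integer(tabInd), names(tabInd))
  }

  af <- rowMeans(allT, na.rm = TRUE) # per-site alt frequency
  panel@maf <- pmin(af, 1 - af)
  all <- t(allT)
  rownames(all) <- hapIds
  lab <- t(labT)
  rownames(lab) <- hapIds
  geno <- GenotypeMatrix(all, individual = ind, ploidy = pl)
  calls <- AncestryCalls(lab, method = "truth", individual = ind, ploidy = pl)
  attr(geno, "phaseSwitchCount") <- nSwitchPts
  list(panel = panel, genotypes = geno, truthCalls = calls)
}

## internal: a source panel drawn directly from its population frequency
drawSourcePanel <- function(n, freqs, prefix) {
  S <- length(freqs)
  hapIds <- paste0(rep(sprintf("%s%03d", prefix, seq_len(n)), each = 2L), ".", 0:1)
  mat <- matrix((runif(2L * n * S) < rep(freqs, each = 2L * n)) * 1L,
    2L * n, S,
    dimnames = list(hapIds, NULL)
  )
  GenotypeMatrix(mat)
}

#' Simulate a full admixed cohort with sources and truth
#'
#' Deterministic given `config$seed`: runs, in order, source-frequency
#' simulation, tract laying, selection injection, genotype emission and
#' source-panel draws under one seeded RNG stream.
#'
#' @param config a [simulationConfig()].
#' @return `list(config, panel, genotypes, sourceHG, sourceF, truth,
#'   truthCalls, freqs)`.
#' @export
simulateCohort <- function(config) {
  set.seed(config$seed)
  freqs <- simulateSourceFrequencies(config)
  truth <- layTracts(config)
  if (!is.null(config$selectionLoci)) {
    truth <- injectSelection(truth, config$selectionLoci, config$p)
  }
  em <- emitGenotypes(truth, freqs, config)
  sourceHG <- drawSourcePanel(config$nSourceHG, freqs$fHG, "hg")
  sourceF <- drawSourcePanel(config$nSourceF, freqs$fF, "anf")
  list(
    config = config, panel = em$panel, genotypes = em$genotypes,
    sourceHG = sourceHG, sourceF = sourceF, truth = truth,
    truthCalls = em$truthCalls, freqs = freqs
  )
}

#' Duplicate haploid samples into pseudo-diploids
#'
#' Diploid-only callers can then process haploid (male X) samples; use
#' [dedupMaleX()] afterwards to drop the duplicated haplotype.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @return A [GenotypeMatrix-class] where every individual has ploidy 2.
#' @export
makePseudoDiploid <- function(genotypes) {
  a <- genotypes@alleles
  ind <- genotypes@individual
  pl <- genotypes@ploidy
  ones <- names(pl)[pl == 1L]
  if (length(ones) == 0L) {
    return(genotypes)
  }
  extra <- a[paste0(ones, ".0"), , drop = FALSE]
  rownames(extra) <- paste0(ones, ".1")
  out <- rbind(a, extra)
  ind2 <- c(ind, ones)
  ord <- order(match(ind2, unique(ind)))
  GenotypeMatrix(out[ord, , drop = FALSE],
    individual = ind2[ord],
    ploidy = setNames(rep(2L, length(pl)), names(pl))
  )
}
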