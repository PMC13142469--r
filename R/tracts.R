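## Ancestry tracts: extraction from SNP-level calls, single-pulse
## exponential tract-length theory, and maximum-likelihood dating of
## the admixture pulse from tract lengths.

#' Extract ancestry tracts from SNP-level calls
#'
#' Maximal same-label runs per haplotype and chromosome, with cM lengths
#' measured between the first and last SNP of the run. Missing-call runs
#' of at most `bridge` SNPs flanked by the same label are bridged
#' (posterior filtering would otherwise shatter tracts); longer missing
#' runs break tracts. Tracts touching a chromosome end are flagged
#' censored on that side.
#'
#' @param calls an [AncestryCalls-class] at SNP level.
#' @param panel the matching [SitePanel-class].
#' @param bridge bridge missing runs of at most this many SNPs
#'   (default 2; 0 disables bridging).
#' @return data.frame with columns `individual`, `haplotype`, `chrom`,
#'   `label`, `startBp`, `endBp`, `startCM`, `endCM`, `lengthCM`,
#'   `censoredStart`, `censoredEnd`.
#' @export
extractTracts <- function(calls, panel, bridge = 2L) {
  lab <- calls@labels
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  cm <- siteCM(panel)
  haps <- rownames(lab)
  ind <- calls@individual
  res <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    n <- length(sel)
    for (h in seq_along(haps)) {
      v <- lab[h, sel]
      if (bridge > 0L) {
        r <- rle(as.vector(v))
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        fix <- which(
          r$values == LBL_MISSING & r$lengths <= bridge &
            seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
        )
        for (k in fix) {
          if (r$values[k - 1L] == r$values[k + 1L] &&
            r$values[k - 1L] != LBL_MISSING) {
            v[s[k]:e[k]] <- r$values[k - 1L]
          }
        }
      }
      r <- rle(as.vector(v))
      e <- cumsum(r$lengths)
      s <- e - r$lengths + 1L
      keep <- r$values != LBL_MISSING
      if (!any(keep)) next
      s <- s[keep]
      e <- e[keep]
      res[[length(res) + 1L]] <- data.frame(
        individual = ind[h], haplotype = haps[h], chrom = ch,
        label = r$values[keep],
        startBp = pos[sel[s]], endBp = pos[sel[e]],
        startCM = cm[sel[s]], endCM = cm[sel[e]],
        censoredStart = s == 1L, censoredEnd = e == n,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out$lengthCM <- out$endCM - out$startCM
  rownames(out) <- NULL
  out[, c(
    "individual", "haplotype", "chrom", "label", "startBp", "endBp",
    "startCM", "endCM", "lengthCM", "censoredStart", "censoredEnd"
  )]
}

#' Convert truth tracts to the extracted-tract schema
#'
#' @param truth tract data.frame from [layTracts()].
#' @return data.frame in the [extractTracts()] schema (bp at 1 cM/Mb),
#'   with exact cM endpoints and chromosome-end censoring flags.
#' @export
truthTractSet <- function(truth) {
  maxEnd <- stats::ave(truth$endCM, truth$chrom, FUN = max)
  data.frame(
    individual = truth$individual, haplotype = truth$haplotype,
    chrom = truth$chrom, label = truth$state,
    startBp = as.integer(round(truth$startCM * 1e6)),
    endBp = as.integer(round(truth$endCM * 1e6)),
    startCM = truth$startCM, endCM = truth$endCM,
    lengthCM = truth$endCM - truth$startCM,
    censoredStart = truth$startCM == 0,
    censoredEnd = truth$endCM == maxEnd,
    stringsAsFactors = FALSE
  )
}

#' Theoretical probability of a tract-length bin
#'
#' Under the single-pulse model, `P(bin) = exp(-lambda * bStart) -
#' exp(-lambda * bEnd)`; bins partitioning \[0, Inf) sum to 1.
#'
#' @param model a [SinglePulseModel-class].
#' @param bStart,bEnd bin edges in cM (`bEnd = Inf` allowed); vectors
#'   are recycled elementwise.
#' @return Bin probabilities.
#' @examples
#' m <- singlePulseModel(35, 0.2)
#' binProbability(m, 0, 10) # 1 - exp(-2.8)
#' @export
binProbability <- function(model, bStart, bEnd) {
  stopifnot(all(bStart >= 0), all(bEnd > bStart))
  lam <- model@lambda
  exp(-lam * bStart) - ifelse(is.infinite(bEnd), 0, exp(-lam * bEnd))
}

#' Expected tract counts per length bin
#'
#' @param model a [SinglePulseModel-class].
#' @param binEdges increasing edges in cM; the final open tail
#'   `[max edge, Inf)` is appended automatically when the last edge is
#'   finite.
#' @param nTracts total tract count.
#' @return data.frame with `bStart`, `bEnd`, `prob`, `expected`.
#' @export
expectedCounts <- function(model, binEdges, nTracts) {
  stopifnot(!is.unsorted(binEdges, strictly = TRUE))
  if (is.finite(binEdges[length(binEdges)])) {
    binEdges <- c(binEdges, Inf)
  }
  b0 <- binEdges[-length(binEdges)]
  b1 <- binEdges[-1L]
  p <- binProbability(model, b0, b1)
  data.frame(bStart = b0, bEnd = b1, prob = p, expected = nTracts * p)
}

#' Fit generations-since-admixture from tract lengths
#'
#' Maximum likelihood under the single-pulse model: tracts of the focal
#' ancestry with observed length at least `minLengthCM` contribute an
#' exponential density term if uncensored and a survival term if they
#' touch a chromosome end, both conditioned on exceeding the length
#' threshold; `lambda = T * (1 - pPop) / 100`. `T` is found by 1-D
#' likelihood optimization on `Tlim`, with a 95% profile-likelihood
#' confidence interval.
#'
#' @param tracts tract data.frame ([extractTracts()] schema).
#' @param pPop genome-wide proportion of the focal ancestry.
#' @param minLengthCM exclude tracts shorter than this (default 10 cM,
#'   suppressing phasing/genotype-noise fragments).
#' @param ancestry focal label to keep (default 1 = hunter-gatherer);
#'   `NULL` uses all supplied tracts.
#' @param Tlim optimization bounds for `T` in generations.
#' @return list with `T`, `CI`, `logLik`, `lambda`, `nTracts`,
#'   `nExcluded`, `nCensored`.
#' @export
fitSinglePulse <- function(tracts, pPop, minLengthCM = 10, ancestry = 1L,
                           Tlim = c(1, 500)) {
  stopifnot(minLengthCM >= 0, pPop > 0, pPop < 1)
  if (!is.null(ancestry)) {
    tracts <- tracts[tracts$label == ancestry, , drop = FALSE]
  }
  len <- tracts$lengthCM
  keep <- len >= minLengthCM
  nExcluded <- sum(!keep)
  if (!any(keep)) {
    stop(
      "no tracts at or above ", minLengthCM, " cM (",
      nExcluded, " excluded)"
    )
  }
  x <- len[keep] - minLengthCM
  cens <- (tracts$censoredStart | tracts$censoredEnd)[keep]
  nUnc <- sum(!cens)
  sumX <- sum(x)
  ll <- function(Tg) {
    lam <- Tg * (1 - pPop) / 100
    nUnc * log(lam) - lam * sumX
  }
  opt <- optimize(ll, interval = Tlim, maximum = TRUE, tol = 1e-10)
  That <- opt$maximum
  llMax <- opt$objective
  if (nUnc == 0L || min(That - Tlim[1L], Tlim[2L] - That) < 1e-4) {
    warning(
      "fitSinglePulse: estimate at the boundary of [",
      Tlim[1L], ", ", Tlim[2L], "] (", nUnc, " uncensored tracts); ",
      "the data carry little information about T"
    )
    That <- if (nUnc == 0L) Tlim[1L] else That
    llMax <- ll(That)
  }
  cut <- llMax - qchisq(0.95, 1) / 2
  lo <- if (ll(Tlim[1L]) >= cut) {
    Tlim[1L]
  } else {
    uniroot(function(t) ll(t) - cut, c(Tlim[1L], That))$root
  }
  hi <- if (ll(Tlim[2L]) >= cut) {
    Tlim[2L]
  } else {
    uniroot(function(t) ll(t) - cut, c(That, Tlim[2L]))$root
  }
  list(
    T = That, CI = c(lower = lo, upper = hi), logLik = llMax,
    lambda = That * (1 - pPop) / 100,
    nTracts = sum(keep), nExcluded = nExcluded, nCensored = sum(cens)
  )
}

#' Matched quantiles of log10 tract lengths
#'
#' @param lengthsA,lengthsB tract lengths in cM.
#' @param probs quantile grid (default percentiles 1-99).
#' @return data.frame with `prob`, `qA`, `qB` (log10 cM).
#' @export
qqCompare <- function(lengthsA, lengthsB, probs = seq(0.01, 0.99, by = 0.01)) {
  data.frame(
    prob = probs,
    qA = quantile(log10(lengthsA), probs, names = FALSE),
    qB = quantile(log10(lengthsB), probs, names = FALSE)
  )
}
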