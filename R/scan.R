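## The ancestry-deviation scan: sliding-window Z-scores per method, a
## covariance-corrected combined Z, masking, candidate-region calling,
## replication and the low-ancestry misclassification diagnostic.

#' Scan configuration
#'
#' @param windowSnps sliding-window size in SNPs (odd, >= 3; default 51).
#' @param step window step in SNPs (default 1).
#' @param discoveryZ discovery threshold on |combined Z| (default 3).
#' @param mergeBp supra-threshold windows whose lead SNPs lie within
#'   this distance merge into one region (default 1 Mb).
#' @param replicationRadius replication is sought within this distance
#'   of the discovery lead SNP (default 2 Mb).
#' @param replicationZ replication threshold on |Z| (default 2.84, the
#'   published Bonferroni constant for 10 discovery hits; see
#'   [pToZThreshold()] for the formulaic route).
#' @param sided sidedness for p-value conversion (default two-sided).
#' @param minCallRate SNPs with a lower call rate are dropped from the
#'   mean-ancestry track (default 0.5).
#' @param masks optional `GRanges` of excluded regions.
#' @return Configuration list.
#' @export
scanConfig <- function(windowSnps = 51L, step = 1L, discoveryZ = 3,
                       mergeBp = 1e6, replicationRadius = 2e6,
                       replicationZ = 2.84, sided = "two.sided",
                       minCallRate = 0.5, masks = NULL) {
  windowSnps <- as.integer(windowSnps)
  stopifnot(
    windowSnps >= 3L, windowSnps %% 2L == 1L, step >= 1L,
    discoveryZ > 0, replicationRadius > 0
  )
  list(
    windowSnps = windowSnps, step = as.integer(step),
    discoveryZ = discoveryZ, mergeBp = mergeBp,
    replicationRadius = replicationRadius, replicationZ = replicationZ,
    sided = sided, minCallRate = minCallRate, masks = masks
  )
}

#' Per-SNP population mean hunter-gatherer ancestry
#'
#' @param calls an [AncestryCalls-class].
#' @param minCallRate SNPs with fewer non-missing calls than this
#'   fraction of haplotypes become missing (reported via message).
#' @return Numeric vector over sites.
#' @export
snpMeanAncestry <- function(calls, minCallRate = 0.5) {
  lab <- calls@labels
  nHG <- colSums(lab == LBL_HG)
  nTot <- colSums(lab != LBL_MISSING)
  out <- ifelse(nTot > 0, nHG / nTot, NA_real_)
  low <- nTot < minCallRate * nrow(lab)
  if (any(low)) {
    message("snpMeanAncestry: ", sum(low), " SNP(s) below ", minCallRate,
      " call rate set to missing")
    out[low] <- NA_real_
  }
  out
}

#' Sliding-window ancestry Z-scores
#'
#' The window statistic is the mean of per-SNP population means over
#' `windowSnps` consecutive SNPs; `Z = (window statistic - genome-wide
#' mean of per-SNP means) / SD of the window statistic over all unmasked
#' windows`, which makes the track self-standardized (null SD close
#' to 1). Windows overlapping a mask, truncated by a chromosome end, or
#' with under half their SNPs informative are masked. A constant track
#' (zero SD) masks everything with a warning rather than dividing by
#' zero.
#'
#' @param snpMeans per-SNP means from [snpMeanAncestry()].
#' @param panel the matching [SitePanel-class].
#' @param config a [scanConfig()].
#' @return data.frame with `chrom`, `leadIdx` (panel index of the
#'   central SNP), `leadBp`, `stat`, `Z`, `masked`.
#' @export
windowZ <- function(snpMeans, panel, config = scanConfig()) {
  w <- config$windowSnps
  half <- (w - 1L) %/% 2L
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  rows <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    n <- length(sel)
    if (n < w) {
      warning("windowZ: chromosome ", ch, " has fewer than ", w,
        " SNPs; all windows masked")
      next
    }
    v <- snpMeans[sel]
    ok <- !is.na(v)
    v0 <- ifelse(ok, v, 0)
    cs <- c(0, cumsum(v0))
    cn <- c(0, cumsum(ok))
    startIdx <- seq(1L, n - w + 1L, by = config$step)
    cnt <- cn[startIdx + w] - cn[startIdx]
    stat <- ifelse(cnt > 0, (cs[startIdx + w] - cs[startIdx]) / cnt, NA_real_)
    lead <- sel[startIdx + half]
    masked <- cnt < ceiling(w / 2)
    if (!is.null(config$masks)) {
      winR <- IRanges::IRanges(pos[sel[startIdx]], pos[sel[startIdx + w - 1L]])
      mk <- config$masks[as.character(GenomicRanges::seqnames(config$masks)) == ch]
      if (length(mk) > 0L) {
        hits <- IRanges::overlapsAny(winR, IRanges::ranges(mk))
        masked <- masked | hits
      }
    }
    rows[[ch]] <- data.frame(
      chrom = ch, leadIdx = lead, leadBp = pos[lead],
      stat = stat, masked = masked, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      chrom = character(0), leadIdx = integer(0), leadBp = integer(0),
      stat = numeric(0), Z = numeric(0), masked = logical(0)
    ))
  }
  rownames(out) <- NULL
  use <- !out$masked & !is.na(out$stat)
  sdW <- if (sum(use) >= 2L) sd(out$stat[use]) else 0
  if (!is.finite(sdW) || sdW < 1e-12) {
    warning("windowZ: constant ancestry track; all windows masked")
    out$masked <- TRUE
    out$Z <- NA_real_
    return(out[, c("chrom", "leadIdx", "leadBp", "stat", "Z", "masked")])
  }
  gm <- mean(snpMeans, na.rm = TRUE)
  out$Z <- ifelse(out$masked, NA_real_, (out$stat - gm) / sdW)
  out[, c("chrom", "leadIdx", "leadBp", "stat", "Z", "masked")]
}

#' Estimate the method covariance matrix of window Z-scores
#'
#' Computed genome-wide over windows unmasked in every method. Negative
#' eigenvalues (numerically possible only after external editing) are
#' floored at zero with a message.
#'
#' @param zMatrix windows x methods matrix of Z-scores (`NA` = masked).
#' @param type `"covariance"` (as defined) or `"correlation"`.
#' @return Symmetric positive semidefinite matrix.
#' @export
estimateMethodCovariance <- function(zMatrix, type = c("covariance", "correlation")) {
  type <- match.arg(type)
  ok <- complete.cases(zMatrix)
  if (sum(ok) < 2L) stop("fewer than 2 jointly unmasked windows")
  S <- if (type == "covariance") cov(zMatrix[ok, , drop = FALSE]) else cor(zMatrix[ok, , drop = FALSE])
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    message("estimateMethodCovariance: flooring negative eigenvalues at 0")
    S <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(S)) %*% t(ev$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

#' Covariance-corrected combined Z-score
#'
#' `Z_combined(w) = sum_i Z_i(w) / sqrt(1' Sigma 1)`. With `Sigma = I`
#' this is Stouffer's method; with perfectly correlated methods it
#' returns the shared score unchanged. Windows where any method is
#' masked are masked (`renormalize = TRUE` instead rescales over the
#' available methods).
#'
#' @param zMatrix windows x methods matrix of Z-scores (`NA` = masked).
#' @param Sigma method covariance; estimated from `zMatrix` when `NULL`.
#' @param renormalize combine partially masked windows over the
#'   available methods.
#' @return Numeric vector of combined Z (NA where masked).
#' @export
combineZ <- function(zMatrix, Sigma = NULL, renormalize = FALSE) {
  zMatrix <- as.matrix(zMatrix)
  stopifnot(ncol(zMatrix) >= 2L)
  if (is.null(Sigma)) Sigma <- estimateMethodCovariance(zMatrix)
  denom <- sqrt(sum(Sigma))
  full <- complete.cases(zMatrix)
  out <- rep(NA_real_, nrow(zMatrix))
  out[full] <- rowSums(zMatrix[full, , drop = FALSE]) / denom
  if (renormalize) {
    part <- !full & rowSums(!is.na(zMatrix)) > 0L
    for (i in which(part)) {
      av <- which(!is.na(zMatrix[i, ]))
      out[i] <- sum(zMatrix[i, av]) / sqrt(sum(Sigma[av, av]))
    }
  }
  out
}

#' Convert a Z-score to a p-value
#'
#' @param z Z-score(s).
#' @param sided `"two.sided"` (default): `2 * (1 - Phi(|z|))`;
#'   `"one.sided"`: upper-tail `1 - Phi(z)`.
#' @return p-value(s).
#' @export
zToP <- function(z, sided = c("two.sided", "one.sided")) {
  sided <- match.arg(sided)
  if (sided == "two.sided") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
}

#' Bonferroni-corrected Z threshold for a p-value cutoff
#'
#' @param alpha family-wise alpha.
#' @param nTests number of tests (Bonferroni divisor).
#' @param sided `"two.sided"` or `"one.sided"`.
#' @return Z threshold (`qnorm(1 - a/2)` or `qnorm(1 - a)` with
#'   `a = alpha / nTests`).
#' @export
pToZThreshold <- function(alpha, nTests = 1, sided = c("two.sided", "one.sided")) {
  sided <- match.arg(sided)
  a <- alpha / nTests
  if (sided == "two.sided") qnorm(1 - a / 2) else qnorm(1 - a)
}

#' Call candidate regions from a combined Z track
#'
#' Windows with `|Z|` above the discovery threshold merge into one
#' region when their lead SNPs lie within `mergeBp`; the region's lead
#' SNP is the window attaining the maximum `|Z|`, and the sign of Z is
#' reported (positive = excess hunter-gatherer ancestry).
#'
#' @param windows data.frame with `chrom`, `leadBp`, `Z` (e.g. the
#'   [windowZ()] frame with the combined Z substituted).
#' @param config a [scanConfig()] (uses `discoveryZ` and `mergeBp`).
#' @return data.frame of regions: `chrom`, `leadBp`, `Z`, `p`, `sign`,
#'   `startBp`, `endBp`, `nWindows`.
#' @export
callCandidateRegions <- function(windows, config = scanConfig()) {
  supra <- which(!is.na(windows$Z) & abs(windows$Z) > config$discoveryZ)
  if (length(supra) == 0L) {
    return(data.frame(
      chrom = character(0), leadBp = integer(0), Z = numeric(0),
      p = numeric(0), sign = integer(0), startBp = integer(0),
      endBp = integer(0), nWindows = integer(0)
    ))
  }
  sub <- windows[supra, , drop = FALSE]
  ord <- order(sub$chrom, sub$leadBp)
  sub <- sub[ord, , drop = FALSE]
  newRegion <- c(
    TRUE,
    sub$chrom[-1L] != sub$chrom[-nrow(sub)] |
      diff(sub$leadBp) > config$mergeBp
  )
  grp <- cumsum(newRegion)
  res <- lapply(split(seq_len(nrow(sub)), grp), function(idx) {
    s <- sub[idx, , drop = FALSE]
    lead <- which.max(abs(s$Z))
    data.frame(
      chrom = s$chrom[lead], leadBp = s$leadBp[lead], Z = s$Z[lead],
      p = zToP(s$Z[lead], config$sided), sign = sign(s$Z[lead]),
      startBp = min(s$leadBp), endBp = max(s$leadBp),
      nWindows = nrow(s), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test discovery regions for replication
#'
#' A region replicates iff some window of the replication track within
#' `replicationRadius` of the discovery lead SNP has `|Z| >=
#' replicationZ` with matching sign.
#'
#' @param regions [callCandidateRegions()] output.
#' @param replWindows replication-track window frame (`chrom`, `leadBp`,
#'   `Z`).
#' @param config a [scanConfig()].
#' @return `regions` with columns `replicated` (logical) and `bestReplZ`
#'   (best matching-sign replication Z; `NA` when no window matches the
#'   sign).
#' @export
replicateRegions <- function(regions, replWindows, config = scanConfig()) {
  regions$replicated <- FALSE
  regions$bestReplZ <- NA_real_
  for (i in seq_len(nrow(regions))) {
    cand <- replWindows[
      replWindows$chrom == regions$chrom[i] &
        abs(replWindows$leadBp - regions$leadBp[i]) <= config$replicationRadius &
        !is.na(replWindows$Z), ,
      drop = FALSE
    ]
    match <- cand[sign(cand$Z) == regions$sign[i], , drop = FALSE]
    if (nrow(match) > 0L) {
      best <- match$Z[which.max(abs(match$Z))]
      regions$bestReplZ[i] <- best
      regions$replicated[i] <- abs(best) >= config$replicationZ
    }
  }
  regions
}

#' Low-ancestry subset diagnostic for candidate regions
#'
#' Individuals close to the admixture pulse (low reference global
#' ancestry) have had little time for selection to act, so a true
#' selection signal should shrink in that subset; deviations that stay
#' high suggest systematic ancestry misclassification. Per region, the
#' deviation is the mean local hunter-gatherer ancestry over a
#' `windowSnps`-SNP window at the lead SNP minus the group's own
#' genome-wide mean, computed for the full cohort and for the subset
#' with reference ancestry below `cutoff`.
#'
#' @param calls an [AncestryCalls-class].
#' @param regions [callCandidateRegions()] output.
#' @param panel the matching [SitePanel-class].
#' @param referenceGlobal named reference global-ancestry estimates.
#' @param cutoff subset threshold (default 0.1).
#' @param ratio a region is `"selection-consistent"` when
#'   `|deviation(subset)| < |deviation(full)| * ratio` (default 0.5),
#'   else `"misclassification-suspect"`.
#' @param windowSnps window size around the lead SNP (default 51).
#' @return `regions` with `devFull`, `devSubset`, `nSubset`, `verdict`.
#' @export
lowAncestryDiagnostic <- function(calls, regions, panel, referenceGlobal,
                                  cutoff = 0.1, ratio = 0.5,
                                  windowSnps = 51L) {
  lab <- calls@labels
  subInd <- names(referenceGlobal)[referenceGlobal < cutoff]
  inSub <- calls@individual %in% subInd
  if (!any(inSub)) {
    warning("no individuals below the ancestry cutoff ", cutoff)
  }
  groupDev <- function(rows, siteIdx) {
    m <- lab[rows, , drop = FALSE]
    gm <- sum(m == LBL_HG) / sum(m != LBL_MISSING)
    loc <- m[, siteIdx, drop = FALSE]
    local <- sum(loc == LBL_HG) / max(sum(loc != LBL_MISSING), 1L)
    local - gm
  }
  half <- (windowSnps - 1L) %/% 2L
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  regions$devFull <- NA_real_
  regions$devSubset <- NA_real_
  for (i in seq_len(nrow(regions))) {
    sel <- which(chrom == regions$chrom[i])
    center <- sel[which.min(abs(pos[sel] - regions$leadBp[i]))]
    rank <- match(center, sel)
    siteIdx <- sel[max(1L, rank - half):min(length(sel), rank + half)]
    regions$devFull[i] <- groupDev(seq_len(nrow(lab)), siteIdx)
    if (any(inSub)) {
      regions$devSubset[i] <- groupDev(which(inSub), siteIdx)
    }
  }
  regions$nSubset <- length(unique(calls@individual[inSub]))
  regions$verdict <- ifelse(
    abs(regions$devSubset) < abs(regions$devFull) * ratio,
    "selection-consistent", "misclassification-suspect"
  )
  regions
}

#' Run the full multi-method deviation scan
#'
#' Computes per-method SNP mean-ancestry tracks, sliding-window
#' Z-scores, the genome-wide method covariance, the combined Z track and
#' candidate regions.
#'
#' @param callsList named list of [AncestryCalls-class], one per method.
#' @param panel the shared [SitePanel-class].
#' @param config a [scanConfig()].
#' @param biasCorrect apply [correctChromosomeBias()] to each per-SNP
#'   mean track first.
#' @return list with `windows` (frame with one Z column per method plus
#'   `combinedZ`), `Sigma`, `regions`, `config`.
#' @export
scanDeviation <- function(callsList, panel, config = scanConfig(),
                          biasCorrect = FALSE) {
  stopifnot(length(callsList) >= 2L, !is.null(names(callsList)))
  perMethod <- lapply(callsList, function(cl) {
    m <- snpMeanAncestry(cl, config$minCallRate)
    if (biasCorrect) m <- correctChromosomeBias(m, siteChrom(panel))
    windowZ(m, panel, config)
  })
  base <- perMethod[[1L]][, c("chrom", "leadIdx", "leadBp")]
  zMat <- do.call(cbind, lapply(perMethod, `[[`, "Z"))
  colnames(zMat) <- names(callsList)
  Sigma <- estimateMethodCovariance(zMat)
  combined <- combineZ(zMat, Sigma)
  windows <- cbind(base, as.data.frame(zMat), combinedZ = combined)
  regWin <- data.frame(
    chrom = base$chrom, leadBp = base$leadBp, Z = combined,
    stringsAsFactors = FALSE
  )
  regions <- callCandidateRegions(regWin, config)
  list(windows = windows, Sigma = Sigma, regions = regions, config = config)
}
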