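## Agreement between ancestry-call tracks in genomic bins, at the
## population and the individual level.

#' Mean hunter-gatherer ancestry in genomic bins
#'
#' Bins are half-open, anchored at position 1 of each chromosome. The
#' population-level track averages the hunter-gatherer indicator over
#' all non-missing haplotype-site calls in the bin; the individual level
#' returns one row per individual. Empty bins (or zero non-missing
#' calls) are missing.
#'
#' @param calls an [AncestryCalls-class].
#' @param panel the matching [SitePanel-class].
#' @param width bin width in bp (10 kb to 100 Mb are the usual grids).
#' @param level `"population"` or `"individual"`.
#' @return For `"population"`: data.frame `chrom`, `binStart`, `binEnd`,
#'   `value`. For `"individual"`: the same frame plus a
#'   `individuals x bins` matrix in attribute `"matrix"` is replaced by
#'   a list with elements `bins` (frame) and `values` (matrix).
#' @export
binAncestry <- function(calls, panel, width,
                        level = c("population", "individual")) {
  level <- match.arg(level)
  stopifnot(width >= 1)
  lab <- calls@labels
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  bin <- paste(chrom, (pos - 1) %/% width)
  ubin <- unique(bin) # panel order = genomic order
  f <- factor(bin, levels = ubin)
  starts <- tapply((pos - 1) %/% width * width + 1, f, `[`, 1L)
  chroms <- tapply(chrom, f, `[`, 1L)
  frame <- data.frame(
    chrom = as.vector(chroms),
    binStart = as.vector(starts),
    binEnd = as.vector(starts) + width - 1,
    stringsAsFactors = FALSE
  )
  if (level == "population") {
    nHG <- tapply(colSums(lab == LBL_HG), f, sum)
    nTot <- tapply(colSums(lab != LBL_MISSING), f, sum)
    frame$value <- as.vector(ifelse(nTot > 0, nHG / nTot, NA_real_))
    frame
  } else {
    ind <- factor(calls@individual, levels = unique(calls@individual))
    hg <- rowsum((lab == LBL_HG) * 1L, ind) # individuals x sites
    tot <- rowsum((lab != LBL_MISSING) * 1L, ind)
    hgB <- t(rowsum(t(hg), f)) # individuals x bins
    totB <- t(rowsum(t(tot), f))
    vals <- ifelse(totB > 0, hgB / totB, NA_real_)
    colnames(vals) <- ubin
    list(bins = frame, values = vals)
  }
}

#' Pairwise Pearson correlation of population-level binned tracks
#'
#' @param tracks named list of population-level [binAncestry()] frames
#'   on the same bin grid (or plain numeric vectors of equal length).
#' @param align `"pairwise"` (bins non-missing in both tracks of each
#'   pair) or `"complete"` (bins non-missing in all tracks).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwisePopulationCorrelation <- function(tracks, align = c("pairwise", "complete")) {
  align <- match.arg(align)
  vecs <- lapply(tracks, function(t) if (is.data.frame(t)) t$value else t)
  m <- do.call(cbind, vecs)
  use <- if (align == "pairwise") "pairwise.complete.obs" else "complete.obs"
  r <- cor(m, use = use)
  diag(r) <- 1
  r
}

#' Individual-level local-ancestry concordance
#'
#' For each individual, the Pearson correlation of its binned ancestry
#' between each pair of methods, averaged over pairs. Individuals with
#' zero ancestry variance in a pair yield an undefined correlation for
#' that pair (dropped from the average; all-undefined individuals are
#' `NA`, with a message reporting the count).
#'
#' @param tracks named list of individual-level [binAncestry()] results
#'   (each `list(bins, values)`), on the same bin grid and individuals.
#' @return Named numeric vector, one mean correlation per individual.
#' @export
individualLevelCorrelation <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  vals <- lapply(tracks, `[[`, "values")
  inds <- rownames(vals[[1L]])
  pairs <- utils::combn(length(vals), 2L)
  out <- setNames(rep(NA_real_, length(inds)), inds)
  for (i in seq_along(inds)) {
    cc <- numeric(0)
    for (k in seq_len(ncol(pairs))) {
      a <- vals[[pairs[1L, k]]][i, ]
      b <- vals[[pairs[2L, k]]][i, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) >= 2L && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
        cc <- c(cc, cor(a[ok], b[ok]))
      }
    }
    if (length(cc) > 0L) out[i] <- mean(cc)
  }
  nUndef <- sum(is.na(out))
  if (nUndef > 0L) {
    message(
      "individualLevelCorrelation: ", nUndef,
      " individual(s) with undefined correlation (zero variance)"
    )
  }
  out
}
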