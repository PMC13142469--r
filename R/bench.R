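## Global-ancestry benchmarking: per-individual proportions, comparison
## statistics against a reference estimator, and the source-subsampling
## experiment harness.

#' Per-individual genome-wide hunter-gatherer proportions
#'
#' Fraction of hunter-gatherer-labeled haplotype-site calls per
#' individual. By default the denominator is the number of non-missing
#' calls (posterior filtering creates missingness); `denominator =
#' "panel"` divides by the fixed haplotype-site count instead.
#'
#' @param calls an [AncestryCalls-class].
#' @param denominator `"nonmissing"` (default) or `"panel"`.
#' @return Named numeric vector of proportions in \[0, 1\].
#' @export
globalProportions <- function(calls, denominator = c("nonmissing", "panel")) {
  denominator <- match.arg(denominator)
  lab <- calls@labels
  ind <- factor(calls@individual, levels = unique(calls@individual))
  nHG <- rowsum(rowSums(lab == LBL_HG), ind)[, 1L]
  nTot <- if (denominator == "nonmissing") {
    rowsum(rowSums(lab != LBL_MISSING), ind)[, 1L]
  } else {
    as.vector(table(ind)) * ncol(lab)
  }
  out <- nHG / nTot
  out[nTot == 0] <- NA_real_
  out
}

#' Comparison statistics between method and reference estimates
#'
#' Pearson correlation `R`, Spearman correlation `rho`, the slope `beta`
#' of the least-squares regression of method estimates on reference
#' estimates (reference on the x-axis), and the mean absolute
#' per-individual difference `delta` (`signed = TRUE` gives the signed
#' mean difference instead). Only individuals present on both sides are
#' used; a dropped count is reported via message.
#'
#' @param method named numeric vector of method estimates.
#' @param reference named numeric vector of reference estimates.
#' @param signed use the signed mean difference for `delta`.
#' @return One-row data.frame with columns `R`, `rho`, `beta`, `delta`,
#'   `n`.
#' @export
compareToReference <- function(method, reference, signed = FALSE) {
  common <- intersect(names(method), names(reference))
  dropped <- length(method) + length(reference) - 2L * length(common)
  if (dropped > 0L) {
    message("compareToReference: dropped ", dropped, " unpaired individual(s)")
  }
  x <- reference[common]
  y <- method[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  d <- y - x
  data.frame(
    R = if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_,
    rho = if (sd(x) > 0 && sd(y) > 0) cor(x, y, method = "spearman") else NA_real_,
    beta = if (sd(x) > 0) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2) else NA_real_,
    delta = if (signed) mean(d) else mean(abs(d)),
    n = length(x)
  )
}

## internal: subset a source GenotypeMatrix to n randomly drawn individuals
subsetSourceIndividuals <- function(src, n) {
  inds <- unique(src@individual)
  if (n >= length(inds)) {
    return(src)
  }
  pick <- sample(inds, n)
  keep <- src@individual %in% pick
  GenotypeMatrix(src@alleles[keep, , drop = FALSE],
    individual = src@individual[keep]
  )
}

## internal: run one engine on a cohort with given source panels
runEngine <- function(cohort, sourceHG, sourceF, engine, engineParams = NULL) {
  if (engine == "hmm") {
    params <- engineParams %||% hmmParams(
      generations = cohort$config$generations, p = cohort$config$p
    )
    callHmm(cohort$panel, cohort$genotypes,
      colMeans(sourceHG@alleles, na.rm = TRUE),
      colMeans(sourceF@alleles, na.rm = TRUE),
      params
    )
  } else if (engine == "mismatch") {
    params <- engineParams %||% defaultMismatchParams(cohort$panel)
    callMismatch(cohort$panel, cohort$genotypes, sourceHG, sourceF, params)
  } else {
    stop("unknown engine: ", engine)
  }
}

#' Mismatch parameters with `minSites` matched to the panel density
#'
#' Keeps the published window geometry (1 Mb span, 0.5 Mb step) but
#' scales the minimum informative-site requirement to one third of the
#' expected sites per window, so sparse simulated panels remain
#' callable.
#'
#' @param panel a [SitePanel-class].
#' @return A [mismatchParams()] list.
#' @export
defaultMismatchParams <- function(panel) {
  dens <- nSites(panel) / max(sitePos(panel)) # sites per bp
  perWin <- dens * 1e6
  mismatchParams(
    minSites = max(5L, as.integer(floor(perWin / 3))),
    maxSites = 2000L
  )
}

#' Method call tracks for a simulated cohort
#'
#' Convenience harness running the in-package engines on a
#' [simulateCohort()] result: the HMM (with one frequency-refinement
#' pass by default) and the minimum-mismatch caller, both against the
#' same (optionally down-sampled) source panels.
#'
#' @param cohort a [simulateCohort()] result.
#' @param nSourceHG optional hunter-gatherer source size (individuals)
#'   drawn without replacement; `NULL` uses the full panel.
#' @param seed seed for the source draw.
#' @param refineIterations frequency-refinement passes for [callHmm()].
#' @param engines engines to run.
#' @return Named list of [AncestryCalls-class] tracks.
#' @export
cohortMethodCalls <- function(cohort, nSourceHG = NULL, seed = NULL,
                              refineIterations = 1L,
                              engines = c("hmm", "mismatch")) {
  srcHG <- cohort$sourceHG
  if (!is.null(nSourceHG)) {
    if (!is.null(seed)) set.seed(seed)
    srcHG <- subsetSourceIndividuals(srcHG, nSourceHG)
  }
  out <- list()
  if ("hmm" %in% engines) {
    hp <- hmmParams(
      generations = cohort$config$generations, p = cohort$config$p,
      panelWeightHG = nHaplotypes(srcHG),
      panelWeightF = nHaplotypes(cohort$sourceF)
    )
    out$hmm <- callHmm(cohort$panel, cohort$genotypes,
      colMeans(alleles(srcHG), na.rm = TRUE),
      colMeans(alleles(cohort$sourceF), na.rm = TRUE),
      hp,
      refineIterations = refineIterations
    )
  }
  if ("mismatch" %in% engines) {
    out$mismatch <- callMismatch(
      cohort$panel, cohort$genotypes, srcHG, cohort$sourceF,
      defaultMismatchParams(cohort$panel)
    )
  }
  out
}

#' Source-subsampling experiment
#'
#' Reruns an engine with the hunter-gatherer source panel down-sampled
#' to each requested size (drawn without replacement per seed) and
#' tabulates [compareToReference()] statistics of the per-individual
#' global proportions against the reference (by default the simulation
#' truth). The recommended size minimizes mean `delta`, ties broken by
#' maximal `R`.
#'
#' @param cohort a [simulateCohort()] result.
#' @param sizes hunter-gatherer source sizes to test.
#' @param seeds integer seeds; each (size, seed) pair is one run.
#' @param engine `"hmm"` or `"mismatch"`.
#' @param reference named reference proportions; defaults to truth.
#' @param engineParams optional engine parameter list.
#' @return data.frame with one row per (size, seed) plus attribute
#'   `recommended` (the selected size).
#' @export
subsampleExperiment <- function(cohort, sizes = c(48, 7, 3, 1), seeds = 1L,
                                engine = c("hmm", "mismatch"),
                                reference = NULL, engineParams = NULL) {
  engine <- match.arg(engine)
  reference <- reference %||% globalProportions(cohort$truthCalls)
  rows <- list()
  for (seed in seeds) {
    for (n in sizes) {
      set.seed(seed)
      src <- subsetSourceIndividuals(cohort$sourceHG, n)
      calls <- runEngine(cohort, src, cohort$sourceF, engine, engineParams)
      st <- compareToReference(globalProportions(calls), reference)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(size = n, seed = seed), st
      )
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(delta, R) ~ size, data = out, FUN = mean)
  best <- agg[order(agg$delta, -agg$R), ][1L, "size"]
  attr(out, "recommended") <- best
  out
}
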