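#' @import methods
NULL

## Internal label encoding shared across the package:
##   0 = farmer, 1 = hunter-gatherer, -1 = missing.
## All ancestry proportions are hunter-gatherer fractions.
LBL_FARMER <- 0L
LBL_HG <- 1L
LBL_MISSING <- -1L

#' SitePanel: ordered site metadata shared by all tracks
#'
#' A `SitePanel` holds the per-site metadata that every genotype or
#' ancestry-call track in the package refers to: chromosome, physical
#' position (1-based bp), genetic position (cM), allele codes, cohort
#' minor-allele frequency, and an optional imputation-quality (INFO)
#' score. Sites are strictly increasing by (chromosome, bp) and genetic
#' positions are non-decreasing within a chromosome.
#'
#' @slot chrom character, chromosome id per site.
#' @slot pos integer, 1-based physical position (bp).
#' @slot cM numeric, genetic position in centimorgans.
#' @slot ref,alt character, allele codes.
#' @slot maf numeric in \[0, 0.5\], cohort minor-allele frequency.
#' @slot info numeric in \[0, 1\] or `NA`, imputation-quality score.
#'
#' @export
setClass("SitePanel",
  representation(
    chrom = "character", pos = "integer", cM = "numeric",
    ref = "character", alt = "character",
    maf = "numeric", info = "numeric"
  )
)

setValidity("SitePanel", function(object) {
  n <- length(object@pos)
  lens <- c(
    length(object@chrom), length(object@cM), length(object@ref),
    length(object@alt), length(object@maf), length(object@info)
  )
  if (any(lens != n)) {
    return("all per-site slots must have the same length")
  }
  if (n == 0L) {
    return(TRUE)
  }
  ## chromosome blocks must be contiguous
  r <- rle(object@chrom)
  if (anyDuplicated(r$values)) {
    return("sites of one chromosome must be contiguous")
  }
  for (i in seq_along(r$values)) {
    idx <- which(object@chrom == r$values[i])
    p <- object@pos[idx]
    if (any(diff(p) <= 0L)) {
      j <- idx[which(diff(p) <= 0L)[1L] + 1L]
      return(sprintf(
        "sites out of order (or duplicated) at record %d (%s:%d)",
        j, object@chrom[j], object@pos[j]
      ))
    }
    if (any(diff(object@cM[idx]) < 0)) {
      return(sprintf("cM positions decrease within chromosome %s", r$values[i]))
    }
  }
  if (any(!is.na(object@maf) & (object@maf < 0 | object@maf > 0.5))) {
    return("maf must lie in [0, 0.5]")
  }
  if (any(!is.na(object@info) & (object@info < 0 | object@info > 1))) {
    return("info must lie in [0, 1]")
  }
  TRUE
})

#' Construct a SitePanel
#'
#' @param chrom chromosome id per site.
#' @param pos 1-based physical position (bp).
#' @param cM genetic position (centimorgans); non-decreasing within a
#'   chromosome.
#' @param ref,alt allele codes (defaults `"A"`/`"G"`).
#' @param maf cohort minor-allele frequency in \[0, 0.5\] (`NA` allowed).
#' @param info imputation-quality score in \[0, 1\] (`NA` = not available).
#' @return A [SitePanel-class] object.
#' @export
SitePanel <- function(chrom, pos, cM, ref = NULL, alt = NULL,
                      maf = NULL, info = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(maf)) maf <- rep(NA_real_, n)
  if (is.null(info)) info <- rep(NA_real_, n)
  new("SitePanel",
    chrom = as.character(chrom), pos = as.integer(pos),
    cM = as.numeric(cM), ref = as.character(ref), alt = as.character(alt),
    maf = as.numeric(maf), info = as.numeric(info)
  )
}

#' @rdname SitePanel
#' @param object,x a `SitePanel`.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname SitePanel
#' @export
setMethod("nSites", "SitePanel", function(x) length(x@pos))

#' @rdname SitePanel
#' @export
setGeneric("siteChrom", function(x) standardGeneric("siteChrom"))
#' @rdname SitePanel
#' @export
setMethod("siteChrom", "SitePanel", function(x) x@chrom)

#' @rdname SitePanel
#' @export
setGeneric("sitePos", function(x) standardGeneric("sitePos"))
#' @rdname SitePanel
#' @export
setMethod("sitePos", "SitePanel", function(x) x@pos)

#' @rdname SitePanel
#' @export
setGeneric("siteCM", function(x) standardGeneric("siteCM"))
#' @rdname SitePanel
#' @export
setMethod("siteCM", "SitePanel", function(x) x@cM)

#' @rdname SitePanel
#' @export
setGeneric("siteMAF", function(x) standardGeneric("siteMAF"))
#' @rdname SitePanel
#' @export
setMethod("siteMAF", "SitePanel", function(x) x@maf)

#' @rdname SitePanel
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @rdname SitePanel
#' @export
setMethod("siteInfo", "SitePanel", function(x) x@info)

setMethod("show", "SitePanel", function(object) {
  cat(sprintf(
    "SitePanel: %d sites on %d chromosome(s) [%s]\n",
    nSites(object), length(unique(object@chrom)),
    paste(utils::head(unique(object@chrom), 5L), collapse = ", ")
  ))
})

#' Subset a SitePanel by site index
#' @param x a `SitePanel`.
#' @param i integer or logical site index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SitePanel", function(x, i, j, ..., drop = FALSE) {
  new("SitePanel",
    chrom = x@chrom[i], pos = x@pos[i], cM = x@cM[i],
    ref = x@ref[i], alt = x@alt[i], maf = x@maf[i], info = x@info[i]
  )
})

#' GenotypeMatrix: phased haplotype alleles
#'
#' Rows are haplotypes (two per diploid individual, one per haploid
#' individual, e.g. males on the X), columns are sites of the matching
#' [SitePanel-class]. Alleles are coded 0/1 with `NA` for missing.
#'
#' @slot alleles integer matrix, haplotypes x sites; rownames are
#'   haplotype ids of the form `"<individual>.0"` / `"<individual>.1"`.
#' @slot individual character, individual id per haplotype (row).
#' @slot ploidy named integer, ploidy (1 or 2) per individual.
#' @export
setClass("GenotypeMatrix",
  representation(
    alleles = "matrix", individual = "character", ploidy = "integer"
  )
)

setValidity("GenotypeMatrix", function(object) {
  a <- object@alleles
  if (!is.integer(a[1L])) {
    if (length(a) > 0L) return("alleles must be an integer matrix")
  }
  if (nrow(a) != length(object@individual)) {
    return("individual must have one entry per haplotype row")
  }
  if (nrow(a) == 0L) {
    return(TRUE) # empty panels are allowed
  }
  if (is.null(rownames(a))) {
    return("alleles must have haplotype ids as rownames")
  }
  if (length(a) > 0L) {
    mn <- suppressWarnings(min(a, na.rm = TRUE)) # Inf when all missing
    if (is.finite(mn) && (mn < 0L || max(a, na.rm = TRUE) > 1L)) {
      return("alleles must be 0, 1 or NA")
    }
  }
  tab <- table(object@individual)
  pl <- object@ploidy
  if (is.null(names(pl)) || !setequal(names(pl), names(tab))) {
    return("ploidy must be named by individual id")
  }
  if (!all(pl[names(tab)] == as.integer(tab))) {
    return("haplotype count per individual must equal its ploidy")
  }
  if (!all(pl %in% c(1L, 2L))) {
    return("ploidy must be 1 or 2")
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param alleles integer matrix (haplotypes x sites), values 0/1/`NA`,
#'   rownames `"<individual>.<k>"`.
#' @param individual individual id per row; derived from rownames when
#'   omitted.
#' @param ploidy named integer vector of per-individual ploidy; derived
#'   from the haplotype count when omitted.
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(alleles, individual = NULL, ploidy = NULL) {
  storage.mode(alleles) <- "integer"
  if (is.null(individual)) {
    individual <- sub("\\.[0-9]+$", "", rownames(alleles))
  }
  if (is.null(ploidy)) {
    tab <- table(individual)
    ploidy <- stats::setNames(as.integer(tab), names(tab))
  }
  new("GenotypeMatrix",
    alleles = alleles, individual = individual, ploidy = ploidy
  )
}

#' @rdname GenotypeMatrix
#' @param x a `GenotypeMatrix` or `AncestryCalls`.
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname GenotypeMatrix
#' @export
setMethod("alleles", "GenotypeMatrix", function(x) x@alleles)

#' @rdname GenotypeMatrix
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname GenotypeMatrix
#' @export
setMethod("nHaplotypes", "GenotypeMatrix", function(x) nrow(x@alleles))

#' @rdname GenotypeMatrix
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))
#' @rdname GenotypeMatrix
#' @export
setMethod("haplotypeIds", "GenotypeMatrix", function(x) rownames(x@alleles))

#' @rdname GenotypeMatrix
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname GenotypeMatrix
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) x@individual)

#' @rdname GenotypeMatrix
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))
#' @rdname GenotypeMatrix
#' @export
setMethod("ploidy", "GenotypeMatrix", function(x) x@ploidy)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d haplotypes (%d individuals) x %d sites; %.2f%% missing\n",
    nrow(object@alleles), length(object@ploidy), ncol(object@alleles),
    100 * mean(is.na(object@alleles))
  ))
})

#' AncestryCalls: per-haplotype, per-site ancestry labels
#'
#' The universal currency of the pipeline: a haplotypes x sites matrix of
#' ancestry labels (0 = farmer, 1 = hunter-gatherer, -1 = missing), an
#' optional matching matrix of posterior probabilities, and a method tag.
#'
#' @slot labels integer matrix, haplotypes x sites, values in
#'   \{0, 1, -1\}; rownames are haplotype ids.
#' @slot posterior numeric matrix of posterior probabilities in \[0, 1\]
#'   (same shape as `labels`), or a 0x0 matrix when the method reports
#'   no posteriors.
#' @slot method character scalar, method tag.
#' @slot individual character, individual id per haplotype.
#' @slot ploidy named integer, per-individual ploidy.
#' @export
setClass("AncestryCalls",
  representation(
    labels = "matrix", posterior = "matrix", method = "character",
    individual = "character", ploidy = "integer"
  )
)

setValidity("AncestryCalls", function(object) {
  lab <- object@labels
  if (length(lab) > 0L) {
    if (anyNA(lab)) {
      return("labels must use -1, not NA, for missing")
    }
    ## integers in [-1, 1] are exactly {-1, 0, 1}
    if (min(lab) < -1L || max(lab) > 1L) {
      return("labels must be 0 (farmer), 1 (hunter-gatherer) or -1 (missing)")
    }
  }
  if (nrow(lab) != length(object@individual)) {
    return("individual must have one entry per haplotype row")
  }
  if (is.null(rownames(lab))) {
    return("labels must have haplotype ids as rownames")
  }
  if (length(object@posterior) > 0L) {
    if (!identical(dim(object@posterior), dim(lab))) {
      return("posterior must match the shape of labels")
    }
    p <- object@posterior
    mn <- suppressWarnings(min(p, na.rm = TRUE))
    if (is.finite(mn) && (mn < 0 || max(p, na.rm = TRUE) > 1)) {
      return("posteriors must lie in [0, 1]")
    }
  }
  tab <- table(object@individual)
  pl <- object@ploidy
  if (is.null(names(pl)) || !setequal(names(pl), names(tab)) ||
    !all(pl[names(tab)] == as.integer(tab))) {
    return("ploidy must be named by individual and match haplotype counts")
  }
  TRUE
})

#' Construct an AncestryCalls object
#'
#' @param labels integer matrix of ancestry labels (0 farmer, 1
#'   hunter-gatherer, -1 missing); rownames `"<individual>.<k>"`.
#' @param posterior optional numeric matrix of posteriors (same shape).
#' @param method method tag (character scalar).
#' @param individual individual ids per row (derived from rownames when
#'   omitted).
#' @param ploidy named per-individual ploidy (derived when omitted).
#' @return An [AncestryCalls-class].
#' @export
AncestryCalls <- function(labels, posterior = NULL, method = "unknown",
                          individual = NULL, ploidy = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(individual)) {
    individual <- sub("\\.[0-9]+$", "", rownames(labels))
  }
  if (is.null(ploidy)) {
    tab <- table(individual)
    ploidy <- stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(posterior)) {
    posterior <- matrix(numeric(0), 0L, 0L)
  } else {
    dimnames(posterior) <- dimnames(labels)
  }
  new("AncestryCalls",
    labels = labels, posterior = posterior, method = method,
    individual = individual, ploidy = ploidy
  )
}

#' @rdname AncestryCalls
#' @param x an `AncestryCalls`.
#' @export
setGeneric("callLabels", function(x) standardGeneric("callLabels"))
#' @rdname AncestryCalls
#' @export
setMethod("callLabels", "AncestryCalls", function(x) x@labels)

#' @rdname AncestryCalls
#' @export
setGeneric("callPosterior", function(x) standardGeneric("callPosterior"))
#' @rdname AncestryCalls
#' @export
setMethod("callPosterior", "AncestryCalls", function(x) {
  if (length(x@posterior) == 0L) NULL else x@posterior
})

#' @rdname AncestryCalls
#' @export
setGeneric("callMethod", function(x) standardGeneric("callMethod"))
#' @rdname AncestryCalls
#' @export
setMethod("callMethod", "AncestryCalls", function(x) x@method)

#' @rdname AncestryCalls
#' @export
setMethod("nHaplotypes", "AncestryCalls", function(x) nrow(x@labels))
#' @rdname AncestryCalls
#' @export
setMethod("haplotypeIds", "AncestryCalls", function(x) rownames(x@labels))
#' @rdname AncestryCalls
#' @export
setMethod("individualIds", "AncestryCalls", function(x) x@individual)
#' @rdname AncestryCalls
#' @export
setMethod("ploidy", "AncestryCalls", function(x) x@ploidy)

setMethod("show", "AncestryCalls", function(object) {
  cat(sprintf(
    "AncestryCalls [%s]: %d haplotypes x %d sites; %.2f%% missing; %s\n",
    object@method, nrow(object@labels), ncol(object@labels),
    100 * mean(object@labels == LBL_MISSING),
    if (length(object@posterior) > 0L) "with posteriors" else "no posteriors"
  ))
})

## internal: subset haplotype rows, keeping ploidy bookkeeping consistent
subsetCallsHaps <- function(calls, keep) {
  lab <- calls@labels[keep, , drop = FALSE]
  post <- if (length(calls@posterior) > 0L) {
    calls@posterior[keep, , drop = FALSE]
  } else {
    NULL
  }
  ind <- calls@individual[keep]
  tab <- table(ind)
  AncestryCalls(lab,
    posterior = post, method = calls@method, individual = ind,
    ploidy = stats::setNames(as.integer(tab), names(tab))
  )
}

## internal: subset site columns
subsetCallsSites <- function(calls, keep) {
  post <- if (length(calls@posterior) > 0L) {
    calls@posterior[, keep, drop = FALSE]
  } else {
    NULL
  }
  AncestryCalls(calls@labels[, keep, drop = FALSE],
    posterior = post, method = calls@method,
    individual = calls@individual, ploidy = calls@ploidy
  )
}

#' Single-pulse admixture model for tract lengths
#'
#' Under a single admixture pulse `T` generations ago, tract lengths of
#' an ancestry with genome-wide proportion `pPop` are exponential with
#' rate `lambda = T * (1 - pPop) / 100` per cM (recombination breaks a
#' tract wherever it meets the other ancestry, at `T * (1 - pPop)`
#' events per Morgan).
#'
#' @slot generations numeric, generations since the pulse (`T`).
#' @slot pPop numeric in (0, 1), proportion of the focal ancestry.
#' @slot lambda numeric, tract-length rate per cM.
#' @export
setClass("SinglePulseModel",
  representation(generations = "numeric", pPop = "numeric", lambda = "numeric")
)

setValidity("SinglePulseModel", function(object) {
  if (object@generations < 1) {
    return("generations must be >= 1")
  }
  if (object@pPop <= 0 || object@pPop >= 1) {
    return("pPop must lie in (0, 1)")
  }
  expect <- object@generations * (1 - object@pPop) / 100
  if (object@lambda <= 0 || abs(object@lambda - expect) > 1e-12) {
    return("lambda must equal generations * (1 - pPop) / 100")
  }
  TRUE
})

#' Construct a single-pulse tract-length model
#'
#' @param generations generations since the admixture pulse.
#' @param pPop genome-wide proportion of the focal ancestry, in (0, 1).
#' @return A [SinglePulseModel-class] with rate
#'   `lambda = generations * (1 - pPop) / 100` per cM.
#' @examples
#' singlePulseModel(35, 0.2) # lambda = 0.28 per cM
#' @export
singlePulseModel <- function(generations, pPop) {
  new("SinglePulseModel",
    generations = as.numeric(generations), pPop = as.numeric(pPop),
    lambda = generations * (1 - pPop) / 100
  )
}

#' @rdname singlePulseModel
#' @param x a `SinglePulseModel`.
#' @export
setGeneric("tractLambda", function(x) standardGeneric("tractLambda"))
#' @rdname singlePulseModel
#' @export
setMethod("tractLambda", "SinglePulseModel", function(x) x@lambda)

setMethod("show", "SinglePulseModel", function(object) {
  cat(sprintf(
    "SinglePulseModel: T = %.3g generations, p = %.3g, lambda = %.4g per cM (mean tract %.3g cM)\n",
    object@generations, object@pPop, object@lambda, 1 / object@lambda
  ))
})
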