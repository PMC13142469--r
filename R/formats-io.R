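## Reading and writing of external representations: phased VCF, the
## msp-style ancestry-call dialect, genetic maps, BED masks and
## reference-ancestry tables. Site coordinates are 1-based inclusive bp
## (VCF convention); BED masks are converted from 0-based half-open on
## load. All conversions live in this file.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 3-column genetic map
#'
#' @param path TSV with columns chromosome, bp, cM (header optional).
#' @return data.frame with columns `chrom`, `bp`, `cM`.
#' @export
readGeneticMap <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][2L])))
  df <- read.table(path, header = hdr, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "bp", "cM")
  df$chrom <- as.character(df$chrom)
  df[order(df$chrom, df$bp), , drop = FALSE]
}

#' Interpolate genetic positions from a map
#'
#' Sites between map points are linearly interpolated; sites beyond the
#' map ends are extrapolated at the chromosome's mean cM/bp rate.
#'
#' @param chrom,pos site coordinates.
#' @param map data.frame as returned by [readGeneticMap()].
#' @return numeric cM per site.
#' @export
interpolateCM <- function(chrom, pos, map) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) {
      stop("chromosome ", ch, " absent from the genetic map")
    }
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (nrow(m) == 1L) {
      out[idx] <- m$cM[1L]
      next
    }
    v <- stats::approx(m$bp, m$cM, xout = p, rule = 1, ties = "ordered")$y
    rate <- (m$cM[nrow(m)] - m$cM[1L]) / (m$bp[nrow(m)] - m$bp[1L])
    lo <- p < m$bp[1L]
    hi <- p > m$bp[nrow(m)]
    v[lo] <- m$cM[1L] + (p[lo] - m$bp[1L]) * rate
    v[hi] <- m$cM[nrow(m)] + (p[hi] - m$bp[nrow(m)]) * rate
    out[idx] <- v
  }
  out
}

## internal: enforce site ordering with an error naming the offender
checkSiteOrder <- function(chrom, pos) {
  r <- rle(chrom)
  if (anyDuplicated(r$values)) {
    ch <- r$values[duplicated(r$values)][1L]
    j <- max(which(chrom == ch))
    stop(sprintf(
      "sites out of order at record %d (%s:%d): chromosome blocks are interleaved",
      j, chrom[j], pos[j]
    ))
  }
  d <- diff(pos)
  bad <- which(d <= 0 & chrom[-1L] == chrom[-length(chrom)])
  if (length(bad) > 0L) {
    j <- bad[1L] + 1L
    stop(sprintf(
      "sites out of order at record %d (%s:%d)", j, chrom[j], pos[j]
    ))
  }
  invisible(TRUE)
}

#' Read a phased VCF into a site panel and genotype matrix
#'
#' Only biallelic SNPs with a GT field are supported. Genotypes must be
#' phased (`|` separator); a non-missing unphased genotype (`/`) is a
#' hard error because phase is assumed to have been resolved upstream.
#' Missing genotypes (`./.`, `.|.` or `.`) become missing alleles.
#' Haploid samples (single-allele GT) contribute one haplotype.
#'
#' @param path VCF file (plain text; may be gzipped).
#' @param map optional genetic map (see [readGeneticMap()]); when absent,
#'   cM is taken from a `CM=` INFO key if present, else from bp at
#'   1 cM/Mb with a message.
#' @return `list(panel = SitePanel, genotypes = GenotypeMatrix)`.
#' @export
readVcfLike <- function(path, map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix # CHROM..INFO, one row per record
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  alt <- as.character(fix[, "ALT"])
  if (any(grepl(",", alt))) {
    stop("multiallelic records are not supported (biallelic SNPs only)")
  }
  checkSiteOrder(chrom, pos)

  gt <- vcf@gt[, -1L, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  samples <- colnames(vcf@gt)[-1L]
  gt <- sub(":.*", "", gt)
  unphased <- grepl("/", gt) & gt != "./."
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unphased genotype '%s' at %s:%d (sample %s); phased input required",
      gt[w[1L], w[2L]], chrom[w[1L]], pos[w[1L]], samples[w[2L]]
    ))
  }

  nsite <- length(pos)
  hapRows <- list()
  individual <- character(0)
  pl <- integer(0)
  parseAllele <- function(x) ifelse(x == ".", NA_integer_, suppressWarnings(as.integer(x)))
  for (j in seq_along(samples)) {
    g <- gt[, j]
    diploid <- any(grepl("[|]", g) | g == "./.")
    if (diploid) {
      g[g == "./."] <- ".|."
      parts <- strsplit(g, "|", fixed = TRUE)
      a0 <- parseAllele(vapply(parts, `[`, "", 1L))
      a1 <- parseAllele(vapply(parts, `[`, "", 2L))
      hapRows[[paste0(samples[j], ".0")]] <- a0
      hapRows[[paste0(samples[j], ".1")]] <- a1
      individual <- c(individual, samples[j], samples[j])
      pl[samples[j]] <- 2L
    } else {
      hapRows[[paste0(samples[j], ".0")]] <- parseAllele(g)
      individual <- c(individual, samples[j])
      pl[samples[j]] <- 1L
    }
  }
  mat <- do.call(rbind, hapRows)
  if (any(!is.na(mat) & mat != 0L & mat != 1L)) {
    stop("allele codes other than 0/1 found; biallelic SNPs only")
  }

  info <- as.character(fix[, "INFO"])
  getKey <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info, perl = TRUE))
    v <- rep(NA_real_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
    v[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
    v
  }
  infoScore <- getKey("INFO")
  if (!is.null(map)) {
    cm <- interpolateCM(chrom, pos, map)
  } else {
    cm <- getKey("CM")
    if (all(is.na(cm))) {
      message("no genetic map or CM key; assuming 1 cM/Mb")
      cm <- pos / 1e6
    }
  }
  af <- colMeans(mat == 1L, na.rm = TRUE)
  af[is.nan(af)] <- NA_real_
  panel <- SitePanel(chrom, pos, cm,
    ref = fix[, "REF"], alt = alt,
    maf = pmin(af, 1 - af), info = infoScore
  )
  geno <- GenotypeMatrix(mat, individual = individual, ploidy = pl)
  list(panel = panel, genotypes = geno)
}

#' Write a panel + genotypes as a phased VCF
#'
#' Genetic position and imputation quality are stored in the INFO column
#' (`CM=` and `INFO=` keys) so that [readVcfLike()] round-trips them.
#'
#' @param panel a [SitePanel-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @export
writeVcfLike <- function(panel, genotypes, path) {
  inds <- unique(genotypes@individual)
  pl <- genotypes@ploidy
  a <- genotypes@alleles
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  cols <- lapply(inds, function(id) {
    rows <- which(genotypes@individual == id)
    if (pl[id] == 2L) {
      paste0(fmt(a[rows[1L], ]), "|", fmt(a[rows[2L], ]))
    } else {
      fmt(a[rows[1L], ])
    }
  })
  info <- sprintf("CM=%.8g", panel@cM)
  has <- !is.na(panel@info)
  info[has] <- paste0(info[has], sprintf(";INFO=%.6g", panel@info[has]))
  body <- cbind(
    panel@chrom, panel@pos, ".", panel@ref, panel@alt, ".", "PASS",
    info, "GT", do.call(cbind, cols)
  )
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position (cM)\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", inds
    ), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

MSP_FIXED_COLS <- c("chm", "spos", "epos", "sgpos", "egpos", "nsnps")

#' Read ancestry calls in the msp dialect
#'
#' The dialect is a superset of RFMix msp output: two header lines (a
#' code legend and a column header), then rows
#' `chm spos epos sgpos egpos nsnps <one label column per haplotype>`.
#' Rows may be window-level (spos < epos) or degenerate SNP-level rows
#' (spos == epos == site bp). Window rows are expanded so that the
#' window's call extends to every panel SNP with
#' `spos <= bp <= epos`; panel sites covered by no row stay missing.
#'
#' @param path msp file.
#' @param panel the [SitePanel-class] the calls are mapped onto.
#' @param posteriorPath optional sidecar TSV of per-site posteriors
#'   (columns chrom, pos, then one column per haplotype).
#' @param haplotypes optional expected haplotype ids; a count mismatch
#'   with the file is an error.
#' @param method method tag for the returned object.
#' @return An [AncestryCalls-class] on the panel's site grid.
#' @export
readMspCalls <- function(path, panel, posteriorPath = NULL,
                         haplotypes = NULL, method = "msp") {
  lines <- readLines(path)
  hdrIdx <- grep("^#chm", lines)
  if (length(hdrIdx) == 0L) stop("no '#chm' header line in ", path)
  hdr <- strsplit(sub("^#", "", lines[hdrIdx[1L]]), "\t")[[1L]]
  hapIds <- hdr[-seq_along(MSP_FIXED_COLS)]
  if (!is.null(haplotypes) && length(hapIds) != length(haplotypes)) {
    stop(sprintf(
      "haplotype count mismatch: file has %d, expected %d",
      length(hapIds), length(haplotypes)
    ))
  }
  dat <- read.table(
    text = lines[-seq_len(hdrIdx[1L])], sep = "\t",
    stringsAsFactors = FALSE
  )
  names(dat) <- hdr
  labs <- as.matrix(dat[, -seq_along(MSP_FIXED_COLS), drop = FALSE])
  storage.mode(labs) <- "integer"
  if (!all(labs %in% c(-1L, 0L, 1L))) {
    bad <- setdiff(unique(as.vector(labs)), c(-1L, 0L, 1L))
    stop("unknown label code(s) in msp file: ", paste(bad, collapse = ", "))
  }

  out <- matrix(LBL_MISSING, length(hapIds), nSites(panel),
    dimnames = list(hapIds, NULL)
  )
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  for (ch in unique(dat$chm)) {
    rows <- which(dat$chm == ch)
    sel <- which(chrom == as.character(ch))
    if (length(sel) == 0L) next
    bp <- pos[sel]
    for (r in rows) {
      lo <- findInterval(dat$spos[r] - 1L, bp) + 1L
      hi <- findInterval(dat$epos[r], bp)
      if (hi >= lo) {
        out[, sel[lo:hi]] <- matrix(labs[r, ], length(hapIds), hi - lo + 1L)
      }
    }
  }
  post <- NULL
  if (!is.null(posteriorPath)) {
    pd <- read.table(posteriorPath, header = TRUE, sep = "\t", check.names = FALSE)
    post <- matrix(NA_real_, length(hapIds), nSites(panel),
      dimnames = list(hapIds, NULL)
    )
    key <- paste(chrom, pos)
    m <- match(paste(pd[[1L]], pd[[2L]]), key)
    ok <- !is.na(m)
    post[, m[ok]] <- t(as.matrix(pd[ok, -(1:2), drop = FALSE]))
  }
  AncestryCalls(out, posterior = post, method = method)
}

#' Write ancestry calls in the msp dialect
#'
#' Consecutive sites (within a chromosome) at which every haplotype
#' carries the same label are collapsed into one window row, so that
#' SNP-level calls round-trip exactly through [readMspCalls()].
#'
#' @param calls an [AncestryCalls-class].
#' @param panel the matching [SitePanel-class].
#' @param path output path.
#' @param posteriorPath optional path for the posterior sidecar TSV.
#' @export
writeMspCalls <- function(calls, panel, path, posteriorPath = NULL) {
  lab <- calls@labels
  stopifnot(ncol(lab) == nSites(panel))
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  cm <- siteCM(panel)
  changed <- c(
    TRUE,
    chrom[-1L] != chrom[-length(chrom)] |
      colSums(lab[, -1L, drop = FALSE] != lab[, -ncol(lab), drop = FALSE]) > 0L
  )
  grp <- cumsum(changed)
  first <- which(changed)
  last <- c(first[-1L] - 1L, length(pos))
  rows <- cbind(
    data.frame(
      chm = chrom[first], spos = pos[first], epos = pos[last],
      sgpos = cm[first], egpos = cm[last], nsnps = last - first + 1L
    ),
    as.data.frame(t(lab[, first, drop = FALSE]))
  )
  con <- file(path, "w")
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1\tmissing=-1",
    paste0("#", paste(c(MSP_FIXED_COLS, rownames(lab)), collapse = "\t"))
  ), con)
  write.table(rows, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  close(con)
  if (!is.null(posteriorPath) && length(calls@posterior) > 0L) {
    pd <- data.frame(chrom = chrom, pos = pos, t(calls@posterior),
      check.names = FALSE
    )
    names(pd)[-(1:2)] <- rownames(lab)
    write.table(pd, posteriorPath,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a two-column reference global-ancestry table
#'
#' @param path TSV with columns individual, proportion (header optional).
#' @return named numeric vector of hunter-gatherer proportions.
#' @export
readReferenceAncestry <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][2L])))
  df <- read.table(path, header = hdr, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read mask regions from a BED file
#'
#' BED intervals (0-based, half-open) are converted to 1-based closed
#' `GRanges` and merged within each category. The BED name column is the
#' category (e.g. `long-range-LD`, `unmappable-flank`); intervals
#' without a name fall in category `"unspecified"`.
#'
#' @param path BED file.
#' @return A `GRanges` with metadata column `category`.
#' @export
readMaskBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  cat <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  cat[is.na(cat) | cat == ""] <- "unspecified"
  out <- GenomicRanges::GRanges()
  for (cc in unique(cat)) {
    red <- GenomicRanges::reduce(gr[cat == cc])
    if (length(red) > 0L) {
      S4Vectors::mcols(red)$category <- cc
      out <- c(out, red)
    }
  }
  sort(out)
}

#' Build exclusion flanks around unmappable regions
#'
#' Returns the intervals covered by each input region extended by
#' `flank` bp on both sides (category `"unmappable-flank"`), merged.
#'
#' @param regions `GRanges` of unmappable regions.
#' @param flank flank width in bp (default 2.5 Mb).
#' @return A merged `GRanges` with `category = "unmappable-flank"`.
#' @export
unmappableFlanks <- function(regions, flank = 2.5e6) {
  ext <- GenomicRanges::resize(regions,
    width = GenomicRanges::width(regions) + 2 * flank, fix = "center"
  )
  ext <- GenomicRanges::reduce(GenomicRanges::restrict(ext, start = 1L))
  S4Vectors::mcols(ext)$category <- "unmappable-flank"
  ext
}

#' Filter sites on MAF and imputation quality
#'
#' Retains strictly those sites with `maf > mafMin` and
#' `info > infoMin` (strict inequalities). Sites with no INFO score
#' (`NA`) are not filtered on quality.
#'
#' @param panel a [SitePanel-class].
#' @param genotypes the matching [GenotypeMatrix-class].
#' @param mafMin minor-allele-frequency threshold in \[0, 0.5\]
#'   (default 0.01).
#' @param infoMin imputation-quality threshold in \[0, 1\] (default 0.8).
#' @return `list(panel, genotypes)` restricted to surviving sites.
#' @export
filterSites <- function(panel, genotypes, mafMin = 0.01, infoMin = 0.8) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, infoMin >= 0, infoMin <= 1)
  maf <- siteMAF(panel)
  info <- siteInfo(panel)
  ## thresholds of exactly 0 are no-ops, so the unfiltered bound is the
  ## identity even for monomorphic or unscored sites
  keepMaf <- if (mafMin == 0) {
    rep(TRUE, nSites(panel))
  } else {
    !is.na(maf) & maf > mafMin
  }
  keepInfo <- if (infoMin == 0) {
    rep(TRUE, nSites(panel))
  } else {
    is.na(info) | info > infoMin
  }
  keep <- which(keepMaf & keepInfo)
  if (length(keep) == 0L) {
    message("filterSites: no sites survive the MAF/INFO filter")
  }
  list(
    panel = panel[keep],
    genotypes = GenotypeMatrix(
      genotypes@alleles[, keep, drop = FALSE],
      individual = genotypes@individual, ploidy = genotypes@ploidy
    )
  )
}

#' Mask low-posterior ancestry calls
#'
#' Calls with posterior `<= q` are set to missing (strict `>` keeps a
#' call, matching the published "posterior probability > 0.9" rule).
#' Calls without posteriors pass unchanged with a warning.
#'
#' @param calls an [AncestryCalls-class].
#' @param q posterior threshold in \[0, 1\] (default 0.9).
#' @return Filtered [AncestryCalls-class].
#' @export
applyPosteriorFilter <- function(calls, q = 0.9) {
  if (q < 0 || q > 1) stop("posterior threshold q must lie in [0, 1]")
  if (length(calls@posterior) == 0L) {
    warning("calls carry no posteriors; returned unchanged")
    return(calls)
  }
  lab <- calls@labels
  post <- calls@posterior
  drop <- !is.na(post) & post <= q & lab != LBL_MISSING
  lab[drop] <- LBL_MISSING
  post[drop] <- NA_real_
  AncestryCalls(lab,
    posterior = post, method = calls@method,
    individual = calls@individual, ploidy = calls@ploidy
  )
}
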