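# Shared fixture builders and independent oracles.

# small site panel on one chromosome; bp at 1 Mb per cM unless given
tinyPanel <- function(cM, chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- as.integer(round(cM * 1e6))
  SitePanel(chrom = rep(chrom, length(cM)), pos = pos, cM = cM)
}

# AncestryCalls from a plain label matrix; rows named ind.0/ind.1
makeCalls <- function(lab, posterior = NULL, method = "test") {
  if (is.null(rownames(lab))) {
    n <- nrow(lab)
    ind <- rep(sprintf("i%02d", seq_len(ceiling(n / 2))), each = 2L)[seq_len(n)]
    hapNo <- unlist(lapply(table(ind)[unique(ind)], seq_len)) - 1L
    rownames(lab) <- paste0(ind, ".", hapNo)
  }
  AncestryCalls(lab, posterior = posterior, method = method)
}

# count ancestry switches between adjacent non-missing sites, per track
countSwitches <- function(calls) {
  lab <- callLabels(calls)
  a <- lab[, -ncol(lab), drop = FALSE]
  b <- lab[, -1L, drop = FALSE]
  sum(a != b & a != -1L & b != -1L)
}

# Hudson-style Fst from the two true population frequencies
hudsonFst <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

# Brute-force posterior decoding of the two-state ancestry HMM by
# enumeration over all 2^S hidden paths. Mirrors callHmm's emission
# conventions (frequency clamping and error adjustment) but shares no
# code with it.
hmmEnumerate <- function(g, fH, fF, cM, Tg = 35, p = 0.2, e = 1e-3) {
  eps <- 1e-3
  adj <- function(f) {
    f <- pmin(pmax(f, eps), 1 - eps)
    f * (1 - e) + (1 - f) * e
  }
  fH <- adj(fH)
  fF <- adj(fF)
  S <- length(g)
  d <- diff(cM)
  stayH <- exp(-Tg * (1 - p) * d / 100)
  stayF <- exp(-Tg * p * d / 100)
  paths <- as.matrix(expand.grid(rep(list(c(0L, 1L)), S)))
  pr <- apply(paths, 1L, function(st) {
    w <- if (st[1L] == 1L) p else 1 - p
    for (s in seq_len(S)) {
      f <- if (st[s] == 1L) fH[s] else fF[s]
      em <- if (is.na(g[s])) 1 else if (g[s] == 1L) f else 1 - f
      w <- w * em
      if (s < S) {
        w <- w * if (st[s] == 1L) {
          if (st[s + 1L] == 1L) stayH[s] else 1 - stayH[s]
        } else {
          if (st[s + 1L] == 0L) stayF[s] else 1 - stayF[s]
        }
      }
    }
    w
  })
  vapply(seq_len(S), function(s) sum(pr[paths[, s] == 1L]) / sum(pr), 0)
}

# one-haplotype GenotypeMatrix wrapper
hapGenotypes <- function(g, id = "a") {
  m <- matrix(as.integer(g), 1L, length(g), dimnames = list(paste0(id, ".0"), NULL))
  GenotypeMatrix(m)
}

# default-sized simulated cohort, scaled down for unit tests
smallCohort <- function(seed, nAdmixed = 10, nChrom = 1, sitesPerChrom = 3000,
                        chromLengthCM = 100, ...) {
  simulateCohort(simulationConfig(
    nAdmixed = nAdmixed, nChrom = nChrom, sitesPerChrom = sitesPerChrom,
    chromLengthCM = chromLengthCM, seed = seed, ...
  ))
}
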