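writeTempVcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcfHeader <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
)

test_that("phased VCF reads into panel + haplotypes with missing handled", {
  f <- writeTempVcf(c(
    vcfHeader,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\t.\tA\tG\t.\tPASS\tCM=0.1;INFO=0.95\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\tCM=0.2;INFO=0.90\tGT\t0|0\t./.",
    "1\t300\t.\tG\tA\t.\tPASS\tCM=0.3;INFO=0.85\tGT\t1|0\t0|1"
  ))
  r <- readVcfLike(f)
  expect_equal(nSites(r$panel), 3L)
  expect_equal(nHaplotypes(r$genotypes), 4L)
  expect_equal(haplotypeIds(r$genotypes), c("S1.0", "S1.1", "S2.0", "S2.1"))
  expect_equal(siteCM(r$panel), c(0.1, 0.2, 0.3))
  expect_equal(siteInfo(r$panel), c(0.95, 0.90, 0.85))
  # "./." becomes missing at both haplotypes of that individual
  expect_true(all(is.na(alleles(r$genotypes)[c("S2.0", "S2.1"), 2L])))
  expect_equal(alleles(r$genotypes)["S1.0", ], c(0L, 0L, 1L))
})

test_that("unsorted sites are a hard error naming the offending record", {
  f <- writeTempVcf(c(
    vcfHeader,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0|0"
  ))
  expect_error(readVcfLike(f), "record 2")
})

test_that("unphased non-missing genotypes are rejected", {
  f <- writeTempVcf(c(
    vcfHeader,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"
  ))
  expect_error(readVcfLike(f), "unphased")
})

test_that("VCF write/read round-trip is the identity", {
  co <- smallCohort(3, nAdmixed = 4, sitesPerChrom = 50)
  f <- tempfile(fileext = ".vcf")
  writeVcfLike(co$panel, co$genotypes, f)
  r <- readVcfLike(f)
  expect_equal(sitePos(r$panel), sitePos(co$panel))
  expect_equal(siteCM(r$panel), siteCM(co$panel), tolerance = 1e-6)
  expect_identical(unname(alleles(r$genotypes)), unname(alleles(co$genotypes)))
  expect_identical(haplotypeIds(r$genotypes), haplotypeIds(co$genotypes))
})

test_that("msp round-trip is the identity and windows expand to SNPs", {
  panel <- tinyPanel(cM = 1:20 / 10, pos = seq(10L, 200L, by = 10L))
  set.seed(1)
  lab <- matrix(sample(c(-1L, 0L, 1L), 4L * 20L, replace = TRUE), 4L, 20L)
  calls <- makeCalls(lab)
  f <- tempfile(fileext = ".msp.tsv")
  writeMspCalls(calls, panel, f)
  back <- readMspCalls(f, panel)
  expect_identical(unname(callLabels(back)), unname(lab))

  # window row covering sites at bp 10..20 inclusive -> both SNPs called
  panel2 <- tinyPanel(cM = c(0.1, 0.15, 0.3), pos = c(10L, 20L, 30L))
  f2 <- tempfile()
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tnsnps\ta.0",
    "1\t10\t20\t0.1\t0.15\t2\t1"
  ), f2)
  out <- readMspCalls(f2, panel2)
  expect_equal(unname(callLabels(out)[1L, ]), c(1L, 1L, -1L))
})

test_that("a window falling between two sites emits zero calls", {
  panel <- tinyPanel(cM = c(0.1, 0.5), pos = c(100L, 500L))
  # brute-force oracle: which panel sites fall inside [spos, epos]?
  spos <- 150L
  epos <- 450L
  inside <- which(sitePos(panel) >= spos & sitePos(panel) <= epos)
  expect_length(inside, 0L)
  f <- tempfile()
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tnsnps\ta.0",
    sprintf("1\t%d\t%d\t0.2\t0.4\t0\t1", spos, epos)
  ), f)
  out <- readMspCalls(f, panel)
  expect_true(all(callLabels(out) == -1L))
})

test_that("msp reader validates haplotype counts and label codes", {
  panel <- tinyPanel(cM = c(0.1, 0.2), pos = c(100L, 200L))
  f <- tempfile()
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tnsnps\ta.0\ta.1",
    "1\t100\t200\t0.1\t0.2\t2\t1\t0"
  ), f)
  expect_error(readMspCalls(f, panel, haplotypes = "a.0"), "mismatch")
  f2 <- tempfile()
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tnsnps\ta.0",
    "1\t100\t200\t0.1\t0.2\t2\t7"
  ), f2)
  expect_error(readMspCalls(f2, panel), "unknown label")
})

test_that("posterior sidecar round-trips alongside the msp file", {
  panel <- tinyPanel(cM = 1:5 / 10, pos = (1:5) * 100L)
  lab <- matrix(c(1L, 0L, 1L, -1L, 0L), 2L, 5L, byrow = TRUE)[c(1, 1), ]
  post <- matrix(runif(10, 0.5, 1), 2L, 5L)
  calls <- makeCalls(lab, posterior = post)
  f <- tempfile()
  fp <- tempfile()
  writeMspCalls(calls, panel, f, posteriorPath = fp)
  back <- readMspCalls(f, panel, posteriorPath = fp)
  expect_equal(unname(callPosterior(back)), unname(post), tolerance = 1e-12)
})

test_that("site filters apply the strict > thresholds from the study", {
  panel <- SitePanel(
    chrom = rep("1", 5L), pos = (1:5) * 100L, cM = 1:5 / 10,
    maf = c(0.005, 0.01, 0.02, 0.3, 0.5), info = rep(1, 5L)
  )
  geno <- GenotypeMatrix(matrix(0L, 2L, 5L, dimnames = list(c("a.0", "a.1"), NULL)))
  r <- filterSites(panel, geno, mafMin = 0.01, infoMin = 0.8)
  expect_equal(siteMAF(r$panel), c(0.02, 0.3, 0.5)) # MAF 0.01 itself drops
  expect_equal(ncol(alleles(r$genotypes)), 3L)

  panel2 <- SitePanel(
    chrom = rep("1", 3L), pos = (1:3) * 100L, cM = 1:3 / 10,
    maf = rep(0.2, 3L), info = c(0.79, 0.8, 0.81)
  )
  geno2 <- GenotypeMatrix(matrix(0L, 1L, 3L, dimnames = list("a.0", NULL)))
  r2 <- filterSites(panel2, geno2, mafMin = 0.01, infoMin = 0.8)
  expect_equal(siteInfo(r2$panel), 0.81) # only the strictly-greater site

  # zero thresholds are the identity, and filtering is idempotent
  r3 <- filterSites(panel, geno, mafMin = 0, infoMin = 0)
  expect_equal(nSites(r3$panel), 5L)
  r4 <- filterSites(r$panel, r$genotypes, mafMin = 0.01, infoMin = 0.8)
  expect_equal(sitePos(r4$panel), sitePos(r$panel))
})

test_that("posterior filtering keeps strictly > q and warns without posteriors", {
  lab <- matrix(c(1L, 1L, 1L), 1L, 3L, dimnames = list("a.0", NULL))
  post <- matrix(c(0.95, 0.90, 0.50), 1L, 3L)
  calls <- AncestryCalls(lab, posterior = post)
  out <- applyPosteriorFilter(calls, 0.9)
  expect_equal(unname(callLabels(out)[1L, ]), c(1L, -1L, -1L))
  out0 <- applyPosteriorFilter(calls, 0)
  expect_equal(unname(callLabels(out0)[1L, ]), c(1L, 1L, 1L))
  bare <- AncestryCalls(lab)
  expect_warning(out2 <- applyPosteriorFilter(bare, 0.9), "no posteriors")
  expect_identical(callLabels(out2), callLabels(bare))
  expect_error(applyPosteriorFilter(calls, 1.5), "\\[0, 1\\]")
})

test_that("genetic map interpolation is linear inside, rate-extrapolated outside", {
  map <- data.frame(chrom = "1", bp = c(1e6, 2e6, 4e6), cM = c(1, 2, 6))
  expect_equal(interpolateCM("1", 1.5e6, map), 1.5)
  expect_equal(interpolateCM("1", 3e6, map), 4)
  # mean rate over the map is (6-1)/(3e6) cM/bp
  rate <- 5 / 3e6
  expect_equal(interpolateCM("1", 5e6, map), 6 + 1e6 * rate)
  expect_equal(interpolateCM("1", 0.5e6, map), 1 - 0.5e6 * rate)
  expect_error(interpolateCM("2", 1e6, map), "absent")
})

test_that("BED masks load 1-based, merged per category, with flanks", {
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "1\t1000\t2000\tlong-range-LD",
    "1\t1500\t3000\tlong-range-LD",
    "2\t100\t200\tunmappable"
  ), f)
  gr <- readMaskBed(f)
  ld <- gr[gr$category == "long-range-LD"]
  expect_length(ld, 1L) # overlapping intervals merged
  expect_equal(GenomicRanges::start(ld), 1001L) # 0-based half-open -> 1-based
  expect_equal(GenomicRanges::end(ld), 3000L)
  fl <- unmappableFlanks(gr[gr$category == "unmappable"], flank = 500)
  expect_equal(GenomicRanges::start(fl), 1L) # trimmed at the contig start
  expect_equal(GenomicRanges::end(fl), 700L)
})

test_that("reference-ancestry tables read as named proportions", {
  f <- tempfile()
  writeLines(c("ind1\t0.25", "ind2\t0.10"), f)
  r <- readReferenceAncestry(f)
  expect_equal(r, c(ind1 = 0.25, ind2 = 0.10))
})

test_that("window expansion then tract extraction recovers tiling windows", {
  panel <- tinyPanel(cM = 1:30 / 2, pos = (1:30) * 50000L)
  f <- tempfile()
  # three windows tiling the panel: sites 1-10 HG, 11-20 F, 21-30 HG
  writeLines(c(
    "#Subpopulation order/codes: farmer=0\thunter_gatherer=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tnsnps\ta.0",
    "1\t50000\t500000\t0.5\t5\t10\t1",
    "1\t550000\t1000000\t5.5\t10\t10\t0",
    "1\t1050000\t1500000\t10.5\t15\t10\t1"
  ), f)
  calls <- readMspCalls(f, panel)
  tr <- extractTracts(calls, panel)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$label, c(1L, 0L, 1L))
  expect_equal(tr$startBp, c(50000L, 550000L, 1050000L))
  expect_equal(tr$endBp, c(500000L, 1000000L, 1500000L))
})
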