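test_that("TSV genotype round-trip preserves the panel", {
  gp <- tinyPanel()
  gpath <- tempfile(fileext = ".tsv"); mpath <- tempfile(fileext = ".tsv")
  writeGenotypes(gp, gpath, mpath)
  gp2 <- readGenotypes(gpath, mpath, format = "tsv")
  expect_identical(dim(dosages(gp2)), c(2L, 3L))
  expect_identical(dosages(gp2), dosages(gp))
  expect_identical(sampleInfo(gp2), sampleInfo(gp))
  expect_equal(GenomicRanges::start(loci(gp2)), GenomicRanges::start(loci(gp)))
  expect_identical(S4Vectors::mcols(loci(gp2))$panel,
                   S4Vectors::mcols(loci(gp))$panel)
})

test_that("malformed genotype files fail with located errors", {
  gpath <- tempfile(fileext = ".tsv"); mpath <- tempfile(fileext = ".tsv")
  writeLines(c("id\tpop\ts1", "a\tp1\t5"), gpath)
  writeLines(c("locus\tchrom\tpos", "s1\t1\t100"), mpath)
  expect_error(readGenotypes(gpath, mpath), "line 2.*s1")
  expect_error(readGenotypes(tempfile(), mpath), "not found")
})

test_that("ped/map parsing normalizes within-genotype allele order", {
  mpath <- tempfile(fileext = ".map")
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t250", "1\ts3\t0\t900"), mpath)
  ped1 <- tempfile(fileext = ".ped")
  ped2 <- tempfile(fileext = ".ped")
  ## same genotypes; ped2 swaps the order of the two alleles in each call
  writeLines(c("hol ind1 0 0 0 -9 A A A C C C",
               "cha ind2 0 0 0 -9 C C 0 0 A A"), ped1)
  writeLines(c("hol ind1 0 0 0 -9 A A C A C C",
               "cha ind2 0 0 0 -9 C C 0 0 A A"), ped2)
  g1 <- readGenotypes(ped1, mpath, format = "ped-map")
  g2 <- readGenotypes(ped2, mpath, format = "ped-map")
  expect_identical(dosages(g1), dosages(g2))
  ## dosage counts the lexicographically larger allele (C)
  expect_identical(unname(dosages(g1)[1, ]), c(0L, 1L, 2L))
  expect_identical(unname(dosages(g1)[2, ]), c(2L, NA, 0L))
  ## inconsistent locus counts are rejected
  bad <- tempfile(fileext = ".ped")
  writeLines(c("hol ind1 0 0 0 -9 A A A C C C",
               "cha ind2 0 0 0 -9 C C A A"), bad)
  expect_error(readGenotypes(bad, mpath, format = "ped-map"), "line 2")
})

test_that("allele frequencies count called chromosomes only", {
  gp <- GenotypePanel(
    dosages = rbind(c(0L, 1L, NA), c(1L, NA, NA), c(2L, 2L, NA),
                    c(2L, NA, NA)),
    samples = data.frame(id = letters[1:4], pop = "p1"),
    loci = data.frame(locus = c("s1", "s2", "s3"), chrom = "1",
                      pos = 1:3))
  af <- alleleFrequencies(gp, "p1")
  expect_equal(af$freq, c(5 / 8, 3 / 4, NA))
  expect_equal(af$nCalled, c(4L, 2L, 0L))
  expect_identical(af$defined, c(TRUE, TRUE, FALSE))
  expect_error(alleleFrequencies(gp, "nope"), "not found")
})

test_that("allele frequencies are invariant to individual ordering", {
  par <- breedSimParams(100, c(c1 = 10e6), seed = 30)
  gp <- sampleGenotypes(simulateBreedFrequencies(par), c(15, 10), seed = 30,
                        missingRate = 0.05)
  perm <- sample(nSamples(gp))
  gp2 <- GenotypePanel(dosages(gp)[perm, ], sampleInfo(gp)[perm, ],
                       data.frame(locus = names(loci(gp)),
                                  chrom = as.character(
                                    GenomicRanges::seqnames(loci(gp))),
                                  pos = GenomicRanges::start(loci(gp))))
  expect_equal(alleleFrequencies(gp, "breed1")$freq,
               alleleFrequencies(gp2, "breed1")$freq)
})

test_that("HWE exact test matches enumeration over small configurations", {
  expect_equal(hweExactTest(5, 0, 0), 1)
  expect_equal(hweExactTest(0, 2, 0), 1)      # both outcomes <= modal prob
  expect_equal(hweExactTest(0, 2, 0), hweEnumOracle(0, 2, 0))
  expect_equal(hweExactTest(25, 50, 25), hweEnumOracle(25, 50, 25))
  expect_equal(hweExactTest(25, 50, 25), 1)
  set.seed(42)
  for (i in 1:40) {
    n <- sample(1:25, 1)
    g <- as.vector(stats::rmultinom(1, n, c(0.3, 0.5, 0.2)))
    expect_equal(hweExactTest(g[1], g[2], g[3]),
                 hweEnumOracle(g[1], g[2], g[3]), tolerance = 1e-12)
  }
})

test_that("QC filters remove loci in the documented order with audit", {
  ## identity configuration removes nothing
  gp <- tinyPanel()
  qc0 <- applyQc(gp, qcConfig(minMaf = 0, maxMissing = 1, hweAlpha = 0))
  expect_identical(dosages(qc0$panel), dosages(gp))
  expect_true(all(qc0$audit$nRemoved == 0))

  ## hand-classified 10-locus fixture: 2 high-missing, 2 low-MAF, 1 HWE
  set.seed(7)
  n <- 40
  mk <- function(p) rbinom(n, 2, p)
  d <- cbind(ok1 = mk(0.4), ok2 = mk(0.3), ok3 = mk(0.5),
             miss1 = mk(0.4), miss2 = mk(0.4),
             rare1 = rbinom(n, 2, 0.01), rare2 = rbinom(n, 2, 0.012),
             hwe1 = rep(1L, n),       # all-heterozygote: gross HWE failure
             ok4 = mk(0.25), ok5 = mk(0.35))
  d[seq_len(10), "miss1"] <- NA; d[seq_len(8), "miss2"] <- NA
  d[, "rare1"][1] <- 1L; d[, "rare2"][1] <- 1L
  gp10 <- GenotypePanel(d, data.frame(id = sprintf("i%02d", 1:n),
                                      pop = rep(c("b1", "b2"), each = n / 2)),
                        data.frame(locus = colnames(d), chrom = "1",
                                   pos = seq_len(ncol(d)) * 1000))
  qc <- applyQc(gp10, qcConfig(minMaf = 0.05, maxMissing = 0.15,
                               hweAlpha = 1e-4))
  audit <- setNames(qc$audit$nRemoved, qc$audit$filter)
  expect_identical(audit[["missingness"]], 2L)
  expect_identical(audit[["maf"]], 2L)
  expect_identical(audit[["hwe"]], 1L)
  expect_identical(audit[["error_rate"]], 0L)
  expect_setequal(qc$removed, c("miss1", "miss2", "rare1", "rare2", "hwe1"))

  ## idempotence
  qc2 <- applyQc(qc$panel, qcConfig(minMaf = 0.05, maxMissing = 0.15,
                                    hweAlpha = 1e-4))
  expect_identical(dosages(qc2$panel), dosages(qc$panel))
  expect_true(all(qc2$audit$nRemoved == 0))
})

test_that("defined-Fst restriction drops jointly fixed loci only", {
  st <- data.frame(p1 = c(0, 1, 1, 0.5), p2 = c(0, 0, 1, 0.5))
  out <- restrictDefinedFst(st)
  expect_equal(out$p1, c(1, 0.5))   # (1,0) retained, (0,0) and (1,1) dropped
})
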