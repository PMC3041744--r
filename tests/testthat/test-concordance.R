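## small hand-built aligned fixtures
mkScan <- function(chrom, pos, fmax) {
  F <- matrix(fmax, ncol = 1, dimnames = list(NULL, "t1"))
  methods::new("ScanResult", grid = data.frame(chrom = chrom, pos = pos),
               F = F, df1 = F * 0 + 2, df2 = F * 0 + 100,
               fmax = fmax, argmaxTrait = rep("t1", length(fmax)))
}
mkTrack <- function(chrom, pos, value)
  data.frame(chrom = chrom, pos = pos, value = value, nLoci = 1L)

test_that("track alignment is an inner join on (chrom, position)", {
  pos <- (1:5) * 1e5
  sc <- mkScan("c1", pos, c(1, 2, 3, 4, 5))
  tr <- mkTrack("c1", pos, pos / 1e6)
  al <- alignTracks(sc, tr, tr, tr, tr)
  expect_equal(nrow(al), 5)
  ## partial overlap keeps the intersection only
  tr3 <- mkTrack("c1", pos[1:3], 1:3)
  al3 <- alignTracks(sc, tr3, tr3, tr3, tr3)
  expect_equal(nrow(al3), 3)
  expect_equal(attr(al3, "nDropped"), 2)
  ## disjoint positions: empty result with warning
  trX <- mkTrack("c1", pos + 5e4, 1:5)
  expect_warning(alX <- alignTracks(sc, trX, trX, trX, trX), "c1")
  expect_equal(nrow(alX), 0)
})

test_that("correlations match a direct covariance-formula oracle", {
  set.seed(3)
  n <- 20
  al <- data.frame(chrom = "c1", pos = seq_len(n) * 1e5,
                   Fmax = rexp(n), delta = runif(n), fst = runif(n),
                   maDelta = runif(n), maFst = runif(n))
  cors <- trackCorrelations(al)
  oracle <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  for (m in c("delta", "fst", "maDelta", "maFst")) {
    r <- cors$r[cors$chrom == "c1" & cors$measure == m]
    expect_equal(r, oracle(al$Fmax, al[[m]]), tolerance = 1e-12)
  }
  ## perfect linear association
  al2 <- transform(al, delta = 2 * Fmax + 1)
  expect_equal(trackCorrelations(al2)$r[
    trackCorrelations(al2)$chrom == "genome" &
      trackCorrelations(al2)$measure == "delta"], 1, tolerance = 1e-12)
  ## correlation invariant to positive affine rescaling of Fmax
  al3 <- transform(al, Fmax = 10 * Fmax + 2)
  expect_equal(trackCorrelations(al3)$r, cors$r, tolerance = 1e-12)
})

test_that("independent tracks decorrelate at large n", {
  set.seed(8)
  n <- 10000
  al <- data.frame(chrom = "c1", pos = seq_len(n) * 1e5,
                   Fmax = rexp(n), delta = runif(n), fst = runif(n),
                   maDelta = runif(n), maFst = runif(n))
  cors <- trackCorrelations(al)
  expect_true(all(abs(cors$r[cors$chrom == "genome"]) < 0.05))
})

test_that("zero-variance and short chromosomes give flagged NA", {
  al <- data.frame(chrom = c("c1", "c1", "c2", "c2", "c2"),
                   pos = c(1e5, 2e5, 1e5, 2e5, 3e5),
                   Fmax = c(1, 2, 1, 2, 3), delta = c(1, 1, 1, 2, 3),
                   fst = 1, maDelta = c(1, 2, 2, 2, 2), maFst = 1:5)
  cors <- trackCorrelations(al)
  expect_true(is.na(cors$r[cors$chrom == "c1" & cors$measure == "delta"]))
  expect_true(is.na(cors$r[cors$chrom == "c2" & cors$measure == "fst"]))
  expect_false(is.na(cors$r[cors$chrom == "c2" & cors$measure == "maFst"]))
})

test_that("threshold grouping excludes chromosomes without highF positions", {
  al <- data.frame(chrom = rep(c("c1", "c2"), each = 4),
                   pos = rep((1:4) * 1e5, 2),
                   Fmax = c(2, 6, 8, 3, 1, 2, 3, 4),
                   delta = c(0.1, 0.5, 0.7, 0.2, 0.1, 0.2, 0.3, 0.4),
                   fst = 0.2, maDelta = 0.3, maFst = 0.1)
  gm <- thresholdGroupMeans(al, c(5, 7, 10))
  ## c2 never exceeds any threshold
  expect_false("c2" %in% gm$chrom)
  d5 <- gm[gm$threshold == 5 & gm$measure == "delta", ]
  expect_equal(d5$meanHigh, mean(c(0.5, 0.7)))
  expect_equal(d5$meanLow, mean(c(0.1, 0.2)))
  expect_equal(d5$nHigh, 2L); expect_equal(d5$nLow, 2L)
  ## threshold 10: nothing anywhere
  expect_false(10 %in% gm$threshold)
  ## ties at the threshold go to lowF
  alT <- transform(al[1:4, ], Fmax = c(5, 5, 8, 3))
  gmT <- thresholdGroupMeans(alT, 5)
  expect_equal(gmT$nHigh[1], 1L)
  ## degenerate: all positions above -> lowF empty and flagged NA
  alHi <- transform(al[1:4, ], Fmax = 20)
  gmH <- thresholdGroupMeans(alHi, 5)
  expect_equal(gmH$nLow[1], 0L)
  expect_true(is.na(gmH$meanLow[1]))
  expect_equal(gmH$meanHigh[gmH$measure == "delta"],
               mean(c(0.1, 0.5, 0.7, 0.2)))
})

test_that("one-tailed signed-rank p-values are exact", {
  ## all-positive signs: p = 2^-n
  expect_equal(wilcoxonSignedRankOneTailed(rep(1, 6))$p.value, 1 / 64)
  expect_equal(wilcoxonSignedRankOneTailed(2)$p.value, 0.5)
  ## random fixtures against full 2^n enumeration, with and without ties
  set.seed(12)
  for (i in 1:12) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:2, 1))
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonSignedRankOneTailed(d)$p.value,
                 signedRankEnumOracle(d), tolerance = 1e-12)
  }
  ## agreement with stats::wilcox.test exact p when there are no ties
  d <- c(1.3, -0.4, 2.2, 0.8, -1.7, 0.6, 3.1)
  expect_equal(wilcoxonSignedRankOneTailed(d)$p.value,
               wilcox.test(d, alternative = "greater", exact = TRUE)$p.value)
  ## zero differences are dropped with a count
  wt <- wilcoxonSignedRankOneTailed(c(0, 0, 1, 2, -1))
  expect_equal(wt$nZeroDropped, 2L)
  expect_equal(wt$nPairs, 3L)
  expect_warning(w0 <- wilcoxonSignedRankOneTailed(c(0, 0)), "zero")
  expect_equal(w0$p.value, 1)
  ## the large-sample path approximates the exact tail
  set.seed(99)
  d30 <- rnorm(30) + 0.3
  pN <- wilcoxonSignedRankOneTailed(d30, exactMax = 25)$p.value
  pE <- wilcoxonSignedRankOneTailed(d30, exactMax = 30)$p.value
  expect_lt(abs(pN - pE), 0.01)
})

test_that("concordance tests pair chromosome means per threshold", {
  gm <- data.frame(threshold = 7, chrom = paste0("c", 1:6),
                   measure = "delta",
                   meanHigh = c(0.5, 0.6, 0.7, 0.4, 0.8, 0.9),
                   meanLow = c(0.2, 0.3, 0.2, 0.2, 0.3, 0.4),
                   nHigh = 2L, nLow = 5L)
  ct <- concordanceTests(gm)
  expect_equal(ct$nPairs, 6L)
  expect_equal(ct$p, 1 / 64)   # all six chromosomes favour highF
})

test_that("panel-subset reanalysis rebuilds tracks and detects bias", {
  set.seed(61)
  par <- breedSimParams(6000, c(c1 = 60e6), backgroundFst = 0.1, seed = 61)
  fr <- simulateBreedFrequencies(par)
  gp <- sampleGenotypes(fr, c(49, 20), seed = 61)
  st <- restrictDefinedFst(locusDiffStats(gp))
  ## label half the loci as panel A and inflate their delta by 0.05
  lab <- ifelse(seq_len(nrow(st)) %% 2 == 0, "A", "B")
  st$panel <- lab
  st$delta <- pmin(st$delta + ifelse(lab == "A", 0.05, 0), 1)
  sc <- mkScan("c1", binTrack(st, "delta")$pos,
               rexp(nrow(binTrack(st, "delta"))))
  full <- subsetReanalysis(st, sc, keep = c("A", "B"))
  subB <- subsetReanalysis(st, sc, keep = "B")
  expect_gt(full$panelMeans[["A"]], full$panelMeans[["B"]])
  expect_lt(subB$panelTest, 0.001)    # inflation detected
  expect_true(is.na(full$panelTest))  # identity subset: nothing excluded
  ## identity subset reproduces the full correlations
  fullDirect <- trackCorrelations(alignTracks(
    sc, binTrack(st, "delta"), binTrack(st, "fst"),
    movingAverage(binTrack(st, "delta")), movingAverage(binTrack(st, "fst"))))
  expect_equal(full$correlations, fullDirect)
  expect_error(subsetReanalysis(st, sc, keep = "Z"), "panel label")
})
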