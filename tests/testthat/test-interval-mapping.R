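test_that("QTL genotype probabilities cover the canonical cases", {
  ## position on a fully informative marker
  expect_equal(unname(qtlGenotypeProbs(2, 2, 0, 12, "F2")[1, ]),
               c(1, 0, 0))
  expect_equal(unname(qtlGenotypeProbs(0, 0, 0, 12, "F2")[1, ]),
               c(0, 0, 1))
  ## no marker information: Mendelian priors
  expect_equal(unname(qtlGenotypeProbs(NA, NA, NA, NA, "F2")[1, ]),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(qtlGenotypeProbs(NA, NA, NA, NA, "BC1")[1, ]),
               c(0.5, 0.5, 0))
  expect_equal(unname(qtlGenotypeProbs(NA, NA, NA, NA, "BC2")[1, ]),
               c(0, 0.5, 0.5))
  ## probabilities always sum to one and are valid
  set.seed(9)
  g <- expand.grid(gL = 0:2, gR = 0:2)
  pr <- qtlGenotypeProbs(g$gL, g$gR, 7, 13, "F2")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)))
  expect_true(all(pr >= 0 & pr <= 1))
  ## backcross individuals cannot carry two non-recurrent alleles
  expect_error(qtlGenotypeProbs(0, 1, 5, 5, "BC1"), "non-recurrent")
})

test_that("F2 flanking probabilities match gamete-pattern enumeration", {
  cases <- expand.grid(gL = 0:2, gR = 0:2, dL = c(3, 10), dR = c(5, 10))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- qtlGenotypeProbs(cs$gL, cs$gR, cs$dL, cs$dR, "F2")[1, ]
    want <- f2ProbsEnumOracle(cs$gL, cs$gR, cs$dL, cs$dR)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
  ## midpoint between discordant homozygous flanks 20 cM apart: both
  ## parental gametes are recombinant, so the QTL allele is near-uniform
  got <- qtlGenotypeProbs(2, 0, 10, 10, "F2")[1, ]
  expect_equal(unname(got), f2ProbsEnumOracle(2, 0, 10, 10),
               tolerance = 1e-12)
  expect_equal(unname(got["pQQ"]), unname(got["pqq"]), tolerance = 1e-12)
  expect_equal(unname(got["pQq"]), 0.5, tolerance = 0.01)
})

test_that("Haley-Knott design scores follow the probability contrasts", {
  expect_equal(unname(hkDesignRow(c(1, 0, 0))), cbind(1, 0),
               ignore_attr = TRUE)
  expect_equal(unname(hkDesignRow(c(0, 1, 0))), cbind(0, 1),
               ignore_attr = TRUE)
  expect_equal(unname(hkDesignRow(c(0.25, 0.5, 0.25))), cbind(0, 0.5),
               ignore_attr = TRUE)
})

test_that("scan design scores stay within their theoretical ranges", {
  st <- smallStudy(seed = 19, nF2 = 80, nBC1 = 20, nBC2 = 20)
  map <- markerMap(st$data)
  gen <- sampleInfo(st$data)$generation
  crossOf <- c(F2 = "F2", CB1 = "BC1", HB1 = "BC2")
  for (posCM in c(0, 7.5, 33)) {
    iL <- findInterval(posCM, map$cM)
    for (g in unique(gen)) {
      ix <- gen == g
      pr <- qtlGenotypeProbs(dosages(st$data)[ix, max(iL, 1)],
                             dosages(st$data)[ix, min(iL + 1, nrow(map))],
                             posCM - map$cM[max(iL, 1)],
                             map$cM[min(iL + 1, nrow(map))] - posCM,
                             crossOf[[g]])
      xa <- pr[, 1] - pr[, 3]; xd <- pr[, 2]
      expect_true(all(xa >= -1 & xa <= 1))
      expect_true(all(xd >= 0 & xd <= 1))
    }
  }
})

test_that("degenerate phenotypes give degenerate scans", {
  st <- smallStudy(seed = 23, nF2 = 100, nBC1 = 0, nBC2 = 0)
  d <- st$data
  dFlat <- LineCrossData(dosages(d), sampleInfo(d), markerMap(d),
                         data.frame(t1 = rep(3.7, nrow(sampleInfo(d)))))
  sc <- scanTrait(dFlat, "t1")
  expect_true(all(sc$F == 0))
})

test_that("a noise-free additive signal peaks exactly at the QTL grid point", {
  st <- smallStudy(seed = 29, nF2 = 150, nBC1 = 30, nBC2 = 30)
  d <- st$data
  map <- markerMap(d)
  qtlPos <- 30e6
  qtlCM <- 30   # 1 Mbp = 1 cM map
  gen <- sampleInfo(d)$generation
  crossOf <- c(F2 = "F2", CB1 = "BC1", HB1 = "BC2")
  iL <- findInterval(qtlPos, map$pos)
  xa <- numeric(nrow(sampleInfo(d)))
  for (g in unique(gen)) {
    ix <- gen == g
    pr <- qtlGenotypeProbs(dosages(d)[ix, iL], dosages(d)[ix, iL + 1],
                           qtlCM - map$cM[iL], map$cM[iL + 1] - qtlCM,
                           crossOf[[g]])
    xa[ix] <- pr[, 1] - pr[, 3]
  }
  dExact <- LineCrossData(dosages(d), sampleInfo(d), map,
                          data.frame(t1 = xa))
  sc <- scanTrait(dExact, "t1")
  expect_equal(sc$pos[which.max(sc$F)], qtlPos)
  expect_gt(max(sc$F), 1e6)   # essentially zero residual at the truth
})

test_that("the scan F equals a general-purpose regression oracle", {
  st <- smallStudy(seed = 37, nF2 = 315, nBC1 = 88, nBC2 = 98,
                   add = 0.5, dom = 0.2)
  d <- st$data
  sc <- scanTrait(d, "t1")
  map <- markerMap(d)
  gen <- sampleInfo(d)$generation
  crossOf <- c(F2 = "F2", CB1 = "BC1", HB1 = "BC2")
  y <- phenotypes(d)$t1
  for (pos in c(5e6, 30e6, 52e6)) {
    posCM <- pos / 1e6   # the fixture map is linear at 1 cM per Mbp
    iL <- findInterval(pos, map$pos)
    xa <- numeric(length(y)); xd <- numeric(length(y))
    for (g in unique(gen)) {
      ix <- gen == g
      pr <- qtlGenotypeProbs(dosages(d)[ix, iL], dosages(d)[ix, iL + 1],
                             posCM - map$cM[iL], map$cM[iL + 1] - posCM,
                             crossOf[[g]])
      xa[ix] <- pr[, 1] - pr[, 3]; xd[ix] <- pr[, 2]
    }
    full <- lm(y ~ gen + xa + xd)
    red <- lm(y ~ gen)
    oracleF <- anova(red, full)$F[2]
    expect_equal(sc$F[sc$pos == pos], oracleF, tolerance = 1e-8)
    expect_equal(sc$df1[sc$pos == pos], 2L)
    expect_equal(sc$df2[sc$pos == pos], full$df.residual)
  }
})

test_that("F-ratios are invariant to affine phenotype rescaling", {
  st <- smallStudy(seed = 41, nF2 = 120, nBC1 = 30, nBC2 = 30)
  d <- st$data
  sc1 <- scanTrait(d, "t1")
  d2 <- LineCrossData(dosages(d), sampleInfo(d), markerMap(d),
                      data.frame(t1 = 3 * phenotypes(d)$t1 + 7))
  sc2 <- scanTrait(d2, "t1")
  expect_equal(sc1$F, sc2$F, tolerance = 1e-9)
})

test_that("Fmax combines trait scans position-wise", {
  g <- data.frame(chrom = "c1", pos = c(1e5, 2e5))
  s1 <- data.frame(chrom = g$chrom, pos = g$pos, F = c(3, 8),
                   df1 = 2L, df2 = 100L)
  s2 <- data.frame(chrom = g$chrom, pos = g$pos, F = c(5, 2),
                   df1 = 2L, df2 = 100L)
  res <- fMax(list(a = s1, b = s2))
  expect_equal(fmaxTrack(res)$Fmax, c(5, 8))
  expect_equal(fmaxTrack(res)$argmaxTrait, c("b", "a"))
  ## single trait: identity
  res1 <- fMax(list(a = s1))
  expect_equal(fmaxTrack(res1)$Fmax, s1$F)
  ## maximum dominates every component everywhere
  expect_true(all(fmaxTrack(res)$Fmax >= fMatrix(res)))
  ## mismatched grids are rejected
  s3 <- s2; s3$pos <- s3$pos + 1e5
  expect_error(fMax(list(a = s1, b = s3)), "same grid")
})

test_that("permutation thresholds are deterministic and honor level = 0", {
  st <- smallStudy(seed = 43, nF2 = 80, nBC1 = 20, nBC2 = 20, add = 0)
  p1 <- permutationThreshold(st$data, "t1", nPerm = 120, level = 0.05,
                             scope = "chromosome", chrom = "c1", seed = 7)
  p2 <- permutationThreshold(st$data, "t1", nPerm = 120, level = 0.05,
                             scope = "chromosome", chrom = "c1", seed = 7)
  expect_identical(p1$threshold, p2$threshold)
  p0 <- permutationThreshold(st$data, "t1", nPerm = 120, level = 0,
                             scope = "chromosome", chrom = "c1", seed = 7)
  expect_equal(p0$threshold, max(p0$maxStats))
  expect_error(permutationThreshold(st$data, "t1", nPerm = 50), ">= 100")
})

test_that("threshold sets must increase", {
  expect_error(thresholdSet(c(5, 5, 10)), "increasing")
  expect_silent(thresholdSet())
})
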