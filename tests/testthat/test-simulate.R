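test_that("Balding-Nichols degenerate and selected-locus cases behave", {
  sel <- data.frame(chrom = "c1", pos = 5e6, p1 = 1, p2 = 0)
  par0 <- breedSimParams(200, c(c1 = 10e6), backgroundFst = 0,
                         selectedLoci = sel, seed = 3)
  fr <- simulateBreedFrequencies(par0)
  neutral <- !fr$selected
  expect_equal(fr$p1[neutral], fr$p0[neutral])
  expect_equal(fr$p2[neutral], fr$p0[neutral])
  expect_equal(abs(fr$p1 - fr$p2)[neutral], rep(0, sum(neutral)))
  expect_equal(fr$p1[fr$selected], 1)
  expect_equal(fr$p2[fr$selected], 0)
  expect_equal(abs(fr$p1 - fr$p2)[fr$selected], 1)
  ## ordering contract
  expect_false(is.unsorted(fr$pos[fr$chrom == "c1"]))
})

test_that("breed simulation parameters are validated", {
  expect_error(breedSimParams(10, c(c1 = 1e6), backgroundFst = 1),
               "backgroundFst")
  expect_error(breedSimParams(10, c(c1 = 1e6), sampleSizes = c(1, 20)),
               ">= 2")
  expect_error(breedSimParams(10, c(c1 = 1e6),
                              selectedLoci = data.frame(chrom = "c1",
                                                        pos = 2e6,
                                                        p1 = 1, p2 = 0)),
               "within their chromosome")
})

test_that("expected delta grows with background Fst", {
  means <- vapply(c(0.02, 0.1, 0.25), function(F) {
    par <- breedSimParams(3000, c(c1 = 50e6), backgroundFst = F, seed = 9)
    fr <- simulateBreedFrequencies(par)
    mean(abs(fr$p1 - fr$p2))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("genotype sampling respects frequencies and missingness", {
  fr <- data.frame(locus = c("a", "b"), chrom = "c1", pos = c(1e6, 2e6),
                   p1 = c(1, 0.5), p2 = c(1, 0.5))
  gp <- sampleGenotypes(fr, c(5000, 5000), seed = 2)
  d <- dosages(gp)
  expect_true(all(d[, "a"] == 2L))
  expect_lt(abs(mean(d[, "b"]) / 2 - 0.5), 0.02)

  fr50 <- data.frame(locus = sprintf("l%02d", 1:50), chrom = "c1",
                     pos = (1:50) * 1e5, p1 = 0.5, p2 = 0.5)
  gpM <- sampleGenotypes(fr50, c(100, 100), seed = 4, missingRate = 0.1)
  expect_lt(abs(mean(is.na(dosages(gpM))) - 0.1), 0.02)
})

test_that("simulation is bit-for-bit reproducible under one seed", {
  par <- breedSimParams(500, c(c1 = 20e6), seed = 21)
  expect_identical(simulateBreedFrequencies(par),
                   simulateBreedFrequencies(par))
  fr <- simulateBreedFrequencies(par)
  expect_identical(dosages(sampleGenotypes(fr, c(10, 10), seed = 21)),
                   dosages(sampleGenotypes(fr, c(10, 10), seed = 21)))
  st1 <- smallStudy(seed = 8)
  st2 <- smallStudy(seed = 8)
  expect_identical(dosages(st1$data), dosages(st2$data))
  expect_identical(phenotypes(st1$data), phenotypes(st2$data))
})

test_that("co-located loci co-transmit and Haldane fractions are realized", {
  ## two markers at the same cM position never recombine
  map <- data.frame(marker = c("a", "b", "c"), chrom = "c1",
                    pos = c(1e6, 1e6 + 1, 11e6), cM = c(1, 1, 11))
  design <- crossDesign(nF1 = 40, nF2 = 0, nBC1 = 3000, nBC2 = 0,
                        nFounders1 = 5)
  cr <- simulateCross(design, map, seed = 13)
  g <- cr$geno - 1L   # BC1: founder contributes one line-1 allele
  expect_true(all(g[, "a"] == g[, "b"]))
  ## 10 cM apart: Haldane expects (1 - exp(-0.2))/2
  rec <- mean(g[, "a"] != g[, "c"])
  expect_lt(abs(rec - haldane(10)), 0.01)
})

test_that("F2 latent QTL genotypes segregate 1:2:1", {
  design <- crossDesign(nF1 = 80, nF2 = 3000, nBC1 = 0, nBC2 = 0)
  map <- makeMarkerMap(c(c1 = 40e6), spacingCM = 10)
  cr <- simulateCross(design, map, list(qtlSpec("c1", 20e6, 1)), seed = 5)
  frac <- table(factor(cr$qtlGeno[, 1], levels = 0:2)) / 3000
  expect_lt(max(abs(frac - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("phenotype model reduces to exact class means without noise", {
  st <- smallStudy(seed = 3, nF2 = 60, nBC1 = 20, nBC2 = 20,
                   add = 1.5, dom = 0.5, sd = 1e-9)
  y <- phenotypes(st$data)$t1
  ## remove the sex covariate contribution before checking class means
  sexEff <- c(male = 0.25, female = -0.25)
  y <- y - 0  # traits from smallStudy carry no covariates
  nQ <- st$cross$qtlGeno[, 1]
  expect_equal(unname(y[nQ == 2]), rep(1.5, sum(nQ == 2)), tolerance = 1e-6)
  expect_equal(unname(y[nQ == 1]), rep(0.5, sum(nQ == 1)), tolerance = 1e-6)
  expect_equal(unname(y[nQ == 0]), rep(-1.5, sum(nQ == 0)), tolerance = 1e-6)
})

test_that("null QTL effects leave phenotypes independent of genotype", {
  st <- smallStudy(seed = 6, nF2 = 1000, nBC1 = 0, nBC2 = 0, add = 0,
                   dom = 0)
  r <- cor(phenotypes(st$data)$t1, st$cross$qtlGeno[, 1])
  expect_lt(abs(r), 0.08)
})

test_that("an additive F2 QTL explains the theoretical variance share", {
  ## a = 1, sd = 1: var explained = (a^2/2) / (a^2/2 + 1) = 1/3
  design <- crossDesign(nF1 = 100, nF2 = 2000, nBC1 = 0, nBC2 = 0)
  map <- makeMarkerMap(c(c1 = 40e6), spacingCM = 10)
  tr <- list(traitSpec("t1", sd = 1,
                       qtls = list(qtlSpec("c1", 20e6, add = 1))))
  st <- simulateLineCrossStudy(design, map, tr, seed = 17)
  y <- phenotypes(st$data)$t1
  g <- st$cross$qtlGeno[, 1]
  r2 <- summary(lm(y ~ g))$r.squared
  expect_lt(abs(r2 - 1 / 3), 0.05)
})

test_that("trait and qtl specs validate their inputs", {
  expect_error(traitSpec("x", sd = 0), "sd must be > 0")
  expect_error(simulateCross(crossDesign(), makeMarkerMap(c(c1 = 10e6)),
                             list(qtlSpec("c9", 1e6, 1))),
               "no markers")
})
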