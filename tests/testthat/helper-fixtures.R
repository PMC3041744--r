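## Shared fixtures and independent oracles, built in code.

## tiny 2-individual x 3-locus panel used by the IO tests
tinyPanel <- function() {
  GenotypePanel(
    dosages = rbind(c(0L, 1L, 2L), c(2L, NA, 0L)),
    samples = data.frame(id = c("ind1", "ind2"), pop = c("hol", "cha")),
    loci = data.frame(locus = c("s1", "s2", "s3"), chrom = "1",
                      pos = c(100L, 250L, 900L),
                      panel = c("holstein", "other", "other")))
}

## scalar, formula-by-formula Weir-Cockerham oracle (independent of the
## vectorized implementation)
wcOracle <- function(p1, n1, h1, p2, n2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 / (r * nbar) + n2^2 / (r * nbar))) / (r - 1)
  pbar <- (n1 * p1) / (r * nbar) + (n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2) / ((r - 1) * nbar) +
    (n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1) / (r * nbar) + (n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

## exact conditional HWE null by full enumeration of heterozygote counts
hweEnumOracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  nA <- 2 * aa + ab
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    exp(h * log(2) + lfactorial(n) - lfactorial(naa) - lfactorial(h) -
          lfactorial(nbb) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, 0)
  pObs <- pr[match(ab, hets)]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

## one-tailed signed-rank p by full 2^n sign enumeration (midranked ties)
signedRankEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  hits <- 0
  for (m in 0:(2^n - 1)) {
    s <- as.integer(intToBits(m)[seq_len(n)])
    if (sum(r[s == 1]) >= v - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

## brute-force enumeration of F2 QTL genotype probabilities given both
## flank genotypes: sums over all maternal/paternal 3-locus gametes
f2ProbsEnumOracle <- function(gL, gR, dL, dR) {
  r1 <- haldane(dL); r2 <- haldane(dR)
  t <- function(x, y, r) if (x == y) 1 - r else r
  acc <- c(0, 0, 0); wtot <- 0
  for (aLm in 0:1) for (aQm in 0:1) for (aRm in 0:1)
    for (aLp in 0:1) for (aQp in 0:1) for (aRp in 0:1) {
      if (aLm + aLp != gL || aRm + aRp != gR) next
      w <- 0.25 * t(aLm, aQm, r1) * t(aQm, aRm, r2) *
        t(aLp, aQp, r1) * t(aQp, aRp, r2)
      nQ <- aQm + aQp
      acc[3 - nQ] <- acc[3 - nQ] + w
      wtot <- wtot + w
    }
  acc / wtot
}

## small deterministic line-cross study for mapping tests
smallStudy <- function(seed = 11, nF2 = 200, nBC1 = 40, nBC2 = 40,
                       add = 0.8, dom = 0, sd = 1, qtlPos = 30e6,
                       chromLen = c(c1 = 60e6), spacing = 10) {
  design <- crossDesign(nF1 = 60, nF2 = nF2, nBC1 = nBC1, nBC2 = nBC2,
                        nFounders1 = 7)
  map <- makeMarkerMap(chromLen, spacingCM = spacing)
  qtls <- if (is.null(qtlPos)) list() else
    list(qtlSpec(names(chromLen)[1], qtlPos, add, dom))
  tr <- list(traitSpec("t1", sd = sd, qtls = qtls))
  simulateLineCrossStudy(design, map, tr, seed = seed)
}
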