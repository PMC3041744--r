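## Three-generation line-cross simulation (F1, F2, reciprocal backcrosses).
##
## Founder line 1 (beef-type sires) and line 2 (dairy-type dams) are crossed
## to give F1; F2 come from F1 x F1 matings and backcrosses from F1 x founder
## matings. Gametes are formed by a Markov walk along each chromosome with
## Haldane recombination fractions between adjacent loci, i.e. recombination
## without interference. QTL are carried as extra latent loci fixed for
## alternative alleles in the founder lines.

#' Haldane map function
#'
#' @param dcM map distance in centiMorgans.
#' @return Recombination fraction `(1 - exp(-2 d)) / 2` with `d` in Morgans.
#' @examples
#' haldane(10)  # ~0.0906
#' @export
haldane <- function(dcM) (1 - exp(-2 * dcM / 100)) / 2

#' Cross design: pedigree sizes of a three-generation F2/backcross herd
#'
#' Defaults mirror a classical beef x dairy resource herd: 7 founder sires,
#' 137 F1, 315 F2, 88 backcrosses to line 1 (CB1) and 98 to line 2 (HB1).
#'
#' @param nF1 number of F1 individuals.
#' @param nF2 number of F2 individuals.
#' @param nBC1 backcrosses to founder line 1.
#' @param nBC2 backcrosses to founder line 2.
#' @param nFounders1 founder line-1 sires.
#' @param nF1Sires how many F1 males sire the F2 generation.
#' @return list of class `CrossDesign`.
#' @export
crossDesign <- function(nF1 = 137L, nF2 = 315L, nBC1 = 88L, nBC2 = 98L,
                        nFounders1 = 7L, nF1Sires = 8L) {
  vals <- c(nF1, nF2, nBC1, nBC2, nFounders1, nF1Sires)
  if (any(vals < 0)) stop("design counts must be >= 0")
  if (nF1 < 2 && nF2 > 0) stop("F2 individuals require at least 2 F1 parents")
  structure(list(nF1 = as.integer(nF1), nF2 = as.integer(nF2),
                 nBC1 = as.integer(nBC1), nBC2 = as.integer(nBC2),
                 nFounders1 = as.integer(nFounders1),
                 nF1Sires = as.integer(min(nF1Sires, nF1))),
            class = "CrossDesign")
}

#' QTL specification for the cross simulator
#'
#' Founder line 1 is fixed for allele Q, line 2 for q (the line-cross
#' assumption); `add` is the additive effect a (half the homozygote
#' difference) and `dom` the dominance deviation d, both in trait units.
#'
#' @param chrom chromosome name.
#' @param pos position in bp.
#' @param add additive effect a.
#' @param dom dominance deviation d.
#' @return list of class `QtlSpec`.
#' @export
qtlSpec <- function(chrom, pos, add, dom = 0) {
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 add = add, dom = dom), class = "QtlSpec")
}

#' Trait specification: mean, residual SD, fixed effects and QTL
#'
#' @param name trait name.
#' @param mean trait mean mu.
#' @param sd residual standard deviation sigma (> 0).
#' @param covariateEffects named list of fixed effects; each element is a
#'   named numeric vector of level values, e.g.
#'   `list(sex = c(male = 0.3, female = -0.3))`. Levels are assigned to
#'   individuals uniformly at random (consistently across traits).
#' @param generationEffects named numeric vector of genetic-composition
#'   effects for F2/CB1/HB1 (always part of the model downstream).
#' @param qtls list of [qtlSpec()] objects.
#' @return list of class `TraitSpec`.
#' @export
traitSpec <- function(name, mean = 0, sd = 1, covariateEffects = list(),
                      generationEffects = c(F2 = 0, CB1 = 0, HB1 = 0),
                      qtls = list()) {
  if (sd <= 0) stop("residual sd must be > 0")
  if (length(covariateEffects) &&
      any(vapply(covariateEffects, length, 1L) < 1))
    stop("every fixed effect needs at least one level")
  structure(list(name = name, mean = mean, sd = sd,
                 covariateEffects = covariateEffects,
                 generationEffects = generationEffects,
                 qtls = qtls), class = "TraitSpec")
}

#' Evenly spaced fully informative marker map
#'
#' Markers every `spacingCM` cM along each chromosome, converted to bp with
#' a linear map (default 1 Mbp = 1 cM).
#'
#' @param chromosomeLengths named vector of chromosome lengths (bp).
#' @param spacingCM marker spacing in cM.
#' @param cmPerMb linear bp-to-cM conversion rate.
#' @return data.frame `marker`, `chrom`, `pos`, `cM`.
#' @export
makeMarkerMap <- function(chromosomeLengths, spacingCM = 15, cmPerMb = 1) {
  if (is.null(names(chromosomeLengths)))
    names(chromosomeLengths) <- as.character(seq_along(chromosomeLengths))
  out <- do.call(rbind, lapply(names(chromosomeLengths), function(cn) {
    lenCM <- chromosomeLengths[[cn]] / 1e6 * cmPerMb
    cm <- seq(0, lenCM, by = spacingCM)
    pos <- pmax(1, round(cm / cmPerMb * 1e6))
    data.frame(marker = sprintf("m_%s_%02d", cn, seq_along(cm)),
               chrom = cn, pos = as.integer(pos), cM = cm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## piecewise-linear bp -> cM within a chromosome's map; beyond the terminal
## markers, extension at the chromosome-average cM/bp rate
interpolateCM <- function(mapChrom, bp) {
  m <- mapChrom[order(mapChrom$pos), , drop = FALSE]
  if (nrow(m) == 1L) return(rep(m$cM, length(bp)))
  rate <- (max(m$cM) - min(m$cM)) / max(1, (max(m$pos) - min(m$pos)))
  cm <- approx(m$pos, m$cM, xout = bp, rule = 2, ties = "ordered")$y
  lo <- bp < min(m$pos)
  hi <- bp > max(m$pos)
  cm[lo] <- min(m$cM) - (min(m$pos) - bp[lo]) * rate
  cm[hi] <- max(m$cM) + (bp[hi] - max(m$pos)) * rate
  cm
}

## vectorized meioses: one gamete per offspring from parent haplotype
## matrices (nInd x L); `r` = recombination fractions between adjacent loci
meiosisMatrix <- function(H1, H2, parentIdx, r) {
  nOff <- length(parentIdx)
  L <- ncol(H1)
  if (L == 1L) {
    pick <- rbinom(nOff, 1L, 0.5)
    return(matrix(ifelse(pick == 0L, H1[parentIdx, 1L], H2[parentIdx, 1L]),
                  ncol = 1L))
  }
  start <- rbinom(nOff, 1L, 0.5)
  sw <- matrix(runif(nOff * (L - 1L)) <
                 rep(r, each = nOff), nrow = nOff)
  state <- (start + t(apply(cbind(0L, sw), 1L, cumsum))) %% 2L
  A <- H1[parentIdx, , drop = FALSE]
  B <- H2[parentIdx, , drop = FALSE]
  out <- A
  out[state == 1L] <- B[state == 1L]
  out
}

#' Simulate marker and QTL genotypes through a three-generation cross
#'
#' Founder haplotypes are fixed for alternative alleles in the two lines
#' when `informative = TRUE` (the default; marker allele count then equals
#' the line-1 origin count required by Haley-Knott line-cross mapping) or
#' drawn from supplied per-line allele frequencies otherwise. QTL loci are
#' always fixed for alternative line alleles. Gametes recombine with
#' Haldane fractions from adjacent-locus cM distances.
#'
#' @param design a [crossDesign()].
#' @param map marker map data.frame (`marker`, `chrom`, `pos`, `cM`),
#'   sorted by map position within chromosome.
#' @param qtls list of [qtlSpec()] objects (may be empty).
#' @param seed integer seed.
#' @param informative logical; fully informative line-coded markers.
#' @param founderFreqs optional data.frame (`marker`, `f1`, `f2`) of
#'   line-wise allele-1 frequencies, used when `informative = FALSE`.
#' @return list of class `CrossSim`: `samples` (id, generation for the
#'   mapping generation: F2/CB1/HB1), `geno` (marker matrix), `qtlGeno`
#'   (line-1 allele counts at QTL), `map`, `qtlMap`, `pedigree`.
#' @export
simulateCross <- function(design, map, qtls = list(), seed = 1L,
                          informative = TRUE, founderFreqs = NULL) {
  stopifnot(inherits(design, "CrossDesign"))
  chroms <- unique(map$chrom)
  for (q in qtls)
    if (!q$chrom %in% chroms)
      stop("QTL chromosome ", q$chrom, " has no markers in the map")
  sp <- split(seq_len(nrow(map)), map$chrom)
  for (ix in sp) {
    if (length(ix) == 0L) stop("empty marker map on a simulated chromosome")
    if (is.unsorted(map$pos[ix]) || is.unsorted(map$cM[ix]))
      stop("map must be sorted with cM monotone in bp")
  }
  set.seed(childSeed(seed, "cross"))

  nFound1 <- design$nFounders1
  nFound2 <- max(design$nF1, 2L)      # line-2 dam pool
  nF1 <- design$nF1
  nF2 <- design$nF2; nBC1 <- design$nBC1; nBC2 <- design$nBC2
  nSecond <- nF2 + nBC1 + nBC2

  ## pedigree indices: founders1, founders2, F1, second generation
  iF0a <- seq_len(nFound1)
  iF0b <- nFound1 + seq_len(nFound2)
  iF1 <- nFound1 + nFound2 + seq_len(nF1)
  iG2 <- nFound1 + nFound2 + nF1 + seq_len(nSecond)
  nAll <- nFound1 + nFound2 + nF1 + nSecond

  f1Sire <- sample(iF0a, nF1, replace = TRUE)
  f1Dam <- sample(iF0b, nF1, replace = FALSE)[seq_len(nF1)]
  f2SirePool <- sample(iF1, design$nF1Sires)
  f2Sire <- sample(f2SirePool, nF2, replace = TRUE)
  f2DamPool <- setdiff(iF1, f2SirePool)
  if (!length(f2DamPool)) f2DamPool <- iF1
  f2Dam <- sample(f2DamPool, nF2, replace = TRUE)
  bc1F1 <- sample(iF1, nBC1, replace = TRUE)
  bc1Founder <- sample(iF0a, nBC1, replace = TRUE)
  bc2F1 <- sample(iF1, nBC2, replace = TRUE)
  bc2Founder <- sample(iF0b, nBC2, replace = TRUE)

  generation <- c(rep("FOUNDER1", nFound1), rep("FOUNDER2", nFound2),
                  rep("F1", nF1),
                  rep(c("F2", "CB1", "HB1"), c(nF2, nBC1, nBC2)))
  sire <- c(rep(NA_integer_, nFound1 + nFound2), f1Sire,
            f2Sire, bc1Founder, bc2F1)
  dam <- c(rep(NA_integer_, nFound1 + nFound2), f1Dam,
           f2Dam, bc1F1, bc2Founder)
  id <- sprintf("%s_%04d", tolower(generation), unlist(lapply(
    rle(generation)$lengths, seq_len)))

  genoG2 <- NULL; qtlG2 <- NULL
  qtlMap <- if (length(qtls))
    data.frame(qtl = vapply(qtls, function(q)
                 sprintf("qtl_%s_%d", q$chrom, as.integer(q$pos)), ""),
               chrom = vapply(qtls, `[[`, "", "chrom"),
               pos = vapply(qtls, function(q) as.integer(q$pos), 1L),
               stringsAsFactors = FALSE)
  else data.frame(qtl = character(), chrom = character(), pos = integer())

  for (cn in chroms) {
    mC <- map[map$chrom == cn, , drop = FALSE]
    qC <- qtlMap[qtlMap$chrom == cn, , drop = FALSE]
    locPos <- c(mC$pos, qC$pos)
    locCM <- c(mC$cM, if (nrow(qC)) interpolateCM(mC, qC$pos) else numeric())
    isQtl <- c(rep(FALSE, nrow(mC)), rep(TRUE, nrow(qC)))
    ord <- order(locPos)
    locPos <- locPos[ord]; locCM <- locCM[ord]; isQtl <- isQtl[ord]
    L <- length(locPos)
    r <- haldane(pmax(0, diff(locCM)))

    ## founder haplotypes
    H1 <- matrix(0L, nAll, L); H2 <- matrix(0L, nAll, L)
    if (informative || is.null(founderFreqs)) {
      H1[iF0a, ] <- 1L; H2[iF0a, ] <- 1L
    } else {
      ff <- founderFreqs[match(mC$marker, founderFreqs$marker), ]
      f1v <- numeric(L); f2v <- numeric(L)
      f1v[!isQtl] <- ff$f1; f2v[!isQtl] <- ff$f2
      f1v[isQtl] <- 1; f2v[isQtl] <- 0
      H1[iF0a, ] <- matrix(rbinom(nFound1 * L, 1L, rep(f1v, each = nFound1)),
                           nFound1)
      H2[iF0a, ] <- matrix(rbinom(nFound1 * L, 1L, rep(f1v, each = nFound1)),
                           nFound1)
      H1[iF0b, ] <- matrix(rbinom(nFound2 * L, 1L, rep(f2v, each = nFound2)),
                           nFound2)
      H2[iF0b, ] <- matrix(rbinom(nFound2 * L, 1L, rep(f2v, each = nFound2)),
                           nFound2)
    }
    ## F1: paternal gamete from line-1 sire, maternal from line-2 dam
    H1[iF1, ] <- meiosisMatrix(H1, H2, f1Sire, r)
    H2[iF1, ] <- meiosisMatrix(H1, H2, f1Dam, r)
    ## second generation
    H1[iG2, ] <- meiosisMatrix(H1, H2, sire[iG2], r)
    H2[iG2, ] <- meiosisMatrix(H1, H2, dam[iG2], r)

    G <- H1[iG2, , drop = FALSE] + H2[iG2, , drop = FALSE]
    gM <- G[, !isQtl, drop = FALSE]; colnames(gM) <- mC$marker
    genoG2 <- cbind(genoG2, gM)
    if (any(isQtl)) {
      gQ <- G[, isQtl, drop = FALSE]
      colnames(gQ) <- qC$qtl[match(locPos[isQtl], qC$pos)]
      qtlG2 <- cbind(qtlG2, gQ)
    }
  }
  if (is.null(qtlG2)) qtlG2 <- matrix(integer(), nSecond, 0)

  samples <- data.frame(id = id[iG2], generation = generation[iG2],
                        stringsAsFactors = FALSE)
  rownames(genoG2) <- samples$id
  rownames(qtlG2) <- samples$id
  structure(list(samples = samples, geno = genoG2, qtlGeno = qtlG2,
                 map = map, qtlMap = qtlMap,
                 pedigree = data.frame(id = id, generation = generation,
                                       sire = sire, dam = dam,
                                       stringsAsFactors = FALSE)),
            class = "CrossSim")
}

#' Simulate phenotypes from latent QTL genotypes
#'
#' The phenotype model is `y = mu + generation effect + fixed effects +
#' sum over QTL of a (nQ - 1) + d 1{het} + N(0, sigma^2)`, where `nQ` is
#' the individual's count of line-1 alleles at the QTL. Fixed-effect levels
#' are assigned uniformly at random, once per individual and consistently
#' across traits sharing a covariate.
#'
#' @param cross a `CrossSim` from [simulateCross()].
#' @param traits list of [traitSpec()] objects; every QTL in every trait
#'   must be present in `cross$qtlMap`.
#' @param seed integer seed.
#' @return list: `pheno` (data.frame of traits), `covariates` (data.frame
#'   of assigned levels, characters), `traitModels`.
#' @export
simulatePhenotypes <- function(cross, traits, seed = 1L) {
  stopifnot(inherits(cross, "CrossSim"))
  set.seed(childSeed(seed, "phenotypes"))
  n <- nrow(cross$samples)
  covEff <- list()
  for (tr in traits)
    for (cv in names(tr$covariateEffects))
      if (is.null(covEff[[cv]])) covEff[[cv]] <- tr$covariateEffects[[cv]]
  covariates <- as.data.frame(lapply(covEff, function(levels)
    sample(names(levels), n, replace = TRUE)),
    stringsAsFactors = FALSE, optional = TRUE)
  if (length(covEff) == 0L)
    covariates <- data.frame(row.names = seq_len(n))

  pheno <- list()
  traitModels <- list()
  for (tr in traits) {
    y <- rep(tr$mean, n)
    ge <- tr$generationEffects
    y <- y + unname(ge[cross$samples$generation])
    for (cv in names(tr$covariateEffects))
      y <- y + unname(tr$covariateEffects[[cv]][covariates[[cv]]])
    for (q in tr$qtls) {
      qid <- sprintf("qtl_%s_%d", q$chrom, as.integer(q$pos))
      if (!qid %in% colnames(cross$qtlGeno))
        stop("trait ", tr$name, " references unsimulated QTL ", qid)
      nQ <- cross$qtlGeno[, qid]
      y <- y + q$add * (nQ - 1) + q$dom * (nQ == 1L)
    }
    y <- y + rnorm(n, 0, tr$sd)
    pheno[[tr$name]] <- y
    traitModels[[tr$name]] <- names(tr$covariateEffects)
  }
  list(pheno = as.data.frame(pheno), covariates = covariates,
       traitModels = traitModels)
}

#' Simulate a complete line-cross mapping study
#'
#' Convenience wrapper: runs [simulateCross()] on the union of the traits'
#' QTL, then [simulatePhenotypes()], and assembles a [LineCrossData-class].
#'
#' @inheritParams simulateCross
#' @param traits list of [traitSpec()] objects.
#' @return list: `data` ([LineCrossData-class]), `cross` (`CrossSim`),
#'   `qtlMap`.
#' @export
simulateLineCrossStudy <- function(design, map, traits, seed = 1L,
                                   informative = TRUE, founderFreqs = NULL) {
  qtls <- list()
  seen <- character()
  for (tr in traits)
    for (q in tr$qtls) {
      key <- sprintf("qtl_%s_%d", q$chrom, as.integer(q$pos))
      if (!key %in% seen) { qtls[[length(qtls) + 1L]] <- q; seen <- c(seen, key) }
    }
  cross <- simulateCross(design, map, qtls, seed = seed,
                         informative = informative,
                         founderFreqs = founderFreqs)
  ph <- simulatePhenotypes(cross, traits, seed = seed)
  data <- LineCrossData(cross$geno, cross$samples, cross$map, ph$pheno,
                        ph$covariates, ph$traitModels)
  list(data = data, cross = cross, qtlMap = cross$qtlMap)
}
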