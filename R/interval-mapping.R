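## Haley-Knott line-cross regression interval mapping.
##
## At each grid position the conditional probabilities of the three QTL
## line-origin genotypes (QQ, Qq, qq; Q = founder-line-1 allele) are
## computed from the nearest informative flanking markers by enumerating
## parental gamete transmission patterns with Haldane recombination
## fractions (no interference; double recombinants handled exactly). The
## phenotype is regressed on fixed effects plus the additive and dominance
## scores x_a = P(QQ) - P(qq), x_d = P(Qq); the position's F-ratio compares
## this full model with the fixed-effects-only reduced model.

## gamete probability that the transmitted QTL allele is line-1, given the
## transmitted flank alleles; r1/r2 = recombination fractions left/right
## flank to QTL, r12 between the flanks. Safe against r12 in {0, 1}.
gamQcond <- function(aL, aR, r1, r2) {
  r12 <- r1 + r2 - 2 * r1 * r2
  num <- ifelse(aL == 1, 1 - r1, r1) * ifelse(aR == 1, 1 - r2, r2)
  den <- ifelse(aL == aR, 1 - r12, r12)
  out <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0.5)
  pmin(pmax(out, 0), 1)
}

## marker-gamete probability P(aL, aR) for one F1 parent
gamPair <- function(aL, aR, r1, r2) {
  r12 <- r1 + r2 - 2 * r1 * r2
  ifelse(aL == aR, (1 - r12) / 2, r12 / 2)
}

#' Conditional QTL genotype probabilities from flanking markers
#'
#' For a putative QTL flanked by line-informative markers at `dLeft` and
#' `dRight` cM, returns `P(QQ)`, `P(Qq)`, `P(qq)` for each individual given
#' its flank genotypes (counts of line-1 alleles). A missing flank
#' (genotype `NA` or distance `NA`) reduces to single-marker conditioning;
#' with both flanks missing the cross-type prior is used (F2: 1/4, 1/2,
#' 1/4; backcrosses: 1/2, 1/2 on the two reachable genotypes). Backcross
#' individuals cannot be homozygous for the non-recurrent line at an
#' informative marker; such genotypes are rejected.
#'
#' @param gLeft,gRight integer vectors of flank genotypes (0/1/2, `NA`).
#' @param dLeft,dRight distances (cM) from the position to each flank;
#'   scalars or vectors; `NA` marks an absent flank.
#' @param cross `"F2"`, `"BC1"` (backcross to line 1) or `"BC2"`.
#' @return numeric matrix n x 3 with columns `pQQ`, `pQq`, `pqq` (rows sum
#'   to 1).
#' @examples
#' qtlGenotypeProbs(2, 2, 0, 10, "F2")      # (1, 0, 0)
#' qtlGenotypeProbs(NA, NA, NA, NA, "F2")   # Mendelian prior
#' @export
qtlGenotypeProbs <- function(gLeft, gRight, dLeft, dRight,
                             cross = c("F2", "BC1", "BC2")) {
  cross <- match.arg(cross)
  n <- max(length(gLeft), length(gRight))
  gL <- rep_len(as.numeric(gLeft), n)
  gR <- rep_len(as.numeric(gRight), n)
  dL <- rep_len(as.numeric(dLeft), n)
  dR <- rep_len(as.numeric(dRight), n)
  if (any(dL < 0 | dR < 0, na.rm = TRUE))
    stop("flank distances must be >= 0 cM")
  hasL <- !is.na(gL) & !is.na(dL)
  hasR <- !is.na(gR) & !is.na(dR)
  r1 <- haldane(dL); r2 <- haldane(dR)

  if (cross == "F2") {
    pQQ <- numeric(n); pQq <- numeric(n); pqq <- numeric(n); wtot <- numeric(n)
    both <- hasL & hasR
    ## both flanks: enumerate maternal gamete (aLm, aRm); paternal follows
    for (aLm in 0:1) for (aRm in 0:1) {
      aLp <- gL - aLm; aRp <- gR - aRm
      ok <- both & aLp >= 0 & aLp <= 1 & aRp >= 0 & aRp <= 1
      if (!any(ok)) next
      w <- gamPair(aLm, aRm, r1, r2) * gamPair(aLp, aRp, r1, r2)
      qm <- gamQcond(aLm, aRm, r1, r2)
      qp <- gamQcond(aLp, aRp, r1, r2)
      w[!ok] <- 0
      pQQ <- pQQ + w * qm * qp
      pQq <- pQq + w * (qm * (1 - qp) + (1 - qm) * qp)
      pqq <- pqq + w * (1 - qm) * (1 - qp)
      wtot <- wtot + w
    }
    ## single flank
    for (side in c("L", "R")) {
      one <- if (side == "L") hasL & !hasR else hasR & !hasL
      if (!any(one)) next
      g <- if (side == "L") gL else gR
      rr <- if (side == "L") r1 else r2
      for (am in 0:1) {
        ap <- g - am
        ok <- one & ap >= 0 & ap <= 1
        if (!any(ok)) next
        w <- rep(0.25, n)
        qm <- ifelse(am == 1, 1 - rr, rr)
        qp <- ifelse(ap == 1, 1 - rr, rr)
        w[!ok] <- 0
        pQQ <- pQQ + w * qm * qp
        pQq <- pQq + w * (qm * (1 - qp) + (1 - qm) * qp)
        pqq <- pqq + w * (1 - qm) * (1 - qp)
        wtot <- wtot + w
      }
    }
    none <- !hasL & !hasR
    pQQ[none] <- 0.25; pQq[none] <- 0.5; pqq[none] <- 0.25; wtot[none] <- 1
    if (any(wtot == 0))
      stop("inconsistent flank genotypes for the F2 cross type")
    out <- cbind(pQQ = pQQ / wtot, pQq = pQq / wtot, pqq = pqq / wtot)
    return(out)
  }

  ## backcrosses: the recurrent founder transmits a fixed allele; only the
  ## F1 gamete is uncertain. BC1 recurrent line 1 (allele 1), BC2 line 2.
  rec <- if (cross == "BC1") 1 else 0
  aLf1 <- gL - rec; aRf1 <- gR - rec
  if (any((hasL & (aLf1 < 0 | aLf1 > 1)) |
          (hasR & (aRf1 < 0 | aRf1 > 1)), na.rm = TRUE))
    stop("backcross genotype homozygous for the non-recurrent line")
  q <- rep(0.5, n)   # P(F1 gamete QTL allele = line 1)
  both <- hasL & hasR
  q[both] <- gamQcond(aLf1[both], aRf1[both], r1[both], r2[both])
  onlyL <- hasL & !hasR
  q[onlyL] <- ifelse(aLf1[onlyL] == 1, 1 - r1[onlyL], r1[onlyL])
  onlyR <- hasR & !hasL
  q[onlyR] <- ifelse(aRf1[onlyR] == 1, 1 - r2[onlyR], r2[onlyR])
  if (cross == "BC1") cbind(pQQ = q, pQq = 1 - q, pqq = 0)
  else cbind(pQQ = 0, pQq = q, pqq = 1 - q)
}

#' Haley-Knott design scores from QTL genotype probabilities
#'
#' @param probs matrix with columns `pQQ`, `pQq`, `pqq` (rows sum to 1).
#' @return matrix with columns `xa = P(QQ) - P(qq)` and `xd = P(Qq)`.
#' @export
hkDesignRow <- function(probs) {
  probs <- rbind(probs)
  stopifnot(ncol(probs) == 3)
  cbind(xa = probs[, 1] - probs[, 3], xd = probs[, 2])
}

## fixed-effect design (always includes genetic composition) and QR basis
fixedEffectBasis <- function(data, trait) {
  covs <- traitModels(data)[[trait]]
  df <- data.frame(generation = sampleInfo(data)$generation,
                   stringsAsFactors = FALSE)
  for (cv in covs) {
    if (!cv %in% names(covariates(data)))
      stop("fixed effect '", cv, "' for trait ", trait,
           " is not a covariate column")
    df[[cv]] <- covariates(data)[[cv]]
  }
  y <- phenotypes(data)[[trait]]
  keep <- !is.na(y) & stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  for (cv in names(df)) {
    if (length(unique(df[[cv]])) < 1L)
      stop("fixed effect '", cv, "' has no levels after listwise deletion")
    ## single-level effects are constants: absorbed by the intercept
    if (length(unique(df[[cv]])) == 1L) df[[cv]] <- NULL
    else df[[cv]] <- factor(df[[cv]])
  }
  X <- if (ncol(df)) stats::model.matrix(~ ., df)
  else matrix(1, nrow(df), 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ## drop aliased columns (e.g. a covariate confounded with generation)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Q <- qr.Q(qrX)
  y <- y[keep]
  yres <- y - Q %*% crossprod(Q, y)
  list(keep = which(keep), Q = Q, rank = qrX$rank, y = y,
       yres = as.numeric(yres), rssRed = sum(yres^2),
       rssTol = 1e-12 * max(sum(y^2), .Machine$double.xmin))
}

## F-statistics for all positions given residualization basis Q.
## XA, XD: n x P score matrices (rows = the trait's complete cases).
hkFStats <- function(XA, XD, Q, yres, rssRed, rankFix,
                     rssTol = .Machine$double.xmin) {
  n <- nrow(XA)
  ## a phenotype fully explained by the fixed effects leaves no contrast
  if (rssRed <= rssTol) {
    z <- numeric(ncol(XA))
    return(list(F = z, df1 = rep(2L, ncol(XA)),
                df2 = rep(n - rankFix - 2L, ncol(XA))))
  }
  QtA <- crossprod(Q, XA)
  QtD <- crossprod(Q, XD)
  saa <- colSums(XA^2) - colSums(QtA^2)
  sdd <- colSums(XD^2) - colSums(QtD^2)
  sad <- colSums(XA * XD) - colSums(QtA * QtD)
  say <- as.numeric(crossprod(XA, yres))
  sdy <- as.numeric(crossprod(XD, yres))
  det <- saa * sdd - sad^2
  tol <- 1e-10 * pmax(saa * sdd, 1e-300)
  full2 <- det > tol & saa > 1e-12 & sdd > 1e-12
  expl <- numeric(length(saa))
  q <- integer(length(saa))
  ## q = 2: both scores identifiable
  i2 <- which(full2)
  expl[i2] <- (sdd[i2] * say[i2]^2 - 2 * sad[i2] * say[i2] * sdy[i2] +
                 saa[i2] * sdy[i2]^2) / det[i2]
  q[i2] <- 2L
  ## q = 1: dominance (or additive) confounded; use the score with the
  ## larger residual variance
  i1 <- which(!full2 & (saa > 1e-12 | sdd > 1e-12))
  useA <- saa[i1] >= sdd[i1]
  expl[i1] <- ifelse(useA, say[i1]^2 / saa[i1], sdy[i1]^2 / sdd[i1])
  q[i1] <- 1L
  ## q = 0: no genetic information at all
  i0 <- which(saa <= 1e-12 & sdd <= 1e-12)
  expl[i0] <- 0; q[i0] <- 1L
  expl <- pmin(pmax(expl, 0), rssRed)
  df2 <- n - rankFix - q
  rssFull <- pmax(rssRed - expl, 0)
  F <- ifelse(df2 > 0 & rssFull > 1e-300 * max(rssRed, 1),
              (expl / q) / (rssFull / df2),
              ifelse(expl > 0, Inf, 0))
  F[rssRed <= 1e-300] <- 0
  list(F = pmax(F, 0), df1 = q, df2 = df2)
}

## score matrices x_a, x_d for all individuals at the grid positions of one
## chromosome; handles per-individual missing flank genotypes by stepping
## to the nearest non-missing marker on each side
chromScores <- function(geno, mapC, gridPos, gridCM, generation) {
  n <- nrow(geno)
  P <- length(gridPos)
  XA <- matrix(0, n, P); XD <- matrix(0, n, P)
  anyMissing <- anyNA(geno)
  crossOf <- c(F2 = "F2", CB1 = "BC1", HB1 = "BC2")
  genClasses <- split(seq_len(n), generation)
  iL0 <- findInterval(gridPos, mapC$pos)
  if (!anyMissing) {
    ## fast path: flanks are shared by all individuals, so probabilities
    ## need computing only once per observed flank-genotype combination
    M <- nrow(mapC)
    for (p in seq_len(P)) {
      iL <- iL0[p]; iR <- iL + 1L
      gLall <- if (iL >= 1L) geno[, iL] else rep(NA_integer_, n)
      gRall <- if (iR <= M) geno[, iR] else rep(NA_integer_, n)
      dLs <- if (iL >= 1L) gridCM[p] - mapC$cM[iL] else NA_real_
      dRs <- if (iR <= M) mapC$cM[iR] - gridCM[p] else NA_real_
      kL <- ifelse(is.na(gLall), 3L, gLall)
      kR <- ifelse(is.na(gRall), 3L, gRall)
      for (gen in names(genClasses)) {
        ix <- genClasses[[gen]]
        key <- kL[ix] * 4L + kR[ix]
        uk <- unique(key)
        ugL <- uk %/% 4L; ugR <- uk %% 4L
        ugL[ugL == 3L] <- NA_integer_; ugR[ugR == 3L] <- NA_integer_
        pr <- qtlGenotypeProbs(ugL, ugR, dLs, dRs, crossOf[[gen]])
        m <- match(key, uk)
        XA[ix, p] <- pr[m, 1] - pr[m, 3]
        XD[ix, p] <- pr[m, 2]
      }
    }
    return(list(XA = XA, XD = XD))
  }
  for (p in seq_len(P)) {
    iL <- rep(iL0[p], n)
    iR <- iL + 1L
    iL[iL < 1L] <- NA_integer_
    iR[iR > nrow(mapC)] <- NA_integer_
    if (anyMissing) {
      ## walk outward past missing genotypes, per individual
      repeat {
        bad <- which(!is.na(iL) & is.na(geno[cbind(seq_len(n), iL)]))
        if (!length(bad)) break
        iL[bad] <- ifelse(iL[bad] > 1L, iL[bad] - 1L, NA_integer_)
      }
      repeat {
        bad <- which(!is.na(iR) & is.na(geno[cbind(seq_len(n), iR)]))
        if (!length(bad)) break
        iR[bad] <- ifelse(iR[bad] < nrow(mapC), iR[bad] + 1L, NA_integer_)
      }
    }
    gL <- ifelse(is.na(iL), NA_integer_, geno[cbind(seq_len(n), iL)])
    gR <- ifelse(is.na(iR), NA_integer_, geno[cbind(seq_len(n), iR)])
    dL <- ifelse(is.na(iL), NA_real_, gridCM[p] - mapC$cM[iL])
    dR <- ifelse(is.na(iR), NA_real_, mapC$cM[iR] - gridCM[p])
    for (gen in names(genClasses)) {
      ix <- genClasses[[gen]]
      pr <- qtlGenotypeProbs(gL[ix], gR[ix], dL[ix], dR[ix],
                             cross = crossOf[[gen]])
      XA[ix, p] <- pr[, 1] - pr[, 3]
      XD[ix, p] <- pr[, 2]
    }
  }
  list(XA = XA, XD = XD)
}

#' Single-trait Haley-Knott regression scan
#'
#' Fits, at every grid position (multiples of `gridStep` bp between the
#' terminal markers of each chromosome), the ordinary-least-squares full
#' model `phenotype ~ fixed effects + x_a + x_d` against the reduced model
#' with fixed effects only, and reports the partial F-ratio. The
#' genetic-composition (generation) fixed effect is always included.
#' Individuals with a missing phenotype or covariate are dropped listwise.
#' If the dominance score is confounded (e.g. in a pure backcross subset)
#' the test drops to 1 numerator degree of freedom.
#'
#' @param data a [LineCrossData-class].
#' @param trait trait (phenotype column) name.
#' @param gridStep grid spacing in bp (default 100,000).
#' @param chroms optional subset of chromosomes to scan.
#' @return data.frame: `chrom`, `pos`, `F`, `df1`, `df2`; attribute
#'   `"trait"`.
#' @export
scanTrait <- function(data, trait, gridStep = 1e5, chroms = NULL) {
  stopifnot(is(data, "LineCrossData"), trait %in% traitNames(data))
  basis <- fixedEffectBasis(data, trait)
  nUse <- length(basis$keep)
  if (nUse < basis$rank + 4L)
    stop("too few phenotyped individuals (", nUse, ") for trait ", trait)
  map <- markerMap(data)
  if (is.null(chroms)) chroms <- unique(map$chrom)
  gen <- sampleInfo(data)$generation[basis$keep]
  res <- lapply(chroms, function(cn) {
    mapC <- map[map$chrom == cn, , drop = FALSE]
    if (!nrow(mapC)) stop("no markers on chromosome ", cn)
    lo <- ceiling(min(mapC$pos) / gridStep) * gridStep
    hi <- floor(max(mapC$pos) / gridStep) * gridStep
    if (hi < lo) return(NULL)
    gridPos <- seq(lo, hi, by = gridStep)
    gridCM <- interpolateCM(mapC, gridPos)
    sc <- chromScores(dosages(data)[basis$keep,
                                    map$chrom == cn, drop = FALSE],
                      mapC, gridPos, gridCM, gen)
    fs <- hkFStats(sc$XA, sc$XD, basis$Q, basis$yres, basis$rssRed,
                   basis$rank, basis$rssTol)
    data.frame(chrom = cn, pos = gridPos, F = fs$F, df1 = fs$df1,
               df2 = fs$df2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  out
}

#' Across-trait maximum F-ratio
#'
#' Combines single-trait scans (all on the same grid) into a
#' [ScanResult-class] carrying the position-wise maximum F over traits
#' (Fmax) and the trait attaining it.
#'
#' @param scans named list of [scanTrait()] data.frames.
#' @return A [ScanResult-class].
#' @export
fMax <- function(scans) {
  stopifnot(length(scans) >= 1)
  if (is.null(names(scans)) || any(names(scans) == ""))
    names(scans) <- vapply(scans, function(s)
      attr(s, "trait") %||% "trait", "")
  ref <- scans[[1]][, c("chrom", "pos")]
  for (s in scans[-1])
    if (!identical(s[, c("chrom", "pos")], ref))
      stop("all traits must be scanned on the same grid")
  Fm <- do.call(cbind, lapply(scans, `[[`, "F"))
  d1 <- do.call(cbind, lapply(scans, `[[`, "df1"))
  d2 <- do.call(cbind, lapply(scans, `[[`, "df2"))
  colnames(Fm) <- colnames(d1) <- colnames(d2) <- names(scans)
  amax <- max.col(Fm, ties.method = "first")
  methods::new("ScanResult", grid = ref, F = Fm, df1 = d1, df2 = d2,
               fmax = Fm[cbind(seq_len(nrow(Fm)), amax)],
               argmaxTrait = colnames(Fm)[amax])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation significance threshold for the scan statistic
#'
#' Churchill-Doerge-style: phenotype and covariate rows are permuted
#' jointly against the genotype rows (implemented as the inverse
#' permutation of the genotype scores, which leaves the fixed-effect model
#' intact), within generation class, and the scope-wide maximum F is
#' recorded per permutation. The threshold is the empirical `1 - level`
#' quantile of those maxima (`level = 0` gives the maximum).
#'
#' @param data a [LineCrossData-class].
#' @param traits trait names (maximum taken over traits as in the scan).
#' @param nPerm number of permutations (>= 100).
#' @param level significance level.
#' @param scope `"chromosome"` (requires `chrom`) or `"genome"`.
#' @param chrom chromosome for chromosome-wise thresholds.
#' @param gridStep grid spacing in bp.
#' @param seed integer seed.
#' @return list of class `PermThreshold`: `threshold`, `level`, `scope`,
#'   `nPerm`, `maxStats` (the permuted maxima).
#' @export
permutationThreshold <- function(data, traits, nPerm = 1000L, level = 0.05,
                                 scope = c("chromosome", "genome"),
                                 chrom = NULL, gridStep = 1e5, seed = 1L) {
  scope <- match.arg(scope)
  if (nPerm < 100L) stop("nPerm must be >= 100")
  if (scope == "chromosome" && is.null(chrom))
    stop("chromosome scope needs a chromosome")
  map <- markerMap(data)
  chroms <- if (scope == "chromosome") chrom else unique(map$chrom)
  ## per-trait fixed bases and score matrices over the scope
  prep <- lapply(traits, function(tr) {
    basis <- fixedEffectBasis(data, tr)
    gen <- sampleInfo(data)$generation[basis$keep]
    mats <- lapply(chroms, function(cn) {
      mapC <- map[map$chrom == cn, , drop = FALSE]
      lo <- ceiling(min(mapC$pos) / gridStep) * gridStep
      hi <- floor(max(mapC$pos) / gridStep) * gridStep
      gridPos <- seq(lo, hi, by = gridStep)
      chromScores(dosages(data)[basis$keep, map$chrom == cn, drop = FALSE],
                  mapC, gridPos, interpolateCM(mapC, gridPos), gen)
    })
    list(basis = basis, gen = gen,
         XA = do.call(cbind, lapply(mats, `[[`, "XA")),
         XD = do.call(cbind, lapply(mats, `[[`, "XD")))
  })
  set.seed(childSeed(seed, paste0("perm-", scope)))
  maxStats <- vapply(seq_len(nPerm), function(b) {
    max(vapply(prep, function(pp) {
      idx <- seq_along(pp$gen)
      for (g in unique(pp$gen)) {
        w <- which(pp$gen == g)
        idx[w] <- w[sample.int(length(w))]
      }
      fs <- hkFStats(pp$XA[idx, , drop = FALSE], pp$XD[idx, , drop = FALSE],
                     pp$basis$Q, pp$basis$yres, pp$basis$rssRed,
                     pp$basis$rank, pp$basis$rssTol)
      max(fs$F)
    }, 0))
  }, 0)
  thr <- sort(maxStats)[ceiling((1 - level) * nPerm)]
  structure(list(threshold = thr, level = level, scope = scope,
                 nPerm = nPerm, maxStats = maxStats),
            class = "PermThreshold")
}

#' Named F-ratio threshold set for highF/lowF grouping
#'
#' @param thresholds increasing positive F values; the defaults (5, 7, 10)
#'   correspond to approximate chromosome-wise 5%, chromosome-wise 1% and
#'   genome-wide 1% significance in a 501-individual line cross.
#' @return named numeric vector of class `ThresholdSet`.
#' @export
thresholdSet <- function(thresholds = c(chromWise05 = 5, chromWise01 = 7,
                                        genomeWide01 = 10)) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and increasing")
  structure(thresholds, class = "ThresholdSet")
}
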