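## Reading/writing genotype, map and phenotype files, and the SNP
## quality-control filters applied before differentiation analysis.
##
## TSV genotype dialect: header `id  pop  locus1  locus2 ...`, dosage cells
## in {0,1,2,NA}; companion map TSV `locus  chrom  pos  panel`. PLINK-style
## .ped/.map pairs are accepted read-only. Positions are 1-based bp on the
## forward strand; the package never flips strand.

#' Write a GenotypePanel to the TSV dialect
#'
#' @param panel a [GenotypePanel-class].
#' @param genoPath path for the genotype TSV.
#' @param mapPath path for the companion map TSV.
#' @return Invisibly, the two paths.
#' @export
writeGenotypes <- function(panel, genoPath, mapPath) {
  d <- dosages(panel)
  out <- cbind(sampleInfo(panel)[, c("id", "pop")],
               as.data.frame(d, optional = TRUE))
  write.table(out, genoPath, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- loci(panel)
  panelLab <- if (!is.null(S4Vectors::mcols(gr)$panel))
    S4Vectors::mcols(gr)$panel else rep(NA_character_, length(gr))
  mp <- data.frame(locus = names(gr),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = GenomicRanges::start(gr),
                   panel = panelLab, stringsAsFactors = FALSE)
  write.table(mp, mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genoPath, mapPath))
}

#' Read genotypes from TSV or PLINK-style ped/map files
#'
#' For `format = "tsv"`, `path` is the genotype TSV and `mapPath` its
#' companion map. For `format = "ped-map"`, `path` is the `.ped` file and
#' `mapPath` the `.map`; allele coding is normalized per locus so the dosage
#' counts the alternate allele (the lexicographically larger of the two
#' observed allele labels), and the within-genotype order of the two alleles
#' is immaterial. Missing calls are `NA` in TSV and `0 0` in ped.
#'
#' @param path genotype (or ped) file path.
#' @param mapPath map file path.
#' @param format `"tsv"` or `"ped-map"`.
#' @return A [GenotypePanel-class].
#' @export
readGenotypes <- function(path, mapPath, format = c("tsv", "ped-map")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(mapPath)) stop("map file not found: ", mapPath)
  if (format == "tsv") readGenotypesTsv(path, mapPath)
  else readGenotypesPed(path, mapPath)
}

readGenotypesTsv <- function(path, mapPath) {
  g <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(g) < 3 || !identical(names(g)[1:2], c("id", "pop")))
    stop("malformed genotype TSV ", path,
         ": header must start with 'id', 'pop'")
  mp <- read.delim(mapPath, stringsAsFactors = FALSE)
  need <- c("locus", "chrom", "pos")
  if (!all(need %in% names(mp)))
    stop("malformed map TSV ", mapPath, ": needs columns ",
         paste(need, collapse = ", "))
  lociNames <- names(g)[-(1:2)]
  if (!setequal(lociNames, mp$locus))
    stop("loci in ", path, " and ", mapPath, " do not match")
  d <- as.matrix(g[, -(1:2), drop = FALSE])
  bad <- which(!(d %in% c(0, 1, 2) | is.na(d)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed line %d in %s: field '%s' is not 0/1/2/NA",
                 bad[1, 1] + 1L, path, lociNames[bad[1, 2]]))
  mp <- mp[match(lociNames, mp$locus), , drop = FALSE]
  if (is.null(mp$panel)) mp$panel <- NA_character_
  GenotypePanel(d, data.frame(id = g$id, pop = g$pop,
                              stringsAsFactors = FALSE), mp)
}

readGenotypesPed <- function(path, mapPath) {
  mp <- read.table(mapPath, stringsAsFactors = FALSE)
  if (ncol(mp) < 4)
    stop("malformed .map ", mapPath, ": expected 4 columns")
  names(mp)[1:4] <- c("chrom", "locus", "cM", "pos")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nl <- nrow(mp)
  ids <- character(length(lines)); pops <- character(length(lines))
  alleles <- matrix("", length(lines), 2L * nl)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * nl)
      stop(sprintf(
        "malformed line %d in %s: %d fields, expected %d (6 + 2 x %d loci)",
        i, path, length(f), 6L + 2L * nl, nl))
    pops[i] <- f[1]; ids[i] <- f[2]
    alleles[i, ] <- f[-(1:6)]
  }
  d <- matrix(NA_integer_, length(lines), nl)
  for (j in seq_len(nl)) {
    a1 <- alleles[, 2L * j - 1L]; a2 <- alleles[, 2L * j]
    obs <- sort(unique(c(a1, a2)))
    obs <- obs[obs != "0"]
    if (length(obs) > 2)
      stop(sprintf("locus %s in %s has >2 alleles: %s", mp$locus[j], path,
                   paste(obs, collapse = ",")))
    alt <- if (length(obs)) obs[length(obs)] else NA_character_
    miss <- a1 == "0" | a2 == "0"
    d[, j] <- (a1 == alt) + (a2 == alt)
    d[miss, j] <- NA_integer_
  }
  mp2 <- data.frame(locus = mp$locus, chrom = as.character(mp$chrom),
                    pos = mp$pos, stringsAsFactors = FALSE)
  GenotypePanel(d, data.frame(id = ids, pop = pops, stringsAsFactors = FALSE),
                mp2)
}

#' Read/write a phenotype + covariate TSV
#'
#' Dialect: header `id  <trait...>  <fixed effect...>`; trait columns are
#' numeric, covariate columns character.
#'
#' @param path file path.
#' @return data.frame with an `id` column.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Per-locus alternate-allele frequency within one population
#'
#' Frequency = sum of dosages / (2 x called individuals); missing calls are
#' excluded. A locus with zero called individuals gets `NA` frequency and
#' `defined = FALSE` rather than a silent zero. Observed heterozygote
#' proportions among the same called individuals are returned for use in
#' the F_ST estimator.
#'
#' @param panel a [GenotypePanel-class].
#' @param population population label (must exist in the sample table).
#' @return data.frame: `locus`, `chrom`, `pos`, `freq`, `nCalled`, `het`,
#'   `defined`.
#' @examples
#' gp <- GenotypePanel(rbind(c(0, 1), c(1, NA), c(2, 2), c(2, 2)),
#'   data.frame(id = letters[1:4], pop = "P1"),
#'   data.frame(locus = c("s1", "s2"), chrom = "1", pos = c(1, 2)))
#' alleleFrequencies(gp, "P1")$freq  # 5/8, 3/6
#' @export
alleleFrequencies <- function(panel, population) {
  if (!population %in% sampleInfo(panel)$pop)
    stop("population label not found: ", population)
  d <- dosages(panel)[sampleInfo(panel)$pop == population, , drop = FALSE]
  nCalled <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * nCalled)
  freq[nCalled == 0] <- NA_real_
  het <- colMeans(d == 1L, na.rm = TRUE)
  het[nCalled == 0] <- NA_real_
  gr <- loci(panel)
  data.frame(locus = names(gr),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             freq = unname(freq), nCalled = unname(nCalled),
             het = unname(het), defined = nCalled > 0,
             stringsAsFactors = FALSE)
}

#' Exact conditional Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, heterozygote counts follow the
#' (parity-preserving) hypergeometric-type distribution
#' `P(nHet | n, nAlt) = C 2^nHet n! / (nHomRef! nHet! nHomAlt!)`.
#' The p-value sums the probabilities of all outcomes no more probable than
#' the observed one. Monomorphic loci give p = 1. Vectorized over loci.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (vectors).
#' @return numeric vector of p-values.
#' @examples
#' hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  n <- length(nHomRef)
  stopifnot(length(nHet) == n, length(nHomAlt) == n,
            all(nHomRef >= 0), all(nHet >= 0), all(nHomAlt >= 0),
            all(nHomRef + nHet + nHomAlt >= 1))
  mapply(function(aa, ab, bb) {
    nInd <- aa + ab + bb
    nA <- 2L * aa + ab
    if (nA == 0L || nA == 2L * nInd) return(1)
    hets <- seq(nA %% 2L, min(nA, 2L * nInd - nA), by = 2L)
    logp <- hets * log(2) + lgamma(nInd + 1) -
      lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
      lgamma(nInd - (nA + hets) / 2 + 1)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    pObs <- p[match(ab, hets)]
    sum(p[p <= pObs * (1 + 1e-7)])
  }, nHomRef, nHet, nHomAlt)
}

#' Quality-control configuration
#'
#' Default thresholds are conventional SNP-array values: minor allele
#' frequency >= 0.05 (pooled), missingness <= 0.10, Hardy-Weinberg exact
#' p >= 1e-4 tested within each population (pooling diverged breeds would
#' reject through the Wahlund effect, which is not a genotyping-quality
#' signal).
#'
#' @param minMaf minimum pooled minor allele frequency.
#' @param maxMissing maximum per-locus missing fraction.
#' @param hweAlpha HWE rejection level.
#' @param hweScope `"per-population"` (reject if any population fails) or
#'   `"pooled"`.
#' @return list of class `QcConfig`.
#' @export
qcConfig <- function(minMaf = 0.05, maxMissing = 0.10, hweAlpha = 1e-4,
                     hweScope = c("per-population", "pooled")) {
  hweScope <- match.arg(hweScope)
  stopifnot(minMaf >= 0, minMaf <= 1, maxMissing >= 0, maxMissing <= 1,
            hweAlpha >= 0, hweAlpha <= 1)
  structure(list(minMaf = minMaf, maxMissing = maxMissing,
                 hweAlpha = hweAlpha, hweScope = hweScope),
            class = "QcConfig")
}

#' Apply SNP quality-control filters
#'
#' Removal order is fixed: missingness, then pooled MAF, then HWE at
#' `hweAlpha` in the configured scope; each locus is counted under the
#' first filter it fails. The audit also carries an `error_rate` category
#' (always 0 here: trio-based error filtering needs family data this
#' package does not model) so downstream report formats are stable.
#'
#' @param panel a [GenotypePanel-class].
#' @param cfg a [qcConfig()].
#' @return list: `panel` (filtered), `audit` (data.frame `filter`, `nRemoved`),
#'   `removed` (character vector of removed locus ids).
#' @export
applyQc <- function(panel, cfg = qcConfig()) {
  stopifnot(inherits(cfg, "QcConfig"))
  d <- dosages(panel)
  L <- ncol(d)
  keep <- rep(TRUE, L)
  missFrac <- colMeans(is.na(d))
  failMiss <- missFrac > cfg$maxMissing
  keep[failMiss] <- FALSE

  nCalled <- colSums(!is.na(d))
  pooledFreq <- ifelse(nCalled > 0, colSums(d, na.rm = TRUE) / (2 * nCalled),
                       NA_real_)
  maf <- pmin(pooledFreq, 1 - pooledFreq)
  failMaf <- keep & (is.na(maf) | maf < cfg$minMaf)
  keep[failMaf] <- FALSE

  failHwe <- rep(FALSE, L)
  if (cfg$hweAlpha > 0 && any(keep)) {
    idx <- which(keep)
    pvals <- rep(1, length(idx))
    if (cfg$hweScope == "pooled") {
      sub <- d[, idx, drop = FALSE]
      pvals <- hweExactTest(colSums(sub == 0L, na.rm = TRUE),
                            colSums(sub == 1L, na.rm = TRUE),
                            colSums(sub == 2L, na.rm = TRUE))
    } else {
      for (popName in unique(sampleInfo(panel)$pop)) {
        sub <- d[sampleInfo(panel)$pop == popName, idx, drop = FALSE]
        ok <- colSums(!is.na(sub)) >= 1
        pv <- rep(1, length(idx))
        pv[ok] <- hweExactTest(colSums(sub == 0L, na.rm = TRUE)[ok],
                               colSums(sub == 1L, na.rm = TRUE)[ok],
                               colSums(sub == 2L, na.rm = TRUE)[ok])
        pvals <- pmin(pvals, pv)
      }
    }
    failHwe[idx] <- pvals < cfg$hweAlpha
    keep[failHwe] <- FALSE
  }

  audit <- data.frame(
    filter = c("missingness", "maf", "hwe", "error_rate"),
    nRemoved = c(sum(failMiss), sum(failMaf), sum(failHwe), 0L),
    stringsAsFactors = FALSE)
  gr <- loci(panel)
  out <- GenotypePanel(d[, keep, drop = FALSE], sampleInfo(panel),
                       {
                         sub <- gr[keep]
                         pl <- S4Vectors::mcols(sub)$panel
                         data.frame(locus = names(sub),
                                    chrom = as.character(
                                      GenomicRanges::seqnames(sub)),
                                    pos = GenomicRanges::start(sub),
                                    panel = if (is.null(pl))
                                      NA_character_ else pl,
                                    stringsAsFactors = FALSE)
                       })
  list(panel = out, audit = audit, removed = names(gr)[!keep])
}

#' Restrict per-locus statistics to loci with defined F_ST
#'
#' Drops loci where the unweighted mean of the two breed frequencies is
#' exactly 0 or 1 (both breeds fixed for the same allele), where the
#' between-population variance decomposition is undefined.
#'
#' @param stats data.frame with columns `p1`, `p2` (e.g. from
#'   [locusDiffStats()]).
#' @return The subset with `mean(p1, p2)` strictly inside (0, 1).
#' @export
restrictDefinedFst <- function(stats) {
  stopifnot(all(c("p1", "p2") %in% names(stats)))
  pbar <- (stats$p1 + stats$p2) / 2
  keep <- !is.na(pbar) & pbar > 0 & pbar < 1
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
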