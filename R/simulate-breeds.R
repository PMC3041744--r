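## Two-breed SNP panel simulation.
##
## Divergence model: Balding-Nichols. Each breed's allele frequency at a
## neutral locus is an independent Beta draw around a shared ancestral
## frequency p0 with Var = F * p0 * (1 - p0), where F is the target
## background differentiation. Loci designated as "selected" are set to
## their target per-breed frequencies exactly (emulating loci fixed or
## nearly fixed for alternative alleles near trait genes).

#' Parameters for two-breed panel simulation
#'
#' @param nLoci number of neutral loci, placed proportionally to chromosome
#'   length at uniform random positions.
#' @param chromosomeLengths named numeric vector of chromosome lengths in bp.
#' @param backgroundFst target differentiation F in `[0, 1)` for neutral
#'   loci under the Balding-Nichols model.
#' @param selectedLoci optional data.frame with columns `chrom`, `pos`,
#'   `p1`, `p2`: loci whose per-breed frequencies are set exactly.
#' @param sampleSizes integer vector of length 2: individuals per breed
#'   (default `c(49, 20)`, a large dairy panel versus a smaller beef panel).
#' @param ancestralFreqRange ancestral frequencies are drawn uniformly on
#'   this interval; the default `(0.05, 0.95)` limits loci later lost to the
#'   defined-F_ST filter.
#' @param seed integer seed.
#' @return A validated list of class `BreedSimParams`.
#' @export
breedSimParams <- function(nLoci, chromosomeLengths,
                           backgroundFst = 0.1,
                           selectedLoci = NULL,
                           sampleSizes = c(49L, 20L),
                           ancestralFreqRange = c(0.05, 0.95),
                           seed = 1L) {
  stopifnot(nLoci >= 1, length(chromosomeLengths) >= 1,
            all(chromosomeLengths > 0))
  if (backgroundFst < 0 || backgroundFst >= 1)
    stop("backgroundFst must lie in [0, 1)")
  if (any(sampleSizes < 2)) stop("sample sizes must be >= 2")
  stopifnot(length(ancestralFreqRange) == 2,
            ancestralFreqRange[1] > 0, ancestralFreqRange[2] < 1,
            ancestralFreqRange[1] <= ancestralFreqRange[2])
  if (is.null(names(chromosomeLengths)))
    names(chromosomeLengths) <- as.character(seq_along(chromosomeLengths))
  if (!is.null(selectedLoci)) {
    stopifnot(all(c("chrom", "pos", "p1", "p2") %in% names(selectedLoci)))
    selectedLoci$chrom <- as.character(selectedLoci$chrom)
    bad <- !(selectedLoci$chrom %in% names(chromosomeLengths)) |
      selectedLoci$pos < 1 |
      selectedLoci$pos > chromosomeLengths[selectedLoci$chrom]
    if (any(bad))
      stop("selected-locus positions must lie within their chromosome")
    if (any(selectedLoci$p1 < 0 | selectedLoci$p1 > 1 |
            selectedLoci$p2 < 0 | selectedLoci$p2 > 1))
      stop("selected-locus target frequencies must lie in [0, 1]")
  }
  structure(list(nLoci = as.integer(nLoci),
                 chromosomeLengths = chromosomeLengths,
                 backgroundFst = backgroundFst,
                 selectedLoci = selectedLoci,
                 sampleSizes = as.integer(sampleSizes),
                 ancestralFreqRange = ancestralFreqRange,
                 seed = as.integer(seed)),
            class = "BreedSimParams")
}

#' Simulate per-breed allele frequencies under the Balding-Nichols model
#'
#' Neutral loci: each breed's frequency is an independent
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` draw (mean `p0`, variance
#' `F p0 (1-p0)`). `F = 0` degenerates to both breeds inheriting the
#' ancestral frequency exactly. Selected loci take their target frequencies
#' exactly. Output is ordered by (chromosome, position).
#'
#' @param params a [breedSimParams()] object.
#' @return data.frame: `locus`, `chrom`, `pos`, `p0` (ancestral), `p1`,
#'   `p2`, `selected` (logical).
#' @export
simulateBreedFrequencies <- function(params) {
  stopifnot(inherits(params, "BreedSimParams"))
  set.seed(childSeed(params$seed, "breed-frequencies"))
  lens <- params$chromosomeLengths
  nPer <- round(params$nLoci * lens / sum(lens))
  ## keep the total exact
  while (sum(nPer) != params$nLoci) {
    i <- which.max(lens)
    nPer[i] <- nPer[i] + sign(params$nLoci - sum(nPer))
  }
  chrom <- rep(names(lens), nPer)
  pos <- unlist(lapply(names(lens), function(cn)
    sort(sample.int(lens[[cn]], nPer[[cn]], replace = FALSE))),
    use.names = FALSE)
  p0 <- runif(length(pos), params$ancestralFreqRange[1],
              params$ancestralFreqRange[2])
  F <- params$backgroundFst
  if (F == 0) {
    p1 <- p0
    p2 <- p0
  } else {
    shape <- (1 - F) / F
    p1 <- rbeta(length(p0), p0 * shape, (1 - p0) * shape)
    p2 <- rbeta(length(p0), p0 * shape, (1 - p0) * shape)
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    p0 = p0, p1 = p1, p2 = p2, selected = FALSE,
                    stringsAsFactors = FALSE)
  sel <- params$selectedLoci
  if (!is.null(sel) && nrow(sel)) {
    out <- rbind(out,
                 data.frame(chrom = sel$chrom, pos = as.integer(sel$pos),
                            p0 = (sel$p1 + sel$p2) / 2, p1 = sel$p1,
                            p2 = sel$p2, selected = TRUE,
                            stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$locus <- sprintf("snp_%s_%d", out$chrom, out$pos)
  rownames(out) <- NULL
  out[, c("locus", "chrom", "pos", "p0", "p1", "p2", "selected")]
}

#' Sample diploid genotypes from per-breed allele frequencies
#'
#' Genotypes are drawn `Binomial(2, p)` per individual per locus
#' (Hardy-Weinberg within breed); an optional uniform missingness rate
#' replaces calls with `NA`.
#'
#' @param freqs data.frame from [simulateBreedFrequencies()] (needs columns
#'   `locus`, `chrom`, `pos`, `p1`, `p2`; an optional `selected` column is
#'   carried into the panel label).
#' @param sampleSizes integer vector of length 2.
#' @param seed integer seed.
#' @param missingRate per-call probability of a missing genotype.
#' @param popNames labels for the two breeds.
#' @return A [GenotypePanel-class]. Loci get a `panel` label:
#'   `"selected"` for selected loci, `"neutral"` otherwise.
#' @export
sampleGenotypes <- function(freqs, sampleSizes = c(49L, 20L), seed = 1L,
                            missingRate = 0,
                            popNames = c("breed1", "breed2")) {
  stopifnot(all(c("locus", "chrom", "pos", "p1", "p2") %in% names(freqs)),
            all(freqs$p1 >= 0 & freqs$p1 <= 1),
            all(freqs$p2 >= 0 & freqs$p2 <= 1),
            missingRate >= 0, missingRate <= 1)
  set.seed(childSeed(seed, "sample-genotypes"))
  n1 <- sampleSizes[1]; n2 <- sampleSizes[2]
  L <- nrow(freqs)
  g1 <- matrix(rbinom(n1 * L, 2L, rep(freqs$p1, each = n1)), nrow = n1)
  g2 <- matrix(rbinom(n2 * L, 2L, rep(freqs$p2, each = n2)), nrow = n2)
  d <- rbind(g1, g2)
  if (missingRate > 0)
    d[runif(length(d)) < missingRate] <- NA_integer_
  samples <- data.frame(
    id = sprintf("%s_%03d", rep(popNames, c(n1, n2)),
                 c(seq_len(n1), seq_len(n2))),
    pop = rep(popNames, c(n1, n2)), stringsAsFactors = FALSE)
  panel <- if (!is.null(freqs$selected))
    ifelse(freqs$selected, "selected", "neutral") else "neutral"
  GenotypePanel(d, samples,
                data.frame(locus = freqs$locus, chrom = freqs$chrom,
                           pos = freqs$pos, panel = panel,
                           stringsAsFactors = FALSE))
}
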