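## Central S4 containers.
##
## GenotypePanel   -- two-breed SNP panel: dosage matrix + sample table + loci
## LineCrossData   -- F2/backcross study: line-origin genotypes, map, phenotypes
## ScanResult      -- interval-mapping F tracks and the across-trait maximum

#' GenotypePanel: samples-by-loci diploid SNP dosages for two (or more) breeds
#'
#' Holds alternate-allele dosages (0, 1, 2 or `NA` for missing) for a set of
#' individuals with population labels, together with locus coordinates as a
#' [GenomicRanges::GRanges] (width-1 positions, 1-based, forward strand) whose
#' names are locus identifiers and whose metadata may carry a `panel` column
#' with the SNP discovery-panel label. Loci are kept sorted by
#' (chromosome, position); the constructor reorders columns as needed.
#'
#' @slot dosages integer matrix, individuals x loci; values in {0,1,2,NA}.
#' @slot samples data.frame with columns `id` and `pop`.
#' @slot loci `GRanges` of locus positions, names = locus ids.
#'
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  slots = c(dosages = "matrix", samples = "data.frame", loci = "GRanges"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@dosages
  if (nrow(d) != nrow(object@samples))
    msg <- c(msg, "nrow(dosages) must equal nrow(samples)")
  if (ncol(d) != length(object@loci))
    msg <- c(msg, "ncol(dosages) must equal length(loci)")
  if (!all(c("id", "pop") %in% names(object@samples)))
    msg <- c(msg, "samples must have columns 'id' and 'pop'")
  bad <- !(d %in% c(0L, 1L, 2L) | is.na(d))
  if (any(bad))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (is.null(names(object@loci)) || anyDuplicated(names(object@loci)))
    msg <- c(msg, "loci must have unique names (locus ids)")
  if (length(object@loci) > 1L && is.unsorted(order(as.character(
      GenomicRanges::seqnames(object@loci)))) == FALSE) {
    ## sortedness is enforced by the constructor; validity only spot-checks
    ## within-chromosome position order
    sp <- split(GenomicRanges::start(object@loci),
                as.character(GenomicRanges::seqnames(object@loci)))
    if (any(vapply(sp, is.unsorted, logical(1))))
      msg <- c(msg, "loci must be sorted by position within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages numeric/integer matrix (individuals x loci) of
#'   alternate-allele counts; `NA` marks missing calls.
#' @param samples data.frame with columns `id`, `pop`.
#' @param loci either a `GRanges` with named ranges, or a data.frame with
#'   columns `locus`, `chrom`, `pos` and optionally `panel`.
#' @return A validated [GenotypePanel-class] object with loci sorted by
#'   (chromosome, position).
#' @examples
#' gp <- GenotypePanel(
#'   dosages = rbind(c(0, 1, 2), c(2, NA, 0)),
#'   samples = data.frame(id = c("a", "b"), pop = c("P1", "P2")),
#'   loci = data.frame(locus = c("s1", "s2", "s3"), chrom = "1",
#'                     pos = c(100, 200, 300)))
#' nLoci(gp)
#' @export
GenotypePanel <- function(dosages, samples, loci) {
  if (is.data.frame(loci)) {
    gr <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$pos, width = 1L))
    names(gr) <- loci$locus
    if (!is.null(loci$panel)) S4Vectors::mcols(gr)$panel <- loci$panel
    loci <- gr
  }
  storage.mode(dosages) <- "integer"
  ord <- order(as.character(GenomicRanges::seqnames(loci)),
               GenomicRanges::start(loci))
  loci <- loci[ord]
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- names(loci)
  rownames(dosages) <- samples$id
  samples$id <- as.character(samples$id)
  samples$pop <- as.character(samples$pop)
  rownames(samples) <- NULL
  methods::new("GenotypePanel", dosages = dosages, samples = samples,
               loci = loci)
}

#' LineCrossData: marker genotypes, map and phenotypes of an F2/backcross herd
#'
#' Marker genotypes are coded by line origin: the count of alleles inherited
#' from founder line 1 (0/1/2, `NA` missing), which for fully informative
#' markers in a line cross equals the allele count itself. Phenotypes and
#' fixed-effect covariates are stored per individual; `traitModels` names,
#' for each trait, the covariate columns entering its linear model (the
#' genetic-composition effect `generation` is always added).
#'
#' @slot geno integer matrix, individuals x markers (line-1 allele counts).
#' @slot samples data.frame with columns `id`, `generation`
#'   (one of "F2", "CB1", "HB1").
#' @slot map data.frame with columns `marker`, `chrom`, `pos` (bp), `cM`,
#'   sorted by (chrom, pos) with cM monotone in bp within chromosome.
#' @slot pheno data.frame of trait values (one column per trait).
#' @slot covariates data.frame of fixed-effect levels (factors/characters).
#' @slot traitModels named list: trait -> character vector of covariate
#'   column names (possibly empty).
#'
#' @aliases LineCrossData-class
#' @exportClass LineCrossData
setClass("LineCrossData",
  slots = c(geno = "matrix", samples = "data.frame", map = "data.frame",
            pheno = "data.frame", covariates = "data.frame",
            traitModels = "list"))

setValidity("LineCrossData", function(object) {
  msg <- character()
  n <- nrow(object@samples)
  if (nrow(object@geno) != n) msg <- c(msg, "geno rows must match samples")
  if (nrow(object@pheno) != n) msg <- c(msg, "pheno rows must match samples")
  if (nrow(object@covariates) != n)
    msg <- c(msg, "covariates rows must match samples")
  if (!all(object@samples$generation %in% c("F2", "CB1", "HB1")))
    msg <- c(msg, "generation labels must be F2, CB1 or HB1")
  m <- object@map
  if (ncol(object@geno) != nrow(m))
    msg <- c(msg, "geno columns must match map rows")
  if (!all(c("marker", "chrom", "pos", "cM") %in% names(m)))
    msg <- c(msg, "map needs columns marker, chrom, pos, cM")
  else {
    sp <- split(seq_len(nrow(m)), m$chrom)
    for (ix in sp) {
      if (is.unsorted(m$pos[ix]))
        msg <- c(msg, "map positions must be sorted within chromosome")
      if (is.unsorted(m$cM[ix]))
        msg <- c(msg, "map cM must be monotone in bp within chromosome")
    }
  }
  g <- object@geno
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g)))
    msg <- c(msg, "geno values must be 0, 1, 2 or NA")
  if (!all(names(object@traitModels) %in% names(object@pheno)))
    msg <- c(msg, "traitModels names must be phenotype columns")
  if (length(msg)) msg else TRUE
})

#' Construct a LineCrossData object
#'
#' @param geno individuals x markers matrix of line-1 allele counts.
#' @param samples data.frame with `id`, `generation`.
#' @param map marker map data.frame (`marker`, `chrom`, `pos`, `cM`).
#' @param pheno data.frame of traits.
#' @param covariates data.frame of fixed-effect levels; may have zero columns.
#' @param traitModels named list mapping traits to covariate column names.
#' @return A validated [LineCrossData-class] object (markers sorted by map
#'   position).
#' @export
LineCrossData <- function(geno, samples, map, pheno, covariates = NULL,
                          traitModels = NULL) {
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  storage.mode(geno) <- "integer"
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- map$marker
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(nrow(samples)))
  if (is.null(traitModels))
    traitModels <- setNames(
      rep(list(character()), ncol(pheno)), names(pheno))
  samples$generation <- as.character(samples$generation)
  methods::new("LineCrossData", geno = geno, samples = samples, map = map,
               pheno = as.data.frame(pheno),
               covariates = as.data.frame(covariates),
               traitModels = traitModels)
}

#' ScanResult: interval-mapping F-ratio tracks on a fixed genomic grid
#'
#' @slot grid data.frame with columns `chrom`, `pos` (bp, multiples of the
#'   grid step).
#' @slot F numeric matrix, grid positions x traits.
#' @slot df1,df2 numeric matrices of numerator/denominator degrees of
#'   freedom, same shape as `F`.
#' @slot fmax numeric vector: position-wise maximum F over traits.
#' @slot argmaxTrait character vector: trait attaining the maximum.
#'
#' @aliases ScanResult-class
#' @exportClass ScanResult
setClass("ScanResult",
  slots = c(grid = "data.frame", F = "matrix", df1 = "matrix",
            df2 = "matrix", fmax = "numeric", argmaxTrait = "character"))

setValidity("ScanResult", function(object) {
  msg <- character()
  n <- nrow(object@grid)
  if (nrow(object@F) != n) msg <- c(msg, "F rows must match grid")
  if (length(object@fmax) != n) msg <- c(msg, "fmax length must match grid")
  if (any(object@F < 0, na.rm = TRUE)) msg <- c(msg, "F-ratios must be >= 0")
  if (n && !isTRUE(all.equal(object@fmax,
      unname(apply(object@F, 1L, max, na.rm = TRUE)))))
    msg <- c(msg, "fmax must be the row-wise maximum of F")
  if (length(msg)) msg else TRUE
})
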