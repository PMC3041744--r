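## Generics, accessors and show methods for the S4 containers.

#' @rdname GenotypePanel
#' @param x a `GenotypePanel` or `LineCrossData`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypePanel
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypePanel
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenotypePanel
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypePanel
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypePanel
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn GenotypePanel individuals-by-loci dosage matrix.
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)

#' @describeIn GenotypePanel sample table (`id`, `pop`).
#' @export
setMethod("sampleInfo", "GenotypePanel", function(x) x@samples)

#' @describeIn GenotypePanel locus coordinates as a `GRanges`.
#' @export
setMethod("loci", "GenotypePanel", function(x) x@loci)

#' @describeIn GenotypePanel unique population labels, in order of appearance.
#' @export
setMethod("populations", "GenotypePanel", function(x) unique(x@samples$pop))

#' @describeIn GenotypePanel number of loci.
#' @export
setMethod("nLoci", "GenotypePanel", function(x) length(x@loci))

#' @describeIn GenotypePanel number of individuals.
#' @export
setMethod("nSamples", "GenotypePanel", function(x) nrow(x@samples))

setMethod("show", "GenotypePanel", function(object) {
  tab <- table(object@samples$pop)
  cat("GenotypePanel:", nrow(object@samples), "individuals x",
      length(object@loci), "loci\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(as.character(GenomicRanges::seqnames(object@loci))),
            collapse = ", "), "\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
})

#' @rdname LineCrossData
#' @param x,object a `LineCrossData`.
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname LineCrossData
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname LineCrossData
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname LineCrossData
#' @export
setGeneric("traitModels", function(x) standardGeneric("traitModels"))

#' @rdname LineCrossData
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @describeIn LineCrossData line-origin genotype matrix.
#' @export
setMethod("dosages", "LineCrossData", function(x) x@geno)

#' @describeIn LineCrossData sample table (`id`, `generation`).
#' @export
setMethod("sampleInfo", "LineCrossData", function(x) x@samples)

#' @describeIn LineCrossData marker map (`marker`, `chrom`, `pos`, `cM`).
#' @export
setMethod("markerMap", "LineCrossData", function(x) x@map)

#' @describeIn LineCrossData phenotype table.
#' @export
setMethod("phenotypes", "LineCrossData", function(x) x@pheno)

#' @describeIn LineCrossData fixed-effect covariate table.
#' @export
setMethod("covariates", "LineCrossData", function(x) x@covariates)

#' @describeIn LineCrossData trait -> covariate-columns mapping.
#' @export
setMethod("traitModels", "LineCrossData", function(x) x@traitModels)

#' @describeIn LineCrossData names of the phenotype columns.
#' @export
setMethod("traitNames", "LineCrossData", function(x) names(x@pheno))

setMethod("show", "LineCrossData", function(object) {
  tab <- table(object@samples$generation)
  cat("LineCrossData:", nrow(object@samples), "individuals,",
      nrow(object@map), "markers,", ncol(object@pheno), "traits\n")
  cat("  generations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(object@map$chrom), collapse = ", "),
      "\n")
})

#' @rdname ScanResult
#' @param x,object a `ScanResult`.
#' @export
setGeneric("scanGrid", function(x) standardGeneric("scanGrid"))

#' @rdname ScanResult
#' @export
setGeneric("fmaxTrack", function(x) standardGeneric("fmaxTrack"))

#' @rdname ScanResult
#' @export
setGeneric("fMatrix", function(x) standardGeneric("fMatrix"))

#' @describeIn ScanResult the (chrom, pos) grid data.frame.
#' @export
setMethod("scanGrid", "ScanResult", function(x) x@grid)

#' @describeIn ScanResult data.frame `chrom, pos, Fmax, argmaxTrait`.
#' @export
setMethod("fmaxTrack", "ScanResult", function(x)
  data.frame(chrom = x@grid$chrom, pos = x@grid$pos, Fmax = x@fmax,
             argmaxTrait = x@argmaxTrait, stringsAsFactors = FALSE))

#' @describeIn ScanResult grid-by-trait matrix of F-ratios.
#' @export
setMethod("fMatrix", "ScanResult", function(x) x@F)

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", nrow(object@grid), "grid positions,",
      ncol(object@F), "trait(s)\n")
  if (nrow(object@grid)) {
    i <- which.max(object@fmax)
    cat(sprintf("  max Fmax = %.3f at %s:%d (trait %s)\n", object@fmax[i],
                object@grid$chrom[i], object@grid$pos[i],
                object@argmaxTrait[i]))
  }
})
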