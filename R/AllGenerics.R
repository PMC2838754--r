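#' @rdname GenotypeData
#' @param x object
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeData
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname GenotypeData
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname GenotypeData
#' @export
setGeneric("indivIds", function(x) standardGeneric("indivIds"))

#' @rdname Pedigree
#' @param x object
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))

#' @rdname HaplotypeSet
#' @param x object
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname RelationshipMatrix
#' @param x object
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' @rdname BayesBFit
#' @param x object
#' @export
setGeneric("snpEffects", function(x) standardGeneric("snpEffects"))

#' @rdname BayesBFit
#' @export
setGeneric("inclusionFreq", function(x) standardGeneric("inclusionFreq"))

#' @rdname EBVResult
#' @param x object
#' @export
setGeneric("ebv", function(x) standardGeneric("ebv"))

#' @rdname Split
#' @param x object
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname Split
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))

#' @rdname Split
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))
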