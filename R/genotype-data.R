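#' Construct a GenotypeData object
#'
#' @param geno individuals x SNPs matrix of 0/1/2/NA allele counts with
#'   individual rownames and SNP colnames (stored internally SNPs x
#'   individuals, the Bioconductor feature-major orientation).
#' @param map data.frame with one row per SNP: columns `chrom`, `bp`,
#'   optionally `cM` and `par` (pseudo-autosomal flag used by the
#'   X-masking rule; defaults to FALSE).
#' @param sex character vector of "male"/"female", one per individual.
#' @return a [GenotypeData-class].
#' @export
GenotypeData <- function(geno, map, sex) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$par)) map$par <- FALSE
  if (is.null(map$cM)) map$cM <- map$bp / 1e6
  stopifnot(nrow(map) == ncol(geno), length(sex) == nrow(geno))
  a <- t(geno)
  rownames(a) <- if (!is.null(map$id)) map$id else colnames(geno)
  rd <- S4Vectors::DataFrame(chrom = map$chrom, bp = map$bp, cM = map$cM,
                             par = map$par, row.names = rownames(a))
  cd <- S4Vectors::DataFrame(sex = sex, row.names = rownames(geno))
  se <- SummarizedExperiment(assays = list(geno = a), rowData = rd,
                             colData = cd)
  new("GenotypeData", se)
}

#' @rdname GenotypeData
#' @export
setMethod("genotypes", "GenotypeData", function(x) t(assay(x, "geno")))

#' @rdname GenotypeData
#' @export
setMethod("snpMap", "GenotypeData", function(x) {
  rd <- rowData(x)
  data.frame(chrom = rd$chrom, id = rownames(x), cM = rd$cM, bp = rd$bp,
             par = rd$par, stringsAsFactors = FALSE)
})

#' @rdname GenotypeData
#' @export
setMethod("indivIds", "GenotypeData", function(x) colnames(x))

#' @rdname GenotypeData
#' @export
setMethod("alleleFreqs", "GenotypeData", function(x) {
  g <- assay(x, "geno")
  p <- rowMeans(g, na.rm = TRUE) / 2
  setNames(p, rownames(x))
})

#' @rdname GenotypeData
#' @param x a GenotypeData
#' @export
sexOf <- function(x) setNames(colData(x)$sex, colnames(x))

setMethod("show", "GenotypeData", function(object) {
  g <- assay(object, "geno")
  cat("GenotypeData:", ncol(object), "individuals x", nrow(object),
      "SNPs;", sprintf("%.2f%% missing", 100 * mean(is.na(g))), "\n")
})

#' Convert phased haplotypes to genotype data
#'
#' @param haps a [HaplotypeSet-class].
#' @param sex named character vector of sexes covering `ids`, or a
#'   [Pedigree-class] to look sexes up in.
#' @param ids individuals to include (default: all in `haps`).
#' @return a [GenotypeData-class].
#' @export
asGenotypeData <- function(haps, sex, ids = indivIds(haps)) {
  if (is(sex, "Pedigree"))
    sex <- setNames(sex@records$sex, sex@records$id)
  sub <- haps[ids, ]
  g <- genotypeMatrix(sub)
  GenotypeData(g, sub@map, unname(sex[ids]))
}
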