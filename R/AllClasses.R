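# Central S4 containers.  Validity methods encode the structural
# invariants every downstream stage relies on; accessors live in the
# module files.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Pedigree container
#'
#' Holds one record per individual: `id`, `sire`, `dam` (NA when
#' unknown), `sex` ("male"/"female") and `birth_year`.  Validity
#' enforces unique ids, that every named parent has its own record and
#' was born strictly before its offspring (which also guarantees
#' acyclicity), and that sires are male and dams female.
#'
#' @slot records data.frame with columns id, sire, dam, sex, birth_year.
#' @exportClass Pedigree
setClass("Pedigree", slots = c(records = "data.frame"))

setValidity("Pedigree", function(object) {
  df <- object@records
  need <- c("id", "sire", "dam", "sex", "birth_year")
  if (!all(need %in% names(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id)) return("individual ids must be unique")
  if (any(is.na(df$id) | df$id == "")) return("empty individual id")
  if (!all(df$sex %in% c("male", "female"))) return("sex must be male/female")
  idx <- match(df$sire, df$id)
  if (any(!is.na(df$sire) & is.na(idx)))
    return("every named sire must appear as a record")
  jdx <- match(df$dam, df$id)
  if (any(!is.na(df$dam) & is.na(jdx)))
    return("every named dam must appear as a record")
  if (any(df$sex[idx[!is.na(idx)]] != "male")) return("sires must be male")
  if (any(df$sex[jdx[!is.na(jdx)]] != "female")) return("dams must be female")
  py <- df$birth_year[idx]; ok <- is.na(py) | py < df$birth_year
  if (!all(ok)) return("sire birth years must strictly precede offspring")
  py <- df$birth_year[jdx]; ok <- is.na(py) | py < df$birth_year
  if (!all(ok)) return("dam birth years must strictly precede offspring")
  TRUE
})

#' Phased haplotype container
#'
#' Two phased 0/1 allele sequences per individual over a shared SNP map.
#' Haplotype rows are stored individual-major: rows `2i - 1` and `2i`
#' belong to `ids[i]`.
#'
#' @slot alleles integer matrix (2 * n individuals) x n SNPs, values 0/1.
#' @slot ids character vector of individual ids.
#' @slot map data.frame with columns chrom, id, cM, bp; positions strictly
#'   increasing within chromosome.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
         slots = c(alleles = "matrix", ids = "character", map = "data.frame"))

setValidity("HaplotypeSet", function(object) {
  a <- object@alleles; m <- object@map
  if (nrow(a) != 2L * length(object@ids))
    return("alleles must have two rows per individual")
  if (ncol(a) != nrow(m)) return("alleles columns must match map rows")
  if (!all(c("chrom", "id", "cM", "bp") %in% names(m)))
    return("map needs columns chrom, id, cM, bp")
  if (anyDuplicated(m$id)) return("SNP ids must be unique")
  if (!all(a %in% c(0L, 1L))) return("allele values must be 0/1")
  for (ch in unique(m$chrom)) {
    bp <- m$bp[m$chrom == ch]
    if (any(diff(bp) <= 0))
      return("positions must be strictly increasing within chromosome")
  }
  TRUE
})

#' Genotype container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `"geno"` assay of 0/1/2/NA allele counts stored SNPs x individuals
#' (Bioconductor feature-major orientation).  `rowData` carries the SNP
#' map (`chrom`, `bp`, `cM`, `par` pseudo-autosomal flag), `colData` the
#' individual `sex`.  Use [genotypes()] for the individuals x SNPs view
#' used by the predictors.
#'
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"geno" %in% assayNames(object)) return("assay 'geno' is required")
  g <- assay(object, "geno")
  if (!all(is.na(g) | g %in% c(0, 1, 2)))
    return("genotype codes must be 0, 1, 2 or NA")
  rd <- rowData(object)
  if (!all(c("chrom", "bp") %in% names(rd)))
    return("rowData needs columns chrom and bp")
  if (!"sex" %in% names(colData(object)))
    return("colData needs a sex column")
  TRUE
})

#' Relationship matrix (numerator or genomic)
#'
#' @slot mat symmetric numeric matrix with id dimnames.
#' @slot kind "numerator" or "genomic".
#' @slot alleleFreqs for genomic matrices, the allele frequencies used
#'   in the centering; NULL for numerator matrices.
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
         slots = c(mat = "matrix", kind = "character",
                   alleleFreqs = "numericOrNULL"))

setValidity("RelationshipMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must carry identical row/column id names")
  if (!isSymmetric(unname(m), tol = 1e-8)) return("matrix must be symmetric")
  if (!object@kind %in% c("numerator", "genomic"))
    return("kind must be 'numerator' or 'genomic'")
  if (object@kind == "numerator") {
    if (any(m < -1e-8)) return("numerator relationships must be >= 0")
    if (any(diag(m) < 1 - 1e-8)) return("numerator diagonal must be >= 1")
  }
  TRUE
})

#' Additive trait architecture
#'
#' QTL positions (SNP ids of the simulated loci), their additive allele
#' substitution effects (scaled at construction so the realized variance
#' of true breeding values in the reference individuals matches
#' `sigma2A`), the residual variance and the heritability of a single
#' daughter record.
#'
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
         slots = c(trait = "character", qtlIds = "character",
                   effects = "numeric", sigma2A = "numeric",
                   sigma2E = "numeric", h2 = "numeric"))

setValidity("TraitArchitecture", function(object) {
  if (length(object@qtlIds) != length(object@effects))
    return("one effect per QTL required")
  if (object@h2 <= 0 || object@h2 > 1) return("h2 must be in (0, 1]")
  if (object@sigma2A < 0 || object@sigma2E < 0)
    return("variances must be non-negative")
  TRUE
})

#' BayesB sampler configuration
#'
#' @slot pi prior probability that a SNP is fitted (in (0, 1]).
#' @slot nuE,nuBeta scaled-inverse-chi-square prior degrees of freedom
#'   for the residual and per-locus effect variances.
#' @slot s2Beta prior scale for the locus effect variance; NA derives it
#'   from the additive variance as sigma2A / (pi * sum 2 p q).
#' @slot chainLength,burnIn,thin MCMC controls (chainLength > burnIn).
#' @slot fixedEffectVariance if TRUE the locus variance is held at its
#'   prior mean (no Metropolis-Hastings variance draw); with pi = 1 this
#'   makes the sampler a weighted RR-BLUP Gibbs sampler.
#' @slot essWarn warn when the effective sample size of the residual
#'   variance trace falls below this.
#' @exportClass BayesBConfig
setClass("BayesBConfig",
         slots = c(pi = "numeric", nuE = "numeric", nuBeta = "numeric",
                   s2Beta = "numeric", chainLength = "numeric",
                   burnIn = "numeric", thin = "numeric",
                   fixedEffectVariance = "logical", essWarn = "numeric"))

setValidity("BayesBConfig", function(object) {
  if (object@pi <= 0 || object@pi > 1) return("pi must be in (0, 1]")
  if (object@chainLength <= object@burnIn)
    return("chainLength must exceed burnIn")
  if (object@thin < 1) return("thin must be >= 1")
  if (object@nuE <= 2 || object@nuBeta <= 2)
    return("prior degrees of freedom must exceed 2")
  TRUE
})

#' Fitted BayesB model
#'
#' Posterior summaries over the post-burn-in samples: `beta` is the
#' posterior mean of the *realised* effect beta_k * delta_k (the
#' quantity entering the GEBV), `inclusion` the posterior inclusion
#' frequency of each SNP.
#'
#' @exportClass BayesBFit
setClass("BayesBFit",
         slots = c(alpha = "numeric", beta = "numeric",
                   inclusion = "numeric", sigma2e = "numeric",
                   traces = "matrix", snpIds = "character",
                   trainIds = "character", config = "BayesBConfig"))

setValidity("BayesBFit", function(object) {
  if (any(object@inclusion < 0 | object@inclusion > 1))
    return("inclusion frequencies must lie in [0, 1]")
  nkeep <- floor((object@config@chainLength - object@config@burnIn) /
                   object@config@thin)
  if (nrow(object@traces) != nkeep)
    return("trace length must equal (chain - burnIn) / thin")
  TRUE
})

#' Estimated breeding values
#'
#' @slot ebv named numeric vector of (G)EBVs.
#' @slot method "BayesB", "G-BLUP" or "P-BLUP".
#' @slot mu fitted overall mean (BLUP models; NA for BayesB where the
#'   intercept is excluded from the breeding value).
#' @exportClass EBVResult
setClass("EBVResult",
         slots = c(ebv = "numeric", method = "character", mu = "numeric"))

setValidity("EBVResult", function(object) {
  if (is.null(names(object@ebv))) return("ebv must be a named vector")
  if (!object@method %in% c("BayesB", "G-BLUP", "P-BLUP", "RR-BLUP"))
    return("unknown method tag")
  TRUE
})

#' Constraints for the relationship-controlled split sampler
#'
#' @exportClass SplitConstraints
setClass("SplitConstraints",
         slots = c(aMax = "numeric", trainSize = "numeric",
                   valSize = "numeric", minValSize = "numeric",
                   maxPerSibFamily = "numeric",
                   forbidSiresInValidation = "logical",
                   uniqueValidation = "logical", nReplicates = "numeric"))

setValidity("SplitConstraints", function(object) {
  if (object@aMax <= 0 || object@aMax > 2) return("aMax must be in (0, 2]")
  if (object@trainSize < 1 || object@minValSize < 1 || object@valSize < 1)
    return("sizes must be positive")
  if (object@nReplicates < 1) return("nReplicates must be >= 1")
  TRUE
})

#' One training/validation split
#'
#' @exportClass Split
setClass("Split",
         slots = c(replicate = "integer", train = "character",
                   validation = "character", excluded = "character",
                   aMax = "numeric", realizedMax = "numeric"))

setValidity("Split", function(object) {
  if (length(intersect(object@train, object@validation)) ||
      length(intersect(object@train, object@excluded)) ||
      length(intersect(object@validation, object@excluded)))
    return("train, validation and excluded sets must be pairwise disjoint")
  if (!is.na(object@realizedMax) &&
      object@realizedMax > object@aMax + 1e-10)
    return("realized maximum relationship exceeds aMax")
  TRUE
})
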