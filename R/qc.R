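# SNP quality control: X-heterozygote masking, missingness/MAF
# filtering, naive imputation.  The intended order mirrors routine
# practice on bull genotypes: mask X first, then compute missingness and
# MAF on what remains, then (for file inputs) impute.

#' Mask heterozygous male calls on the non-pseudo-autosomal X
#'
#' Males are hemizygous outside the pseudo-autosomal region (PAR), so a
#' heterozygous call there is a genotyping artifact: it is set to
#' missing.  All other cells are unchanged.  X SNPs are those with
#' `chrom == "X"` in the map; the `par` flag marks pseudo-autosomal
#' SNPs, which are exempt.
#'
#' @param gd a [GenotypeData-class] with sexes and an X/PAR-flagged map.
#' @return a [GenotypeData-class] with masked calls.
#' @export
maskXHeterozygotes <- function(gd) {
  a <- assay(gd, "geno")
  rd <- rowData(gd)
  xs <- which(as.character(rd$chrom) == "X" & !rd$par)
  if (length(xs)) {
    males <- which(colData(gd)$sex == "male")
    block <- a[xs, males, drop = FALSE]
    block[block == 1] <- NA
    a[xs, males] <- block
  }
  out <- gd
  assay(out, "geno") <- a
  out
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Retains SNPs with missing rate strictly below `maxMissingRate` and
#' minor allele frequency strictly above `minMaf` (both thresholds are
#' strict, matching the "less than 5% missing, MAF greater than 3%"
#' convention).  Frequencies are computed over non-missing calls.  An
#' exclusion log (SNP id and the first failing reason, "missingness"
#' before "maf") is attached to the result's metadata and retrievable
#' with [exclusionLog()].
#'
#' @param gd a [GenotypeData-class].
#' @param maxMissingRate,minMaf thresholds in `[0, 1]`.
#' @return the filtered [GenotypeData-class].
#' @export
filterSnps <- function(gd, maxMissingRate = 0.05, minMaf = 0.03) {
  stopifnot(maxMissingRate >= 0, maxMissingRate <= 1,
            minMaf >= 0, minMaf <= 1)
  a <- assay(gd, "geno")
  missRate <- rowMeans(is.na(a))
  p <- rowMeans(a, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNP: treated as monomorphic
  failMiss <- missRate >= maxMissingRate
  failMaf <- maf <= minMaf
  keep <- !failMiss & !failMaf
  if (!any(keep))
    stop("empty-panel error: no SNP passes the filters")
  log <- data.frame(
    snp = rownames(a)[!keep],
    reason = ifelse(failMiss[!keep], "missingness", "maf"),
    stringsAsFactors = FALSE)
  out <- gd[keep, ]
  metadata(out)$exclusions <- rbind(metadata(gd)$exclusions, log)
  out
}

#' @rdname filterSnps
#' @return for `exclusionLog`: data.frame of (snp, reason) rows
#'   accumulated by [filterSnps()].
#' @export
exclusionLog <- function(gd) {
  log <- metadata(gd)$exclusions
  if (is.null(log))
    log <- data.frame(snp = character(), reason = character(),
                      stringsAsFactors = FALSE)
  log
}

#' Impute missing genotype calls
#'
#' Naive single-SNP imputation for file inputs: `"mean_rounded"`
#' replaces missing calls with the rounded mean of the observed calls at
#' that SNP; `"allele_frequency_draw"` draws two alleles at the observed
#' frequency.  Non-missing cells are never altered.
#'
#' @param gd a [GenotypeData-class].
#' @param method imputation method.
#' @param seed RNG seed (used by the frequency draw).
#' @return a complete [GenotypeData-class].
#' @export
imputeMissing <- function(gd,
                          method = c("mean_rounded",
                                     "allele_frequency_draw"),
                          seed = NULL) {
  method <- match.arg(method)
  a <- assay(gd, "geno")
  bad <- rowSums(!is.na(a)) == 0
  if (any(bad))
    stop("cannot impute SNP(s) with all calls missing: ",
         paste(head(rownames(a)[bad], 5), collapse = ", "))
  run <- function() {
    for (k in which(rowSums(is.na(a)) > 0)) {
      miss <- is.na(a[k, ])
      a[k, miss] <- switch(method,
        mean_rounded = round(mean(a[k, !miss])),
        allele_frequency_draw =
          stats::rbinom(sum(miss), 2L, mean(a[k, !miss]) / 2))
    }
    a
  }
  a <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- gd
  assay(out, "geno") <- a
  out
}
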