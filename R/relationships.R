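# Pedigree (numerator, A) and SNP-based (genomic, G) relationship
# matrices, plus cross-set relationship queries.

#' @rdname RelationshipMatrix
#' @export
setMethod("relMatrix", "RelationshipMatrix", function(x) x@mat)

#' @rdname RelationshipMatrix
#' @export
setMethod("indivIds", "RelationshipMatrix",
          function(x) rownames(x@mat))

setMethod("show", "RelationshipMatrix", function(object) {
  cat(object@kind, "relationship matrix over", nrow(object@mat),
      "individuals; mean diagonal",
      sprintf("%.3f", mean(diag(object@mat))), "\n")
})

#' @rdname RelationshipMatrix
#' @param x a RelationshipMatrix
#' @param i,j id vectors (character) or indices
#' @param ... ignored
#' @param drop passed to matrix subsetting
#' @export
setMethod("[", "RelationshipMatrix",
          function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@mat))
  if (missing(j)) j <- i
  x@mat[i, j, drop = drop]
})

#' Numerator relationship matrix by the tabular method
#'
#' Recurses over the pedigree in parents-before-offspring order:
#' `A[i, j] = (A[j, sire] + A[j, dam]) / 2` for earlier j, and
#' `A[i, i] = 1 + A[sire, dam] / 2`, so inbreeding accumulates on the
#' diagonal.  Unknown parents are treated as unrelated, non-inbred
#' founders.  When `subsetIds` is given, the pedigree is first pruned to
#' those individuals and their ancestors and the submatrix is returned.
#'
#' @param pedigree a [Pedigree-class].
#' @param subsetIds ids of the returned submatrix (default: everyone).
#' @return a [RelationshipMatrix-class] of kind `"numerator"`.
#' @examples
#' ped <- simulatePedigree(1, c(2, 4), 2, 2, seed = 1,
#'                         familySizeDispersion = 0)
#' A <- numeratorRelationshipMatrix(ped)
#' @export
numeratorRelationshipMatrix <- function(pedigree, subsetIds = NULL) {
  df <- pedigree@records
  if (!is.null(subsetIds)) {
    miss <- setdiff(subsetIds, df$id)
    if (length(miss))
      stop("subset ids not in pedigree: ",
           paste(head(miss, 5), collapse = ", "))
    # prune to subset + ancestors
    keep <- subsetIds
    repeat {
      par <- unique(c(df$sire[df$id %in% keep], df$dam[df$id %in% keep]))
      par <- par[!is.na(par)]
      add <- setdiff(par, keep)
      if (!length(add)) break
      keep <- c(keep, add)
    }
    df <- df[df$id %in% keep, , drop = FALSE]
  }
  ord <- order(df$birth_year)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  s <- match(df$sire, df$id)
  d <- match(df$dam, df$id)
  A <- matrix(0, n, n, dimnames = list(df$id, df$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + A[j, si]
      if (!is.na(di)) row <- row + A[j, di]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
  }
  out <- if (is.null(subsetIds)) A else A[subsetIds, subsetIds, drop = FALSE]
  new("RelationshipMatrix", mat = out, kind = "numerator",
      alleleFreqs = NULL)
}

#' Genomic relationship matrix (centered cross-product form)
#'
#' `G = sum_k (x_k - 2 p_k 1)(x_k - 2 p_k 1)' / (2 sum_k p_k (1 - p_k))`
#' over the SNP panel; frequencies default to those observed in the
#' supplied individuals (training and validation pooled).  This is the
#' form under which G-BLUP is exactly equivalent to RR-BLUP with a
#' common SNP-effect variance.
#'
#' @param gd a complete (no missing calls) [GenotypeData-class] with at
#'   least two polymorphic SNPs.
#' @param alleleFreqs optional externally supplied frequencies (named by
#'   SNP or in panel order).
#' @return a [RelationshipMatrix-class] of kind `"genomic"`.
#' @export
genomicRelationshipMatrix <- function(gd, alleleFreqs = NULL) {
  a <- assay(gd, "geno")
  if (anyNA(a))
    stop("genotypes contain missing calls; run imputeMissing() first")
  p <- if (is.null(alleleFreqs)) rowMeans(a) / 2 else {
    if (!is.null(names(alleleFreqs))) alleleFreqs[rownames(a)]
    else rep_len(alleleFreqs, nrow(a))
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("zero denominator: panel is monomorphic at the supplied ",
         "frequencies")
  if (sum(p > 0 & p < 1) < 2)
    stop("at least two polymorphic SNPs are required")
  Z <- t(a - 2 * p)              # individuals x SNPs, centered
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2            # enforce exact symmetry
  new("RelationshipMatrix", mat = G, kind = "genomic",
      alleleFreqs = setNames(as.numeric(p), rownames(a)))
}

#' Maximum relationship between two sets
#'
#' The largest pairwise relationship `A[t, v]` over training bulls t and
#' validation bulls v — the quantity the split sampler constrains
#' (a_max).
#'
#' @param A a [RelationshipMatrix-class].
#' @param setTrain,setVal disjoint, non-empty id sets covered by `A`.
#' @return the maximum cross-set relationship (scalar).
#' @export
maxRelationship <- function(A, setTrain, setVal) {
  if (!length(setTrain) || !length(setVal))
    stop("both sets must be non-empty")
  if (length(intersect(setTrain, setVal)))
    stop("design error: training and validation sets overlap")
  ids <- rownames(A@mat)
  miss <- setdiff(c(setTrain, setVal), ids)
  if (length(miss))
    stop("ids not covered by the relationship matrix: ",
         paste(head(miss, 5), collapse = ", "))
  max(A@mat[setTrain, setVal, drop = FALSE])
}
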