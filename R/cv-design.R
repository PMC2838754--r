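# Relationship-constrained training/validation splits: the sampler
# controls the maximum pedigree relationship (a_max) between any
# training and any validation bull, caps validation membership per
# paternal half-sib family, keeps sires of training bulls out of
# validation, and never re-uses a validation bull across replicates.

#' Constraints for the split sampler
#'
#' @param aMax maximum permitted additive-genetic relationship between
#'   any training and any validation bull.
#' @param trainSize target training size (trimmed down to this by
#'   random removal when more bulls are available).
#' @param valSize target validation size per replicate.
#' @param minValSize smallest acceptable validation size; the sampler
#'   reports the binding constraint when it cannot be reached.
#' @param maxPerSibFamily maximum validation bulls per paternal
#'   half-sib family (default 2).
#' @param forbidSiresInValidation keep fathers of training bulls out of
#'   validation (default TRUE).
#' @param uniqueValidation forbid re-use of validation bulls across
#'   replicates (default TRUE).
#' @param nReplicates number of training/validation pairs.
#' @return a [SplitConstraints-class].
#' @export
splitConstraints <- function(aMax, trainSize, valSize = 33,
                             minValSize = 30, maxPerSibFamily = 2,
                             forbidSiresInValidation = TRUE,
                             uniqueValidation = TRUE, nReplicates = 15) {
  new("SplitConstraints", aMax = aMax, trainSize = trainSize,
      valSize = valSize, minValSize = minValSize,
      maxPerSibFamily = maxPerSibFamily,
      forbidSiresInValidation = forbidSiresInValidation,
      uniqueValidation = uniqueValidation, nReplicates = nReplicates)
}

#' @rdname Split
#' @export
setMethod("trainIds", "Split", function(x) x@train)

#' @rdname Split
#' @export
setMethod("validationIds", "Split", function(x) x@validation)

#' @rdname Split
#' @export
setMethod("excludedIds", "Split", function(x) x@excluded)

setMethod("show", "Split", function(object) {
  cat(sprintf(paste0("Split (replicate %d, aMax = %g): %d training, ",
                     "%d validation, %d excluded; realized max = %.4f\n"),
              object@replicate, object@aMax, length(object@train),
              length(object@validation), length(object@excluded),
              object@realizedMax))
})

# one randomized greedy attempt at a validation set; returns NULL when
# the minimum validation size cannot be reached
.greedyAttempt <- function(Am, cand, valPool, fam, sonsOf, cn) {
  val <- character(0)
  excl <- character(0)
  famCount <- integer(0)
  for (v in sample(valPool)) {
    if (length(val) >= cn@valSize) break
    f <- fam[[v]]
    if (!is.null(famCount[f]) && !is.na(famCount[f]) &&
        famCount[f] >= cn@maxPerSibFamily) next
    conflict <- cand[Am[cand, v] > cn@aMax]
    if (cn@forbidSiresInValidation)
      conflict <- union(conflict, sonsOf[[v]])
    conflict <- setdiff(conflict, c(val, v))
    val <- c(val, v)
    excl <- union(excl, conflict)
    famCount[f] <- if (is.na(famCount[f])) 1L else famCount[f] + 1L
  }
  if (length(val) < cn@minValSize) return(NULL)
  excl <- setdiff(excl, val)     # a conflicted bull chosen into
                                 # validation is no longer excluded
  list(val = val, excl = excl)
}

#' Sample relationship-constrained training/validation splits
#'
#' Randomized greedy sampler: validation candidates are drawn in random
#' order subject to the family and sire rules; every training bull whose
#' relationship with a chosen validation bull exceeds `aMax` is excluded
#' from the analysis of that replicate.  Each replicate is attempted
#' `nTries` times and the assignment excluding the fewest bulls is
#' kept, approximating the "exclude as few bulls as possible"
#' objective.  The remaining bulls form training, trimmed to the target
#' size by random removal.
#'
#' @param A a [RelationshipMatrix-class] (pedigree-based) covering the
#'   candidates.
#' @param pedigree the [Pedigree-class] (supplies paternal half-sib
#'   family and sire/son structure).
#' @param candidateIds genotyped, phenotyped bulls available for either
#'   set.
#' @param constraints a [SplitConstraints-class].
#' @param seed RNG seed.
#' @param nTries greedy restarts per replicate.
#' @return list of [Split-class] objects.
#' @export
sampleSplits <- function(A, pedigree, candidateIds, constraints,
                         seed = NULL, nTries = 10) {
  cn <- constraints
  validObject(cn)
  Am <- A@mat
  miss <- setdiff(candidateIds, rownames(Am))
  if (length(miss))
    stop("relationship matrix does not cover candidates: ",
         paste(head(miss, 5), collapse = ", "))
  famVec <- halfSibFamilies(pedigree, candidateIds)
  fam <- as.list(famVec)
  df <- pedigree@records
  sonsOf <- lapply(setNames(candidateIds, candidateIds), function(v)
    intersect(df$id[!is.na(df$sire) & df$sire == v], candidateIds))
  run <- function() {
    used <- character(0)
    out <- vector("list", cn@nReplicates)
    for (rep_ in seq_len(cn@nReplicates)) {
      valPool <- if (cn@uniqueValidation)
        setdiff(candidateIds, used) else candidateIds
      best <- NULL
      for (t in seq_len(nTries)) {
        att <- .greedyAttempt(Am, candidateIds, valPool, fam, sonsOf, cn)
        if (is.null(att)) next
        if (is.null(best) || length(att$excl) < length(best$excl))
          best <- att
      }
      if (is.null(best))
        stop("constraints unsatisfiable at replicate ", rep_,
             ": cannot reach the minimum validation size of ",
             cn@minValSize, " (binding constraint: aMax = ", cn@aMax,
             if (cn@uniqueValidation)
               paste0(", ", length(used), " bulls already used in ",
                      "validation"), ")")
      train <- setdiff(candidateIds, c(best$val, best$excl))
      if (length(train) > cn@trainSize)
        train <- sample(train, cn@trainSize)
      if (!length(train))
        stop("constraints unsatisfiable at replicate ", rep_,
             ": no training bulls remain")
      used <- c(used, best$val)
      out[[rep_]] <- new("Split", replicate = as.integer(rep_),
                         train = train, validation = best$val,
                         excluded = best$excl, aMax = cn@aMax,
                         realizedMax = max(Am[train, best$val]))
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Halve a training set while protecting close relatives of validation
#'
#' Removes random training bulls down to `targetSize`, never removing a
#' bull whose relationship to any validation bull is at least
#' `protectThreshold` (default 0.25: fathers, full sibs and half sibs of
#' validation bulls stay), so the number of close relatives between the
#' sets is unchanged and only the precision of the SNP effects drops.
#'
#' @param split a [Split-class].
#' @param targetSize reduced training size.
#' @param A the pedigree [RelationshipMatrix-class].
#' @param protectThreshold protection cut-off on the relationship.
#' @param seed RNG seed.
#' @return a [Split-class] with the reduced training set.
#' @export
downsampleTraining <- function(split, targetSize, A,
                               protectThreshold = 0.25, seed = NULL) {
  train <- split@train
  if (targetSize > length(train))
    stop("targetSize exceeds the current training size")
  rel <- A@mat[train, split@validation, drop = FALSE]
  protected <- train[apply(rel, 1L, max) >= protectThreshold]
  if (length(protected) > targetSize)
    stop("infeasibility error: ", length(protected),
         " protected bulls exceed the target size ", targetSize)
  free <- setdiff(train, protected)
  run <- function() {
    keep <- c(protected, sample(free, targetSize - length(protected)))
    new("Split", replicate = split@replicate, train = keep,
        validation = split@validation,
        excluded = union(split@excluded, setdiff(train, keep)),
        aMax = split@aMax,
        realizedMax = max(A@mat[keep, split@validation]))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
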