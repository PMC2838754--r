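# Accuracy estimation from validation DYDs, the LD/relationship
# accuracy decomposition, and the r2 LD decay profile.

#' Progeny-test (selection index) accuracy of a DYD
#'
#' `r_gy = sqrt((n h2 / 4) / (1 + (n - 1) h2 / 4))`: the correlation
#' between a sire's true breeding value and the mean performance of `n`
#' daughters with per-record heritability `h2`.  Approaches 1 as the
#' daughter count grows.
#'
#' @param nDaughters daughter count(s), >= 1.
#' @param h2 heritability of a daughter record, in (0, 1].
#' @return vector of accuracies.
#' @examples
#' dydAccuracy(c(1, 50, 5000), 0.53)
#' @export
dydAccuracy <- function(nDaughters, h2) {
  stopifnot(all(nDaughters >= 1), h2 > 0, h2 <= 1)
  t <- h2 / 4
  sqrt(nDaughters * t / (1 + (nDaughters - 1) * t))
}

#' Estimate GEBV accuracy from validation DYDs
#'
#' Within each replicate, validation EBVs are centered by that
#' replicate's mean EBV; bulls are then pooled across replicates and
#' the accuracy is estimated as
#' `rho = cor(ghat, y) / mean(r_gy)`, where `mean(r_gy)` is the
#' arithmetic mean of the per-bull DYD accuracies of the pooled
#' validation bulls.  The estimate is reported unclipped; a value
#' outside `[-1, 1]` triggers a warning rather than truncation.
#'
#' @param ebvByReplicate list (one element per replicate) of named
#'   numeric vectors: the validation bulls' EBVs.
#' @param phenotypes data.frame with id, dyd, n_daughters covering the
#'   pooled validation bulls (one trait).
#' @param h2 heritability of a daughter record for the trait.
#' @return list with elements `accuracy` (rho), `rawCorrelation`,
#'   `meanDydAccuracy`, `nPooled`, and `perReplicate` (raw correlation
#'   within each replicate, NA when a replicate has < 3 bulls).
#' @export
estimateAccuracy <- function(ebvByReplicate, phenotypes, h2) {
  stopifnot(is.list(ebvByReplicate))
  centered <- lapply(ebvByReplicate, function(e) e - mean(e))
  ghat <- unlist(unname(centered))
  ids <- unlist(lapply(ebvByReplicate, names))
  if (length(ghat) < 3)
    stop("undefined correlation: fewer than 3 pooled validation bulls")
  ph <- phenotypes[match(ids, phenotypes$id), , drop = FALSE]
  if (anyNA(ph$id))
    stop("phenotypes missing for validation bull(s): ",
         paste(head(ids[is.na(ph$id)], 5), collapse = ", "))
  rgy <- dydAccuracy(ph$n_daughters, h2)
  raw <- cor(ghat, ph$dyd)
  rho <- raw / mean(rgy)
  if (is.finite(rho) && abs(rho) > 1)
    warning(sprintf("estimated accuracy %.3f exceeds 1 in magnitude %s",
                    rho, "(estimator noise; reported unclipped)"))
  perRep <- vapply(seq_along(ebvByReplicate), function(i) {
    e <- ebvByReplicate[[i]]
    if (length(e) < 3) return(NA_real_)
    y <- phenotypes$dyd[match(names(e), phenotypes$id)]
    cor(e, y)
  }, numeric(1))
  list(accuracy = rho, rawCorrelation = raw,
       meanDydAccuracy = mean(rgy), nPooled = length(ghat),
       perReplicate = perRep)
}

#' Decompose GEBV accuracy into LD and relationship components
#'
#' Regresses the GEBV accuracy across a_max scenarios on the normalised
#' P-BLUP accuracy `x(a_max) = rho_PBLUP(a_max) / rho_PBLUP(ref)`:
#' `rho_GEBV(a_max) = rho_LD + d * x(a_max) + eps` (ordinary least
#' squares).  The intercept `rho_LD` is the accuracy attributable to
#' linkage disequilibrium, persistent when relationships decay; the
#' slope `d` is the relationship component at the reference scenario.
#'
#' @param gebvAccuracies named numeric vector of GEBV accuracies, names
#'   are a_max values.
#' @param pblupAccuracies named numeric vector of P-BLUP accuracies on
#'   the same scenarios.
#' @param referenceAmax name of the reference scenario (default "0.6").
#' @return list with `rhoLD`, `d`, `x`, `fitted`, `residuals` and the
#'   underlying `lm` fit.
#' @examples
#' x <- c(1, 0.9, 0.7, 0.5)
#' rho <- 0.30 + 0.35 * x
#' names(rho) <- names(x) <- c("0.6", "0.49", "0.249", "0.1249")
#' ldAccuracyRegression(rho, x * 0.5 / max(x) * 2, "0.6")$rhoLD
#' @export
ldAccuracyRegression <- function(gebvAccuracies, pblupAccuracies,
                                 referenceAmax = "0.6") {
  sc <- names(gebvAccuracies)
  if (is.null(sc) || is.null(names(pblupAccuracies)))
    stop("accuracy vectors must be named by a_max scenario")
  if (!referenceAmax %in% names(pblupAccuracies))
    stop("reference scenario '", referenceAmax, "' not present")
  miss <- setdiff(sc, names(pblupAccuracies))
  if (length(miss))
    stop("P-BLUP accuracy missing for scenario(s): ",
         paste(miss, collapse = ", "))
  if (length(sc) < 3)
    stop("at least 3 a_max scenarios are required")
  x <- pblupAccuracies[sc] / pblupAccuracies[[referenceAmax]]
  if (max(x) - min(x) < 1e-12)
    stop("unidentifiable: all scenario predictors are identical")
  fit <- lm(gebvAccuracies ~ x)
  list(rhoLD = unname(coef(fit)[1]), d = unname(coef(fit)[2]),
       x = x, fitted = fitted(fit), residuals = resid(fit),
       model = fit)
}

#' LD decay profile: mean r2 by map distance
#'
#' Computes `r2` (squared allele-indicator correlation over haplotypes)
#' between all syntenic SNP pairs up to the largest bin edge, averages
#' per distance bin within each chromosome, then reports the
#' across-chromosome mean and standard deviation per bin, plus the mean
#' distance and mean r2 of adjacent SNP pairs.
#'
#' @param haps a phased [HaplotypeSet-class].
#' @param binEdgesMb increasing distance bin edges in Mb (default 0 to
#'   1 Mb in 0.02 Mb steps).
#' @return list with `profile` (data.frame binLo, binHi, meanR2, sdR2,
#'   nPairs), `adjacentMeanR2` and `adjacentMeanDistMb`.  Monomorphic
#'   SNPs are dropped with a warning.
#' @export
ldR2Profile <- function(haps, binEdgesMb = seq(0, 1, by = 0.02)) {
  stopifnot(length(binEdgesMb) >= 2, all(diff(binEdgesMb) > 0))
  a <- haps@alleles
  map <- haps@map
  mono <- apply(a, 2L, function(x) var(x) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from the LD profile")
    a <- a[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
  }
  maxD <- max(binEdgesMb)
  nb <- length(binEdgesMb) - 1L
  chroms <- unique(map$chrom)
  perChrom <- matrix(NA_real_, length(chroms), nb)
  nPairs <- integer(nb)
  adjR2 <- numeric(0); adjD <- numeric(0)
  for (ci in seq_along(chroms)) {
    cc <- which(map$chrom == chroms[ci])
    if (length(cc) < 2) next
    r2 <- cor(a[, cc, drop = FALSE])^2
    dMb <- abs(outer(map$bp[cc], map$bp[cc], "-")) / 1e6
    ut <- upper.tri(r2)
    d <- dMb[ut]; v <- r2[ut]
    sel <- d <= maxD
    bin <- findInterval(d[sel], binEdgesMb, rightmost.closed = TRUE)
    sums <- tapply(v[sel], factor(bin, levels = seq_len(nb)), mean)
    perChrom[ci, ] <- as.numeric(sums)
    cnt <- tabulate(bin, nbins = nb)
    nPairs <- nPairs + cnt
    adjIdx <- cbind(seq_len(length(cc) - 1L), seq(2L, length(cc)))
    adjR2 <- c(adjR2, r2[adjIdx])
    adjD <- c(adjD, diff(map$bp[cc]) / 1e6)
  }
  profile <- data.frame(
    binLo = binEdgesMb[-length(binEdgesMb)],
    binHi = binEdgesMb[-1],
    meanR2 = colMeans(perChrom, na.rm = TRUE),
    sdR2 = apply(perChrom, 2L, sd, na.rm = TRUE),
    nPairs = nPairs)
  list(profile = profile,
       adjacentMeanR2 = mean(adjR2),
       adjacentMeanDistMb = mean(adjD))
}
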