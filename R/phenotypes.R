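# QTL architectures and daughter-yield-deviation (DYD) phenotypes.

#' Sample an additive QTL architecture
#'
#' Draws `nQtl` QTL among the simulated loci and assigns additive allele
#' substitution effects, then rescales them so that the realized
#' variance of true breeding values over `referenceIds` equals
#' `sigma2A`.  A reflected-gamma effect distribution (shape < 1) gives
#' the "few large, many small" architecture; "normal" gives the
#' classical infinitesimal-like spread over the chosen loci.
#'
#' @param haps a [HaplotypeSet-class] carrying the loci.
#' @param nQtl number of QTL.
#' @param sigma2A target additive-genetic variance (trait units squared).
#' @param sigma2E residual variance of a single daughter record.
#' @param h2 heritability of a daughter record, in (0, 1].
#' @param effectDistribution "gamma" (heavy-tailed, random sign) or
#'   "normal".
#' @param gammaShape shape of the gamma effect distribution.
#' @param referenceIds individuals over which the variance is scaled
#'   (default: all individuals in `haps`, typically the founders).
#' @param trait trait label.
#' @param seed RNG seed.
#' @return a [TraitArchitecture-class].
#' @export
traitArchitecture <- function(haps, nQtl, sigma2A = 1, sigma2E = NULL,
                              h2 = 0.53,
                              effectDistribution = c("gamma", "normal"),
                              gammaShape = 0.4,
                              referenceIds = indivIds(haps),
                              trait = "trait", seed = NULL) {
  effectDistribution <- match.arg(effectDistribution)
  if (h2 <= 0 || h2 > 1)
    stop("configuration error: h2 must be in (0, 1]")
  if (is.null(sigma2E)) sigma2E <- sigma2A * (1 - h2) / h2
  map <- haps@map
  stopifnot(nQtl >= 1, nQtl <= nrow(map))
  run <- function() {
    qtl <- sort(sample.int(nrow(map), nQtl))
    eff <- switch(effectDistribution,
      gamma = stats::rgamma(nQtl, shape = gammaShape, rate = 1) *
        sample(c(-1, 1), nQtl, replace = TRUE),
      normal = stats::rnorm(nQtl))
    g <- genotypeMatrix(haps[referenceIds, map$id[qtl]]) %*% eff
    v <- stats::var(as.vector(g))
    if (v <= 0)
      stop("degenerate architecture: true breeding values have zero ",
           "variance over the reference individuals")
    new("TraitArchitecture", trait = trait, qtlIds = map$id[qtl],
        effects = eff * sqrt(sigma2A / v), sigma2A = sigma2A,
        sigma2E = sigma2E, h2 = h2)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

setMethod("show", "TraitArchitecture", function(object) {
  cat("TraitArchitecture '", object@trait, "': ", length(object@qtlIds),
      " QTL, sigma2A = ", object@sigma2A, ", h2 = ", object@h2, "\n",
      sep = "")
})

#' True breeding values under an architecture
#'
#' @param haps a [HaplotypeSet-class].
#' @param architecture a [TraitArchitecture-class].
#' @param ids individuals (default all).
#' @return named numeric vector of true breeding values.
#' @export
trueBreedingValues <- function(haps, architecture, ids = indivIds(haps)) {
  miss <- setdiff(architecture@qtlIds, haps@map$id)
  if (length(miss))
    stop("QTL not resolvable on this haplotype map: ",
         paste(head(miss, 5), collapse = ", "))
  g <- genotypeMatrix(haps[ids, architecture@qtlIds]) %*%
    architecture@effects
  setNames(as.vector(g), ids)
}

#' Default daughter-count sampler
#'
#' Log-normal counts spanning tens to thousands of daughters, truncated
#' below at 30 (progeny-tested bulls) and above at 5000.
#'
#' @param n number of bulls.
#' @return integer vector of daughter counts.
#' @export
defaultDaughterCounts <- function(n) {
  pmin(pmax(round(stats::rlnorm(n, log(120), 0.9)), 30L), 5000L)
}

#' Simulate daughter yield deviations
#'
#' DYDs are generated as `y_i = g_i + e_i` where `g_i` is the true
#' breeding value and the noise variance is calibrated per bull so that
#' `cor(g_i, y_i)` equals the selection-index progeny-test accuracy
#' `r_gy(n_i, h2)` (see [dydAccuracy()]):
#' `Var(e_i) = sigma2A * (1 - r_gy^2) / r_gy^2`.  The reliability weight
#' is the squared accuracy, `w_i = r_gy^2`.  As `n_i` grows the noise
#' vanishes and the DYD converges to the true breeding value.
#'
#' @param haps a [HaplotypeSet-class].
#' @param architecture a [TraitArchitecture-class].
#' @param ids bulls receiving a DYD (males only, by convention of the
#'   caller).
#' @param nDaughters integer vector (recycled), named vector matched by
#'   id, or a function of the number of bulls; default
#'   [defaultDaughterCounts()].
#' @param seed RNG seed.
#' @return data.frame with columns id, trait, dyd, n_daughters, weight,
#'   tbv.  If the architecture is degenerate (zero genetic variance over
#'   `ids`) a warning flags it and the returned table carries attribute
#'   `degenerate = TRUE`.
#' @export
simulatePhenotypes <- function(haps, architecture, ids = indivIds(haps),
                               nDaughters = defaultDaughterCounts,
                               seed = NULL) {
  g <- trueBreedingValues(haps, architecture, ids)
  run <- function() {
    n <- length(ids)
    nd <- if (is.function(nDaughters)) nDaughters(n)
      else if (!is.null(names(nDaughters))) unname(nDaughters[ids])
      else rep_len(nDaughters, n)
    nd <- as.integer(nd)
    if (any(is.na(nd) | nd < 1))
      stop("daughter counts must be integers >= 1 for every bull")
    r <- dydAccuracy(nd, architecture@h2)
    sdE <- sqrt(architecture@sigma2A * (1 - r^2) / r^2)
    y <- g + stats::rnorm(n, 0, sdE)
    out <- data.frame(id = ids, trait = architecture@trait, dyd = y,
                      n_daughters = nd, weight = r^2, tbv = unname(g),
                      stringsAsFactors = FALSE)
    if (stats::var(unname(g)) <= 0) {
      warning("degenerate architecture: Var(g) = 0 over the phenotyped ",
              "bulls; cor(g, y) is undefined")
      attr(out, "degenerate") <- TRUE
    }
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
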