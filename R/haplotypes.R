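# Founder haplotype simulation, Mendelian gene dropping and the
# HaplotypeSet <-> GenotypeData bridge.

# Calibration constant of the founder LD model: latent correlation
# between adjacent loci is exp(-LD_DECAY_C0 * Ne * d_Mb).  Calibrated
# once so that Ne = 50 yields an adjacent-SNP mean r2 of ~0.22 at the
# panel's 0.064 Mb mean spacing (see the methods vignette).
LD_DECAY_C0 <- 0.07

#' Construct a HaplotypeSet
#'
#' @param alleles integer 0/1 matrix with two consecutive rows per
#'   individual (rows `2i - 1`, `2i` belong to `ids[i]`).
#' @param ids individual ids.
#' @param map SNP map data.frame with columns chrom, id, cM, bp.
#' @return a [HaplotypeSet-class].
#' @export
HaplotypeSet <- function(alleles, ids, map) {
  storage.mode(alleles) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$id <- as.character(map$id)
  colnames(alleles) <- map$id
  rownames(alleles) <- paste0(rep(ids, each = 2L), c("_1", "_2"))
  new("HaplotypeSet", alleles = alleles, ids = as.character(ids), map = map)
}

#' @rdname HaplotypeSet
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) x@alleles)

#' @rdname HaplotypeSet
#' @export
setMethod("snpMap", "HaplotypeSet", function(x) x@map)

#' @rdname HaplotypeSet
#' @export
setMethod("indivIds", "HaplotypeSet", function(x) x@ids)

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@ids), "individuals,",
      nrow(object@map), "SNPs on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
})

#' @rdname HaplotypeSet
#' @param x a HaplotypeSet
#' @param i individual ids (character) or indices
#' @param j SNP ids (character) or indices
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  ids <- x@ids; map <- x@map
  if (!missing(i)) {
    idx <- if (is.character(i)) match(i, ids) else i
    if (anyNA(idx)) stop("unknown individual id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    ids <- ids[idx]
  } else rows <- seq_len(nrow(x@alleles))
  if (!missing(j)) {
    jdx <- if (is.character(j)) match(j, map$id) else j
    if (anyNA(jdx)) stop("unknown SNP id(s)")
    jdx <- sort(jdx)
    map <- map[jdx, , drop = FALSE]
  } else jdx <- seq_len(nrow(map))
  HaplotypeSet(x@alleles[rows, jdx, drop = FALSE], ids, map)
})

#' Genotype matrix from phased haplotypes
#'
#' @param haps a [HaplotypeSet-class].
#' @return integer individuals x SNPs matrix of 0/1/2 allele counts.
#' @export
genotypeMatrix <- function(haps) {
  a <- haps@alleles
  n <- length(haps@ids)
  g <- a[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    a[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- haps@ids
  g
}

#' Simulate founder haplotypes with distance-decaying LD
#'
#' Haplotypes are generated from a latent Gaussian copula: along each
#' chromosome a stationary AR(1) process with inter-locus correlation
#' `exp(-c0 * Ne * d_Mb)` is thresholded at the per-SNP allele-frequency
#' quantile.  This yields pairwise r2 that decays monotonically with map
#' distance at a rate controlled by the effective population size, and
#' minor allele frequencies close to uniform (frequencies are drawn from
#' U(0.05, 0.95) unless supplied).
#'
#' @param nIndividuals number of founder individuals (2 haplotypes each).
#' @param nChromosomes,nSnpsPerChrom panel dimensions.
#' @param chromLengthBp chromosome length in base pairs; SNP positions
#'   are drawn uniformly without replacement, so the mean adjacent
#'   spacing is about `chromLengthBp / nSnpsPerChrom`.
#' @param effectivePopSize controls the LD decay rate (larger = faster
#'   decay, less LD), analogous to drift-driven LD in a small population.
#' @param alleleFreqs optional vector of allele frequencies, length
#'   `nChromosomes * nSnpsPerChrom` (recycled if shorter).
#' @param seed RNG seed.
#' @return a [HaplotypeSet-class] for the founders.
#' @examples
#' h <- simulateFounderHaplotypes(50, 1, 100, 6.4e6, seed = 1)
#' @export
simulateFounderHaplotypes <- function(nIndividuals, nChromosomes,
                                      nSnpsPerChrom, chromLengthBp,
                                      effectivePopSize = 50,
                                      alleleFreqs = NULL, seed = NULL) {
  stopifnot(nIndividuals >= 1, nChromosomes >= 1, nSnpsPerChrom >= 2,
            chromLengthBp > nSnpsPerChrom, effectivePopSize >= 0)
  run <- function() {
    H <- 2L * nIndividuals
    K <- nChromosomes * nSnpsPerChrom
    p <- if (is.null(alleleFreqs)) stats::runif(K, 0.05, 0.95) else
      rep_len(alleleFreqs, K)
    alle <- matrix(0L, H, K)
    map <- vector("list", nChromosomes)
    off <- 0L
    for (ch in seq_len(nChromosomes)) {
      bp <- sort(sample.int(chromLengthBp, nSnpsPerChrom))
      dMb <- diff(bp) / 1e6
      phi <- exp(-LD_DECAY_C0 * effectivePopSize * dMb)
      z <- matrix(0, H, nSnpsPerChrom)
      z[, 1L] <- stats::rnorm(H)
      for (k in seq_len(nSnpsPerChrom - 1L))
        z[, k + 1L] <- phi[k] * z[, k] +
          sqrt(1 - phi[k]^2) * stats::rnorm(H)
      cols <- off + seq_len(nSnpsPerChrom)
      thr <- stats::qnorm(p[cols])
      alle[, cols] <- (z < rep(thr, each = H)) + 0L
      map[[ch]] <- data.frame(chrom = ch,
                              id = sprintf("snp%d_%d", ch,
                                           seq_len(nSnpsPerChrom)),
                              cM = bp / 1e6, bp = bp,
                              stringsAsFactors = FALSE)
      off <- off + nSnpsPerChrom
    }
    HaplotypeSet(alle, sprintf("F0_%d", seq_len(nIndividuals)),
                 do.call(rbind, map))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# one recombined gamete from a parent's two haplotypes on one chromosome
.meiosisChrom <- function(h1, h2, bp, ratePerBp) {
  span <- bp[length(bp)] - bp[1]
  nx <- if (ratePerBp > 0 && span > 0)
    stats::rpois(1L, ratePerBp * span) else 0L
  start <- sample.int(2L, 1L)
  if (nx == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(nx, bp[1], bp[length(bp)]))
  seg <- (start - 1L + findInterval(bp, xo)) %% 2L
  ifelse(seg == 0L, h1, h2)
}

#' Drop founder haplotypes through a pedigree
#'
#' Standard Mendelian gene dropping: every non-founder receives one
#' recombined gamete from each parent, with crossovers placed as a
#' Poisson process of intensity `recombRatePerBp` along each
#' chromosome (the default 1e-8 per bp corresponds to 1 cM per Mb).
#'
#' @param pedigree a [Pedigree-class]; every founder (both parents
#'   unknown) must have haplotypes in `founderHaps`.
#' @param founderHaps a [HaplotypeSet-class] covering the founders.
#' @param recombRatePerBp recombination rate per base pair (Morgans/bp).
#' @param seed RNG seed.
#' @return a [HaplotypeSet-class] covering every pedigree individual, in
#'   pedigree record order.
#' @export
geneDrop <- function(pedigree, founderHaps, recombRatePerBp = 1e-8,
                     seed = NULL) {
  df <- pedigree@records
  fnd <- founderIds(pedigree)
  missingF <- setdiff(fnd, founderHaps@ids)
  if (length(missingF))
    stop("lineage error: founders without haplotypes: ",
         paste(head(missingF, 5), collapse = ", "))
  half <- xor(is.na(df$sire), is.na(df$dam))
  if (any(half))
    stop("lineage error: individuals with exactly one known parent: ",
         paste(head(df$id[half], 5), collapse = ", "))
  map <- founderHaps@map
  chroms <- unique(map$chrom)
  chromCols <- lapply(chroms, function(ch) which(map$chrom == ch))
  chromBp <- lapply(chromCols, function(cc) map$bp[cc])
  run <- function() {
    n <- nrow(df)
    K <- nrow(map)
    alle <- matrix(0L, 2L * n, K)
    rowOf <- setNames(seq_len(n), df$id)
    fidx <- match(fnd, founderHaps@ids)
    for (i in seq_along(fnd)) {
      r <- rowOf[fnd[i]]
      alle[c(2L * r - 1L, 2L * r), ] <-
        founderHaps@alleles[c(2L * fidx[i] - 1L, 2L * fidx[i]), ]
    }
    gamete <- function(pr) {
      h1 <- alle[2L * pr - 1L, ]; h2 <- alle[2L * pr, ]
      out <- integer(K)
      for (c in seq_along(chroms)) {
        cc <- chromCols[[c]]
        out[cc] <- .meiosisChrom(h1[cc], h2[cc], chromBp[[c]],
                                 recombRatePerBp)
      }
      out
    }
    for (i in .pedOrder(pedigree)) {
      if (is.na(df$sire[i])) next
      r <- rowOf[df$id[i]]
      alle[2L * r - 1L, ] <- gamete(rowOf[df$sire[i]])
      alle[2L * r, ] <- gamete(rowOf[df$dam[i]])
    }
    HaplotypeSet(alle, df$id, map)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
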