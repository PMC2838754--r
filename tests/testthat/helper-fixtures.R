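# Fixtures are built in code (no stored data) and cached per session so
# expensive populations are simulated once.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# five-individual pedigree with a full-sib mating: E is the offspring
# of full sibs C x D, so A[E, E] = 1.25 by the tabular method by hand
fullSibMatingPedigree <- function() {
  Pedigree(data.frame(
    id = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D"),
    sex = c("male", "female", "male", "female", "male"),
    birth_year = c(2000L, 2000L, 2005L, 2005L, 2010L)))
}

# small three-generation population with genotypes and phenotypes
smallPopulation <- function() {
  cached("smallPop", {
    ped <- simulatePedigree(3, c(20, 120), 18, 6, fullSibRate = 0.06,
                            seed = 401)
    fh <- simulateFounderHaplotypes(length(founderIds(ped)), 3, 120,
                                    7.68e6, 50, seed = 402)
    fh@ids <- founderIds(ped)
    rownames(fh@alleles) <- paste0(rep(fh@ids, each = 2), c("_1", "_2"))
    haps <- geneDrop(ped, fh, seed = 403)
    df <- pedRecords(ped)
    bulls <- df$id[df$sex == "male" & !is.na(df$sire)]
    arch <- traitArchitecture(haps, 15, sigma2A = 1, h2 = 0.53,
                              referenceIds = bulls, seed = 404)
    pheno <- simulatePhenotypes(haps, arch, ids = bulls, seed = 405)
    markers <- setdiff(snpMap(haps)$id, arch@qtlIds)
    gd <- filterSnps(asGenotypeData(haps[bulls, markers], ped))
    # base-population (founder) allele frequencies for the retained
    # markers: centering G there makes E[G_ij] = A_ij exact
    fndFreq <- colMeans(haplotypes(haps[founderIds(ped),
                                        rownames(gd)]))
    names(fndFreq) <- rownames(gd)
    list(ped = ped, haps = haps, bulls = bulls, arch = arch,
         pheno = pheno, gd = gd,
         A = numeratorRelationshipMatrix(ped, bulls),
         G = genomicRelationshipMatrix(gd),
         Gf = genomicRelationshipMatrix(gd, alleleFreqs = fndFreq))
  })
}

# hand-built genotype data with an X chromosome for the QC rules
qcFixture <- function() {
  geno <- rbind(
    m1 = c(1, 1, 1, 0, 1),
    m2 = c(0, 1, 2, 1, NA),
    f1 = c(1, 1, 0, 2, 1),
    f2 = c(2, 0, 1, 1, 0))
  colnames(geno) <- paste0("s", 1:5)
  map <- data.frame(chrom = c("1", "1", "X", "X", "X"),
                    id = colnames(geno), bp = c(100, 200, 100, 200, 300),
                    par = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  GenotypeData(geno, map, c("male", "male", "female", "female"))
}

# independent single-locus gene-dropping oracle for additive
# relationships: label founder alleles uniquely, drop them through the
# pedigree without recombination, and estimate a_ij as twice the
# probability that random alleles from i and j are identical by descent
geneDropRelationshipOracle <- function(ped, ids, nRep = 2000,
                                       seed = 99) {
  df <- pedRecords(ped)
  ord <- order(df$birth_year)
  n <- nrow(df)
  sIdx <- match(df$sire, df$id)
  dIdx <- match(df$dam, df$id)
  m <- length(ids)
  acc <- matrix(0, m, m, dimnames = list(ids, ids))
  withr::with_seed(seed, {
    for (r in seq_len(nRep)) {
      al <- matrix(0L, n, 2)
      nextLab <- 1L
      for (i in ord) {
        if (is.na(sIdx[i])) {
          al[i, ] <- c(nextLab, nextLab + 1L)
          nextLab <- nextLab + 2L
        } else {
          al[i, 1] <- al[sIdx[i], sample.int(2L, 1L)]
          al[i, 2] <- al[dIdx[i], sample.int(2L, 1L)]
        }
      }
      rows <- match(ids, df$id)
      for (a in seq_len(m)) for (b in a:m) {
        ia <- al[rows[a], ]; ib <- al[rows[b], ]
        f <- mean(outer(ia, ib, "=="))
        acc[a, b] <- acc[a, b] + 2 * f
      }
    }
  })
  acc <- acc / nRep
  acc[lower.tri(acc)] <- t(acc)[lower.tri(acc)]
  acc
}

# exhaustive split-sampler oracle on toy pedigrees: minimum number of
# exclusions over all feasible validation sets of the target size
bruteForceMinExclusions <- function(A, ped, cand, cn) {
  Am <- relMatrix(A)
  fam <- halfSibFamilies(ped, cand)
  df <- pedRecords(ped)
  best <- Inf
  combos <- utils::combn(cand, cn@valSize, simplify = FALSE)
  for (val in combos) {
    if (any(table(fam[val]) > cn@maxPerSibFamily)) next
    sons <- df$id[!is.na(df$sire) & df$sire %in% val]
    train0 <- setdiff(cand, val)
    excl <- train0[apply(Am[train0, val, drop = FALSE], 1, max) > cn@aMax]
    if (cn@forbidSiresInValidation)
      excl <- union(excl, intersect(sons, train0))
    if (length(setdiff(train0, excl)) < 1) next
    best <- min(best, length(excl))
  }
  best
}
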