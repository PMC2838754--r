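test_that("tabular A reproduces the definitional relationships", {
  ped <- fullSibMatingPedigree()
  A <- relMatrix(numeratorRelationshipMatrix(ped))
  expect_equal(A["A", "C"], 0.5)          # parent-offspring
  expect_equal(A["C", "D"], 0.5)          # full sibs
  expect_equal(A["E", "E"], 1.25)         # offspring of full sibs
  expect_equal(A["A", "B"], 0)            # unrelated founders
  # paternal half sibs in a simulated pedigree
  ped2 <- simulatePedigree(1, c(2, 6), 2, 3, familySizeDispersion = 0,
                           fullSibRate = 0, seed = 71)
  df <- pedRecords(ped2)
  off <- df$id[!is.na(df$sire)]
  A2 <- relMatrix(numeratorRelationshipMatrix(ped2, off))
  sib <- off[df$sire[match(off, df$id)] == df$sire[match(off[1], df$id)]]
  sameDam <- df$dam[match(sib, df$id)] == df$dam[match(sib[1], df$id)]
  halfs <- sib[!sameDam]
  if (length(halfs)) expect_equal(A2[sib[1], halfs[1]], 0.25)
})

test_that("A submatrices agree with the full tabular matrix", {
  pop <- smallPopulation()
  some <- sample(pop$bulls, 10)
  Afull <- relMatrix(numeratorRelationshipMatrix(pop$ped))
  Asub <- relMatrix(numeratorRelationshipMatrix(pop$ped, some))
  expect_equal(Asub, Afull[some, some])
  expect_error(numeratorRelationshipMatrix(pop$ped, "ghost"),
               "not in pedigree")
})

test_that("tabular A matches an independent gene-dropping oracle", {
  ped <- Pedigree(data.frame(
    id = c("f1", "f2", "f3", "f4", "m1", "m2", "o1", "o2", "o3", "x1"),
    sire = c(NA, NA, NA, NA, "f1", "f1", "m1", "m1", "m2", "o1"),
    dam = c(NA, NA, NA, NA, "f2", "f2", "f3", "f3", "f4", "f4"),
    sex = c("male", "female", "female", "female", "male", "male",
            "male", "female", "male", "male"),
    birth_year = c(2000, 2000, 2000, 2000, 2005, 2005, 2010, 2010,
                   2010, 2015)))
  ids <- pedIds(ped)
  A <- relMatrix(numeratorRelationshipMatrix(ped))
  Amc <- geneDropRelationshipOracle(ped, ids, nRep = 3000, seed = 72)
  # binomial-ish Monte-Carlo error per entry
  se <- sqrt(0.25 / 3000) * 2
  expect_lt(max(abs(A - Amc)), 3 * se + 0.02)
})

test_that("genomic relationship matrix follows the centered cross-product form", {
  # one individual heterozygous everywhere with p = 0.5: centered row is
  # zero, so its diagonal (and every entry involving it) is 0
  geno <- rbind(i1 = c(1, 1, 1, 1),
                i2 = c(0, 2, 0, 2),
                i3 = c(0, 2, 0, 2))
  colnames(geno) <- paste0("s", 1:4)
  map <- data.frame(chrom = 1, id = colnames(geno), bp = 1:4 * 1e5)
  gd <- GenotypeData(geno, map, rep("male", 3))
  G <- relMatrix(genomicRelationshipMatrix(gd, alleleFreqs = rep(0.5, 4)))
  expect_equal(G["i1", "i1"], 0)
  # duplicate genotype rows give identical entries
  expect_equal(G["i2", "i3"], G["i2", "i2"])
  expect_equal(G["i2", "i3"], G["i3", "i3"])
  # hand value: centered row for i2 is (-1, 1, -1, 1), denom = 2*4*0.25
  expect_equal(G["i2", "i2"], 4 / 2)
  expect_error(genomicRelationshipMatrix(gd, alleleFreqs = rep(1, 4)),
               "zero denominator")
})

test_that("mean G diagonal is near 1 in an unrelated founder cohort", {
  h <- simulateFounderHaplotypes(400, 2, 150, 9.6e6, 50, seed = 73)
  gd <- asGenotypeData(h, setNames(rep("male", 400), indivIds(h)))
  G <- relMatrix(genomicRelationshipMatrix(gd))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("realized G regresses on pedigree A with slope near 1", {
  pop <- smallPopulation()
  ids <- intersect(rownames(relMatrix(pop$Gf)), pop$bulls)
  A <- relMatrix(pop$A)[ids, ids]
  G <- relMatrix(pop$Gf)[ids, ids]
  ut <- upper.tri(A)
  fit <- lm(G[ut] ~ A[ut])
  expect_lt(abs(coef(fit)[2] - 1), 0.15)
})

test_that("maxRelationship scans the cross block and validates sets", {
  m <- matrix(c(1, .5, .1, .5, 1, .3, .1, .3, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  A <- new("RelationshipMatrix", mat = m, kind = "numerator",
           alleleFreqs = NULL)
  expect_equal(maxRelationship(A, c("a", "b"), "c"), 0.3)
  expect_error(maxRelationship(A, c("a", "b"), "b"), "design error")
  expect_error(maxRelationship(A, character(0), "b"), "non-empty")
  # parent in training bounds the maximum from below
  ped <- fullSibMatingPedigree()
  An <- numeratorRelationshipMatrix(ped)
  expect_gte(maxRelationship(An, c("A", "B"), "C"), 0.5)
})
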