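test_that("sampled splits satisfy every constraint on a structured population", {
  pop <- smallPopulation()
  df <- pedRecords(pop$ped)
  for (amax in c(0.6, 0.249)) {
    cn <- splitConstraints(aMax = amax, trainSize = 120, valSize = 8,
                           minValSize = 4, nReplicates = 4)
    splits <- sampleSplits(pop$A, pop$ped, pop$bulls, cn, seed = 121)
    expect_length(splits, 4)
    allVal <- character(0)
    for (s in splits) {
      expect_lte(maxRelationship(pop$A, trainIds(s), validationIds(s)),
                 amax)
      fam <- halfSibFamilies(pop$ped, validationIds(s))
      expect_true(all(table(fam) <= 2))
      # no validation bull is the sire of a training bull
      sires <- df$sire[match(trainIds(s), df$id)]
      expect_length(intersect(validationIds(s), sires), 0)
      expect_lte(length(trainIds(s)), 120)
      expect_gte(length(validationIds(s)), 4)
      allVal <- c(allVal, validationIds(s))
    }
    expect_false(any(duplicated(allVal)))   # unique across replicates
  }
})

test_that("tight relationship caps remove parents and half sibs from training", {
  pop <- smallPopulation()
  df <- pedRecords(pop$ped)
  cn <- splitConstraints(aMax = 0.249, trainSize = 200, valSize = 8,
                         minValSize = 4, nReplicates = 3)
  splits <- sampleSplits(pop$A, pop$ped, pop$bulls, cn, seed = 122)
  for (s in splits) {
    expect_lt(maxRelationship(pop$A, trainIds(s), validationIds(s)),
              0.25)
    for (v in validationIds(s)) {
      rel <- c(df$sire[df$id == v],
               df$id[!is.na(df$sire) & df$sire == df$sire[df$id == v]])
      expect_length(intersect(trainIds(s), setdiff(rel, v)), 0)
    }
  }
  # with a loose cap the close relatives may stay in training
  cnL <- splitConstraints(aMax = 0.6, trainSize = 200, valSize = 8,
                          minValSize = 4, nReplicates = 3)
  splitsL <- sampleSplits(pop$A, pop$ped, pop$bulls, cnL, seed = 122)
  hasClose <- any(vapply(splitsL, function(s)
    maxRelationship(pop$A, trainIds(s), validationIds(s)) >= 0.25,
    logical(1)))
  expect_true(hasClose)
})

test_that("greedy exclusions stay within 1.5x of the brute-force optimum on toys", {
  ped <- simulatePedigree(1, c(3, 9), 3, 4, fullSibRate = 0,
                          familySizeDispersion = 0, seed = 123)
  df <- pedRecords(ped)
  cand <- df$id[!is.na(df$sire)]           # 12 candidate bulls
  A <- numeratorRelationshipMatrix(ped, cand)
  cn <- splitConstraints(aMax = 0.249, trainSize = 12, valSize = 3,
                         minValSize = 3, nReplicates = 1,
                         uniqueValidation = FALSE)
  opt <- bruteForceMinExclusions(A, ped, cand, cn)
  expect_true(is.finite(opt))
  for (seed in c(1, 2, 3)) {
    s <- sampleSplits(A, ped, cand, cn, seed = seed, nTries = 30)[[1]]
    expect_lte(length(excludedIds(s)), max(ceiling(1.5 * opt), opt))
  }
})

test_that("unsatisfiable constraints report the binding constraint", {
  ped <- fullSibMatingPedigree()
  cand <- c("C", "D", "E")
  A <- numeratorRelationshipMatrix(ped, cand)
  cn <- splitConstraints(aMax = 0.1, trainSize = 2, valSize = 3,
                         minValSize = 3, nReplicates = 2)
  expect_error(sampleSplits(A, ped, cand, cn, seed = 1),
               "constraints unsatisfiable")
})

test_that("training halving protects close relatives of validation bulls", {
  pop <- smallPopulation()
  cn <- splitConstraints(aMax = 0.6, trainSize = 150, valSize = 8,
                         minValSize = 4, nReplicates = 1)
  s <- sampleSplits(pop$A, pop$ped, pop$bulls, cn, seed = 124)[[1]]
  Am <- relMatrix(pop$A)
  rel <- apply(Am[trainIds(s), validationIds(s), drop = FALSE], 1, max)
  protected <- names(rel)[rel >= 0.25]
  target <- max(75, length(protected))
  half <- downsampleTraining(s, target, pop$A, seed = 125)
  expect_length(trainIds(half), target)
  expect_true(all(protected %in% trainIds(half)))
  expect_identical(validationIds(half), validationIds(s))
  # infeasible when the protected set alone exceeds the target
  if (length(protected) > 1)
    expect_error(downsampleTraining(s, length(protected) - 1, pop$A),
                 "infeasibility")
  # unconstrained case: random subset of exactly the target size
  free <- setdiff(trainIds(s), protected)
  s2 <- new("Split", replicate = 1L, train = free,
            validation = validationIds(s), excluded = character(0),
            aMax = 0.6, realizedMax = 0)
  s2@realizedMax <- max(Am[free, validationIds(s)])
  s2@aMax <- max(0.6, s2@realizedMax)
  sub <- downsampleTraining(s2, min(20, length(free)), pop$A,
                            protectThreshold = 1.9, seed = 126)
  expect_length(trainIds(sub), min(20, length(free)))
})
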