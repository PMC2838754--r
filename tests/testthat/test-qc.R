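test_that("X-heterozygote masking hits exactly male non-PAR X heterozygotes", {
  gd <- qcFixture()
  out <- maskXHeterozygotes(gd)
  g0 <- genotypes(gd); g1 <- genotypes(out)
  expect_true(is.na(g1["m1", "s3"]))      # male, X non-PAR, code 1
  expect_identical(g1["m1", "s5"], 1)     # male, X PAR: unchanged
  expect_identical(g1["m1", "s1"], 1)     # autosomal het: unchanged
  expect_identical(g1["f1", "s3"], 0)     # female X: unchanged
  changed <- which(is.na(g1) & !is.na(g0), arr.ind = TRUE)
  expect_identical(rownames(changed), c("m1", "m2"))
})

test_that("SNP filter applies strict thresholds and logs exclusions", {
  # 4 SNPs with MAFs 0.02, 0.03, 0.10, 0.40 and no missing calls:
  # MAF must be strictly greater than 0.03, so only SNPs 3 and 4 stay
  geno <- cbind(
    snpA = c(rep(0, 96), rep(1, 4)),          # MAF 4/200 = 0.02
    snpB = c(rep(0, 94), rep(1, 6)),          # MAF 6/200 = 0.03 (boundary)
    snpC = c(rep(0, 80), rep(1, 20)),         # MAF 0.10
    snpD = c(rep(0, 20), rep(1, 80)))         # MAF 0.40
  rownames(geno) <- sprintf("i%03d", 1:100)
  map <- data.frame(chrom = 1, id = colnames(geno), bp = 1:4 * 1e5)
  gd <- GenotypeData(geno, map, rep("male", 100))
  out <- filterSnps(gd)
  expect_identical(rownames(out), c("snpC", "snpD"))
  log <- exclusionLog(out)
  expect_setequal(log$snp, c("snpA", "snpB"))
  expect_true(all(log$reason == "maf"))
})

test_that("missingness rule is strict and reported before MAF", {
  geno <- cbind(snpA = c(rep(1, 50), rep(0, 44), rep(NA, 6)),  # 6% missing
                snpB = c(rep(1, 50), rep(0, 50)))
  rownames(geno) <- sprintf("i%03d", 1:100)
  map <- data.frame(chrom = 1, id = colnames(geno), bp = c(1e5, 2e5))
  gd <- GenotypeData(geno, map, rep("male", 100))
  out <- filterSnps(gd)
  log <- exclusionLog(out)
  expect_identical(log$snp, "snpA")
  expect_identical(log$reason, "missingness")
  # exactly 5% missing also fails (strictly less than)
  geno[, "snpA"] <- c(rep(1, 50), rep(0, 45), rep(NA, 5))
  gd5 <- GenotypeData(geno, map, rep("male", 100))
  expect_identical(exclusionLog(filterSnps(gd5))$snp, "snpA")
})

test_that("filtering is idempotent, conserves counts, and can be vacuous", {
  pop <- smallPopulation()
  gd <- pop$gd
  once <- filterSnps(gd)
  twice <- filterSnps(once)
  expect_identical(rownames(twice), rownames(once))
  expect_equal(nrow(exclusionLog(once)) - nrow(exclusionLog(gd)) +
                 nrow(once), nrow(gd))
  # vacuous thresholds keep every polymorphic SNP
  lax <- filterSnps(gd, maxMissingRate = 1, minMaf = 0)
  p <- alleleFreqs(gd)
  expect_equal(nrow(lax), sum(p > 0 & p < 1))
  # all SNPs removed -> empty-panel error
  expect_error(filterSnps(gd, minMaf = 1), "empty-panel")
})

test_that("imputation fills missing cells as specified and only those", {
  geno <- cbind(snpA = c(0, 0, 2, NA),
                snpB = c(1, 2, 0, 1),
                snpC = c(NA, NA, NA, NA))
  rownames(geno) <- paste0("i", 1:4)
  map <- data.frame(chrom = 1, id = colnames(geno), bp = 1:3 * 1e5)
  gd <- GenotypeData(geno, map, rep("male", 4))
  expect_error(imputeMissing(gd), "snpC")
  gd2 <- GenotypeData(geno[, 1:2], map[1:2, ], rep("male", 4))
  out <- imputeMissing(gd2, "mean_rounded")
  g <- genotypes(out)
  expect_identical(g["i4", "snpA"], 1)       # round(2/3) = 1
  expect_identical(g[, "snpB"], genotypes(gd2)[, "snpB"])
  # no missing cells -> identity
  expect_identical(genotypes(imputeMissing(out)), g)
  # allele-frequency draw at p = 1 is deterministic: always 2
  geno3 <- cbind(snpZ = c(2, 2, 2, NA))
  rownames(geno3) <- paste0("i", 1:4)
  gd3 <- GenotypeData(geno3, data.frame(chrom = 1, id = "snpZ", bp = 1e5),
                      rep("male", 4))
  out3 <- imputeMissing(gd3, "allele_frequency_draw", seed = 1)
  expect_identical(genotypes(out3)["i4", "snpZ"], 2)
})
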