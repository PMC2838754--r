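test_that("progeny-test accuracy follows the selection-index formula", {
  expect_equal(dydAccuracy(1, 0.53), sqrt(0.1325))
  expect_equal(dydAccuracy(50, 0.53),
               sqrt(50 * 0.1325 / (1 + 49 * 0.1325)))
  # perfect progeny test in the limit
  expect_gt(dydAccuracy(1e8, 0.23), 0.9999)
  # monotone in heritability at fixed daughter count
  expect_gt(dydAccuracy(40, 0.53), dydAccuracy(40, 0.23))
  expect_error(dydAccuracy(0, 0.5))
})

test_that("accuracy estimator centers per replicate and divides by mean DYD accuracy", {
  # ghat proportional to y in one replicate: raw correlation exactly 1,
  # so rho = 1 / mean(r_gy), reported above 1 with a warning
  ph <- data.frame(id = sprintf("b%d", 1:20),
                   dyd = withr::with_seed(131, rnorm(20)),
                   n_daughters = 50)
  r <- dydAccuracy(50, 0.53)
  one <- list(setNames(2 * ph$dyd, ph$id))
  expect_warning(est <- estimateAccuracy(one, ph, 0.53), "exceeds 1")
  expect_equal(est$accuracy, 1 / r)
  expect_equal(est$rawCorrelation, 1)
  expect_equal(est$nPooled, 20)
  # invariance to a per-replicate constant shift, multi-replicate
  ebvs <- list(setNames(2 * ph$dyd[1:10], ph$id[1:10]),
               setNames(2 * ph$dyd[11:20] + 7, ph$id[11:20]))
  shifted <- list(ebvs[[1]] + 100, ebvs[[2]] - 3)
  est1 <- suppressWarnings(estimateAccuracy(ebvs, ph, 0.53))
  est2 <- suppressWarnings(estimateAccuracy(shifted, ph, 0.53))
  expect_equal(est2$accuracy, est1$accuracy)
})

test_that("independent EBVs estimate accuracy near zero and tiny sets error", {
  ph <- data.frame(id = sprintf("b%d", 1:400),
                   dyd = withr::with_seed(132, rnorm(400)),
                   n_daughters = 100)
  ebvs <- list(setNames(withr::with_seed(133, rnorm(400)), ph$id))
  est <- estimateAccuracy(ebvs, ph, 0.53)
  expect_lt(abs(est$accuracy), 0.15)
  expect_error(estimateAccuracy(list(setNames(1:2, ph$id[1:2])), ph,
                                0.53), "fewer than 3")
})

test_that("estimated accuracy agrees with the direct correlation to true breeding values", {
  # simulation oracle: DYD-based estimator vs corr(ghat, g_true) when
  # ghat is a noisy version of g
  h <- simulateFounderHaplotypes(500, 1, 80, 5.1e6, 50, seed = 134)
  arch <- traitArchitecture(h, 10, sigma2A = 1, h2 = 0.53, seed = 135)
  ph <- simulatePhenotypes(h, arch, seed = 136)
  ghat <- withr::with_seed(137, ph$tbv + rnorm(nrow(ph), 0, 0.8))
  names(ghat) <- ph$id
  reps <- split(seq_len(nrow(ph)), rep(1:5, each = 100))
  ebvs <- lapply(reps, function(i) ghat[i])
  est <- estimateAccuracy(ebvs, ph, 0.53)
  direct <- cor(ghat, ph$tbv)
  expect_lt(abs(est$accuracy - direct), 0.05)
})

test_that("the LD regression recovers noiseless coefficients exactly", {
  pb <- setNames(c(0.60, 0.54, 0.42, 0.30),
                 c("0.6", "0.49", "0.249", "0.1249"))
  x <- pb / pb[["0.6"]]
  ga <- 0.30 + 0.35 * x
  reg <- ldAccuracyRegression(ga, pb, "0.6")
  expect_equal(reg$rhoLD, 0.30)
  expect_equal(reg$d, 0.35)
  expect_equal(max(abs(reg$residuals)), 0, tolerance = 1e-12)
  # OLS residuals orthogonal to the predictor on noisy inputs
  ga2 <- ga + c(0.02, -0.01, 0.03, -0.015)
  reg2 <- ldAccuracyRegression(ga2, pb, "0.6")
  expect_equal(sum(reg2$residuals * reg2$x), 0, tolerance = 1e-12)
  # pure-relationship case: GEBV accuracy proportional to x -> rhoLD = 0
  reg3 <- ldAccuracyRegression(setNames(0.5 * x, names(x)), pb, "0.6")
  expect_equal(reg3$rhoLD, 0, tolerance = 1e-12)
})

test_that("the LD regression validates its inputs", {
  pb <- setNames(c(0.5, 0.5, 0.5), c("a", "b", "c"))
  ga <- setNames(c(0.6, 0.5, 0.4), c("a", "b", "c"))
  expect_error(ldAccuracyRegression(ga, pb, "a"), "unidentifiable")
  expect_error(ldAccuracyRegression(ga[1:2], pb[1:2], "a"),
               "at least 3")
  expect_error(ldAccuracyRegression(ga, pb, "zz"), "not present")
})

test_that("r2 is computed from haplotype counts as D-squared over allele frequencies", {
  map <- data.frame(chrom = 1, id = c("L1", "L2"), cM = c(0.1, 0.2),
                    bp = c(1e5, 2e5))
  # 8 haplotypes, counts {00:4, 11:4}: perfect LD
  a1 <- cbind(rep(c(0L, 1L), each = 4), rep(c(0L, 1L), each = 4))
  h1 <- HaplotypeSet(a1, sprintf("i%d", 1:4), map)
  p1 <- ldR2Profile(h1, binEdgesMb = c(0, 0.5))
  expect_equal(p1$adjacentMeanR2, 1)
  # counts {00:2, 01:2, 10:2, 11:2}: independence
  a2 <- cbind(rep(c(0L, 1L), each = 4), rep(c(0L, 1L), 4))
  h2 <- HaplotypeSet(a2, sprintf("i%d", 1:4), map)
  p2 <- ldR2Profile(h2, binEdgesMb = c(0, 0.5))
  expect_equal(p2$adjacentMeanR2, 0)
  # independent loci over many haplotypes: r2 near zero
  a3 <- withr::with_seed(138,
    matrix(rbinom(2000, 1, 0.5), 1000, 2))
  h3 <- HaplotypeSet(a3, sprintf("i%d", 1:500), map)
  expect_lt(ldR2Profile(h3, binEdgesMb = c(0, 0.5))$adjacentMeanR2,
            0.02)
})
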