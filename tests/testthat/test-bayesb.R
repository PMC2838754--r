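# small weighted training instance shared by the sampler tests
.bayesbInstance <- function() {
  cached("bayesbInst", {
    h <- simulateFounderHaplotypes(120, 2, 75, 4.8e6, 50, seed = 81)
    arch <- traitArchitecture(h, 6, sigma2A = 1, h2 = 0.53, seed = 82)
    ph <- simulatePhenotypes(h, arch, seed = 83)
    gd <- filterSnps(asGenotypeData(
      h, setNames(rep("male", 120), indivIds(h))))
    list(h = h, ph = ph, gd = gd,
         vc = list(sigma2A = 1, sigma2E = 0.2))
  })
}

test_that("null phenotypes give null effect and intercept estimates", {
  inst <- .bayesbInstance()
  ph0 <- inst$ph; ph0$dyd <- 0
  fit <- suppressWarnings(fitBayesB(
    ph0, inst$gd, inst$vc,
    bayesBConfig(chainLength = 800, burnIn = 300), seed = 84))
  expect_lt(max(abs(snpEffects(fit))), 0.02)
  expect_lt(abs(fit@alpha), 0.02)
  expect_true(all(inclusionFreq(fit) >= 0 & inclusionFreq(fit) <= 1))
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  inst <- .bayesbInstance()
  cfg <- bayesBConfig(chainLength = 400, burnIn = 100)
  f1 <- suppressWarnings(fitBayesB(inst$ph, inst$gd, inst$vc, cfg,
                                   seed = 85))
  f2 <- suppressWarnings(fitBayesB(inst$ph, inst$gd, inst$vc, cfg,
                                   seed = 85))
  expect_identical(f1@traces, f2@traces)
  expect_identical(snpEffects(f1), snpEffects(f2))
})

test_that("pi = 1 with fixed locus variance reproduces weighted RR-BLUP", {
  inst <- .bayesbInstance()
  fit <- suppressWarnings(fitBayesB(
    inst$ph, inst$gd, inst$vc,
    bayesBConfig(pi = 1, fixedEffectVariance = TRUE,
                 chainLength = 3000, burnIn = 1000), seed = 86))
  gb <- ebv(predictGebv(fit, inst$gd))
  rr <- fitRrBlup(inst$ph, inst$gd, inst$vc)
  expect_gt(cor(gb, ebv(rr$ebvResult)), 0.98)
})

test_that("posterior residual variance tracks the generating value on null-QTL data", {
  inst <- .bayesbInstance()
  # pure-noise DYDs: y ~ N(0, sigma2e / w), no QTL signal
  ph <- inst$ph
  s2e <- 0.4
  ph$dyd <- withr::with_seed(87,
    rnorm(nrow(ph), 0, sqrt(s2e / ph$weight)))
  fit <- suppressWarnings(fitBayesB(
    ph, inst$gd, list(sigma2A = 1, sigma2E = s2e),
    bayesBConfig(chainLength = 1500, burnIn = 500), seed = 88))
  post <- fit@traces[, "sigma2e"]
  expect_lt(abs(fit@sigma2e - s2e), 4 * sd(post) + 0.05)
})

test_that("GEBV prediction is linear in genotypes and panel-checked", {
  inst <- .bayesbInstance()
  fit <- suppressWarnings(fitBayesB(
    inst$ph, inst$gd, inst$vc,
    bayesBConfig(chainLength = 300, burnIn = 100), seed = 89))
  # null fit: zero effects -> zero GEBVs
  fit0 <- fit
  fit0@beta[] <- 0
  expect_true(all(ebv(predictGebv(fit0, inst$gd)) == 0))
  # single-SNP arithmetic
  fit1 <- fit0
  fit1@beta[3] <- 2
  g <- genotypes(inst$gd)[, 3]
  expect_equal(unname(ebv(predictGebv(fit1, inst$gd))), unname(2 * g))
  # in-sample consistency: training GEBVs equal X beta for training rows
  pr <- ebv(predictGebv(fit, inst$gd))[fit@trainIds]
  expect_equal(unname(pr),
               unname(as.vector(genotypes(inst$gd)[fit@trainIds, ] %*%
                                  fit@beta)))
  # panel mismatch is an alignment error naming the SNPs
  expect_error(predictGebv(fit, inst$gd[-1, ]), "alignment error")
})

test_that("low effective sample size triggers a warning, not silence", {
  inst <- .bayesbInstance()
  expect_warning(
    fitBayesB(inst$ph, inst$gd, inst$vc,
              bayesBConfig(chainLength = 60, burnIn = 10, thin = 1,
                           essWarn = 1e6), seed = 90),
    "effective sample size")
})
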