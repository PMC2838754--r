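#' BayesB configuration
#'
#' Defaults follow routine dairy practice for 50K-chip analyses:
#' `pi = 0.01` (about 1% of SNPs fitted per MCMC round),
#' scaled-inverse-chi-square priors with 4.2 degrees of freedom on both
#' the residual and the per-locus effect variance, and a 50,000-round
#' chain with 40,000 rounds of burn-in.  Desk-scale analyses shorten the
#' chain (see the methods vignette).
#'
#' @param pi prior inclusion probability.
#' @param nuE,nuBeta prior degrees of freedom.
#' @param s2Beta prior scale of the locus effect variance; `NA` (the
#'   default) derives it at fit time from
#'   `sigma2Beta = sigma2A / (pi * sum_k 2 p_k (1 - p_k))`, the standard
#'   partition of the additive variance over the expected `pi * K`
#'   included loci, with scale `s2Beta = sigma2Beta * (nuBeta - 2) /
#'   nuBeta` so the prior mean equals `sigma2Beta`.
#' @param chainLength,burnIn,thin MCMC controls.
#' @param fixedEffectVariance hold the locus variance at `sigma2Beta`
#'   (no variance proposal); with `pi = 1` the sampler then reduces to
#'   weighted RR-BLUP, which is used as an oracle check.
#' @param essWarn effective-sample-size warning threshold for the
#'   residual-variance trace.
#' @return a [BayesBConfig-class].
#' @export
bayesBConfig <- function(pi = 0.01, nuE = 4.2, nuBeta = 4.2,
                         s2Beta = NA_real_, chainLength = 50000,
                         burnIn = 40000, thin = 10,
                         fixedEffectVariance = FALSE, essWarn = 30) {
  new("BayesBConfig", pi = pi, nuE = nuE, nuBeta = nuBeta,
      s2Beta = s2Beta, chainLength = chainLength, burnIn = burnIn,
      thin = thin, fixedEffectVariance = fixedEffectVariance,
      essWarn = essWarn)
}

# effective sample size via the initial-positive-sequence lag sum
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  maxLag <- min(n - 2L, 200L)
  ac <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' Fit BayesB by MCMC
#'
#' Bayesian variable-selection regression of training DYDs on SNP
#' genotypes: each SNP enters the model with prior probability `pi` and
#' its own effect variance; residuals are weighted by the DYD
#' reliability (`Var(e_i) = sigma2e / w_i`).  The intercept has a flat
#' prior.  `(delta_k, sigma2_beta_k)` is sampled by Metropolis-Hastings
#' with the effect integrated out, effects by Gibbs.
#'
#' A warning reports low effective sample size of the residual-variance
#' trace (poor mixing is never silent).
#'
#' @param phenotypes data.frame with columns id, dyd, weight (as
#'   produced by [simulatePhenotypes()]); training bulls.
#' @param gd complete [GenotypeData-class] covering the training bulls.
#' @param variances list with elements `sigma2A` and `sigma2E` (trait
#'   variance components, taken as known inputs).
#' @param config a [BayesBConfig-class].
#' @param seed RNG seed (fixed seed gives identical traces).
#' @return a [BayesBFit-class].
#' @export
fitBayesB <- function(phenotypes, gd, variances, config = bayesBConfig(),
                      seed = NULL) {
  validObject(config)
  ids <- phenotypes$id
  miss <- setdiff(ids, indivIds(gd))
  if (length(miss))
    stop("training bulls without genotypes: ",
         paste(head(miss, 5), collapse = ", "))
  X <- genotypes(gd)[ids, , drop = FALSE]
  if (anyNA(X)) stop("genotypes must be complete (post-QC)")
  w <- phenotypes$weight
  if (any(w <= 0 | w > 1)) stop("weights must lie in (0, 1]")
  p <- colMeans(X) / 2
  sum2pq <- sum(2 * p * (1 - p))
  if (sum2pq <= 0) stop("monomorphic panel")
  sigma2Beta <- variances$sigma2A / (config@pi * sum2pq)
  s2B <- if (is.na(config@s2Beta)) sigma2Beta *
    (config@nuBeta - 2) / config@nuBeta else config@s2Beta
  s2E <- variances$sigma2E * (config@nuE - 2) / config@nuE
  run <- function() .bayesb_mcmc(
    X, phenotypes$dyd, w, config@pi, config@nuE, s2E, config@nuBeta,
    s2B, config@fixedEffectVariance, sigma2Beta,
    as.integer(config@chainLength), as.integer(config@burnIn),
    as.integer(config@thin))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ess <- .ess(res$trace[, 2])
  if (ess < config@essWarn)
    warning(sprintf(paste0("low effective sample size for sigma2e ",
                           "(ESS = %.1f over %d kept samples); ",
                           "consider a longer chain"),
                    ess, nrow(res$trace)))
  tr <- res$trace
  colnames(tr) <- c("alpha", "sigma2e", "nIncluded")
  new("BayesBFit",
      alpha = res$alpha,
      beta = setNames(as.numeric(res$beta), colnames(X)),
      inclusion = setNames(as.numeric(res$inclusion), colnames(X)),
      sigma2e = res$sigma2e, traces = tr,
      snpIds = colnames(X), trainIds = ids, config = config)
}

#' @rdname BayesBFit
#' @export
setMethod("snpEffects", "BayesBFit", function(x) x@beta)

#' @rdname BayesBFit
#' @export
setMethod("inclusionFreq", "BayesBFit", function(x) x@inclusion)

setMethod("show", "BayesBFit", function(object) {
  cat("BayesBFit:", length(object@snpIds), "SNPs,",
      length(object@trainIds), "training bulls; pi =",
      object@config@pi, "\n  posterior mean sigma2e =",
      sprintf("%.4f", object@sigma2e), "; mean SNPs in model =",
      sprintf("%.1f", mean(object@traces[, "nIncluded"])), "\n")
})

#' Predict GEBVs from estimated SNP effects
#'
#' `ghat_i = sum_k x_ik betahat_k`; the intercept is excluded from the
#' breeding value.
#'
#' @param fit a [BayesBFit-class].
#' @param gd [GenotypeData-class] for the target bulls; must carry
#'   exactly the training SNP panel.
#' @return an [EBVResult-class] with method `"BayesB"`.
#' @export
predictGebv <- function(fit, gd) {
  target <- colnames(genotypes(gd))
  if (!identical(target, fit@snpIds)) {
    off <- c(setdiff(target, fit@snpIds), setdiff(fit@snpIds, target))
    stop("alignment error: target panel differs from training panel ",
         "at SNP(s): ", paste(head(off, 5), collapse = ", "),
         if (length(off) > 5) sprintf(" (and %d more)", length(off) - 5))
  }
  X <- genotypes(gd)
  g <- as.vector(X %*% fit@beta)
  new("EBVResult", ebv = setNames(g, rownames(X)), method = "BayesB",
      mu = NA_real_)
}

#' @rdname EBVResult
#' @export
setMethod("ebv", "EBVResult", function(x) x@ebv)

setMethod("show", "EBVResult", function(object) {
  cat(object@method, "EBVs for", length(object@ebv), "individuals",
      if (!is.na(object@mu)) sprintf("(mu = %.4f)", object@mu), "\n")
})
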