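# Animal-model BLUP on a relationship matrix (G-BLUP / P-BLUP) and the
# equivalent SNP-effect ridge model (RR-BLUP).

#' Animal-model BLUP with reliability-weighted residuals
#'
#' Solves `y_i = mu + g_i + e_i` with `g ~ (0, K sigma2A)`,
#' `Var(e_i) = sigma2E / w_i`, for `K` either a genomic (G-BLUP) or a
#' numerator (P-BLUP) relationship matrix.  The system is solved in the
#' phenotype-space GLS form `V = sigma2A K_tt + sigma2E diag(1/w)`,
#' `ghat = sigma2A K[., t] V^{-1} (y - mu hat)`, which is algebraically
#' identical to the joint mixed-model equations including the
#' unphenotyped target equations and requires no inverse of `K`, so a
#' singular G needs no regularisation.  Non-phenotyped targets obtain
#' EBVs through their relationship rows; an unrelated target (zero row)
#' gets EBV 0.
#'
#' @param phenotypes data.frame with columns id, dyd, weight; the
#'   training bulls.
#' @param K a [RelationshipMatrix-class] covering training and targets.
#' @param variances list with elements `sigma2A`, `sigma2E`.
#' @param targets ids to predict (default: all ids in `K`); training
#'   bulls are always included in the output.
#' @param ridge optional ridge added to the diagonal of `K` before
#'   solving (disabled by default; if used it is reported via message).
#' @return an [EBVResult-class] tagged `"G-BLUP"` or `"P-BLUP"`
#'   according to the kind of `K`, with the fitted overall mean in `mu`.
#' @export
fitBlup <- function(phenotypes, K, variances, targets = NULL,
                    ridge = 0) {
  ids <- phenotypes$id
  allIds <- rownames(K@mat)
  if (is.null(targets)) targets <- allIds
  miss <- setdiff(union(ids, targets), allIds)
  if (length(miss))
    stop("relationship matrix does not cover: ",
         paste(head(miss, 5), collapse = ", "))
  w <- phenotypes$weight
  if (any(w <= 0 | w > 1)) stop("weights must lie in (0, 1]")
  Km <- K@mat
  if (ridge > 0) {
    message("adding ridge of ", ridge, " to the relationship diagonal")
    diag(Km) <- diag(Km) + ridge
  }
  s2a <- variances$sigma2A; s2e <- variances$sigma2E
  stopifnot(s2a > 0, s2e > 0)
  V <- s2a * Km[ids, ids, drop = FALSE] + diag(s2e / w, length(ids))
  ch <- tryCatch(chol(V), error = function(e) {
    stop("solver error: phenotype covariance not positive definite ",
         "(reciprocal condition estimate ",
         format(rcond(V), digits = 3), "); consider a ridge on K")
  })
  Vi <- chol2inv(ch)
  y <- phenotypes$dyd
  mu <- sum(Vi %*% y) / sum(Vi)
  out <- unique(c(ids, targets))
  g <- s2a * (Km[out, ids, drop = FALSE] %*% (Vi %*% (y - mu)))
  new("EBVResult", ebv = setNames(as.vector(g), out),
      method = if (K@kind == "genomic") "G-BLUP" else "P-BLUP",
      mu = mu)
}

#' Weighted ridge-regression BLUP on SNP effects
#'
#' The SNP-effect formulation equivalent to G-BLUP: genotypes are
#' centered by twice the allele frequency and all effects share the
#' variance `sigma2A / (2 sum_k p_k (1 - p_k))`.  Solved in closed form
#' from the weighted mixed-model equations.  Used both as a predictor
#' and as the independent oracle for the G-BLUP equivalence and the
#' BayesB `pi = 1` checks.
#'
#' @param phenotypes data.frame with id, dyd, weight (training bulls).
#' @param gd complete [GenotypeData-class]; targets are all its
#'   individuals, with allele frequencies pooled over them.
#' @param variances list with `sigma2A`, `sigma2E`.
#' @param sigma2Beta optional common SNP-effect variance overriding the
#'   default partition.
#' @return list with `alpha` (intercept), `beta` (named effects),
#'   `ebvResult` (an [EBVResult-class] of centered GEBVs
#'   `Zc betahat` for every individual in `gd`).
#' @export
fitRrBlup <- function(phenotypes, gd, variances, sigma2Beta = NULL) {
  ids <- phenotypes$id
  X <- genotypes(gd)
  if (anyNA(X)) stop("genotypes must be complete (post-QC)")
  p <- colMeans(X) / 2
  sum2pq <- sum(2 * p * (1 - p))
  if (sum2pq <= 0) stop("monomorphic panel")
  if (is.null(sigma2Beta)) sigma2Beta <- variances$sigma2A / sum2pq
  Zc <- sweep(X, 2L, 2 * p)
  Zt <- Zc[ids, , drop = FALSE]
  w <- phenotypes$weight
  y <- phenotypes$dyd
  lambda <- variances$sigma2E / sigma2Beta
  K <- ncol(Zt)
  # MME for (alpha, beta), flat prior on alpha
  C <- rbind(
    c(sum(w), colSums(w * Zt)),
    cbind(colSums(w * Zt), crossprod(Zt, w * Zt) + diag(lambda, K)))
  rhs <- c(sum(w * y), crossprod(Zt, w * y))
  sol <- solve(C, rhs)
  beta <- setNames(sol[-1], colnames(X))
  g <- as.vector(Zc %*% beta)
  list(alpha = sol[1], beta = beta,
       ebvResult = new("EBVResult", ebv = setNames(g, rownames(X)),
                       method = "RR-BLUP", mu = sol[1]))
}
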