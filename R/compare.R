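#' @include AllClasses.R tf.R
#' @importFrom stats dnorm
NULL

#' Akaike information criterion of a fitted model
#'
#' Gaussian log-likelihood with the maximum-likelihood residual variance
#' \code{sigma2 = max(RSS/n, 1e-12)} (floored so a perfect fit does not give
#' an infinite likelihood): \code{AIC = -2 l + 2k} with \code{k} the number
#' of nonzero slope coefficients (the intercept is excluded, so a
#' promoter-only and a full model are penalized comparably).
#'
#' @param fit a \linkS4class{FitResult} produced from \code{(X, y)}
#' @param X predictor matrix (columns must cover the fit's predictors)
#' @param y response (length >= 2)
#' @return scalar AIC
#' @export
aicFit <- function(fit, X, y) {
  n <- length(y)
  if (n < 2L) stop("need n >= 2")
  yhat <- predictExpression(fit, as.matrix(X))
  rss <- sum((y - yhat)^2)
  sigma2 <- max(rss / n, 1e-12)
  ll <- sum(dnorm(y - yhat, mean = 0, sd = sqrt(sigma2), log = TRUE))
  -2 * ll + 2 * fit@n_nonzero
}

#' Compare a full CRE-network model with a promoter-only model
#'
#' \code{delta_aic = aic_full - aic_promoter}; negative values favor the
#' model using the full distal CRE set. The relative probability
#' \code{exp(delta_aic / 2)} is the likelihood of the promoter-only model
#' relative to the full one.
#'
#' @param fit_full,fit_promoter \linkS4class{FitResult}s for the same
#'   response
#' @param X_full,X_prom their predictor matrices
#' @param y the shared response
#' @return one-row data.frame: gene_id, aic_full, aic_promoter, delta_aic,
#'   rel_probability
#' @export
compareModels <- function(fit_full, fit_promoter, X_full, X_prom, y) {
  a_full <- aicFit(fit_full, X_full, y)
  a_prom <- aicFit(fit_promoter, X_prom, y)
  d <- a_full - a_prom
  data.frame(gene_id = fit_full@gene_id, aic_full = a_full,
             aic_promoter = a_prom, delta_aic = d,
             rel_probability = exp(d / 2), stringsAsFactors = FALSE)
}

#' Jaccard index of two sets
#'
#' \code{|A intersect B| / |A union B|}; two empty sets are identical and
#' score 1 (with a warning).
#'
#' @param set_a,set_b finite sets (vectors; duplicates ignored)
#' @return value in [0, 1]
#' @export
jaccardIndex <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- union(a, b)
  if (length(u) == 0L) {
    warning("both sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(u)
}
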