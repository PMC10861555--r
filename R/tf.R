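#' @include AllClasses.R enet.R
NULL

.empty_tf_links <- function() {
  data.frame(tf_id = character(), gene_id = character(), beta = numeric(),
             se = numeric(), pvalue = numeric(), stringsAsFactors = FALSE)
}

#' Fit a gene's TF model (stage 2)
#'
#' Adaptive elastic net of the gene's expression on the expression of its
#' nominated candidate TFs, followed by bootstrap significance filtering.
#' Single cells are the recommended input; pseudocells are accepted.
#' Self-regulation (the gene among its own predictors) is removed unless
#' \code{allow_self}.
#'
#' @param gene_id gene to model
#' @param expr expression \linkS4class{OmicsMatrix} containing the gene and
#'   the candidate TFs as features
#' @param candidates candidate TF ids from \code{\link{candidateTfs}} or
#'   \code{\link{enrichedTfs}}
#' @param config an \code{\link{enetConfig}} (stage-2 defaults:
#'   \code{l2_weight} 0.5, \code{n_boot} 100)
#' @param allow_self keep the gene itself as a predictor (TF autoregulation)
#' @return list with \code{fit} (\linkS4class{FitResult} or \code{NULL} when
#'   skipped), \code{links} (data.frame: tf_id, gene_id, beta, se, pvalue)
#'   and \code{reason} (\code{NA} or why the gene was skipped)
#' @export
fitGeneTfs <- function(gene_id, expr,
                       candidates, config = enetConfig(l2_weight = 0.5,
                                                       n_boot = 100),
                       allow_self = FALSE) {
  if (!allow_self) candidates <- setdiff(candidates, gene_id)
  candidates <- intersect(candidates, featureIds(expr))
  if (length(candidates) == 0L)
    return(list(fit = NULL, links = .empty_tf_links(),
                reason = "no candidate TFs"))
  if (!gene_id %in% featureIds(expr)) stop("gene absent from expr: ", gene_id)

  y <- as.numeric(omicsValues(expr)[, gene_id])
  X <- as.matrix(omicsValues(expr)[, candidates, drop = FALSE])
  cfg <- config
  cfg$seed <- deriveSeed(config$seed, gene_id, 10L)
  fit <- fitAdaptiveEnet(X, y, cfg, gene_id = gene_id)
  if (length(fit@predictor_ids)) fit <- bootstrapSignificance(X, y, fit, cfg)

  keep <- fit@beta != 0
  links <- if (any(keep)) {
    data.frame(tf_id = fit@predictor_ids[keep], gene_id = gene_id,
               beta = fit@beta[keep], se = fit@se[keep],
               pvalue = fit@pvalue[keep], stringsAsFactors = FALSE)
  } else .empty_tf_links()
  rownames(links) <- NULL
  list(fit = fit, links = links, reason = NA_character_)
}

#' Predict expression from a fitted model
#'
#' \code{yhat = intercept + sum_p beta_p x[, p]}; exactly linear, no
#' clipping.
#'
#' @param fit a \linkS4class{FitResult}
#' @param tf_expr \linkS4class{OmicsMatrix} or matrix whose columns include
#'   every fit predictor
#' @return named numeric vector of predictions, one per row of
#'   \code{tf_expr}
#' @export
predictExpression <- function(fit, tf_expr) {
  v <- if (methods::is(tf_expr, "OmicsMatrix")) omicsValues(tf_expr) else tf_expr
  miss <- setdiff(fit@predictor_ids, colnames(v))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "))
  if (length(fit@predictor_ids) == 0L)
    return(stats::setNames(rep(fit@intercept, nrow(v)), rownames(v)))
  yhat <- as.numeric(v[, fit@predictor_ids, drop = FALSE] %*% fit@beta) +
    fit@intercept
  stats::setNames(yhat, rownames(v))
}

#' Proportion of variance explained
#'
#' \code{1 - RSS/TSS}; negative values indicate a fit worse than the mean
#' and are permitted. Returns \code{NA} (with a warning) when the response
#' has zero variance.
#'
#' @param y observed values (length >= 2)
#' @param yhat predictions
#' @return scalar r-squared
#' @export
r2Score <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("y and yhat must share length >= 2")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    warning("zero-variance response: r2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / tss
}
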