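#' @include AllClasses.R utils.R
#' @useDynLib adenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd pnorm setNames
NULL

#' Adaptive elastic-net configuration
#'
#' Hyperparameters shared by both modeling stages. \code{l2_weight} is the
#' ridge weight relative to the adaptive L1 term: the penalty is
#' \code{lambda * (l2_weight * ||beta||^2 + sum_j w_j |beta_j|)} with the
#' overall \code{lambda} chosen by cross-validation, so smaller
#' \code{l2_weight} means a relatively stronger L1 term and sparser models.
#' The stages use 0.25 (CRE) and 0.5 (TF) with 1000 and 100 bootstrap
#' resamples respectively.
#'
#' @param l2_weight relative ridge weight, >= 0
#' @param gamma adaptive-weight exponent, > 0
#' @param cv_folds cross-validation folds, >= 2
#' @param n_boot bootstrap resamples for coefficient standard errors
#' @param alpha_sig significance level for retaining coefficients
#' @param seed integer RNG seed
#' @param lambda_rule \code{"min"} (CV-minimum, default) or \code{"1se"}
#' @param nlambda points on the penalty path
#' @param lambda_min_ratio smallest path lambda as a fraction of lambda_max
#' @return an object of class \code{EnetConfig}
#' @export
enetConfig <- function(l2_weight = 0.25, gamma = 1, cv_folds = 10,
                       n_boot = 100, alpha_sig = 0.05, seed = 1L,
                       lambda_rule = c("min", "1se"), nlambda = 50L,
                       lambda_min_ratio = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (l2_weight < 0) stop("l2_weight must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (n_boot < 0) stop("n_boot must be >= 0")
  structure(list(l2_weight = l2_weight, gamma = gamma,
                 cv_folds = as.integer(cv_folds), n_boot = as.integer(n_boot),
                 alpha_sig = alpha_sig, seed = as.integer(seed),
                 lambda_rule = lambda_rule, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "EnetConfig")
}

# Standardization used throughout: population sd; zero-variance columns get
# an infinite penalty weight so their coefficient is pinned at zero.
.std_stats <- function(X) {
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm, "-")^2))
  list(xm = xm, xs = xs)
}

.standardize <- function(X, st) {
  Xs <- sweep(X, 2, st$xm, "-")
  sc <- ifelse(st$xs > 0, st$xs, 1)
  sweep(Xs, 2, sc, "/")
}

#' Solve the weighted elastic net at fixed penalty levels
#'
#' Low-level solver for
#' \code{min ||y - X beta||^2 + lambda (l2_weight ||beta||^2 +
#' sum_j w_j |beta_j|)} by cyclic coordinate descent with warm starts along a
#' decreasing \code{lambda} path. With \code{standardize = TRUE} the penalty
#' applies to z-scored predictors and coefficients are returned on both
#' scales; the intercept is unpenalized (handled by centering).
#'
#' @param X numeric predictor matrix (n x p)
#' @param y numeric response (length n)
#' @param lambda decreasing vector of penalty levels
#' @param l2_weight relative ridge weight
#' @param penalty_weights per-predictor L1 weights (default 1); \code{Inf}
#'   pins a coefficient at zero
#' @param standardize z-score predictors internally
#' @param intercept fit an unpenalized intercept
#' @param tol,maxit coordinate-descent convergence controls
#' @return list with \code{beta} (p x nlambda, original scale),
#'   \code{beta_std}, \code{intercept} (per lambda), \code{lambda}
#' @export
enetSolve <- function(X, y, lambda, l2_weight = 0, penalty_weights = NULL,
                      standardize = TRUE, intercept = TRUE, tol = 1e-10,
                      maxit = 100000L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  w <- penalty_weights %||% rep(1, p)
  if (length(w) != p) stop("penalty_weights length must equal ncol(X)")
  if (intercept) {
    st <- .std_stats(X)
    ym <- mean(y)
    if (!standardize) st$xs <- rep(1, ncol(X))
    Xw <- .standardize(X, st)
    yc <- y - ym
  } else {
    st <- list(xm = rep(0, p), xs = rep(1, p))
    ym <- 0
    Xw <- X
    yc <- y
  }
  w_eff <- ifelse(st$xs > 0, w, Inf)
  bs <- .enet_cd_path(Xw, yc, as.numeric(lambda), l2_weight,
                      as.numeric(w_eff), tol, as.integer(maxit))
  sc <- ifelse(st$xs > 0, st$xs, 1)
  b <- bs / sc
  b0 <- ym - as.numeric(crossprod(st$xm, b))
  dimnames(b) <- dimnames(bs) <- list(colnames(X), NULL)
  list(beta = b, beta_std = bs, intercept = b0, lambda = as.numeric(lambda))
}

#' Cross-validated elastic-net fit
#'
#' Builds a log-spaced penalty path from the data, selects \code{lambda} by
#' k-fold cross-validated mean squared prediction error, and refits on the
#' full data. Fold assignment is deterministic given \code{seed}.
#'
#' @inheritParams enetSolve
#' @param cv_folds number of folds
#' @param nlambda,lambda_min_ratio path geometry
#' @param lambda_rule \code{"min"} or \code{"1se"}
#' @param seed RNG seed for fold assignment
#' @return list with the selected-\code{lambda} fit: \code{beta},
#'   \code{beta_std}, \code{intercept}, \code{lambda}, \code{lambda_path},
#'   \code{cvm}, \code{cvsd}, standardization stats \code{xm}, \code{xs},
#'   \code{ym}
#' @export
cvEnet <- function(X, y, l2_weight = 0, penalty_weights = NULL, cv_folds = 10,
                   nlambda = 50L, lambda_min_ratio = NULL,
                   lambda_rule = c("min", "1se"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  # glmnet-style default: do not chase a dense, ill-determined solution
  # at the path end when p exceeds n
  lambda_min_ratio <- lambda_min_ratio %||% if (n < p) 1e-2 else 1e-3
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < cv_folds)
    stop(sprintf("need at least cv_folds = %d rows, have %d", cv_folds, n))
  w <- penalty_weights %||% rep(1, p)
  st <- .std_stats(X)
  ym <- mean(y)
  Xs <- .standardize(X, st)
  yc <- y - ym
  w_eff <- ifelse(st$xs > 0, w, Inf)
  fin <- is.finite(w_eff)

  zero_fit <- function() {
    list(beta = setNames(rep(0, p), colnames(X)),
         beta_std = setNames(rep(0, p), colnames(X)), intercept = ym,
         lambda = 0, lambda_path = numeric(), cvm = numeric(),
         cvsd = numeric(), xm = st$xm, xs = st$xs, ym = ym)
  }
  if (!any(fin) || sd(y) == 0) return(zero_fit())

  lam_max <- max(2 * abs(as.numeric(crossprod(Xs[, fin, drop = FALSE], yc))) /
                 w_eff[fin])
  if (!is.finite(lam_max) || lam_max <= 0) return(zero_fit())
  path <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = nlambda))

  folds <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(cv_folds), n)))
  err <- matrix(NA_real_, cv_folds, length(path))
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    fit_k <- enetSolve(X[tr, , drop = FALSE], y[tr], path, l2_weight, w)
    pred <- X[!tr, , drop = FALSE] %*% fit_k$beta
    pred <- sweep(pred, 2, fit_k$intercept, "+")
    err[k, ] <- colMeans((pred - y[!tr])^2)
  }
  cvm <- colMeans(err)
  cvsd <- apply(err, 2, sd) / sqrt(cv_folds)
  i_min <- which.min(cvm)
  i_sel <- if (lambda_rule == "1se") {
    min(which(cvm <= cvm[i_min] + cvsd[i_min]))
  } else i_min

  full <- enetSolve(X, y, path, l2_weight, w)
  list(beta = setNames(full$beta[, i_sel], colnames(X)),
       beta_std = setNames(full$beta_std[, i_sel], colnames(X)),
       intercept = full$intercept[i_sel], lambda = path[i_sel],
       lambda_path = path, cvm = cvm, cvsd = cvsd,
       xm = st$xm, xs = st$xs, ym = ym)
}

#' Pilot elastic-net fit
#'
#' First stage of the adaptive elastic net: an ordinary (unit-weight)
#' elastic-net fit with cross-validated penalty level, providing the pilot
#' coefficients from which adaptive weights are computed.
#'
#' @param X predictor matrix
#' @param y response vector
#' @param config an \code{\link{enetConfig}}
#' @return as \code{\link{cvEnet}}; \code{$beta} holds the pilot coefficients
#'   on the original predictor scale
#' @export
fitEnet <- function(X, y, config = enetConfig()) {
  X <- as.matrix(X)
  if (nrow(X) < config$cv_folds)
    stop(sprintf("fewer rows (%d) than cv_folds (%d)", nrow(X),
                 config$cv_folds))
  if (sd(y) == 0) {
    warning("constant response; returning all-zero coefficients")
    return(cvEnet(X, y, config$l2_weight, cv_folds = config$cv_folds,
                  seed = config$seed))
  }
  cvEnet(X, y, l2_weight = config$l2_weight, cv_folds = config$cv_folds,
         nlambda = config$nlambda, lambda_min_ratio = config$lambda_min_ratio,
         lambda_rule = config$lambda_rule, seed = config$seed)
}

#' Adaptive penalty weights from pilot coefficients
#'
#' \code{w_j = |beta_j|^(-gamma)} for nonzero pilot coefficients; predictors
#' whose pilot coefficient is exactly zero receive an infinite penalty and
#' are excluded from the adaptive stage.
#'
#' @param beta_enet pilot coefficient vector (named)
#' @param gamma positive exponent
#' @return list with \code{weights} (named, over kept predictors only) and
#'   \code{kept} (indices into \code{beta_enet})
#' @export
adaptiveWeights <- function(beta_enet, gamma = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  kept <- which(beta_enet != 0)
  list(weights = abs(beta_enet[kept])^(-gamma), kept = kept)
}

.empty_fit <- function(gene_id, n, l2_weight, r2 = 0) {
  new("FitResult", gene_id = gene_id, predictor_ids = character(),
      beta = numeric(), intercept = NA_real_, se = numeric(),
      pvalue = numeric(), lambda1 = NA_real_, lambda2 = l2_weight,
      lambda2_abs = NA_real_, penalty_weights = numeric(), r2 = r2,
      n_obs = as.integer(n), n_nonzero = 0L)
}

#' Two-stage adaptive elastic-net fit
#'
#' Fits the pilot elastic net, converts its coefficients to adaptive weights
#' \code{|beta|^(-gamma)} (zero pilot coefficients drop out), refits the
#' weighted-L1 elastic net with its own cross-validated penalty level, and
#' rescales the selected coefficients by \code{(1 + lambda2_abs / n)} where
#' \code{lambda2_abs} is the absolute ridge level at the chosen path point.
#' Deterministic given \code{config$seed}.
#'
#' @inheritParams fitEnet
#' @param gene_id label stored on the result
#' @return a \linkS4class{FitResult} (standard errors and p-values are filled
#'   by \code{\link{bootstrapSignificance}})
#' @export
fitAdaptiveEnet <- function(X, y, config = enetConfig(), gene_id = "gene") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < config$cv_folds)
    stop(sprintf("fewer rows (%d) than cv_folds (%d)", n, config$cv_folds))
  if (sd(y) == 0) {
    warning(sprintf("%s: constant response; no model fitted", gene_id))
    return(.empty_fit(gene_id, n, config$l2_weight))
  }

  pilot <- cvEnet(X, y, l2_weight = config$l2_weight,
                  cv_folds = config$cv_folds, nlambda = config$nlambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  lambda_rule = config$lambda_rule, seed = config$seed)
  aw <- adaptiveWeights(pilot$beta_std, config$gamma)
  if (length(aw$kept) == 0L) return(.empty_fit(gene_id, n, config$l2_weight))

  Xk <- X[, aw$kept, drop = FALSE]
  final <- cvEnet(Xk, y, l2_weight = config$l2_weight,
                  penalty_weights = as.numeric(aw$weights),
                  cv_folds = config$cv_folds, nlambda = config$nlambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  lambda_rule = config$lambda_rule,
                  seed = deriveSeed(config$seed, gene_id, 1L))
  lambda2_abs <- final$lambda * config$l2_weight
  rescale <- 1 + lambda2_abs / n
  beta <- final$beta * rescale
  b0 <- mean(y) - as.numeric(crossprod(colMeans(Xk), beta))
  yhat <- as.numeric(Xk %*% beta) + b0
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

  new("FitResult", gene_id = gene_id, predictor_ids = colnames(Xk),
      beta = as.numeric(beta), intercept = b0,
      se = rep(NA_real_, ncol(Xk)), pvalue = rep(NA_real_, ncol(Xk)),
      lambda1 = final$lambda, lambda2 = config$l2_weight,
      lambda2_abs = lambda2_abs,
      penalty_weights = as.numeric(aw$weights), r2 = r2,
      n_obs = as.integer(n), n_nonzero = sum(beta != 0))
}

#' Bootstrap standard errors and significance filtering
#'
#' Resamples rows with replacement \code{config$n_boot} times and refits the
#' adaptive elastic net at the already-selected penalty level and adaptive
#' weights on each resample. The standard error of each coefficient is the
#' standard deviation of its resampled estimates; p-values come from a
#' two-sided normal reference centered at the full-data estimate,
#' \code{p_j = 2 (1 - Phi(|beta_j| / se_j))}. Predictors with
#' \code{p >= config$alpha_sig} are removed. A degenerate standard error
#' (< 1e-12) yields p = 0 for a nonzero coefficient and p = 1 otherwise.
#'
#' @param X,y the data the fit was produced from
#' @param fit a \linkS4class{FitResult} from \code{\link{fitAdaptiveEnet}}
#' @param config an \code{\link{enetConfig}}; \code{n_boot} must be >= 2
#' @return the filtered \linkS4class{FitResult} with \code{se} and
#'   \code{pvalue} filled
#' @export
bootstrapSignificance <- function(X, y, fit, config = enetConfig()) {
  if (config$n_boot < 2) stop("n_boot must be >= 2 for bootstrap inference")
  ids <- fit@predictor_ids
  if (length(ids) == 0L) return(fit)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, ids, drop = FALSE]
  n <- nrow(X)
  lam <- fit@lambda1
  w <- fit@penalty_weights
  B <- withr::with_seed(deriveSeed(config$seed, fit@gene_id, 2L), {
    vapply(seq_len(config$n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sol <- enetSolve(X[idx, , drop = FALSE], y[idx], lam, fit@lambda2, w)
      sol$beta[, 1] * (1 + lam * fit@lambda2 / n)
    }, numeric(length(ids)))
  })
  if (length(ids) == 1L) B <- matrix(B, nrow = 1L)
  se <- apply(B, 1, sd)
  p <- ifelse(se < 1e-12,
              ifelse(fit@beta != 0, 0, 1),
              2 * pnorm(abs(fit@beta) / se, lower.tail = FALSE))
  keep <- p < config$alpha_sig
  new("FitResult", gene_id = fit@gene_id, predictor_ids = ids[keep],
      beta = fit@beta[keep], intercept = fit@intercept, se = se[keep],
      pvalue = p[keep], lambda1 = fit@lambda1, lambda2 = fit@lambda2,
      lambda2_abs = fit@lambda2_abs,
      penalty_weights = fit@penalty_weights[keep], r2 = fit@r2,
      n_obs = fit@n_obs, n_nonzero = sum(fit@beta[keep] != 0))
}
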