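test_that("orthonormal designs reduce to soft-thresholding", {
  set.seed(11)
  for (r in 1:5) {
    n <- 8; p <- 2
    Q <- qr.Q(qr(matrix(rnorm(n * p), n)))
    y <- rnorm(n)
    lam <- runif(1, 0.05, 1)
    sol <- enetSolve(Q, y, lam, l2_weight = 0, standardize = FALSE,
                     intercept = FALSE)
    b_ols <- as.numeric(crossprod(Q, y))
    expect_equal(unname(sol$beta[, 1]),
                 sign(b_ols) * pmax(abs(b_ols) - lam / 2, 0),
                 tolerance = 1e-8)
  }
})

test_that("solver attains the proximal-gradient oracle objective", {
  set.seed(21)
  for (r in 1:8) {
    X <- matrix(rnorm(50 * 8), 50)
    y <- rnorm(50)
    w <- runif(8, 0.3, 3)
    lam <- runif(1, 0.1, 3)
    sol <- enetSolve(X, y, lam, l2_weight = 0.25, penalty_weights = w,
                     standardize = FALSE, intercept = FALSE)
    gap <- enet_objective(X, y, sol$beta[, 1], lam, 0.25, w) -
      enet_objective(X, y, pgd_oracle(X, y, lam, 0.25, w), lam, 0.25, w)
    expect_lt(gap, 1e-6)
  }
})

test_that("pilot fit matches glmnet under the parameter mapping", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", 1:p)
  y <- X[, 1] * 1.5 - X[, 4] + rnorm(n, 0, 0.5)
  lam <- 4; l2w <- 0.25
  mine <- enetSolve(X, y, lam, l2w, standardize = FALSE)
  # glmnet objective: (1/2n)||y - b0 - Xb||^2 + lg[(1-a)/2 ||b||^2 + a||b||_1]
  # maps to ours via a = 1/(1 + 2 l2w), lg = lam / (2 n a)
  alpha <- 1 / (1 + 2 * l2w)
  lg <- lam / (2 * n * alpha)
  gfit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lg,
                         standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(mine$beta[, 1]), as.numeric(gfit$beta),
               tolerance = 0.02)
  # at the mapped penalty both minimize the same objective; ours must be
  # at least as good
  obj <- function(b, b0) sum((y - b0 - X %*% b)^2) +
    lam * (l2w * sum(b^2) + sum(abs(b)))
  expect_lte(obj(mine$beta[, 1], mine$intercept[1]),
             obj(as.numeric(gfit$beta), as.numeric(gfit$a0)) + 1e-8)
})

test_that("degenerate responses and the OLS limit behave", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(f0 <- fitEnet(X, rep(0, 20), enetConfig(seed = 1)),
                 "constant")
  expect_true(all(f0$beta == 0))
  expect_equal(f0$intercept, 0)

  x <- rnorm(60)
  s <- enetSolve(matrix(x, ncol = 1), x, 1e-10, 0)
  expect_equal(unname(s$beta[1, 1]), 1, tolerance = 1e-6)
})

test_that("adaptive weights follow the inverse-power law and drop zeros", {
  aw <- adaptiveWeights(c(a = 0.5, b = 0.25, c = 0), gamma = 1)
  expect_equal(unname(aw$weights), c(2, 4))
  expect_identical(names(aw$weights), c("a", "b"))
  expect_equal(unname(adaptiveWeights(c(x = 0.5), gamma = 2)$weights), 4)
  expect_error(adaptiveWeights(c(1, 2), gamma = 0), "gamma")
  # strictly decreasing in |beta| for fixed gamma
  b <- sort(runif(20, 0.01, 3))
  w <- adaptiveWeights(b, gamma = 1.3)$weights
  expect_true(all(diff(w) < 0))
})

test_that("sparsity is monotone along the penalty path", {
  set.seed(31)
  X <- matrix(rnorm(60 * 15), 60)
  y <- X[, 1:3] %*% c(1, -2, 0.5) + rnorm(60)
  path <- exp(seq(log(50), log(0.05), length.out = 30))
  sol <- enetSolve(X, y, path, l2_weight = 0)
  nnz <- colSums(sol$beta != 0)
  expect_true(all(diff(nnz) >= 0))  # lambda decreasing -> support grows
})

test_that("adaptive elastic net recovers a planted single effect", {
  set.seed(42)
  n <- 200; p <- 50
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", 1:p)
  y <- 2 * X[, 3] + rnorm(n, 0, 0.3)
  fit <- fitAdaptiveEnet(X, y, enetConfig(l2_weight = 0.25, seed = 9), "g")
  b <- coef(fit)
  expect_true("x3" %in% names(b)[b != 0])
  expect_lt(abs(b["x3"] - 2) / 2, 0.15)
  expect_lte(sum(b[names(b) != "x3"] != 0), 5)
})

test_that("perfectly collinear predictors share the effect without crashing", {
  set.seed(8)
  n <- 100
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  y <- 1.5 * x + rnorm(n, 0, 0.2)
  fit <- fitAdaptiveEnet(X, y, enetConfig(l2_weight = 0.5, seed = 2), "g")
  b <- coef(fit)
  expect_equal(unname(b["a"] + b["b"]), 1.5, tolerance = 0.2)
})

test_that("fits are deterministic given the seed and error on tiny n", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  cfg <- enetConfig(seed = 77, n_boot = 20)
  f1 <- fitAdaptiveEnet(X, y, cfg, "g")
  f2 <- fitAdaptiveEnet(X, y, cfg, "g")
  expect_identical(f1, f2)
  b1 <- bootstrapSignificance(X, y, f1, cfg)
  b2 <- bootstrapSignificance(X, y, f2, cfg)
  expect_identical(b1, b2)
  expect_error(fitAdaptiveEnet(X[1:4, ], y[1:4],
                               enetConfig(cv_folds = 10), "g"),
               "cv_folds")
})

test_that("bootstrap inference flags noiseless fits and rejects n_boot < 2", {
  set.seed(12)
  n <- 60
  x1 <- rnorm(n)
  X <- cbind(x1 = x1)
  y <- x1
  cfg <- enetConfig(l2_weight = 0, n_boot = 30, seed = 4,
                    lambda_min_ratio = 1e-6)
  fit <- fitAdaptiveEnet(X, y, cfg, "g")
  bs <- bootstrapSignificance(X, y, fit, cfg)
  expect_identical(bs@predictor_ids, "x1")
  expect_lt(bs@pvalue[1], 1e-10)
  expect_error(bootstrapSignificance(X, y, fit, enetConfig(n_boot = 1)),
               "n_boot")
})
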