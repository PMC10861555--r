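# Independent oracles used across tests. These deliberately avoid the
# package's solver path: proximal gradient descent for the penalized
# objective, power iteration for PageRank, hypergeometric arithmetic for
# Fisher p-values.

enet_objective <- function(X, y, b, lam, l2w, w = rep(1, length(b))) {
  sum((y - X %*% b)^2) + lam * (l2w * sum(b^2) + sum(w * abs(b)))
}

# 10,000-step proximal gradient descent on the same objective.
pgd_oracle <- function(X, y, lam, l2w, w = rep(1, ncol(X)), iters = 10000L) {
  p <- ncol(X)
  b <- rep(0, p)
  L <- 2 * (max(eigen(crossprod(X), symmetric = TRUE,
                      only.values = TRUE)$values) + lam * l2w)
  for (i in seq_len(iters)) {
    g <- -2 * as.numeric(crossprod(X, y - X %*% b)) + 2 * lam * l2w * b
    z <- b - g / L
    b <- sign(z) * pmax(abs(z) - lam * w / L, 0)
  }
  b
}

pagerank_power <- function(adj_weighted, damping = 0.85, tol = 1e-12) {
  # adj_weighted: directed weight matrix W[i, j] = weight of edge i -> j
  n <- nrow(adj_weighted)
  out <- rowSums(adj_weighted)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (out[i] > 0) P[i, ] <- adj_weighted[i, ] / out[i]
  }
  dangling <- out == 0
  r <- rep(1 / n, n)
  repeat {
    r_new <- damping * (as.numeric(r %*% P) + sum(r[dangling]) / n) +
      (1 - damping) / n
    if (max(abs(r_new - r)) < tol) break
    r <- r_new
  }
  stats::setNames(r_new, rownames(adj_weighted))
}

fisher_greater_oracle <- function(a, b, c_, d) {
  # one-sided (greater) p for table rbind(c(a, c_), c(b, d)) via the
  # hypergeometric tail
  m <- a + b; n2 <- c_ + d; k <- a + c_
  sum(dhyper(max(a, 0):min(m, k), m, n2, k))
}

# Small cached simulation shared by unit tests (built once per session).
.test_cache <- new.env(parent = emptyenv())

mini_sim <- function() {
  if (is.null(.test_cache$mini)) {
    .test_cache$mini <- simulateMultiome(n_cells = 400, n_genes = 10,
                                         n_tfs = 8, peaks_per_gene = 30,
                                         seed = 7)
  }
  .test_cache$mini
}

mini_pseudo <- function() {
  if (is.null(.test_cache$mini_pc)) {
    sim <- mini_sim()
    pc <- buildPseudocells(embedding = sim$embedding, target_size = 10,
                           seed = 3)
    .test_cache$mini_pc <- list(pc = pc,
                                expr = aggregateCells(sim$expr, pc),
                                acc = aggregateCells(sim$acc, pc))
  }
  .test_cache$mini_pc
}
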