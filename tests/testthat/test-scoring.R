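toy_links <- function() {
  data.frame(tf_id = c("T1", "T1", "T2"),
             gene_id = c("gUpB", "gUpA", "gUpA"),
             beta = c(0.5, 0.5, -0.25))
}

test_that("axis scores follow the hand-computed formula", {
  deg <- degTable(c("gUpA", "gUpB"), c(1, -1))
  me <- c(T1 = 2, T2 = 2)
  sc <- tfAxisScore(toy_links(), deg, me)
  # T1: 2 * (0.5 * -1 + 0.5 * +1) = 0 ; T2: 2 * (-0.25 * +1) = -0.5
  expect_equal(sc$score[sc$tf_id == "T1"], 0)
  expect_equal(sc$score[sc$tf_id == "T2"], -0.5)
  one <- data.frame(tf_id = "T", gene_id = "gUpB", beta = 0.5)
  expect_equal(tfAxisScore(one, deg, c(T = 2))$score, -1)
  one$gene_id <- "gUpA"
  expect_equal(tfAxisScore(one, deg, c(T = 2))$score, 1)
  expect_error(tfAxisScore(one, deg, c(X = 1)), "missing mean expression")
  expect_error(tfAxisScore(data.frame(tf_id = "T", gene_id = "zz",
                                      beta = 1), deg, c(T = 1)), "absent")
})

test_that("axis scores are linear and negate with the DEG directions", {
  set.seed(7)
  links <- data.frame(tf_id = sample(paste0("T", 1:4), 20, TRUE),
                      gene_id = sample(paste0("g", 1:6), 20, TRUE),
                      beta = rnorm(20))
  deg <- degTable(paste0("g", 1:6), rep(c(1, -1), 3))
  me <- stats::setNames(runif(4, 1, 3), paste0("T", 1:4))
  s1 <- tfAxisScore(links, deg, me)
  s2 <- tfAxisScore(transform(links, beta = 2 * beta), deg, me)
  expect_equal(s2$score[match(s1$tf_id, s2$tf_id)], 2 * s1$score)
  s3 <- tfAxisScore(links, deg, 3 * me)
  expect_equal(s3$score[match(s1$tf_id, s3$tf_id)], 3 * s1$score)
  deg_flip <- degTable(deg$gene_id, -deg$direction)
  s4 <- tfAxisScore(links, deg_flip, me)
  expect_equal(s4$score[match(s1$tf_id, s4$tf_id)], -s1$score)
})

test_that("cell-type scores respect marker sets and mean expression", {
  links <- data.frame(tf_id = c("T1", "T1", "T2"),
                      gene_id = c("g1", "g2", "g1"),
                      beta = c(1, 0.5, -2))
  me <- matrix(c(2, 0, 1, 1), 2, 2,
               dimnames = list(c("T1", "T2"), c("ctA", "ctB")))
  sc <- tfCelltypeScores(links, list(ctA = c("g1", "g2"), ctB = "g1"), me)
  expect_equal(sc["T1", "ctA"], 2 * 1.5)
  expect_equal(sc["T2", "ctA"], 0)        # zero mean expression there
  expect_equal(sc["T2", "ctB"], -2)
  sc2 <- tfCelltypeScores(links, list(ctA = c("g1", "g2"), ctB = "g1"),
                          2 * me)
  expect_equal(sc2, 2 * sc)
  expect_error(tfCelltypeScores(links, list(ctZ = "g1"), me), "unknown")
  # top-k utility feeds Jaccard comparisons
  expect_equal(jaccardIndex(topTfs(sc[, "ctA"], 1), topTfs(sc2[, "ctA"], 1)),
               1)
})

test_that("reversed PageRank makes heavily-targeting regulators central", {
  links <- data.frame(tf_id = "hub", gene_id = paste0("g", 1:5),
                      beta = rep(1, 5))
  g <- buildGraph(links, c(hub = 1))
  pr <- pageRankScores(g)
  expect_identical(names(pr)[1], "hub")
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # forward direction spreads rank to targets instead
  prf <- pageRankScores(g, direction = "forward")
  expect_lt(prf["hub"], max(prf))
})

test_that("PageRank matches a power-iteration oracle on a 3-cycle", {
  links <- data.frame(tf_id = c("a", "b", "c"), gene_id = c("b", "c", "a"),
                      beta = c(1, 1, 1))
  g <- buildGraph(links, c(a = 1, b = 1, c = 1))
  pr <- pageRankScores(g)
  expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-10)
  # general graph vs oracle
  set.seed(9)
  links2 <- unique(data.frame(tf_id = sample(letters[1:5], 12, TRUE),
                              gene_id = sample(letters[1:8], 12, TRUE),
                              beta = round(runif(12, 0.5, 2), 2)))
  links2 <- links2[links2$tf_id != links2$gene_id, ]
  me <- stats::setNames(rep(1, 5), letters[1:5])
  g2 <- buildGraph(links2, me)
  pr2 <- pageRankScores(g2)
  nodes <- graphNodes(g2)$id
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- graphEdges(g2)
  for (i in seq_len(nrow(e))) W[e$gene[i], e$tf[i]] <- W[e$gene[i], e$tf[i]] + e$weight[i]
  orc <- pagerank_power(W)
  expect_equal(unname(pr2[nodes]), unname(orc[nodes]), tolerance = 1e-10)
  expect_equal(sum(pr2), 1, tolerance = 1e-9)
})

test_that("betweenness uses inverse-weight distances on the directed graph", {
  links <- data.frame(tf_id = c("a", "m", "a"), gene_id = c("m", "z", "q"),
                      beta = c(1, 1, 1))
  bw <- betweennessScores(buildGraph(links, c(a = 1, m = 1)))
  expect_gt(bw["m"], bw["z"])  # m lies on the a -> z path
  expect_error(pageRankScores(new("GRNGraph",
                                  edges = data.frame(tf = character(),
                                                     gene = character(),
                                                     beta = numeric(),
                                                     weight = numeric(),
                                                     sign = numeric()),
                                  nodes = data.frame(id = character(),
                                                     role = character()))),
               "empty")
})

test_that("identity perturbation yields exactly zero displacement", {
  sim <- mini_sim()
  pcs <- mini_pseudo()
  cfg <- enetConfig(l2_weight = 0.5, n_boot = 20, seed = 3)
  expr_n <- normalizeCells(sim$expr)
  fits <- lapply(paste0("gene00", 1:3), function(g)
    fitGeneTfs(g, expr_n, paste0("TF0", 1:8), config = cfg)$fit)
  feats <- c(paste0("gene00", 1:3), paste0("TF0", 1:8))
  set.seed(1)
  L <- matrix(rnorm(length(feats) * 2), length(feats), 2,
              dimnames = list(feats, c("d1", "d2")))
  res <- simulatePerturbation(list(TF01 = list(rule = "scale", factor = 1)),
                              expr_n, fits, L)
  expect_true(all(res$displacement == 0))
  expect_error(simulatePerturbation(list(NOPE = list(rule = "scale",
                                                     factor = 1)),
                                    expr_n, fits, L), "unknown TF")
})

test_that("knocking down an all-positive TF never raises its targets", {
  fit <- new("FitResult", gene_id = "gY", predictor_ids = c("TFp", "TFq"),
             beta = c(1.2, 0.4), intercept = 0.1, se = c(0.1, 0.1),
             pvalue = c(0.01, 0.01), lambda1 = 0.1, lambda2 = 0.5,
             lambda2_abs = 0.05, penalty_weights = c(1, 1), r2 = 0.9,
             n_obs = 20L, n_nonzero = 2L)
  set.seed(8)
  m <- cbind(TFp = runif(10, 0, 3), TFq = runif(10, 0, 3),
             gY = runif(10, 0, 3))
  rownames(m) <- paste0("c", 1:10)
  expr <- OmicsMatrix(m, "rna")
  L <- matrix(c(1, 0, 0), 3, 1, dimnames = list(c("gY", "TFp", "TFq"), "d"))
  res <- simulatePerturbation(list(TFp = list(rule = "knockdown_to_zero")),
                              expr, list(fit), L)
  expect_true(all(res$displacement <= 1e-12))
})

test_that("upregulating the stateB-driving TFs moves stateA cells toward stateB", {
  sim <- mini_sim()
  cfg <- enetConfig(l2_weight = 0.5, n_boot = 25, seed = 13)
  expr_n <- normalizeCells(sim$expr)
  genes <- geneIds(sim$genes)
  truth <- sim$truth$true_tf_links
  fits <- lapply(genes, function(g) {
    cand <- truth$tf_id[truth$gene_id == g]
    fitGeneTfs(g, expr_n, cand, config = cfg)$fit
  })
  fits <- Filter(Negate(is.null), fits)
  # loadings: project expression onto the planted state-shift axis
  se <- sim$truth$state_effects[genes]
  L <- matrix(se / sqrt(sum(se^2)), length(genes), 1,
              dimnames = list(genes, "state_axis"))
  # the TF pushing hardest toward state B by planted axis score
  deg <- sim$deg
  me <- Matrix::colMeans(omicsValues(expr_n))
  links <- fitTable(fits)
  names(links)[names(links) == "element"] <- "tf_id"
  names(links)[names(links) == "gene"] <- "gene_id"
  links$beta <- links$coefficient
  ax <- tfAxisScore(links, deg, me)
  tfB <- ax$tf_id[which.min(ax$score)]
  res <- simulatePerturbation(
    stats::setNames(list(list(rule = "set_to_quantile", q = 0.95)), tfB),
    expr_n, fits, L)
  states <- sim$truth$cell_states[rownames(res$original)]
  cA <- mean(res$original[states == "stateA", 1])
  cB <- mean(res$original[states == "stateB", 1])
  cA_new <- mean(res$perturbed[states == "stateA", 1])
  expect_lt(abs(cA_new - cB), abs(cA - cB))
})
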