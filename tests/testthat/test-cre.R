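test_that("candidate windows anchor at the TSS and include boundary overlaps", {
  g <- GeneAnnotation("g", "chr1", "+", 1000000, 1020000)  # tss = 1e6
  pk <- PeakSet("chr1", c(499900, 1500100, 600000), c(500100, 1500200, 600500))
  cand <- candidatePeaks(g, pk, window = 500000)
  expect_true("chr1:499900-500100" %in% cand)   # overlaps window start
  expect_false("chr1:1500100-1500200" %in% cand)
  # ordered by position
  expect_identical(cand, c("chr1:499900-500100", "chr1:600000-600500"))

  # minus-strand gene: tss = body_end - 1
  gm <- GeneAnnotation("m", "chr1", "-", 5000, 9000)  # tss = 8999
  pkm <- PeakSet("chr1", c(508000, 510000), c(508500, 510500))
  expect_identical(candidatePeaks(gm, pkm, window = 500000),
                   "chr1:508000-508500")
  # wrong chromosome -> empty
  expect_length(candidatePeaks(g, PeakSet("chrX", 1, 10)), 0L)
})

test_that("window extent is strand-independent", {
  gp <- GeneAnnotation("p", "chr1", "+", 1000000, 1001000)
  gm <- GeneAnnotation("m", "chr1", "-", 999001, 1000001)  # same tss 1e6
  pk <- PeakSet("chr1", seq(600000, 1400000, 100000),
                seq(600000, 1400000, 100000) + 400)
  expect_identical(candidatePeaks(gp, pk), candidatePeaks(gm, pk))
})

test_that("stage-1 fitting recovers planted CREs with correct signs", {
  sim <- mini_sim()
  pcs <- mini_pseudo()
  cfg <- enetConfig(l2_weight = 0.25, n_boot = 60, seed = 42)
  truth <- sim$truth$true_cre_links
  res <- lapply(c("gene001", "gene002"), function(g)
    fitGeneCres(g, pcs$expr, pcs$acc, sim$peaks, sim$genes, config = cfg))
  links <- do.call(rbind, lapply(res, `[[`, "links"))
  ev <- evaluateRecovery(links,
                         truth[truth$gene_id %in% c("gene001", "gene002"), ])
  expect_gte(ev$recall, 0.8)
  expect_equal(ev$sign_accuracy, 1)
  # links carry signed distances within the window and a class label
  expect_true(all(abs(links$distance_to_tss) <= 500000))
  expect_true(all(links$annotation %in%
                    c("promoter", "gene_body", "intergenic")))
  # r2 recorded
  expect_gt(res[[1]]$fit@r2, 0.5)
})

test_that("constant expression and empty windows are flagged, not fatal", {
  pcs <- mini_pseudo()
  sim <- mini_sim()
  v <- as.matrix(omicsValues(pcs$expr))
  v[, "gene003"] <- 1
  expr2 <- OmicsMatrix(v, "rna")
  expect_warning(
    res <- fitGeneCres("gene003", expr2, pcs$acc, sim$peaks, sim$genes,
                       config = enetConfig(n_boot = 10, seed = 1)),
    "constant")
  expect_equal(nrow(res$links), 0L)

  far <- GeneAnnotation("gene003", "chr9", "+", 100, 2000)
  names(far) <- "gene003"
  expect_warning(
    res2 <- fitGeneCres("gene003", pcs$expr, pcs$acc, sim$peaks, far,
                        config = enetConfig(n_boot = 10, seed = 1)),
    "no candidate peaks")
  expect_true(is.na(res2$fit@r2))
})

test_that("CRE classification follows sign(beta) x direction", {
  links <- data.frame(gene_id = c("gA", "gA", "gB"),
                      peak_id = c("p1", "p2", "p3"),
                      beta = c(0.3, -0.3, 0.5))
  deg <- degTable(c("gA", "gB"), c(1, -1))
  cl <- classifyCres(links, deg)
  expect_identical(cl$label, c("stateA-promoting", "stateB-promoting",
                               "stateB-promoting"))
  expect_error(classifyCres(data.frame(gene_id = "gZ", peak_id = "p",
                                       beta = 1), deg), "absent")
  expect_error(classifyCres(data.frame(gene_id = "gA", peak_id = "p",
                                       beta = 0), deg), "zero-coefficient")
})

test_that("peak scores aggregate beta x mean accessibility with tertiles", {
  acc <- OmicsMatrix(matrix(rep(c(2, 1, 1), each = 4), 4, 3,
                            dimnames = list(paste0("c", 1:4),
                                            c("p1", "p2", "p3"))), "atac")
  links <- data.frame(gene_id = c("g1", "g1", "g2"),
                      peak_id = c("p1", "p2", "p2"),
                      beta = c(0.5, 0.5, -0.2))
  sc <- scoreCres(links, acc)
  expect_equal(sc$score[sc$peak_id == "p1"], 1.0)   # 0.5 * 2
  expect_equal(sc$score[sc$peak_id == "p2"], 0.3)   # (0.5 - 0.2) * 1
  expect_equal(sc$abs_score[sc$peak_id == "p2"], 0.3)
  expect_error(scoreCres(links, acc, cells = character()), "empty")

  # 9 peaks -> three tertiles of three, ordered by decreasing |score|
  acc9 <- OmicsMatrix(matrix(1, 2, 9, dimnames = list(c("c1", "c2"),
                                                      paste0("q", 1:9))),
                      "atac")
  l9 <- data.frame(gene_id = "g", peak_id = paste0("q", 1:9),
                   beta = c(9:1) / 10)
  s9 <- scoreCres(l9, acc9)
  expect_equal(as.vector(table(s9$tertile)), c(3L, 3L, 3L))
  expect_true(all(diff(s9$abs_score) <= 0))
})

test_that("promoter links carry larger absolute scores when planted larger", {
  sim <- mini_sim()
  pcs <- mini_pseudo()
  cfg <- enetConfig(l2_weight = 0.25, n_boot = 40, seed = 11)
  links <- do.call(rbind, lapply(paste0("gene00", 4:7), function(g)
    fitGeneCres(g, pcs$expr, pcs$acc, sim$peaks, sim$genes,
                config = cfg)$links))
  sc <- scoreCres(links, pcs$acc)
  ann <- links$annotation[match(sc$peak_id, links$peak_id)]
  expect_gt(mean(sc$abs_score[ann == "promoter"]),
            mean(sc$abs_score[ann == "intergenic"]))
})
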