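#' @include cre.R motif.R tf.R scoring.R compare.R pseudocell.R
NULL

#' Run the full two-stage GRN inference pipeline
#'
#' Orchestrates micropooling, stage-1 CRE models, motif-based TF nomination,
#' stage-2 TF models, axis scoring, graph centralities and the
#' CRE-network-vs-promoter AIC comparison, writing one TSV per stage plus a
#' manifest. Per-gene RNG streams derive from \code{seed} and the gene id,
#' so results do not depend on gene order. Rerunning with the same inputs
#' and seed reproduces identical outputs.
#'
#' @param data list with \code{expr}, \code{acc}
#'   (\linkS4class{OmicsMatrix}s over the same cells), \code{peaks},
#'   \code{genes} (GRanges), \code{deg} (\code{\link{degTable}}),
#'   \code{hits} (\linkS4class{PeakMotifHits}), \code{motifs}
#'   (\linkS4class{MotifSet}), and \code{embedding} and/or \code{graph} for
#'   micropooling; \code{\link{simulateMultiome}} returns this shape, or
#'   assemble it from the readers in this package
#' @param out_dir output directory (created); \code{NULL} skips writing
#' @param genes_to_model gene ids to model (default: the DEG table's genes)
#' @param stage1,stage2 \code{\link{enetConfig}}s for the CRE and TF stages
#' @param pseudocell_target cells per pseudocell for stage 1
#' @param pseudocell_mode \code{"single"} (one shared partition at
#'   \code{pseudocell_target}, keeping X and y rows aligned exactly) or
#'   \code{"dual"} (coarser ATAC pooling at \code{atac_target}, row-aligned
#'   to the RNA pseudocells by plurality membership)
#' @param atac_target cells per ATAC pseudocell in dual mode
#' @param normalize library-size normalize the expression matrix used for
#'   stage 2 (see Details in the methods vignette)
#' @param window CRE candidate window half-width (bp)
#' @param promoter_upstream,promoter_downstream promoter extent for TF
#'   nomination (bp from TSS)
#' @param tf_mode \code{"presence"} (motif present in a CRE/promoter peak)
#'   or \code{"enrichment"} (GC-matched Fisher enrichment filter)
#' @param expressed_min_frac expression prevalence filter for candidate TFs
#' @param seed global seed (stage configs' seeds are derived from it)
#' @return list: pseudocells, cre_fits, cre_links, candidates (per gene),
#'   tf_fits, tf_links, axis_scores, graph, pagerank, betweenness,
#'   comparison, skipped (genes with reasons)
#' @export
runPipeline <- function(data, out_dir = NULL, genes_to_model = NULL,
                        stage1 = enetConfig(l2_weight = 0.25, n_boot = 100),
                        stage2 = enetConfig(l2_weight = 0.5, n_boot = 50),
                        pseudocell_target = 10,
                        pseudocell_mode = c("single", "dual"),
                        atac_target = 100, window = 500000,
                        promoter_upstream = 2000, promoter_downstream = 0,
                        tf_mode = c("presence", "enrichment"),
                        expressed_min_frac = 0.01, normalize = TRUE,
                        seed = 1L) {
  tf_mode <- match.arg(tf_mode)
  pseudocell_mode <- match.arg(pseudocell_mode)
  stage1$seed <- deriveSeed(seed, "stage1")
  stage2$seed <- deriveSeed(seed, "stage2")
  genes_to_model <- genes_to_model %||% data$deg$gene_id
  genes_to_model <- intersect(genes_to_model,
                              intersect(geneIds(data$genes),
                                        featureIds(data$expr)))
  if (length(genes_to_model) == 0L) stop("no genes to model")

  ## --- depth normalization: stage 2 only. At single-cell resolution the
  ##     per-cell size factor is a confounder shared by the response and
  ##     every TF predictor, so it must come out of the expression matrix
  ##     used for TF fitting. Stage 1 consumes raw ("non-binarized")
  ##     values on both sides: pseudocell averaging suppresses the size
  ##     factor there, and a depth estimate would re-inject correlated
  ##     noise into the response. ---
  expr_sc <- if (normalize) normalizeCells(data$expr) else data$expr

  ## --- micropooling ---
  pc <- buildPseudocells(graph = data$graph, embedding = data$embedding,
                         target_size = pseudocell_target,
                         seed = deriveSeed(seed, "pseudocell"))
  expr_pc <- aggregateCells(data$expr, pc)
  if (pseudocell_mode == "single") {
    acc_pc <- aggregateCells(data$acc, pc)
  } else {
    # coarser ATAC pooling, row-aligned to the RNA pseudocells by plurality
    pc_atac <- buildPseudocells(graph = data$graph,
                                embedding = data$embedding,
                                target_size = atac_target,
                                seed = deriveSeed(seed, "pseudocell"))
    m <- mapPseudocells(pc, pc_atac)
    coarse <- aggregateCells(data$acc, pc_atac)
    acc_pc <- OmicsMatrix(omicsValues(coarse)[m[cellIds(expr_pc)], ,
                                              drop = FALSE],
                          modality = "atac", cell_ids = cellIds(expr_pc),
                          units = "normalized")
  }

  ## --- stage 1: CRE models ---
  cre_fits <- list(); cre_links <- list()
  for (g in genes_to_model) {
    res <- fitGeneCres(g, expr_pc, acc_pc, data$peaks, data$genes,
                       config = stage1, window = window)
    cre_fits[[g]] <- res$fit
    cre_links[[g]] <- res$links
  }
  links1 <- do.call(rbind, cre_links)
  rownames(links1) <- NULL

  ## --- TF nomination ---
  tf_universe <- unique(unname(data$motifs@tfNames))
  expressed <- expressedTfs(expr_sc, tf_universe, expressed_min_frac)
  gc_frac <- data$gc %||% NULL
  candidates <- list(); skipped <- list()
  for (g in genes_to_model) {
    gene <- data$genes[match(g, geneIds(data$genes))]
    prom <- promoterPeaks(gene, data$peaks, promoter_upstream,
                          promoter_downstream)
    if (tf_mode == "presence") {
      candidates[[g]] <- candidateTfs(g, links1, data$hits, prom, expressed,
                                      data$motifs)
    } else {
      cre_pk <- unique(c(links1$peak_id[links1$gene_id == g], prom))
      candidates[[g]] <- if (length(cre_pk) == 0L) character() else {
        if (is.null(gc_frac))
          stop("tf_mode = 'enrichment' requires data$gc (GC per peak)")
        intersect(enrichedTfs(g, cre_pk, peakIds(data$peaks), data$hits,
                              gc_frac, data$motifs,
                              seed = deriveSeed(seed, g, 4L)),
                  expressed)
      }
    }
  }

  ## --- stage 2: TF models on single cells ---
  tf_fits <- list(); tf_links <- list()
  for (g in genes_to_model) {
    res <- fitGeneTfs(g, expr_sc, candidates[[g]], config = stage2)
    if (is.null(res$fit)) {
      skipped[[g]] <- res$reason
      next
    }
    tf_fits[[g]] <- res$fit
    tf_links[[g]] <- res$links
  }
  links2 <- do.call(rbind, tf_links)
  rownames(links2) <- NULL
  if (is.null(links2)) links2 <- .empty_tf_links()

  ## --- scoring and centralities ---
  mean_expr <- Matrix::colMeans(omicsValues(expr_sc))
  axis <- if (nrow(links2) > 0 && nrow(data$deg) > 0) {
    tfAxisScore(links2, data$deg, mean_expr)
  } else data.frame(tf_id = character(), score = numeric())
  graph <- if (nrow(links2) > 0) buildGraph(links2, mean_expr) else NULL
  pr <- if (!is.null(graph)) pageRankScores(graph) else numeric()
  bw <- if (!is.null(graph)) betweennessScores(graph) else numeric()

  ## --- CRE-network vs promoter-only comparison ---
  comparison <- list()
  for (g in genes_to_model) {
    gene <- data$genes[match(g, geneIds(data$genes))]
    prom <- intersect(
      peakIds(data$peaks)[overlapsAny(
        data$peaks, promoterInterval(gene, promoter_upstream,
                                     pmax(promoter_downstream,
                                          promoter_upstream)),
        ignore.strand = TRUE)],
      featureIds(acc_pc))
    full_fit <- cre_fits[[g]]
    if (is.null(full_fit) || length(full_fit@predictor_ids) == 0L) next
    if (length(prom) == 0L) next
    y <- as.numeric(omicsValues(expr_pc)[, g])
    Xp <- as.matrix(omicsValues(acc_pc)[, prom, drop = FALSE])
    cfgp <- stage1
    cfgp$seed <- deriveSeed(stage1$seed, g, 5L)
    prom_fit <- fitAdaptiveEnet(Xp, y, cfgp, gene_id = g)
    Xf <- as.matrix(omicsValues(acc_pc)[, full_fit@predictor_ids,
                                        drop = FALSE])
    comparison[[g]] <- compareModels(full_fit, prom_fit, Xf, Xp, y)
  }
  comparison <- do.call(rbind, comparison)

  out <- list(pseudocells = pc, cre_fits = cre_fits, cre_links = links1,
              candidates = candidates, tf_fits = tf_fits, tf_links = links2,
              axis_scores = axis, graph = graph, pagerank = pr,
              betweenness = bw, comparison = comparison, skipped = skipped)

  if (!is.null(out_dir)) .write_pipeline(out, out_dir, seed)
  out
}

.write_pipeline <- function(out, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  writeLines(paste(names(assignment(out$pseudocells)),
                   assignment(out$pseudocells), sep = "\t"),
             p("pseudocells.tsv"))
  writeFitResults(out$cre_links, p("cres.tsv"))
  writeFitResults(out$tf_links, p("tfs.tsv"))
  .write_tsv(out$axis_scores, p("axis_scores.tsv"))
  if (!is.null(out$graph)) {
    writeEdgeTable(out$graph, p("edges.tsv"))
    .write_tsv(data.frame(id = names(out$pagerank),
                          pagerank = as.numeric(out$pagerank)),
               p("pagerank.tsv"))
    .write_tsv(data.frame(id = names(out$betweenness),
                          betweenness = as.numeric(out$betweenness)),
               p("betweenness.tsv"))
  }
  if (!is.null(out$comparison)) .write_tsv(out$comparison, p("compare.tsv"))
  files <- list.files(out_dir, pattern = "\\.tsv$")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(key = c("seed", "package_version", files),
                         value = c(seed, as.character(utils::packageVersion("adenet")),
                                   unname(sums)))
  write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out_dir)
}
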