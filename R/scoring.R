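#' @include AllClasses.R tf.R
#' @importFrom igraph graph_from_data_frame page_rank betweenness V
NULL

#' Rank TFs along a two-state axis
#'
#' \code{score(TF) = mean_expr(TF) x sum_g s_g beta_TF,g} where \code{s_g}
#' is +1 for stateA-up genes and -1 for stateB-up genes. Positive scores
#' mark stateA-promoting TFs, negative scores stateB-promoting TFs.
#'
#' @param links stage-2 TF link data.frame (tf_id, gene_id, beta)
#' @param deg \code{\link{degTable}} covering every linked gene
#' @param mean_expr named mean TF expression in the relevant cell population
#' @return data.frame (tf_id, score) sorted by decreasing score
#' @export
tfAxisScore <- function(links, deg, mean_expr) {
  idx <- match(links$gene_id, deg$gene_id)
  if (anyNA(idx)) stop("gene(s) absent from DEG table: ",
                       paste(unique(links$gene_id[is.na(idx)]), collapse = ", "))
  miss <- setdiff(unique(links$tf_id), names(mean_expr))
  if (length(miss)) stop("missing mean expression for TF(s): ",
                         paste(miss, collapse = ", "))
  s <- deg$direction[idx]
  raw <- tapply(links$beta * s, links$tf_id, sum)
  score <- as.numeric(raw) * mean_expr[names(raw)]
  out <- data.frame(tf_id = names(raw), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$tf_id), ]
  rownames(out) <- NULL
  out
}

#' TF-by-cell-type regulatory scores
#'
#' \code{score(TF, c) = mean_expr_c(TF) x sum over marker genes of c of
#' beta_TF,g}. Marker sets may overlap.
#'
#' @param links stage-2 TF link data.frame
#' @param markers named list of marker gene sets, one per cell type
#' @param mean_expr TF x cell-type matrix of mean expression (dimnames
#'   required; columns must cover \code{names(markers)})
#' @return TF x cell-type numeric matrix
#' @export
tfCelltypeScores <- function(links, markers, mean_expr) {
  if (!all(names(markers) %in% colnames(mean_expr)))
    stop("unknown cell type(s): ",
         paste(setdiff(names(markers), colnames(mean_expr)), collapse = ", "))
  tfs <- sort(unique(links$tf_id))
  out <- matrix(0, length(tfs), length(markers),
                dimnames = list(tfs, names(markers)))
  for (ct in names(markers)) {
    sub <- links[links$gene_id %in% markers[[ct]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    raw <- tapply(sub$beta, sub$tf_id, sum)
    out[names(raw), ct] <- as.numeric(raw) * mean_expr[names(raw), ct]
  }
  out
}

#' Top-k ids by score
#'
#' @param scores named numeric vector or (tf_id, score) data.frame
#' @param k how many
#' @param by \code{"value"} (most positive), \code{"abs"}, or \code{"neg"}
#'   (most negative)
#' @return character vector of ids
#' @export
topTfs <- function(scores, k = 25L, by = c("value", "abs", "neg")) {
  by <- match.arg(by)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$tf_id)
  key <- switch(by, value = -scores, abs = -abs(scores), neg = scores)
  names(scores)[order(key, names(scores))][seq_len(min(k, length(scores)))]
}

#' Assemble the TF-to-gene regulatory graph
#'
#' Directed edges tf -> gene with weight \code{|beta| x mean TF expression}
#' and the sign of beta. TFs regulating other TFs appear with role
#' \code{"both"}.
#'
#' @param links stage-2 TF link data.frame
#' @param mean_expr named mean TF expression
#' @return a \linkS4class{GRNGraph}
#' @export
buildGraph <- function(links, mean_expr) {
  if (nrow(links) == 0L) stop("no edges to build a graph from")
  miss <- setdiff(unique(links$tf_id), names(mean_expr))
  if (length(miss)) stop("missing mean expression for TF(s): ",
                         paste(miss, collapse = ", "))
  edges <- data.frame(tf = links$tf_id, gene = links$gene_id,
                      beta = links$beta,
                      weight = abs(links$beta) * mean_expr[links$tf_id],
                      sign = sign(links$beta), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  ids <- unique(c(edges$tf, edges$gene))
  role <- ifelse(ids %in% edges$tf & ids %in% edges$gene, "both",
                 ifelse(ids %in% edges$tf, "tf", "gene"))
  new("GRNGraph", edges = edges,
      nodes = data.frame(id = ids, role = role, stringsAsFactors = FALSE))
}

.as_igraph <- function(graph, reverse = FALSE, drop_zero = FALSE) {
  e <- graphEdges(graph)
  if (drop_zero) e <- e[e$weight > 0, , drop = FALSE]
  d <- if (reverse) data.frame(from = e$gene, to = e$tf, weight = e$weight)
       else data.frame(from = e$tf, to = e$gene, weight = e$weight)
  graph_from_data_frame(d, directed = TRUE,
                        vertices = graphNodes(graph)$id)
}

#' PageRank centrality of the regulatory graph
#'
#' By default computed on the edge-reversed weighted graph, so regulators
#' accrue rank from the genes they target (a TF driving many
#' highly-regulated genes is central); \code{direction = "forward"} keeps
#' the regulatory orientation. Scores sum to 1.
#'
#' @param graph a \linkS4class{GRNGraph} with at least one edge
#' @param damping damping factor (default 0.85)
#' @param direction \code{"reversed"} (default) or \code{"forward"}
#' @return named numeric vector of PageRank scores, decreasing
#' @export
pageRankScores <- function(graph, damping = 0.85,
                           direction = c("reversed", "forward")) {
  direction <- match.arg(direction)
  if (nrow(graphEdges(graph)) == 0L) stop("empty graph")
  g <- .as_igraph(graph, reverse = direction == "reversed")
  pr <- page_rank(g, damping = damping,
                  weights = igraph::E(g)$weight)$vector
  sort(pr, decreasing = TRUE)
}

#' Betweenness centrality of the regulatory graph
#'
#' Computed on the original directed graph; edge weight (strength) is
#' converted to a distance \code{1/weight}. Zero-weight edges are dropped
#' (infinite distance).
#'
#' @param graph a \linkS4class{GRNGraph} with at least one edge
#' @return named numeric vector of betweenness scores, decreasing
#' @export
betweennessScores <- function(graph) {
  if (nrow(graphEdges(graph)) == 0L) stop("empty graph")
  g <- .as_igraph(graph, drop_zero = TRUE)
  bw <- betweenness(g, directed = TRUE, weights = 1 / igraph::E(g)$weight)
  sort(bw, decreasing = TRUE)
}

#' In-silico TF perturbation
#'
#' Applies perturbation rules to the TF columns of the expression matrix,
#' recomputes every modeled gene's predicted expression \code{yhat =
#' X_perturb beta}, substitutes predictions into each cell's profile
#' (unmodeled genes keep their observed values; perturbed TF columns take
#' their perturbed values), and projects baseline and perturbed profiles
#' through caller-supplied linear embedding loadings. The baseline profile
#' substitutes the unperturbed predictions \code{yhat(X)} for the same
#' genes, so an identity perturbation yields exactly zero displacement.
#' One propagation step; no iterative cascade.
#'
#' @param spec named list: TF id -> rule, each rule a list with
#'   \code{rule = "knockdown_to_zero"}, \code{rule = "scale", factor = f}
#'   (f >= 0), or \code{rule = "set_to_quantile", q = q} (q in [0, 1],
#'   quantile of the TF's expression across cells)
#' @param expr cells x features \linkS4class{OmicsMatrix} holding genes and
#'   TFs
#' @param fits list of stage-2 \linkS4class{FitResult}s (one per modeled
#'   gene)
#' @param loadings features x dims projection matrix (rownames = features)
#' @param center,scale optional named centering/scaling applied to profiles
#'   before projection (defaults 0 / 1)
#' @return list with \code{original} and \code{perturbed} cell x dim
#'   coordinate matrices and \code{displacement} (perturbed - original)
#' @export
simulatePerturbation <- function(spec, expr, fits, loadings,
                                 center = NULL, scale = NULL) {
  v <- as.matrix(omicsValues(expr))
  unknown <- setdiff(names(spec), colnames(v))
  if (length(unknown)) stop("perturbation rule references unknown TF(s): ",
                            paste(unknown, collapse = ", "))
  fits <- Filter(function(f) !is.null(f) && length(f@predictor_ids) > 0, fits)
  modeled_tfs <- unique(unlist(lapply(fits, function(f) f@predictor_ids)))
  off_model <- setdiff(names(spec), modeled_tfs)
  if (length(off_model) && length(names(spec)))
    warning("perturbed TF(s) appear in no fitted model: ",
            paste(off_model, collapse = ", "))

  vp <- v
  for (tf in names(spec)) {
    r <- spec[[tf]]
    vp[, tf] <- switch(r$rule,
      knockdown_to_zero = 0,
      scale = {
        if (is.null(r$factor) || r$factor < 0) stop("scale factor must be >= 0")
        v[, tf] * r$factor
      },
      set_to_quantile = {
        if (is.null(r$q) || r$q < 0 || r$q > 1) stop("q must be in [0, 1]")
        as.numeric(quantile(v[, tf], r$q))
      },
      stop("unknown perturbation rule: ", r$rule))
  }

  base <- v
  pert <- vp
  for (f in fits) {
    base[, f@gene_id] <- predictExpression(f, v)
    pert[, f@gene_id] <- predictExpression(f, vp)
  }

  feats <- rownames(loadings)
  miss <- setdiff(feats, colnames(v))
  if (length(miss)) stop("loadings cover feature(s) absent from expr: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ctr <- if (is.null(center)) rep(0, length(feats)) else center[feats]
  scl <- if (is.null(scale)) rep(1, length(feats)) else scale[feats]
  proj <- function(m) {
    z <- sweep(sweep(m[, feats, drop = FALSE], 2, ctr, "-"), 2, scl, "/")
    z %*% loadings
  }
  c0 <- proj(base)
  c1 <- proj(pert)
  list(original = c0, perturbed = c1, displacement = c1 - c0)
}
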