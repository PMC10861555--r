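#' @include AllClasses.R utils.R
#' @importFrom stats kmeans dist quantile
#' @importFrom igraph graph_from_adjacency_matrix cluster_louvain membership
NULL

# kNN adjacency (symmetrized, unit weights) from embedding coordinates.
.knn_graph <- function(emb, k = 20L) {
  n <- nrow(emb)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(emb))
  adj <- matrix(0, n, n, dimnames = list(rownames(emb), rownames(emb)))
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    adj[i, nb] <- 1
  }
  pmax(adj, t(adj))
}

# Split the rows of `coords` into k groups by k-means; falls back to
# contiguous chunks along the first coordinate when k-means is infeasible
# (fewer unique points than centers).
.split_kmeans <- function(coords, k, seed) {
  n <- nrow(coords)
  if (k <= 1L) return(rep(1L, n))
  uniq <- nrow(unique(coords))
  if (uniq < k) {
    ord <- order(coords[, 1], coords[, ncol(coords)])
    grp <- integer(n)
    grp[ord] <- ceiling(seq_len(n) / ceiling(n / k))
    return(grp)
  }
  km <- withr::with_seed(seed, kmeans(coords, centers = k, nstart = 5L,
                                      iter.max = 50L))
  km$cluster
}

#' Partition cells into pseudocells
#'
#' Micropooling: cells are first grouped into communities by Louvain
#' modularity clustering of a joint neighbor graph, then each community is
#' split by k-means on the embedding coordinates of its members into
#' \code{ceiling(size / target_size)} pseudocells, so no pseudocell mixes
#' communities. Supply a weighted cell-by-cell adjacency \code{graph}, an
#' \code{embedding} (cells x dims, a k-nearest-neighbor graph with
#' \code{knn_k} neighbors is built from it), or both.
#'
#' @param graph symmetric weighted adjacency matrix with cell dimnames, or
#'   \code{NULL}
#' @param embedding cells x dims coordinate matrix with rownames, or
#'   \code{NULL}
#' @param target_size targeted maximum cells per pseudocell (>= 1)
#' @param seed RNG seed (Louvain and k-means are seed-deterministic)
#' @param knn_k neighbors used when building a graph from the embedding
#' @return a \linkS4class{PseudocellAssignment}
#' @export
buildPseudocells <- function(graph = NULL, embedding = NULL, target_size = 10L,
                             seed = 1L, knn_k = 20L) {
  if (is.null(graph) && is.null(embedding))
    stop("supply a graph, an embedding, or both")
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size < 1L) stop("target_size must be >= 1")
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (is.null(rownames(embedding))) stop("embedding must have cell rownames")
  }
  if (is.null(graph)) graph <- .knn_graph(embedding, knn_k)
  graph <- as.matrix(graph)
  if (nrow(graph) == 0L) stop("empty input")
  cells <- rownames(graph)
  if (is.null(cells)) stop("graph must have cell dimnames")
  if (!is.null(embedding) && !all(cells %in% rownames(embedding)))
    stop("embedding must cover all graph cells")

  if (target_size == 1L) {
    pc <- paste0("pc_", cells)
    return(new("PseudocellAssignment",
               assignment = stats::setNames(pc, cells),
               sizes = stats::setNames(rep(1L, length(cells)), pc),
               community = stats::setNames(rep("c1", length(cells)), pc),
               target_size = 1L, seed = as.integer(seed)))
  }

  g <- graph_from_adjacency_matrix(graph, mode = "undirected",
                                   weighted = TRUE, diag = FALSE)
  comm <- withr::with_seed(as.integer(seed),
                           membership(cluster_louvain(g)))
  comm <- stats::setNames(as.integer(comm), cells)

  assign <- character(0)
  for (cm in sort(unique(comm))) {
    members <- cells[comm == cm]
    k <- ceiling(length(members) / target_size)
    coords <- if (!is.null(embedding)) {
      embedding[members, , drop = FALSE]
    } else {
      # spectral coordinates of the community subgraph when no embedding given
      sub <- graph[members, members, drop = FALSE]
      nev <- min(10L, length(members))
      ev <- eigen(sub, symmetric = TRUE)
      ev$vectors[, seq_len(nev), drop = FALSE]
    }
    grp <- .split_kmeans(as.matrix(coords), k, deriveSeed(seed, cm))
    assign[members] <- sprintf("pc_c%d_k%d", cm, grp)
  }
  sizes <- table(assign)
  pc_comm <- vapply(names(sizes), function(p) {
    sprintf("c%d", comm[[names(assign)[match(p, assign)]]])
  }, "")
  new("PseudocellAssignment",
      assignment = assign[cells],
      sizes = stats::setNames(as.integer(sizes), names(sizes)),
      community = pc_comm, target_size = target_size,
      seed = as.integer(seed))
}

#' Average cell profiles within pseudocells
#'
#' Each output row is the arithmetic mean of the member cells' rows, so the
#' size-weighted mean of pseudocell profiles reproduces the global cell mean
#' exactly (conservation), and \code{target_size = 1} is the identity on
#' values.
#'
#' @param x an \linkS4class{OmicsMatrix}
#' @param assign a \linkS4class{PseudocellAssignment} covering all cells of
#'   \code{x}
#' @return an \linkS4class{OmicsMatrix} whose cell ids are pseudocell ids
#'   (sorted)
#' @export
aggregateCells <- function(x, assign) {
  v <- omicsValues(x)
  a <- assignment(assign)
  missing <- setdiff(rownames(v), names(a))
  if (length(missing))
    stop("unassigned cells present: ", paste(utils::head(missing, 5), collapse = ", "))
  a <- a[rownames(v)]
  pcs <- sort(unique(a))
  ind <- sparseMatrix(i = match(a, pcs), j = seq_along(a), x = 1,
                      dims = c(length(pcs), length(a)),
                      dimnames = list(pcs, names(a)))
  ind <- ind / Matrix::rowSums(ind)
  agg <- ind %*% v
  OmicsMatrix(as(agg, "CsparseMatrix"), modality = modality(x),
              units = "normalized")
}

#' Align a fine pseudocell partition to a coarser one
#'
#' For dual-target micropooling (e.g. RNA pseudocells of ~10 cells, ATAC
#' pseudocells of ~100), maps each fine pseudocell to the coarse pseudocell
#' containing the plurality of its member cells (ties broken by pseudocell
#' id order), so the two aggregated matrices can be row-aligned.
#'
#' @param fine,coarse \linkS4class{PseudocellAssignment}s over the same
#'   cells
#' @return named character: fine pseudocell id -> coarse pseudocell id
#' @export
mapPseudocells <- function(fine, coarse) {
  af <- assignment(fine); ac <- assignment(coarse)
  if (!setequal(names(af), names(ac)))
    stop("assignments must cover the same cells")
  ac <- ac[names(af)]
  vapply(split(ac, af), function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }, "")
}
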