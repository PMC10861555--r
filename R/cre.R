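#' @include AllClasses.R ranges.R enet.R
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Candidate peaks within a window around a gene's TSS
#'
#' All peaks whose interval overlaps \code{[tss - window, tss + window)}
#' (0-based) in any position, ordered by genomic position. The window is
#' symmetric about the TSS; strand affects only where the TSS sits.
#'
#' @param gene single-row gene \code{GRanges} (see
#'   \code{\link{GeneAnnotation}})
#' @param peaks peak \code{GRanges}
#' @param window half-width in bp (default 500 kb)
#' @return character vector of peak ids (possibly empty)
#' @export
candidatePeaks <- function(gene, peaks, window = 500000) {
  stopifnot(length(gene) == 1L)
  tss <- mcols(gene)$tss
  win <- GRanges(seqnames(gene),
                 IRanges(max(1, tss - window + 1), tss + window))
  # a gene on a chromosome absent from the peak set is a legitimate
  # empty-result case, not a warning
  ov <- suppressWarnings(findOverlaps(win, peaks, ignore.strand = TRUE))
  hits <- subjectHits(ov)
  hits <- hits[order(start(peaks)[hits], end(peaks)[hits])]
  peakIds(peaks)[hits]
}

# Signed distance (bp) from the TSS to the peak midpoint, negative upstream
# on the gene's strand; and the CRE class label.
.annotate_peak <- function(peak_gr, gene, promoter_flank = 2000) {
  tss <- mcols(gene)$tss
  mid0 <- (start(peak_gr) - 1 + end(peak_gr)) / 2
  d <- if (as.character(strand(gene)) == "+") mid0 - tss else tss - mid0
  prom <- GRanges(seqnames(gene),
                  IRanges(max(1, tss - promoter_flank + 1),
                          tss + promoter_flank + 1))
  is_prom <- overlapsAny(peak_gr, prom, ignore.strand = TRUE)
  in_body <- overlapsAny(peak_gr, gene, ignore.strand = TRUE)
  ann <- ifelse(is_prom, "promoter", ifelse(in_body, "gene_body", "intergenic"))
  list(distance = d, annotation = ann)
}

#' Fit a gene's CRE model (stage 1)
#'
#' Selects accessible peaks within \code{window} of the gene's TSS and fits
#' the adaptive elastic net of pseudocell expression on pseudocell peak
#' accessibility (untransformed, non-binarized), followed by bootstrap
#' significance filtering. Significant peaks become CRE links carrying the
#' signed TSS distance and a promoter / gene-body / intergenic label
#' (promoter = within \code{promoter_flank} bp of the TSS).
#'
#' @param gene_id gene to model (must be a feature of \code{expr})
#' @param expr pseudocell expression \linkS4class{OmicsMatrix}
#' @param acc pseudocell accessibility \linkS4class{OmicsMatrix}, row-aligned
#'   with \code{expr}
#' @param peaks peak \code{GRanges}
#' @param genes gene \code{GRanges}
#' @param config an \code{\link{enetConfig}} (stage-1 defaults:
#'   \code{l2_weight} 0.25, \code{n_boot} 1000)
#' @param window candidate window half-width, bp
#' @param promoter_flank promoter label half-width around the TSS, bp
#' @return list with \code{fit} (a \linkS4class{FitResult}) and \code{links}
#'   (data.frame: gene_id, peak_id, beta, se, pvalue, distance_to_tss,
#'   annotation)
#' @export
fitGeneCres <- function(gene_id, expr, acc, peaks, genes,
                        config = enetConfig(l2_weight = 0.25, n_boot = 1000),
                        window = 500000, promoter_flank = 2000) {
  if (!identical(cellIds(expr), cellIds(acc)))
    stop("expr and acc must share row (pseudocell) ids in the same order")
  if (!gene_id %in% featureIds(expr)) stop("gene absent from expr: ", gene_id)
  gene <- genes[match(gene_id, geneIds(genes))]
  if (is.na(match(gene_id, geneIds(genes))))
    stop("gene absent from annotation: ", gene_id)

  empty <- list(fit = .empty_fit(gene_id, nrow(omicsValues(expr)),
                                 config$l2_weight, r2 = NA_real_),
                links = .empty_links())
  cand <- candidatePeaks(gene, peaks, window)
  cand <- intersect(cand, featureIds(acc))
  if (length(cand) == 0L) {
    warning(gene_id, ": no candidate peaks in window; gene flagged")
    return(empty)
  }

  y <- as.numeric(omicsValues(expr)[, gene_id])
  X <- as.matrix(omicsValues(acc)[, cand, drop = FALSE])
  cfg <- config
  cfg$seed <- deriveSeed(config$seed, gene_id)
  fit <- fitAdaptiveEnet(X, y, cfg, gene_id = gene_id)
  if (length(fit@predictor_ids)) fit <- bootstrapSignificance(X, y, fit, cfg)

  keep <- fit@beta != 0
  ids <- fit@predictor_ids[keep]
  if (length(ids) == 0L) return(list(fit = fit, links = .empty_links()))
  pk <- peaks[match(ids, peakIds(peaks))]
  ann <- .annotate_peak(pk, gene, promoter_flank)
  links <- data.frame(gene_id = gene_id, peak_id = ids,
                      beta = fit@beta[keep], se = fit@se[keep],
                      pvalue = fit@pvalue[keep],
                      distance_to_tss = ann$distance,
                      annotation = ann$annotation,
                      stringsAsFactors = FALSE)
  rownames(links) <- NULL
  list(fit = fit, links = links)
}

.empty_links <- function() {
  data.frame(gene_id = character(), peak_id = character(), beta = numeric(),
             se = numeric(), pvalue = numeric(), distance_to_tss = numeric(),
             annotation = character(), stringsAsFactors = FALSE)
}

#' Classify CRE links along a two-state axis
#'
#' A link promotes state A when it positively regulates a stateA-up gene or
#' negatively regulates a stateB-up gene: label A iff
#' \code{sign(beta) * direction > 0}.
#'
#' @param links CRE link data.frame (from \code{\link{fitGeneCres}})
#' @param deg \code{\link{degTable}} covering every linked gene
#' @param labels length-2 labels for (stateA-, stateB-)promoting
#' @return \code{links} with a \code{label} column appended
#' @export
classifyCres <- function(links, deg,
                         labels = c("stateA-promoting", "stateB-promoting")) {
  idx <- match(links$gene_id, deg$gene_id)
  if (anyNA(idx))
    stop("gene(s) absent from DEG table: ",
         paste(unique(links$gene_id[is.na(idx)]), collapse = ", "))
  if (any(links$beta == 0))
    stop("zero-coefficient links are not classifiable (filter upstream)")
  s <- deg$direction[idx]
  links$label <- ifelse(sign(links$beta) * s > 0, labels[1], labels[2])
  links
}

#' Aggregate regulatory scores per peak
#'
#' \code{score(peak) = sum over target genes of beta x mean accessibility} of
#' the peak in the chosen cell group; peaks are ranked by \code{|score|} and
#' binned into tertiles (1 = highest).
#'
#' @param links CRE link data.frame
#' @param acc accessibility \linkS4class{OmicsMatrix}
#' @param cells optional cell-id subset defining the group (default: all)
#' @return data.frame: peak_id, score, abs_score, tertile; ordered by
#'   decreasing \code{|score|}
#' @export
scoreCres <- function(links, acc, cells = NULL) {
  v <- omicsValues(acc)
  if (!is.null(cells)) {
    if (length(cells) == 0L) stop("empty cell group")
    v <- v[cells, , drop = FALSE]
  }
  miss <- setdiff(unique(links$peak_id), colnames(v))
  if (length(miss)) stop("peaks absent from accessibility matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  macc <- Matrix::colMeans(v[, unique(links$peak_id), drop = FALSE])
  contrib <- links$beta * macc[links$peak_id]
  score <- tapply(contrib, links$peak_id, sum)
  out <- data.frame(peak_id = names(score), score = as.numeric(score),
                    abs_score = abs(as.numeric(score)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_score, out$peak_id), ]
  out$tertile <- ceiling(3 * seq_len(nrow(out)) / nrow(out))
  rownames(out) <- NULL
  out
}
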