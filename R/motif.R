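#' @include AllClasses.R ranges.R
#' @importFrom Biostrings DNAStringSet reverseComplement letterFrequency width
#' @importFrom IRanges overlapsAny
#' @importFrom Matrix sparseMatrix
#' @importFrom stats fisher.test p.adjust
NULL

# Per-motif log-odds score matrix (5 rows: A, C, G, T, N). Column
# probabilities use a small pseudocount against zero counts; N contributes a
# background (zero log-odds) score.
.logodds <- function(pfm, bg, pseudocount = 0.01) {
  pr <- sweep(pfm + pseudocount, 2, colSums(pfm + pseudocount), "/")
  lo <- log2(pr / bg)
  rbind(lo, N = 0)
}

.seq_codes <- function(s) {
  chartr("ACGTN", "12345", toupper(s))
}

# Max sliding-window log-odds score of one coded sequence against `lo`.
.best_score <- function(codes, lo) {
  w <- ncol(lo)
  m <- length(codes)
  if (w > m) return(-Inf)
  npos <- m - w + 1L
  sc <- numeric(npos)
  for (k in seq_len(w)) sc <- sc + lo[codes[k:(k + npos - 1L)], k]
  max(sc)
}

#' Scan peak sequences for motif matches
#'
#' Log-odds scoring of each motif against each sequence on both strands. A
#' sequence is a hit for a motif when its best window score reaches
#' \code{rel_threshold} on the relative scale that maps the minimum
#' achievable score to 0 and the maximum to 1. \code{N} bases score as
#' background. A motif wider than a sequence simply produces no hit.
#'
#' @param sequences named character vector or \code{DNAStringSet} over
#'   A/C/G/T/N, one per peak
#' @param motifs a \linkS4class{MotifSet}
#' @param rel_threshold relative score threshold in [0, 1] (default 0.80)
#' @return a \linkS4class{PeakMotifHits}
#' @export
scanMotifs <- function(sequences, motifs, rel_threshold = 0.80) {
  if (length(sequences) == 0L) stop("empty sequence set")
  seq_chr <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(seq_chr))) stop("sequences must be named by peak id")
  rc_chr <- as.character(reverseComplement(DNAStringSet(seq_chr)))
  codes <- lapply(seq_chr, function(s) as.integer(strsplit(.seq_codes(s), "")[[1]]))
  codes_rc <- lapply(rc_chr, function(s) as.integer(strsplit(.seq_codes(s), "")[[1]]))

  ids <- names(motifs@pfms)
  ii <- integer(); jj <- integer()
  for (j in seq_along(ids)) {
    pfm <- motifs@pfms[[j]]
    lo <- .logodds(pfm, motifs@background[[j]])
    smax <- sum(apply(lo[1:4, , drop = FALSE], 2, max))
    smin <- sum(apply(lo[1:4, , drop = FALSE], 2, min))
    thr <- smin + rel_threshold * (smax - smin)
    for (i in seq_along(codes)) {
      best <- max(.best_score(codes[[i]], lo), .best_score(codes_rc[[i]], lo))
      if (is.finite(best) && best >= thr) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  hits <- sparseMatrix(i = ii, j = jj,
                       dims = c(length(codes), length(ids)),
                       dimnames = list(names(seq_chr), ids), x = 1)
  new("PeakMotifHits", hits = hits, scan_threshold = rel_threshold)
}

#' Wrap a precomputed peak-by-motif matrix
#'
#' @param hits binary peaks x motifs matrix with dimnames
#' @return a \linkS4class{PeakMotifHits} with \code{scan_threshold = NA}
#' @export
peakMotifHits <- function(hits) {
  new("PeakMotifHits", hits = as(Matrix::Matrix(hits, sparse = TRUE),
                                 "CsparseMatrix"),
      scan_threshold = NA_real_)
}

#' Strand-aware promoter interval
#'
#' The promoter is the interval \code{upstream} bp upstream through
#' \code{downstream} bp downstream of the TSS on the gene's strand (defaults
#' -2000..0). On the + strand this is \code{[tss - upstream, tss +
#' downstream)} in 0-based coordinates; on the - strand the reflected
#' interval.
#'
#' @param gene single-row gene \code{GRanges}
#' @param upstream,downstream extent in bp
#' @return a \code{GRanges} interval (zero-width when
#'   \code{upstream + downstream == 0})
#' @export
promoterInterval <- function(gene, upstream = 2000, downstream = 0) {
  stopifnot(length(gene) == 1L)
  tss <- mcols(gene)$tss
  if (as.character(strand(gene)) == "+") {
    s0 <- tss - upstream; e0 <- tss + downstream
  } else {
    s0 <- tss + 1 - downstream; e0 <- tss + 1 + upstream
  }
  GRanges(seqnames(gene), IRanges(s0 + 1, e0), strand = strand(gene))
}

#' @rdname promoterInterval
#' @param peaks peak \code{GRanges}
#' @return for \code{promoterPeaks}: ids of peaks overlapping the promoter
#' @export
promoterPeaks <- function(gene, peaks, upstream = 2000, downstream = 0) {
  prom <- promoterInterval(gene, upstream, downstream)
  if (GenomicRanges::width(prom) == 0L) return(character())
  peakIds(peaks)[overlapsAny(peaks, prom, ignore.strand = TRUE)]
}

#' Nominate candidate TFs for a gene
#'
#' TFs whose motif hits fall in a significant CRE peak or in a
#' promoter-overlapping peak, intersected with the expressed-TF set;
#' deduplicated, sorted for determinism.
#'
#' @param gene_id gene
#' @param cre_links stage-1 link data.frame for this gene (significant CREs)
#' @param hits a \linkS4class{PeakMotifHits} covering the CRE and promoter
#'   peaks
#' @param promoter_peak_ids ids of peaks overlapping the gene's promoter
#' @param expressed_tfs TF ids considered expressed
#' @param motifs the \linkS4class{MotifSet} mapping motif ids to TF names
#' @return character vector of TF ids
#' @export
candidateTfs <- function(gene_id, cre_links, hits, promoter_peak_ids,
                         expressed_tfs, motifs) {
  pk <- unique(c(cre_links$peak_id[cre_links$gene_id == gene_id],
                 promoter_peak_ids))
  pk <- intersect(pk, rownames(hitMatrix(hits)))
  if (length(pk) == 0L) return(character())
  h <- hitMatrix(hits)[pk, , drop = FALSE]
  motif_ids <- colnames(h)[Matrix::colSums(h) > 0]
  tfs <- unique(unname(motifs@tfNames[motif_ids]))
  sort(intersect(tfs, expressed_tfs))
}

#' GC fraction of sequences
#'
#' @param sequences named character vector or \code{DNAStringSet}
#' @return named numeric vector of GC fractions
#' @export
gcContent <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  as.numeric(letterFrequency(sequences, "GC")) / width(sequences)
}

#' Motif-enrichment TF nomination
#'
#' One-sided Fisher exact test of motif hit counts in a gene's CRE set
#' against a GC-matched background sampled (without replacement) from
#' non-CRE peaks within GC-decile bins; Benjamini-Hochberg across motifs,
#' keeping adjusted p < \code{alpha}. A stricter alternative to
#' \code{\link{candidateTfs}}: its nominations are always a subset of the
#' presence-based ones for the same peak set.
#'
#' @param gene_id gene
#' @param cre_peak_ids ids of the gene's significant CRE peaks (nonempty)
#' @param all_peak_ids the full peak universe
#' @param hits a \linkS4class{PeakMotifHits}
#' @param gc named GC fraction per peak (all peaks)
#' @param motifs the \linkS4class{MotifSet}
#' @param n_background background peaks to sample (default 200)
#' @param alpha BH-adjusted significance cutoff
#' @param seed sampling seed
#' @return character vector of TF ids with enriched motifs
#' @export
enrichedTfs <- function(gene_id, cre_peak_ids, all_peak_ids, hits, gc, motifs,
                        n_background = 200L, alpha = 0.05, seed = 1L) {
  if (length(cre_peak_ids) == 0L) stop("empty CRE set for ", gene_id)
  if (!all(all_peak_ids %in% names(gc))) stop("gc must cover all peaks")
  pool <- setdiff(all_peak_ids, cre_peak_ids)
  qs <- unique(quantile(gc[all_peak_ids], probs = seq(0, 1, 0.1)))
  bin <- cut(gc[all_peak_ids], breaks = qs, include.lowest = TRUE)
  names(bin) <- all_peak_ids
  cre_tab <- table(bin[cre_peak_ids])
  want <- round(n_background * cre_tab / sum(cre_tab))
  bg <- withr::with_seed(deriveSeed(seed, gene_id, 3L), {
    unlist(lapply(names(want), function(b) {
      avail <- pool[!is.na(bin[pool]) & bin[pool] == b]
      sample(avail, min(length(avail), want[[b]]))
    }), use.names = FALSE)
  })
  if (length(bg) == 0L) stop("no background peaks available")

  h <- hitMatrix(hits)
  n_cre <- length(cre_peak_ids); n_bg <- length(bg)
  a <- Matrix::colSums(h[cre_peak_ids, , drop = FALSE])
  c_ <- Matrix::colSums(h[bg, , drop = FALSE])
  pv <- vapply(seq_along(a), function(j) {
    tab <- matrix(c(a[j], n_cre - a[j], c_[j], n_bg - c_[j]), 2)
    fisher.test(tab, alternative = "greater")$p.value
  }, 0)
  padj <- p.adjust(pv, "BH")
  motif_ids <- colnames(h)[padj < alpha]
  sort(unique(unname(motifs@tfNames[motif_ids])))
}

#' TFs expressed in at least a fraction of cells
#'
#' @param expr expression \linkS4class{OmicsMatrix}
#' @param tf_ids TF feature ids to consider
#' @param min_frac minimum fraction of cells with nonzero expression
#' @return character vector of expressed TF ids
#' @export
expressedTfs <- function(expr, tf_ids, min_frac = 0.01) {
  tf_ids <- intersect(tf_ids, featureIds(expr))
  v <- omicsValues(expr)[, tf_ids, drop = FALSE]
  frac <- Matrix::colMeans(v != 0)
  tf_ids[frac >= min_frac]
}
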