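#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# Coordinates follow the BED convention (0-based half-open) at every external
# boundary; internally peaks and genes are GRanges (1-based closed) carrying
# the original BED coordinates inside their ids, so string ids and interval
# arithmetic never disagree.

#' Construct a peak set
#'
#' @param chrom chromosome per peak
#' @param start,end 0-based half-open interval bounds
#' @param peak_id optional ids; defaults to canonical
#'   \code{"chrom:start-end"}
#' @return \code{GRanges} with metadata column \code{peak_id}
#' @export
PeakSet <- function(chrom, start, end, peak_id = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-numeric peak coordinates")
  if (any(start >= end)) stop("peak start must be < end (0-based half-open)")
  if (is.null(peak_id))
    peak_id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  if (anyDuplicated(peak_id)) stop("duplicate peak ids")
  gr <- GRanges(chrom, IRanges(start + 1, end))
  mcols(gr)$peak_id <- peak_id
  names(gr) <- peak_id
  gr
}

#' @rdname PeakSet
#' @param peaks a peak \code{GRanges}
#' @export
peakIds <- function(peaks) mcols(peaks)$peak_id

#' Parse canonical peak ids back to a peak set
#'
#' @param ids ids of the form \code{"chrom:start-end"} (BED coordinates)
#' @return \code{GRanges} as \code{\link{PeakSet}}
#' @export
peakIdToRanges <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable peak id(s): ", paste(ids[bad], collapse = ", "))
  PeakSet(vapply(m, `[`, "", 2L), as.numeric(vapply(m, `[`, "", 3L)),
          as.numeric(vapply(m, `[`, "", 4L)), peak_id = ids)
}

#' Construct a gene annotation
#'
#' Strand determines the transcription start site: \code{body_start} for
#' \code{+} genes and \code{body_end - 1} for \code{-} genes (0-based).
#'
#' @param gene_id gene ids (unique)
#' @param chrom chromosome
#' @param strand \code{"+"} or \code{"-"}
#' @param body_start,body_end 0-based half-open gene body
#' @return \code{GRanges} with metadata columns \code{gene_id} and \code{tss}
#'   (0-based TSS position)
#' @export
GeneAnnotation <- function(gene_id, chrom, strand, body_start, body_end) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  body_start <- as.numeric(body_start); body_end <- as.numeric(body_end)
  if (any(body_start >= body_end)) stop("body_start must be < body_end")
  tss <- ifelse(strand == "+", body_start, body_end - 1)
  gr <- GRanges(chrom, IRanges(body_start + 1, body_end), strand = strand)
  mcols(gr)$gene_id <- gene_id
  mcols(gr)$tss <- tss
  names(gr) <- gene_id
  gr
}

#' @rdname GeneAnnotation
#' @param genes a gene \code{GRanges}
#' @export
geneIds <- function(genes) mcols(genes)$gene_id

#' @rdname GeneAnnotation
#' @export
geneTss <- function(genes) stats::setNames(mcols(genes)$tss, geneIds(genes))
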