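#' @import methods
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

setClassUnion("MatrixLike", c("matrix", "Matrix"))

#' Cells-by-features omics matrix
#'
#' Container for one modality of a single-cell multiome experiment: a
#' cells (rows) by features (columns) numeric matrix holding either raw or
#' normalized values. Gene expression (\code{modality = "rna"}) and peak
#' accessibility (\code{modality = "atac"}) from the same barcodes are held in
#' two \code{OmicsMatrix} objects whose rows align by cell id.
#'
#' Values are stored feature-major sparse where the input is sparse;
#' densification happens only per gene at fit time. Raw values must be
#' nonnegative; cell and feature ids must be unique.
#'
#' @slot values numeric matrix (dense or \pkg{Matrix} sparse), cells x features
#' @slot modality \code{"rna"} or \code{"atac"}
#' @slot units \code{"counts"} (must be nonnegative) or \code{"normalized"}
#' @export
setClass("OmicsMatrix",
  representation(values = "MatrixLike", modality = "character",
                 units = "character"),
  prototype(units = "normalized"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!object@modality %in% c("rna", "atac"))
    msg <- c(msg, "modality must be 'rna' or 'atac'")
  if (!object@units %in% c("counts", "normalized"))
    msg <- c(msg, "units must be 'counts' or 'normalized'")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate cell ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate feature ids")
  }
  if (identical(object@units, "counts") && min(v) < 0)
    msg <- c(msg, "negative values not allowed in counts")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values cells x features numeric matrix, dense or sparse
#' @param modality \code{"rna"} or \code{"atac"}
#' @param cell_ids,feature_ids optional dimnames; taken from \code{values}
#'   when omitted
#' @param units \code{"counts"} or \code{"normalized"}
#' @return an \linkS4class{OmicsMatrix}
#' @export
OmicsMatrix <- function(values, modality, cell_ids = NULL, feature_ids = NULL,
                        units = "normalized") {
  if (!is.null(cell_ids)) rownames(values) <- cell_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  new("OmicsMatrix", values = values, modality = modality, units = units)
}

#' One gene's fitted regulatory model
#'
#' Result of a two-stage adaptive elastic-net fit of a target gene's
#' expression on a set of candidate predictors (peak accessibility in stage 1,
#' TF expression in stage 2). Coefficients are on the original predictor
#' scale; \code{se} and \code{pvalue} are filled by
#' \code{\link{bootstrapSignificance}} and are \code{NA} before it runs.
#'
#' @slot gene_id target gene
#' @slot predictor_ids predictors retained by the pilot elastic net
#' @slot beta coefficient per predictor (original scale, post-rescale)
#' @slot intercept model intercept
#' @slot se bootstrap standard error per predictor
#' @slot pvalue two-sided normal p-value per predictor
#' @slot lambda1 CV-selected overall penalty level of the adaptive stage
#' @slot lambda2 relative ridge weight used (0.25 CRE stage, 0.5 TF stage)
#' @slot lambda2_abs absolute ridge level \code{lambda1 * lambda2}
#' @slot penalty_weights adaptive weights (standardized scale) per predictor
#' @slot r2 proportion of variance explained on the training rows (may be
#'   negative)
#' @slot n_obs rows used
#' @slot n_nonzero number of nonzero coefficients
#' @export
setClass("FitResult",
  representation(gene_id = "character", predictor_ids = "character",
    beta = "numeric", intercept = "numeric", se = "numeric",
    pvalue = "numeric", lambda1 = "numeric", lambda2 = "numeric",
    lambda2_abs = "numeric", penalty_weights = "numeric", r2 = "numeric",
    n_obs = "integer", n_nonzero = "integer"))

setValidity("FitResult", function(object) {
  p <- length(object@predictor_ids)
  msg <- character()
  if (length(object@beta) != p || length(object@se) != p ||
      length(object@pvalue) != p)
    msg <- c(msg, "predictor_ids, beta, se, pvalue must share length")
  if (length(object@r2) == 1L && !is.na(object@r2) && object@r2 > 1)
    msg <- c(msg, "r2 cannot exceed 1")
  if (object@n_nonzero > p) msg <- c(msg, "n_nonzero exceeds predictor count")
  if (length(msg)) msg else TRUE
})

#' Transcription factor motif collection
#'
#' Position frequency matrices (4 x width, rows A/C/G/T) with per-motif
#' background base probabilities, as parsed from a JASPAR-format file.
#'
#' @slot pfms named list of 4 x width nonnegative matrices
#' @slot tfNames TF name per motif id
#' @slot background named list of length-4 base probability vectors
#' @export
setClass("MotifSet",
  representation(pfms = "list", tfNames = "character", background = "list"))

setValidity("MotifSet", function(object) {
  msg <- character()
  ids <- names(object@pfms)
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate motif ids")
  if (!identical(ids, names(object@tfNames)) ||
      !identical(ids, names(object@background)))
    msg <- c(msg, "pfms, tfNames and background must share names")
  for (id in ids) {
    m <- object@pfms[[id]]
    if (!is.matrix(m) || nrow(m) != 4L || ncol(m) < 4L || min(m) < 0)
      msg <- c(msg, sprintf("motif %s: pfm must be nonnegative 4 x width>=4", id))
    else if (any(colSums(m) <= 0))
      msg <- c(msg, sprintf("motif %s: pfm columns must sum to > 0", id))
    bg <- object@background[[id]]
    if (length(bg) != 4L || abs(sum(bg) - 1) > 1e-9)
      msg <- c(msg, sprintf("motif %s: background must sum to 1", id))
  }
  if (length(msg)) msg else TRUE
})

#' Sparse peak-by-motif hit matrix
#'
#' Binary incidence of motif matches in peak sequences, either produced by
#' \code{\link{scanMotifs}} or supplied precomputed (bypassing sequence
#' scanning entirely).
#'
#' @slot hits sparse binary peaks x motifs matrix
#' @slot scan_threshold relative log-odds score threshold in [0, 1] used for
#'   scanning (\code{NA} for precomputed matrices)
#' @export
setClass("PeakMotifHits",
  representation(hits = "MatrixLike", scan_threshold = "numeric"))

setValidity("PeakMotifHits", function(object) {
  h <- object@hits
  msg <- character()
  if (is.null(rownames(h)) || is.null(colnames(h)))
    msg <- c(msg, "hits must carry peak (row) and motif (column) names")
  if (length(object@scan_threshold) != 1L)
    msg <- c(msg, "scan_threshold must be a scalar (NA allowed)")
  vals <- unique(as.vector(as.matrix(h)))
  if (!all(vals %in% c(0, 1))) msg <- c(msg, "hits must be binary")
  if (length(msg)) msg else TRUE
})

#' Directed, signed TF-to-gene regulatory graph
#'
#' Nodes are TFs and genes (a TF regulating another TF appears in both
#' roles); each edge tf -> gene carries weight = |beta| x mean TF expression
#' and the sign of beta.
#'
#' @slot edges data.frame with columns tf, gene, beta, weight, sign
#' @slot nodes data.frame with columns id, role (\code{"tf"}, \code{"gene"}
#'   or \code{"both"})
#' @export
setClass("GRNGraph",
  representation(edges = "data.frame", nodes = "data.frame"))

setValidity("GRNGraph", function(object) {
  msg <- character()
  need <- c("tf", "gene", "beta", "weight", "sign")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges must have columns tf, gene, beta, weight, sign")
  else {
    if (any(object@edges$weight < 0)) msg <- c(msg, "edge weights must be >= 0")
    ep <- unique(c(object@edges$tf, object@edges$gene))
    if (!all(ep %in% object@nodes$id)) msg <- c(msg, "edge endpoint missing from nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Pseudocell assignment
#'
#' Total mapping of cells to pseudocells produced by
#' \code{\link{buildPseudocells}}: every cell belongs to exactly one
#' pseudocell and no pseudocell mixes graph communities.
#'
#' @slot assignment named character: cell id -> pseudocell id
#' @slot sizes named integer: pseudocell id -> member count
#' @slot community named character: pseudocell id -> community label
#' @slot target_size targeted maximum members per pseudocell
#' @slot seed RNG seed used
#' @export
setClass("PseudocellAssignment",
  representation(assignment = "character", sizes = "integer",
    community = "character", target_size = "integer", seed = "integer"))

setValidity("PseudocellAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@assignment))) msg <- c(msg, "assignment must be named by cell id")
  if (sum(object@sizes) != length(object@assignment))
    msg <- c(msg, "sizes must sum to the number of cells")
  tab <- table(object@assignment)
  if (!identical(sort(names(tab)), sort(names(object@sizes))))
    msg <- c(msg, "sizes names must match assignment values")
  if (object@target_size < 1L) msg <- c(msg, "target_size must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d cells x %d features\n", object@modality,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult for %s: %d predictors (%d nonzero), r2 = %s\n",
              object@gene_id, length(object@predictor_ids), object@n_nonzero,
              format(object@r2, digits = 3)))
})

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet: %d motifs (widths %s)\n", length(object@pfms),
              paste(range(vapply(object@pfms, ncol, 1L)), collapse = "-")))
})

setMethod("show", "PeakMotifHits", function(object) {
  cat(sprintf("PeakMotifHits: %d peaks x %d motifs, %d hits (threshold %s)\n",
              nrow(object@hits), ncol(object@hits), sum(object@hits),
              format(object@scan_threshold)))
})

setMethod("show", "GRNGraph", function(object) {
  cat(sprintf("GRNGraph: %d nodes, %d edges (%d TFs)\n", nrow(object@nodes),
              nrow(object@edges), length(unique(object@edges$tf))))
})

setMethod("show", "PseudocellAssignment", function(object) {
  cat(sprintf("PseudocellAssignment: %d cells -> %d pseudocells (target %d)\n",
              length(object@assignment), length(object@sizes),
              object@target_size))
})
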