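#' @include AllClasses.R
NULL

#' @rdname OmicsMatrix-class
#' @param object,x an object
#' @export
setGeneric("omicsValues", function(object) standardGeneric("omicsValues"))
#' @rdname OmicsMatrix-class
#' @export
setMethod("omicsValues", "OmicsMatrix", function(object) object@values)

#' @rdname OmicsMatrix-class
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname OmicsMatrix-class
#' @export
setMethod("cellIds", "OmicsMatrix", function(object) rownames(object@values))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname OmicsMatrix-class
#' @export
setMethod("featureIds", "OmicsMatrix", function(object) colnames(object@values))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname OmicsMatrix-class
#' @export
setMethod("modality", "OmicsMatrix", function(object) object@modality)

#' @describeIn FitResult-class named coefficient vector
#' @param object a \code{FitResult}
#' @export
setMethod("coef", "FitResult", function(object) {
  stats::setNames(object@beta, object@predictor_ids)
})

#' Tabulate one or more fits
#'
#' Long-format view of fitted regulatory models, one row per
#' (gene, predictor) pair.
#'
#' @param fits a \code{FitResult} or list of them
#' @return data.frame with columns gene, element, coefficient, se, p, r2
#' @export
fitTable <- function(fits) {
  if (is(fits, "FitResult")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    if (length(f@predictor_ids) == 0L) return(NULL)
    data.frame(gene = f@gene_id, element = f@predictor_ids,
               coefficient = f@beta, se = f@se, p = f@pvalue, r2 = f@r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), element = character(),
                      coefficient = numeric(), se = numeric(), p = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname GRNGraph-class
#' @param object a \code{GRNGraph}
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname GRNGraph-class
#' @export
setMethod("graphEdges", "GRNGraph", function(object) object@edges)

#' @rdname GRNGraph-class
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
#' @rdname GRNGraph-class
#' @export
setMethod("graphNodes", "GRNGraph", function(object) object@nodes)

#' @rdname PeakMotifHits-class
#' @param object a \code{PeakMotifHits}
#' @export
setGeneric("hitMatrix", function(object) standardGeneric("hitMatrix"))
#' @rdname PeakMotifHits-class
#' @export
setMethod("hitMatrix", "PeakMotifHits", function(object) object@hits)

#' @rdname PseudocellAssignment-class
#' @param object a \code{PseudocellAssignment}
#' @export
setGeneric("assignment", function(object) standardGeneric("assignment"))
#' @rdname PseudocellAssignment-class
#' @export
setMethod("assignment", "PseudocellAssignment", function(object) object@assignment)

#' @rdname PseudocellAssignment-class
#' @export
setGeneric("pseudocellSizes", function(object) standardGeneric("pseudocellSizes"))
#' @rdname PseudocellAssignment-class
#' @export
setMethod("pseudocellSizes", "PseudocellAssignment", function(object) object@sizes)
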