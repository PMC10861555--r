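#' @include AllClasses.R
NULL

#' Library-size normalization
#'
#' Divides each cell's profile by its relative sequencing depth (total
#' signal over all features, scaled to mean 1 across cells), optionally
#' followed by \code{log1p}. Removes the per-cell size factor that would
#' otherwise act as a confounder shared by every predictor in the
#' regression stages. Values already on a normalized scale only need the
#' depth division; \code{log = TRUE} is intended for raw counts.
#'
#' @param x an \linkS4class{OmicsMatrix}
#' @param log also apply \code{log1p}
#' @return a normalized \linkS4class{OmicsMatrix} (units
#'   \code{"normalized"})
#' @export
normalizeCells <- function(x, log = FALSE) {
  v <- omicsValues(x)
  depth <- Matrix::rowSums(v)
  if (any(depth <= 0)) stop("cell(s) with zero total signal cannot be normalized")
  f <- depth / mean(depth)
  v <- v / f
  if (log) v <- log1p(v)
  OmicsMatrix(v, modality = modality(x), units = "normalized")
}
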