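#' @include AllClasses.R ranges.R
#' @importFrom Matrix readMM writeMM sparseMatrix t
#' @importFrom utils read.table write.table
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

# Numeric columns are serialized with 17 significant digits so that every
# writer/reader pair round-trips doubles exactly (well inside the 1e-12
# contract).
.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sparse counts matrix with feature and barcode lists
#'
#' MatrixMarket triplet file with one barcode (cell) per matrix row and one
#' feature per matrix column, plus plain-text id lists in matching order.
#'
#' @param matrix_path MatrixMarket (.mtx) triplet file, rows = cells
#' @param features_path text file, one feature id per line
#' @param barcodes_path text file, one barcode per line
#' @param modality \code{"rna"} or \code{"atac"}
#' @param units \code{"counts"} (negative entries are an error) or
#'   \code{"normalized"}
#' @return an \linkS4class{OmicsMatrix} with features as columns
#' @export
readSparseCounts <- function(matrix_path, features_path, barcodes_path,
                             modality, units = "counts") {
  m <- as(readMM(matrix_path), "CsparseMatrix")
  feats <- readLines(features_path)
  bcs <- readLines(barcodes_path)
  if (nrow(m) != length(bcs))
    stop(sprintf("matrix has %d rows but %d barcodes", nrow(m), length(bcs)))
  if (ncol(m) != length(feats))
    stop(sprintf("matrix has %d columns but %d features", ncol(m),
                 length(feats)))
  if (anyDuplicated(bcs)) stop("duplicate barcodes")
  if (anyDuplicated(feats)) stop("duplicate feature ids")
  if (units == "counts" && min(m) < 0)
    stop("negative entries in a matrix declared as counts")
  dimnames(m) <- list(bcs, feats)
  new("OmicsMatrix", values = m, modality = modality, units = units)
}

#' @rdname readSparseCounts
#' @param x an \linkS4class{OmicsMatrix}
#' @param prefix path prefix; writes \code{<prefix>.mtx},
#'   \code{<prefix>.features.txt}, \code{<prefix>.barcodes.txt}
#' @export
writeSparseCounts <- function(x, prefix) {
  writeMM(as(Matrix::Matrix(x@values, sparse = TRUE), "generalMatrix"),
          paste0(prefix, ".mtx"))
  writeLines(featureIds(x), paste0(prefix, ".features.txt"))
  writeLines(cellIds(x), paste0(prefix, ".barcodes.txt"))
  invisible(prefix)
}

#' Read peaks from a BED file
#'
#' BED3 or BED4; 0-based half-open coordinates are preserved. When the name
#' column is absent, ids are synthesized as \code{"chrom:start-end"}.
#'
#' @param path BED file
#' @return peak \code{GRanges} (see \code{\link{PeakSet}})
#' @export
readBedPeaks <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", fill = FALSE)
  if (ncol(df) < 3L) stop("BED requires at least 3 columns")
  s <- suppressWarnings(as.numeric(df[[2]]))
  e <- suppressWarnings(as.numeric(df[[3]]))
  if (any(is.na(s)) || any(is.na(e)))
    stop("non-numeric BED coordinates at line ",
         paste(which(is.na(s) | is.na(e)), collapse = ", "))
  PeakSet(df[[1]], s, e, peak_id = if (ncol(df) >= 4L) df[[4]] else NULL)
}

#' @rdname readBedPeaks
#' @param peaks peak \code{GRanges}
#' @export
writeBedPeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   name = peakIds(peaks))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{body_start}, \code{body_end} (0-based half-open).
#'
#' @param path TSV file
#' @return gene \code{GRanges} (see \code{\link{GeneAnnotation}})
#' @export
readGeneAnnotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "body_start", "body_end")
  if (!all(need %in% names(df)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  GeneAnnotation(df$gene_id, df$chrom, df$strand, df$body_start, df$body_end)
}

#' @rdname readGeneAnnotation
#' @param genes gene \code{GRanges}
#' @export
writeGeneAnnotation <- function(genes, path) {
  df <- data.frame(gene_id = geneIds(genes),
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   strand = as.character(GenomicRanges::strand(genes)),
                   body_start = GenomicRanges::start(genes) - 1L,
                   body_end = GenomicRanges::end(genes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Records start with \code{">motif_id tf_name"}, followed by four lines of
#' base counts (A, C, G, T), with or without the \code{"A [ ... ]"}
#' bracketed layout. A uniform background is attached to each motif.
#'
#' @param path JASPAR PFM file
#' @return a \linkS4class{MotifSet}
#' @export
readMotifsJaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records found in ", path)
  pfms <- list(); tfs <- character(); bgs <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    body <- lines[(from + 1L):to]
    if (length(body) != 4L)
      stop("malformed JASPAR record (need 4 base rows): ", lines[from])
    head_toks <- strsplit(sub("^>", "", lines[from]), "[ \t]+")[[1]]
    motif_id <- head_toks[1]
    tf_name <- if (length(head_toks) > 1) head_toks[2] else motif_id
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt][ \t]*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged JASPAR record: ", motif_id)
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(is.na(pfm)) || any(pfm < 0))
      stop("malformed counts in JASPAR record: ", motif_id)
    pfms[[motif_id]] <- pfm
    tfs[motif_id] <- tf_name
    bgs[[motif_id]] <- stats::setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  }
  new("MotifSet", pfms = pfms, tfNames = tfs, background = bgs)
}

#' @rdname readMotifsJaspar
#' @param motifs a \linkS4class{MotifSet}
#' @export
writeMotifsJaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(motifs@pfms)) {
    writeLines(sprintf(">%s %s", id, motifs@tfNames[[id]]), con)
    pfm <- motifs@pfms[[id]]
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(.fmt_num(pfm[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a FASTA sequence set
#'
#' @param path FASTA file
#' @return named \code{DNAStringSet}
#' @export
readFastaSet <- function(path) readDNAStringSet(path)

#' @rdname readFastaSet
#' @param sequences named character vector or \code{DNAStringSet}
#' @export
writeFastaSet <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  writeXStringSet(sequences, path)
  invisible(path)
}

#' Write / read fitted models as a long-format table
#'
#' One row per (gene, element): columns gene, element, coefficient, se, p,
#' r2. Numerics round-trip exactly.
#'
#' @param fits \code{FitResult} or list of them (or a \code{fitTable}
#'   data.frame)
#' @param path output TSV
#' @export
writeFitResults <- function(fits, path) {
  df <- if (is.data.frame(fits)) fits else fitTable(fits)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname writeFitResults
#' @export
readFitResults <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a regulatory graph as an attributed edge table
#'
#' @param graph a \linkS4class{GRNGraph}
#' @param path output TSV with columns source, target, weight, sign, beta
#' @export
writeEdgeTable <- function(graph, path) {
  e <- graphEdges(graph)
  .write_tsv(data.frame(source = e$tf, target = e$gene, weight = e$weight,
                        sign = e$sign, beta = e$beta), path)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Differential-direction table for a two-state contrast
#'
#' @param gene_id gene ids (unique)
#' @param direction +1 for stateA-up, -1 for stateB-up
#' @param padj optional adjusted p-values
#' @return data.frame with class-checked columns
#' @export
degTable <- function(gene_id, direction, padj = NULL) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in DEG table")
  if (!all(direction %in% c(-1, 1))) stop("directions must be +1 or -1")
  df <- data.frame(gene_id = gene_id, direction = as.integer(direction),
                   stringsAsFactors = FALSE)
  if (!is.null(padj)) df$padj <- padj
  df
}

#' @rdname degTable
#' @param path TSV with columns gene_id, direction (+1/-1)
#' @export
readDegTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  degTable(df$gene_id, df$direction, df$padj)
}

#' @rdname degTable
#' @param deg a DEG table
#' @export
writeDegTable <- function(deg, path) {
  .write_tsv(deg, path)
  invisible(path)
}
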