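#' Read an expression matrix from TSV
#'
#' Expects a header row of experiment (feature) ids and a first column of
#' row ids (genes or isoforms). All cells must be numeric; missing or
#' non-numeric values and duplicated row ids are errors, so data problems
#' surface at load time rather than as silent NAs downstream.
#'
#' @param path path to a tab-separated file.
#' @return A numeric matrix with row ids as rownames and experiment ids
#'   as colnames, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\te1\te2", "g1\t1\t2", "g2\t3\t4"), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("empty expression file (need a header and at least one row): ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  colIds <- header[-1L]
  if (anyDuplicated(colIds))
    stop("duplicate id ", colIds[duplicated(colIds)][1L], " in header of ", path)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  rowIds <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(rowIds))
    stop("duplicate id ", rowIds[duplicated(rowIds)][1L], " in ", path)
  nf <- length(colIds)
  vals <- matrix(NA_real_, nrow = length(body), ncol = nf,
                 dimnames = list(rowIds, colIds))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    if (length(cells) != nf)
      stop(sprintf("row '%s' has %d values, expected %d", rowIds[i],
                   length(cells), nf))
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   cells[j], rowIds[i], colIds[j]))
    }
    vals[i, ] <- v
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' Values are written with full precision (`format(..., digits = 17)`),
#' so write-then-read round-trips decimal-representable inputs exactly.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[i],
      format(x[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
      collapse = "\t"), con)
  invisible(path)
}

#' Read a gene-to-isoform mapping from TSV
#'
#' @param path two-column TSV: gene id, isoform id.
#' @param header does the file carry a header row? Default `FALSE`.
#' @return A [GeneIsoformMap-class].
#' @export
readGeneIsoformMap <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("mapping file needs two columns: ", path)
  GeneIsoformMap(df[[1L]], df[[2L]])
}

#' Read gene-term annotations from TSV
#'
#' @param path two-column TSV: gene id, term id.
#' @param header does the file carry a header row? Default `FALSE`.
#' @return A data.frame with columns `gene_id`, `term_id`.
#' @export
readAnnotations <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("annotation file needs two columns: ", path)
  stats::setNames(df[, 1:2], c("gene_id", "term_id"))
}

#' Read homolog groups from TSV
#'
#' Genes absent from the file are treated as singleton groups by
#' [groupKfold()].
#'
#' @param path two-column TSV: gene id, group id.
#' @param header does the file carry a header row? Default `FALSE`.
#' @return A data.frame with columns `gene_id`, `group_id`.
#' @export
readGroups <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("group file needs two columns: ", path)
  stats::setNames(df[, 1:2], c("gene_id", "group_id"))
}

#' Filter terms by annotation-set size
#'
#' Term sizes are computed only over genes present in the dataset (pass
#' `genes`); terms that are too specific or too general as function labels
#' are dropped. The conventional bounds are 5 and 1000 annotated genes.
#'
#' @param annotations data.frame with `gene_id`, `term_id` columns.
#' @param genes character vector of genes present in the expression data;
#'   `NULL` keeps all annotation rows in the size computation.
#' @param minSize,maxSize inclusive size bounds (minSize >= 1).
#' @return The annotation table restricted to retained terms. Warns if no
#'   term survives.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3", "g1"),
#'                   term_id = c("T1", "T1", "T1", "T2"))
#' filterTerms(ann, minSize = 2, maxSize = 10)  # keeps only T1
#' @export
filterTerms <- function(annotations, genes = NULL, minSize = 5L,
                        maxSize = 1000L) {
  stopifnot(minSize >= 1L, maxSize >= minSize)
  ann <- annotations
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  ann <- unique(ann)
  sizes <- table(ann$term_id)
  keep <- names(sizes)[sizes >= minSize & sizes <= maxSize]
  out <- ann[ann$term_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no term within size bounds [", minSize, ", ", maxSize, "]")
  out
}

#' Write a feature-selection result as TSV
#'
#' Columns: `feature_id`, `count`, `selection_probability`. With
#' `trajectory = TRUE` the per-iteration chain trace is written instead.
#'
#' @param result a [FrogResult-class].
#' @param path output path.
#' @param trajectory write the chain trajectory instead of the counts.
#' @return Invisibly, `path`.
#' @export
writeFrogResult <- function(result, path, trajectory = FALSE) {
  df <- if (trajectory) result@trajectory else
    data.frame(feature_id = names(result@counts),
               count = as.integer(result@counts),
               selection_probability = result@probabilities)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a threshold scan as TSV
#'
#' @param scan a [ThresholdScan-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeThresholdScan <- function(scan, path) {
  utils::write.table(scan@scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
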