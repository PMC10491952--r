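# Column-center a matrix, returning the matrix and the removed means.
.centerColumns <- function(x) {
  mu <- colMeans(x)
  list(x = sweep(x, 2L, mu, "-"), center = mu)
}

#' Assemble one term's prediction task
#'
#' Builds the binary gene label vector for `termId` (1 = annotated, 0 =
#' not; genes without annotation rows are negatives under the closed-world
#' assumption), checks that the mapping covers both matrices exactly, and
#' centers each matrix by its own column means. Per-domain centering
#' aligns the distributional means of the gene and isoform domains, which
#' the latent-variable model relies on.
#'
#' @param Xg genes x features matrix (raw expression, rownames = gene ids).
#' @param Xiso isoforms x features matrix with the same columns as `Xg`.
#' @param map a [GeneIsoformMap-class]; must cover exactly the rows of
#'   the two matrices (unmapped isoforms are rejected, not dropped).
#' @param annotations data.frame with `gene_id`, `term_id` columns.
#' @param termId the term to build labels for.
#' @return A [PredictionTask-class].
#' @examples
#' sim <- simulateIsoformData(nSig = 20, nMig = 5, nFeatures = 6,
#'                            nInformative = 2, seed = 1)
#' task <- buildTask(sim$geneExpr, sim$isoExpr, sim$map, sim$annotations,
#'                   "T1")
#' task
#' @export
buildTask <- function(Xg, Xiso, map, annotations, termId) {
  if (!identical(colnames(Xg), colnames(Xiso)))
    stop("column mismatch: Xg and Xiso must share identical experiment ids in identical order")
  extraIso <- setdiff(rownames(Xiso), map@isoform)
  if (length(extraIso))
    stop("isoform(s) in expression data but absent from the map: ",
         paste(utils::head(extraIso, 3L), collapse = ", "))
  missingIso <- setdiff(map@isoform, rownames(Xiso))
  if (length(missingIso))
    stop("mapped isoform(s) missing from the expression data: ",
         paste(utils::head(missingIso, 3L), collapse = ", "))
  if (!setequal(rownames(Xg), unique(map@gene)))
    stop("gene ids of Xg and of the map differ")
  pos <- unique(annotations$gene_id[annotations$term_id == termId])
  yg <- as.numeric(rownames(Xg) %in% pos)
  if (sum(yg) == 0 || sum(yg) == length(yg))
    stop("degenerate label vector: term '", termId,
         "' annotates ", if (sum(yg) == 0) "zero" else "all",
         " genes in the dataset")
  cg <- .centerColumns(Xg)
  ci <- .centerColumns(Xiso)
  new("PredictionTask", termId = as.character(termId), Xg = cg$x,
      Xiso = ci$x, yg = yg, map = map, geneCenter = cg$center,
      isoCenter = ci$center)
}

#' Restrict a task to a feature subset
#'
#' Both matrices are restricted to the given columns, keeping the original
#' column order regardless of the order of `subset`, and re-centered
#' (a no-op for freshly centered inputs, but it guards against stale
#' numerics).
#'
#' @param task a [PredictionTask-class].
#' @param subset integer column indices (unique, within range) or a
#'   [ThresholdScan-class] whose chosen subset is applied.
#' @return A new [PredictionTask-class] on the restricted feature space.
#' @export
applyFeatureSubset <- function(task, subset) {
  if (is(subset, "ThresholdScan")) subset <- subset@chosenSubset
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("empty feature subset")
  if (anyDuplicated(subset)) stop("feature subset has duplicate indices")
  if (any(subset < 1L) || any(subset > ncol(task@Xg)))
    stop("feature subset index out of range [1, ", ncol(task@Xg), "]")
  subset <- sort(subset)
  rawG <- sweep(task@Xg, 2L, task@geneCenter, "+")[, subset, drop = FALSE]
  rawI <- sweep(task@Xiso, 2L, task@isoCenter, "+")[, subset, drop = FALSE]
  cg <- .centerColumns(rawG)
  ci <- .centerColumns(rawI)
  new("PredictionTask", termId = task@termId, Xg = cg$x, Xiso = ci$x,
      yg = task@yg, map = task@map, geneCenter = cg$center,
      isoCenter = ci$center)
}

# Restrict a task to a set of genes (and their isoforms), recovering raw
# values and re-centering on the retained rows. Used to carve the inner
# and outer CV training tasks out of a full task without label leakage
# through the column means.
.taskSubsetGenes <- function(task, genes) {
  keepG <- rownames(task@Xg) %in% genes
  if (!any(keepG)) stop("no genes retained")
  isoKeep <- task@map@isoform[task@map@gene %in% genes]
  rawG <- sweep(task@Xg, 2L, task@geneCenter, "+")[keepG, , drop = FALSE]
  rawI <- sweep(task@Xiso, 2L, task@isoCenter, "+")[isoKeep, , drop = FALSE]
  keepPairs <- task@map@gene %in% genes
  map <- GeneIsoformMap(task@map@gene[keepPairs], task@map@isoform[keepPairs])
  yg <- task@yg[keepG]
  if (sum(yg) == 0 || sum(yg) == length(yg))
    stop("gene subset loses a label class")
  cg <- .centerColumns(rawG)
  ci <- .centerColumns(rawI)
  new("PredictionTask", termId = task@termId, Xg = cg$x, Xiso = ci$x,
      yg = yg, map = map, geneCenter = cg$center, isoCenter = ci$center)
}

# Raw (uncentered) isoform rows of a task, by isoform id.
.rawIsoformRows <- function(task, isoformIds) {
  sweep(task@Xiso[isoformIds, , drop = FALSE], 2L, task@isoCenter, "+")
}
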