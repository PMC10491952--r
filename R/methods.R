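#' Accessors for GeneIsoformMap
#'
#' `sigGenes` returns the single-isoform genes (SIGs), `migGenes` the
#' genes with two or more isoforms (MIGs), `mappedGenes` /
#' `mappedIsoforms` the unique ids on each side, and `isoformsOf` the
#' isoforms of one gene.
#'
#' @param x a [GeneIsoformMap-class].
#' @param gene a single gene id.
#' @return Character vectors of ids.
#' @name GeneIsoformMap-accessors
NULL

#' @rdname GeneIsoformMap-accessors
setMethod("sigGenes", "GeneIsoformMap", function(x) {
  tab <- table(x@gene)
  names(tab)[tab == 1L]
})

#' @rdname GeneIsoformMap-accessors
setMethod("migGenes", "GeneIsoformMap", function(x) {
  tab <- table(x@gene)
  names(tab)[tab >= 2L]
})

#' @rdname GeneIsoformMap-accessors
setMethod("mappedGenes", "GeneIsoformMap", function(x) unique(x@gene))

#' @rdname GeneIsoformMap-accessors
setMethod("mappedIsoforms", "GeneIsoformMap", function(x) x@isoform)

#' @rdname GeneIsoformMap-accessors
setMethod("isoformsOf", "GeneIsoformMap", function(x, gene) {
  x@isoform[x@gene %in% gene]
})

setMethod("length", "GeneIsoformMap", function(x) length(x@isoform))

setMethod("show", "GeneIsoformMap", function(object) {
  cat(sprintf("GeneIsoformMap: %d isoforms of %d genes (%d SIGs, %d MIGs)\n",
    length(object@isoform), length(unique(object@gene)),
    length(sigGenes(object)), length(migGenes(object))))
})

setMethod("show", "PredictionTask", function(object) {
  cat(sprintf("PredictionTask for term '%s'\n", object@termId))
  cat(sprintf("  genes: %d (%d positive), isoforms: %d, features: %d\n",
    nrow(object@Xg), sum(object@yg), nrow(object@Xiso), ncol(object@Xg)))
})

setMethod("show", "DiplsModel", function(object) {
  cat(sprintf("DiplsModel: %d features, %d latent components, lambda = %g\n",
    nrow(object@W), ncol(object@W), object@config@lambda))
  if (length(object@selected))
    cat(sprintf("  %d positive-MIG isoforms selected (loop ran %d sweep(s))\n",
      length(object@selected), object@milIterations))
})

setMethod("show", "FrogResult", function(object) {
  cat(sprintf("FrogResult: %d features over %d iterations\n",
    length(object@counts), object@nIterations))
  sp <- sort(object@probabilities, decreasing = TRUE)
  topn <- min(5L, length(sp))
  cat("  top selection probabilities:\n")
  for (i in seq_len(topn))
    cat(sprintf("    %s: %.3f\n", names(sp)[i], sp[i]))
})

setMethod("show", "ThresholdScan", function(object) {
  cat(sprintf(
    "ThresholdScan: %d thresholds; chosen %.4g keeping %d features (AUC %.3f)\n",
    nrow(object@scan), object@chosenThreshold, length(object@chosenSubset),
    object@scan$auc[object@scan$chosen == 1L][1L]))
})

#' Accessors for FrogResult
#'
#' @param x a [FrogResult-class].
#' @return `selectionProbabilities` returns the named numeric vector
#'   sp_i = N_i / N; `selectionCounts` the named integer N_i.
#' @name FrogResult-accessors
NULL

#' @rdname FrogResult-accessors
setMethod("selectionProbabilities", "FrogResult",
  function(x) x@probabilities)

#' @rdname FrogResult-accessors
setMethod("selectionCounts", "FrogResult", function(x) x@counts)

#' Accessors for DiplsModel
#'
#' @param object a [DiplsModel-class].
#' @return `coefVector` returns the regression coefficient vector b;
#'   `selectedIsoforms` the named vector mapping each positive MIG to its
#'   selected isoform.
#' @name DiplsModel-accessors
NULL

#' @rdname DiplsModel-accessors
setMethod("coefVector", "DiplsModel", function(object) object@b)

#' @rdname DiplsModel-accessors
setMethod("selectedIsoforms", "DiplsModel", function(object) object@selected)

#' Accessors for ThresholdScan
#'
#' @param x a [ThresholdScan-class].
#' @return `chosenSubset` returns the integer feature indices of the
#'   selected subset; `chosenThreshold` the winning cutoff.
#' @name ThresholdScan-accessors
NULL

#' @rdname ThresholdScan-accessors
setMethod("chosenSubset", "ThresholdScan", function(x) x@chosenSubset)

#' @rdname ThresholdScan-accessors
setMethod("chosenThreshold", "ThresholdScan", function(x) x@chosenThreshold)
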