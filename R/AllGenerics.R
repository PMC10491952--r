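#' @rdname GeneIsoformMap-accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))

#' @rdname GeneIsoformMap-accessors
#' @export
setGeneric("migGenes", function(x) standardGeneric("migGenes"))

#' @rdname GeneIsoformMap-accessors
#' @export
setGeneric("mappedGenes", function(x) standardGeneric("mappedGenes"))

#' @rdname GeneIsoformMap-accessors
#' @export
setGeneric("mappedIsoforms", function(x) standardGeneric("mappedIsoforms"))

#' @rdname GeneIsoformMap-accessors
#' @export
setGeneric("isoformsOf", function(x, gene) standardGeneric("isoformsOf"))

#' @rdname FrogResult-accessors
#' @export
setGeneric("selectionProbabilities",
  function(x) standardGeneric("selectionProbabilities"))

#' @rdname FrogResult-accessors
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' @rdname DiplsModel-accessors
#' @export
setGeneric("coefVector", function(object) standardGeneric("coefVector"))

#' @rdname DiplsModel-accessors
#' @export
setGeneric("selectedIsoforms",
  function(object) standardGeneric("selectedIsoforms"))

#' @rdname ThresholdScan-accessors
#' @export
setGeneric("chosenSubset", function(x) standardGeneric("chosenSubset"))

#' @rdname ThresholdScan-accessors
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))
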