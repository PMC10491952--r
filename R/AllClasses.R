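#' @import methods
NULL

#' Gene-to-isoform mapping
#'
#' Records which isoforms belong to which gene. Every isoform maps to
#' exactly one gene. Genes with a single isoform are SIGs (single-isoform
#' genes); genes with two or more are MIGs (multi-isoform genes). The
#' SIG/MIG partition is derived on demand via [sigGenes()] / [migGenes()].
#'
#' @slot gene character vector of gene ids, one entry per isoform.
#' @slot isoform character vector of isoform ids (unique).
#'
#' @seealso [GeneIsoformMap()], [readGeneIsoformMap()]
#' @exportClass GeneIsoformMap
setClass("GeneIsoformMap",
  representation(gene = "character", isoform = "character"))

setValidity("GeneIsoformMap", function(object) {
  msgs <- character()
  if (length(object@gene) != length(object@isoform))
    msgs <- c(msgs, "gene and isoform vectors must have equal length")
  if (anyDuplicated(object@isoform))
    msgs <- c(msgs, sprintf("isoform mapped to more than one gene: %s",
      object@isoform[duplicated(object@isoform)][1L]))
  if (length(object@gene) && (anyNA(object@gene) || anyNA(object@isoform)))
    msgs <- c(msgs, "mapping contains missing ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneIsoformMap
#'
#' @param gene character vector of gene ids (one per isoform).
#' @param isoform character vector of isoform ids, same length as `gene`.
#' @return A [GeneIsoformMap-class] object.
#' @examples
#' map <- GeneIsoformMap(c("g1", "g2", "g2"), c("i1", "i2a", "i2b"))
#' sigGenes(map)  # "g1"
#' migGenes(map)  # "g2"
#' @export
GeneIsoformMap <- function(gene, isoform) {
  new("GeneIsoformMap", gene = as.character(gene),
      isoform = as.character(isoform))
}

#' Configuration of the domain-invariant PLS predictor
#'
#' @slot nComponents integer, dimension of the latent-variable space
#'   (number of extracted weight vectors).
#' @slot lambda non-negative penalty weight of the domain regularizer that
#'   aligns latent-score variances of the gene and isoform domains.
#' @slot maxMilIterations cap on the multiple-instance relabeling loop.
#' @slot milEnabled if `FALSE` no isoform rows are stacked into the
#'   training objective and no relabeling is run (plain diPLS on genes).
#'
#' @seealso [diplsConfig()]
#' @exportClass DiplsConfig
setClass("DiplsConfig",
  representation(nComponents = "integer", lambda = "numeric",
                 maxMilIterations = "integer", milEnabled = "logical"))

setValidity("DiplsConfig", function(object) {
  msgs <- character()
  if (object@nComponents < 1L) msgs <- c(msgs, "nComponents must be >= 1")
  if (object@lambda < 0) msgs <- c(msgs, "lambda must be >= 0")
  if (object@maxMilIterations < 1L)
    msgs <- c(msgs, "maxMilIterations must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Create a predictor configuration
#'
#' Defaults: 5 latent components and lambda = 1, both of which matter most
#' when the gene and isoform domains differ in scale; the relabeling loop
#' caps at 100 iterations.
#'
#' @param nComponents number of latent components (>= 1, <= number of
#'   features of the task it is fitted to).
#' @param lambda domain-regularizer penalty, >= 0. 0 disables alignment.
#' @param maxMilIterations iteration cap of the relabeling loop.
#' @param milEnabled logical; stack labeled isoform rows and run the
#'   multiple-instance loop.
#' @return A [DiplsConfig-class] object.
#' @export
diplsConfig <- function(nComponents = 5L, lambda = 1, maxMilIterations = 100L,
                        milEnabled = TRUE) {
  new("DiplsConfig", nComponents = as.integer(nComponents),
      lambda = as.numeric(lambda),
      maxMilIterations = as.integer(maxMilIterations),
      milEnabled = as.logical(milEnabled))
}

#' Parameters of the stochastic feature-subset search
#'
#' @slot nIterations total chain length N.
#' @slot qInit initial subset cardinality Q (1 <= Q <= number of features).
#' @slot alpha variance factor of the cardinality proposal: the candidate
#'   cardinality is drawn from Normal(Q0, alpha * Q0), truncated to
#'   [Q0 - alpha*Q0, Q0 + alpha*Q0].
#' @slot mu candidate-pool expansion factor (>= 1) used when growing.
#' @slot omega ceiling of the acceptance probability for a worse subset.
#' @slot innerCvFolds folds of the inner gene-stratified CV that scores
#'   subsets by AUC.
#' @slot seed master seed; the whole chain is reproducible from it.
#' @slot cacheAuc0 if `TRUE` the current subset's AUC is carried over from
#'   the previous iteration instead of being recomputed on the fresh folds.
#'
#' @seealso [frogParams()], [runFrog()]
#' @exportClass FrogParams
setClass("FrogParams",
  representation(nIterations = "integer", qInit = "integer",
                 alpha = "numeric", mu = "numeric", omega = "numeric",
                 innerCvFolds = "integer", seed = "integer",
                 cacheAuc0 = "logical"))

setValidity("FrogParams", function(object) {
  msgs <- character()
  if (object@nIterations < 1L) msgs <- c(msgs, "nIterations must be >= 1")
  if (object@qInit < 1L) msgs <- c(msgs, "qInit must be >= 1")
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (object@mu < 1) msgs <- c(msgs, "mu must be >= 1")
  if (object@omega < 0 || object@omega > 1)
    msgs <- c(msgs, "omega must be in [0, 1]")
  if (object@innerCvFolds < 2L) msgs <- c(msgs, "innerCvFolds must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Create search parameters for the stochastic subset search
#'
#' Defaults follow the random-frog recommendations: a long chain
#' (N = 2000), a tiny initial subset (Q = 2) that the trans-dimensional
#' moves grow as needed, alpha = 0.3, mu = 10, omega = 0.1.
#'
#' @param nIterations chain length N.
#' @param qInit initial cardinality Q.
#' @param alpha cardinality-proposal variance factor (> 0).
#' @param mu candidate-pool expansion factor (>= 1).
#' @param omega acceptance-probability ceiling in [0, 1].
#' @param innerCvFolds inner CV folds (default 3).
#' @param seed master RNG seed.
#' @param cacheAuc0 carry the incumbent AUC across iterations (speed-up;
#'   default recomputes on each iteration's folds).
#' @return A [FrogParams-class] object.
#' @export
frogParams <- function(nIterations = 2000L, qInit = 2L, alpha = 0.3,
                       mu = 10, omega = 0.1, innerCvFolds = 3L,
                       seed = 1L, cacheAuc0 = FALSE) {
  new("FrogParams", nIterations = as.integer(nIterations),
      qInit = as.integer(qInit), alpha = as.numeric(alpha),
      mu = as.numeric(mu), omega = as.numeric(omega),
      innerCvFolds = as.integer(innerCvFolds), seed = as.integer(seed),
      cacheAuc0 = as.logical(cacheAuc0))
}

#' One GO term's learning problem
#'
#' Holds the column-centered gene and isoform expression matrices, the
#' binary gene label vector for one term, and the gene-isoform map. Both
#' matrices are centered by their own column means (stored in
#' `geneCenter` / `isoCenter` so raw values are recoverable and new data
#' can be centered consistently at prediction time).
#'
#' @slot termId the term the labels encode.
#' @slot Xg genes x features matrix, column-centered.
#' @slot Xiso isoforms x features matrix, column-centered; identical
#'   column ids in identical order as `Xg`.
#' @slot yg 0/1 vector over rows of `Xg` (1 = gene annotated to the term).
#' @slot map [GeneIsoformMap-class] covering exactly the rows of the
#'   two matrices.
#' @slot geneCenter,isoCenter the column means removed from each matrix.
#'
#' @seealso [buildTask()], [applyFeatureSubset()]
#' @exportClass PredictionTask
setClass("PredictionTask",
  representation(termId = "character", Xg = "matrix", Xiso = "matrix",
                 yg = "numeric", map = "GeneIsoformMap",
                 geneCenter = "numeric", isoCenter = "numeric"))

setValidity("PredictionTask", function(object) {
  msgs <- character()
  if (!identical(colnames(object@Xg), colnames(object@Xiso)))
    msgs <- c(msgs, "Xg and Xiso must share identical column ids in order")
  if (length(object@yg) != nrow(object@Xg))
    msgs <- c(msgs, "yg length must equal nrow(Xg)")
  if (!all(object@yg %in% c(0, 1)))
    msgs <- c(msgs, "yg must be binary 0/1")
  if (length(object@yg) && (sum(object@yg) == 0 ||
      sum(object@yg) == length(object@yg)))
    msgs <- c(msgs, "degenerate label vector: need >= 1 positive and >= 1 negative gene")
  if (ncol(object@Xg) > 0) {
    if (max(abs(colMeans(object@Xg))) > 1e-8)
      msgs <- c(msgs, "Xg is not column-centered")
    if (max(abs(colMeans(object@Xiso))) > 1e-8)
      msgs <- c(msgs, "Xiso is not column-centered")
  }
  if (!setequal(rownames(object@Xiso), object@map@isoform))
    msgs <- c(msgs, "Xiso rows and mapped isoforms differ")
  if (!setequal(rownames(object@Xg), unique(object@map@gene)))
    msgs <- c(msgs, "Xg rows and mapped genes differ")
  if (length(msgs)) msgs else TRUE
})

#' State of the multiple-instance relabeling loop
#'
#' The augmented isoform training set: isoform rows of SIGs and of
#' negative MIGs appear exactly once with their gene's label; at most one
#' isoform per positive MIG is included, labeled 1.
#'
#' @slot X stacked isoform expression rows (centered, task feature space).
#' @slot y matching 0/1 labels.
#' @slot rowIds isoform ids of the rows of `X`.
#' @slot selected named character vector: positive MIG gene id -> the
#'   isoform currently chosen as its function carrier.
#' @slot iterations number of relabeling sweeps performed.
#' @slot converged `TRUE` if the selected set reached a fixed point before
#'   the iteration cap.
#'
#' @seealso [milUpdate()]
#' @exportClass MilState
setClass("MilState",
  representation(X = "matrix", y = "numeric", rowIds = "character",
                 selected = "character", iterations = "integer",
                 converged = "logical"))

#' Fitted domain-invariant PLS model
#'
#' @slot W features x components weight matrix, unit-norm columns.
#' @slot P features x components loading matrix of the stacked source.
#' @slot q inner coefficients (one per component).
#' @slot b regression coefficient vector, `b = W (P'W)^-1 q`.
#' @slot isoCenter column means used to center isoform rows at predict time.
#' @slot featureNames column ids the model was trained on.
#' @slot config the [DiplsConfig-class] used.
#' @slot selected per-positive-MIG chosen isoform (empty if the
#'   relabeling loop was disabled or there were no positive MIGs).
#' @slot milIterations sweeps the relabeling loop ran.
#'
#' @seealso [fitDipls()], [predictScores()]
#' @exportClass DiplsModel
setClass("DiplsModel",
  representation(W = "matrix", P = "matrix", q = "numeric", b = "numeric",
                 isoCenter = "numeric", featureNames = "character",
                 config = "DiplsConfig", selected = "character",
                 milIterations = "integer"))

setValidity("DiplsModel", function(object) {
  msgs <- character()
  if (!identical(dim(object@W), dim(object@P)))
    msgs <- c(msgs, "W and P must have identical dimensions")
  if (length(object@q) != ncol(object@W))
    msgs <- c(msgs, "length(q) must equal ncol(W)")
  if (length(object@b) != nrow(object@W))
    msgs <- c(msgs, "length(b) must equal nrow(W)")
  if (length(msgs)) msgs else TRUE
})

#' Result of the stochastic feature-subset search
#'
#' Per feature, the number of the N accepted subsets it belonged to
#' (`counts`) and the selection probability `counts / N`.
#'
#' @slot counts named integer vector N_i per feature.
#' @slot probabilities named numeric vector sp_i = N_i / N.
#' @slot nIterations chain length N.
#' @slot trajectory per-iteration data.frame: `iteration`, `cardinality`
#'   (of the accepted subset), `auc0`, `aucNew`, `accepted`.
#'
#' @seealso [runFrog()], [selectionProbabilities()]
#' @exportClass FrogResult
setClass("FrogResult",
  representation(counts = "integer", probabilities = "numeric",
                 nIterations = "integer", trajectory = "data.frame"))

setValidity("FrogResult", function(object) {
  msgs <- character()
  if (length(object@counts) != length(object@probabilities))
    msgs <- c(msgs, "counts and probabilities must align")
  if (any(object@counts < 0L) || any(object@counts > object@nIterations))
    msgs <- c(msgs, "counts must lie in [0, nIterations]")
  if (any(object@probabilities < 0) || any(object@probabilities > 1))
    msgs <- c(msgs, "selection probabilities must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Threshold scan over selection probabilities
#'
#' @slot scan data.frame with one row per candidate threshold:
#'   `threshold`, `nFeatures`, `auc`, `chosen`.
#' @slot chosenThreshold the cutoff with maximal CV AUC (ties resolved
#'   toward the larger cutoff, i.e. fewer features).
#' @slot chosenSubset integer column indices of the final feature subset.
#'
#' @seealso [selectSubset()]
#' @exportClass ThresholdScan
setClass("ThresholdScan",
  representation(scan = "data.frame", chosenThreshold = "numeric",
                 chosenSubset = "integer"))
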