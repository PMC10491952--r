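#' Candidate selection-probability thresholds
#'
#' The sorted unique positive selection probabilities. Exactly these
#' values change the surviving subset (features with sp >= threshold), so
#' scanning them is exhaustive over distinct subsets; the maximum sp is
#' the last usable threshold (it keeps the top features, never an empty
#' set).
#'
#' @param result a [FrogResult-class].
#' @return Ascending numeric vector of cutoffs.
#' @export
candidateThresholds <- function(result) {
  sp <- result@probabilities
  if (all(sp == 0))
    stop("no feature ever selected; increase the number of iterations")
  sort(unique(sp[sp > 0]))
}

#' Threshold scan extracting the final feature subset
#'
#' Evaluates, for each candidate threshold in ascending order, the subset
#' of features whose selection probability is at least the threshold,
#' using inner cross-validated AUC ([cvAuc()]) with the same folds across
#' all thresholds (removing fold noise from the comparison). The
#' threshold with the highest AUC wins; ties go to the larger threshold,
#' i.e. the smaller subset.
#'
#' @param result a [FrogResult-class].
#' @param task the [PredictionTask-class] the search ran on (training
#'   genes only).
#' @param config a [DiplsConfig-class].
#' @param folds inner CV folds (default 3).
#' @param foldSeed seed shared by all thresholds' CV splits.
#' @return A [ThresholdScan-class].
#' @export
selectSubset <- function(result, task, config = diplsConfig(), folds = 3L,
                         foldSeed = 1L) {
  ths <- candidateThresholds(result)
  sp <- result@probabilities
  nFeat <- integer(length(ths))
  auc <- numeric(length(ths))
  for (i in seq_along(ths)) {
    subset <- which(sp >= ths[i])
    nFeat[i] <- length(subset)
    auc[i] <- tryCatch(
      cvAuc(subset, task, folds, config, foldSeed),
      error = function(e) stop("CV failed at threshold ", ths[i], ": ",
                               conditionMessage(e)))
  }
  best <- max(which(auc == max(auc)))  # ties -> larger threshold
  scan <- data.frame(threshold = ths, nFeatures = nFeat, auc = auc,
                     chosen = as.integer(seq_along(ths) == best))
  new("ThresholdScan", scan = scan, chosenThreshold = ths[best],
      chosenSubset = which(sp >= ths[best]))
}
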