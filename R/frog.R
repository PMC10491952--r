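# Components cannot exceed the feature count of a (sub)task.
.clampComponents <- function(config, nf) {
  if (config@nComponents <= nf) return(config)
  cfg <- config
  cfg@nComponents <- as.integer(nf)
  cfg
}

#' Sample a candidate subset cardinality
#'
#' Draws from Normal(q0, alpha * q0), rounds to the nearest integer, and
#' bounds the result into [1, p]. The standard deviation alpha * q0 makes
#' the typical jump proportional to the current cardinality: large
#' subsets allow large trans-dimensional moves, small ones keep the chain
#' local. The untruncated normal keeps every cardinality reachable from
#' every other — in particular a chain at a single feature can still grow
#' (truncating the proposal to within one standard deviation would make
#' cardinality 1 an absorbing state and freeze the chain there).
#'
#' @param q0 current cardinality (1 <= q0 <= p).
#' @param alpha variance factor (> 0); the normal's sd is alpha * q0.
#' @param p total number of features.
#' @return Integer cardinality in [1, p]. Uses the current RNG stream.
#' @export
sampleCardinality <- function(q0, alpha, p) {
  stopifnot(q0 >= 1L, q0 <= p, alpha > 0)
  d <- stats::rnorm(1L, mean = q0, sd = alpha * q0)
  as.integer(max(1, min(p, round(d))))
}

#' Rank the features of a subset by model importance
#'
#' Fits the predictor on the task restricted to `subset`; feature
#' importance is the magnitude of its regression coefficient |b_j|.
#' Returned indices are ordered by decreasing importance, ties broken by
#' ascending column index.
#'
#' @param subset integer feature indices.
#' @param task a [PredictionTask-class].
#' @param config a [DiplsConfig-class].
#' @return Integer vector: `subset` reordered by importance.
#' @export
rankFeatures <- function(subset, task, config = diplsConfig()) {
  subset <- sort(as.integer(subset))
  subTask <- applyFeatureSubset(task, subset)
  model <- fitDipls(subTask, .clampComponents(config, length(subset)))
  imp <- abs(model@b)
  subset[order(-imp, subset)]
}

#' Propose a candidate feature subset of a given cardinality
#'
#' Shrinking keeps the top-ranked features of the current subset; growing
#' pools the current subset with `ceil(mu * (qNew - |v0|))` features drawn
#' uniformly (without replacement) from outside it, ranks the pool, and
#' keeps the top `qNew` — so incumbent features can be displaced by
#' stronger newcomers. Equal cardinality returns the subset unchanged.
#'
#' @param v0 current feature subset (integer indices).
#' @param qNew target cardinality (1 <= qNew <= p).
#' @param mu candidate-pool expansion factor (>= 1).
#' @param task a [PredictionTask-class].
#' @param config a [DiplsConfig-class].
#' @return Integer vector of exactly `min(qNew, p)` feature indices.
#'   Uses the current RNG stream when growing.
#' @export
proposeSubset <- function(v0, qNew, mu, task, config = diplsConfig()) {
  p <- ncol(task@Xg)
  v0 <- sort(as.integer(v0))
  qNew <- as.integer(min(qNew, p))
  if (qNew == length(v0)) return(v0)
  if (qNew < length(v0)) {
    ranked <- rankFeatures(v0, task, config)
    return(sort(ranked[seq_len(qNew)]))
  }
  outside <- setdiff(seq_len(p), v0)
  nDraw <- min(ceiling(mu * (qNew - length(v0))), length(outside))
  drawn <- outside[sample.int(length(outside), nDraw)]
  ranked <- rankFeatures(sort(c(v0, drawn)), task, config)
  sort(ranked[seq_len(qNew)])
}

#' Cross-validated AUC of a feature subset
#'
#' Gene-stratified k-fold CV on the task restricted to `subset`: the
#' predictor is fitted on k-1 folds (isoforms follow their genes; fold
#' training matrices are re-centered on training rows only) and the
#' held-out genes are scored on their evaluable units — SIG isoforms
#' directly, MIGs by max-aggregation over their isoforms. Held-out
#' predictions are pooled over folds into one AUC. Deterministic given
#' `foldSeed`, and leaves the caller's RNG stream untouched.
#'
#' @param subset integer feature indices (non-empty).
#' @param task a [PredictionTask-class].
#' @param folds number of CV folds (>= 2).
#' @param config a [DiplsConfig-class].
#' @param foldSeed seed for the stratified fold assignment.
#' @return Pooled AUC in [0, 1].
#' @export
cvAuc <- function(subset, task, folds = 3L, config = diplsConfig(),
                  foldSeed = 1L) {
  if (length(subset) == 0L) stop("empty feature subset")
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  subTask <- applyFeatureSubset(task, subset)
  cfg <- .clampComponents(config, ncol(subTask@Xg))
  assign <- withr::with_seed(as.integer(foldSeed),
                             .stratifiedFolds(subTask@yg, folds))
  geneIds <- rownames(subTask@Xg)
  geneLabels <- stats::setNames(subTask@yg, geneIds)
  allScores <- numeric(0)
  allLabels <- numeric(0)
  for (f in seq_len(folds)) {
    testGenes <- geneIds[assign == f]
    if (length(testGenes) == 0L) next
    trainTask <- .taskSubsetGenes(subTask, geneIds[assign != f])
    model <- fitDipls(trainTask, cfg)
    testIso <- subTask@map@isoform[subTask@map@gene %in% testGenes]
    scores <- predictScores(model, .rawIsoformRows(subTask, testIso))
    units <- .evaluableUnits(scores, testGenes, subTask@map, geneLabels)
    allScores <- c(allScores, units$score)
    allLabels <- c(allLabels, units$label)
  }
  aucScore(allScores, allLabels)
}

#' Acceptance probability of a candidate subset
#'
#' An improving candidate (aucNew > auc0) is always accepted (P' = 1).
#' A non-improving one is accepted with probability
#' `omega * (aucNew + 0.001) / (auc0 + 0.001)`, which is at most `omega`;
#' the 0.001 guards the ratio when auc0 = 0. Occasional downhill moves
#' keep the chain from trapping in local optima while the low ceiling
#' preserves convergence toward good subsets.
#'
#' @param auc0 incumbent subset's AUC.
#' @param aucNew candidate subset's AUC.
#' @param omega ceiling in [0, 1].
#' @return Acceptance probability in [0, 1].
#' @examples
#' acceptanceProbability(0.70, 0.75, 0.1)  # 1
#' acceptanceProbability(0.75, 0.75, 0.1)  # exactly omega
#' @export
acceptanceProbability <- function(auc0, aucNew, omega) {
  stopifnot(auc0 >= 0, auc0 <= 1, aucNew >= 0, aucNew <= 1,
            omega >= 0, omega <= 1)
  if (aucNew > auc0) return(1)
  omega * (aucNew + 0.001) / (auc0 + 0.001)
}

#' Stochastic trans-dimensional feature-subset search
#'
#' A reversible-jump-flavoured chain over feature subsets: starting from
#' `qInit` uniformly drawn features, each iteration samples a candidate
#' cardinality ([sampleCardinality()]), builds a candidate subset
#' ([proposeSubset()]), scores incumbent and candidate by inner
#' cross-validated AUC on the same folds ([cvAuc()]; folds are re-seeded
#' deterministically per iteration from the master seed), and accepts the
#' candidate with probability [acceptanceProbability()]. The subset held
#' at the end of each iteration is recorded; after N iterations each
#' feature's selection probability is its count divided by N — the
#' measure of feature importance for the given term.
#'
#' @param task a [PredictionTask-class] (training genes only).
#' @param params a [FrogParams-class].
#' @param config a [DiplsConfig-class] for the inner models.
#' @return A [FrogResult-class]. Fully reproducible from `params@seed`.
#' @export
runFrog <- function(task, params = frogParams(), config = diplsConfig()) {
  p <- ncol(task@Xg)
  if (params@qInit > p)
    stop("qInit exceeds the number of features")
  N <- params@nIterations
  counts <- stats::setNames(integer(p), colnames(task@Xg))
  trajIter <- seq_len(N)
  trajCard <- integer(N)
  trajAuc0 <- trajAucNew <- numeric(N)
  trajAcc <- integer(N)
  withr::with_seed(params@seed, {
    v0 <- sort(sample.int(p, params@qInit))
    auc0 <- NA_real_
    for (iter in seq_len(N)) {
      foldSeed <- as.integer((params@seed + 7919 * iter) %% 2147483629)
      qNew <- sampleCardinality(length(v0), params@alpha, p)
      vNew <- proposeSubset(v0, qNew, params@mu, task, config)
      if (!params@cacheAuc0 || is.na(auc0))
        auc0 <- cvAuc(v0, task, params@innerCvFolds, config, foldSeed)
      aucNew <- if (identical(vNew, v0)) auc0 else
        cvAuc(vNew, task, params@innerCvFolds, config, foldSeed)
      pAcc <- acceptanceProbability(auc0, aucNew, params@omega)
      accepted <- stats::runif(1L) < pAcc
      trajAuc0[iter] <- auc0
      if (accepted) {
        v0 <- vNew
        auc0 <- aucNew
      }
      counts[v0] <- counts[v0] + 1L
      trajCard[iter] <- length(v0)
      trajAucNew[iter] <- aucNew
      trajAcc[iter] <- as.integer(accepted)
    }
  })
  new("FrogResult", counts = counts, probabilities = counts / N,
      nIterations = N,
      trajectory = data.frame(iteration = trajIter, cardinality = trajCard,
                              auc0 = trajAuc0, aucNew = trajAucNew,
                              accepted = trajAcc))
}
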