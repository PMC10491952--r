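#' Homolog-group-aware k-fold assignment
#'
#' Genes from the same homolog group (duplicated/related genes) are forced
#' into the same fold so that near-identical expression profiles cannot
#' leak between training and test. Genes absent from the group table form
#' singleton groups. Groups are assigned greedily, largest first, to the
#' currently smallest fold, which keeps fold sizes balanced; group order
#' among equal sizes is shuffled under `seed`, so the plan is
#' deterministic given the seed.
#'
#' @param genes character vector of gene ids.
#' @param groups optional data.frame with `gene_id`, `group_id` columns.
#' @param k number of folds (>= 2; there must be at least k groups).
#' @param seed RNG seed for the shuffle.
#' @return Named integer vector: fold index in 1..k per gene.
#' @examples
#' groupKfold(paste0("g", 1:10), k = 5, seed = 1)
#' @export
groupKfold <- function(genes, groups = NULL, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  groupOf <- stats::setNames(genes, genes)
  if (!is.null(groups)) {
    known <- groups$gene_id %in% genes
    groupOf[groups$gene_id[known]] <- paste0("grp:", groups$group_id[known])
  }
  members <- split(names(groupOf), unname(groupOf))
  if (length(members) < k)
    stop("fewer groups (", length(members), ") than folds (", k, ")")
  withr::with_seed(seed, {
    members <- members[sample.int(length(members))]
  })
  members <- members[order(-lengths(members))]  # stable: ties keep shuffle
  foldSize <- integer(k)
  fold <- stats::setNames(integer(length(genes)), genes)
  for (m in members) {
    f <- which.min(foldSize)
    fold[m] <- f
    foldSize[f] <- foldSize[f] + length(m)
  }
  fold
}

# Gene-stratified fold assignment for the inner CV: shuffle within class,
# deal round-robin, so every fold holds positives as long as there are at
# least as many positives as folds and the training side never loses a
# class for n_pos >= 2.
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic with half credit for ties:
#' (concordant + 0.5 * tied) / (n_pos * n_neg), computed via midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8, 0.3), c(1, 1, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation: scores are grouped by distinct value in
#' descending order and the area is
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}, the precision at each threshold
#' weighted by the recall it adds (no trapezoidal interpolation, which is
#' known to overstate PR area). With all scores tied this reduces to the
#' class prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, at least one positive.
#' @return AUPRC in [0, 1].
#' @export
auprcScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  if (np == 0L) stop("at least one positive required for AUPRC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- cumsum(y)[last]
  n <- seq_along(y)[last]
  prec <- tp / n
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Max-aggregated gene scores for multi-isoform genes
#'
#' MIGs have no isoform-level ground truth; for evaluation against gene
#' labels each MIG is scored by the maximum prediction score among its
#' isoforms (a positive gene needs only one function-carrying isoform).
#'
#' @param scores named numeric vector of isoform scores.
#' @param map a [GeneIsoformMap-class].
#' @return Named numeric vector, one score per MIG present in `scores`.
#' @export
migGeneScores <- function(scores, map) {
  migs <- migGenes(map)
  migs <- migs[vapply(migs, function(g)
    any(isoformsOf(map, g) %in% names(scores)), logical(1L))]
  if (length(migs) == 0L) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(migs, function(g) {
    iso <- intersect(isoformsOf(map, g), names(scores))
    if (length(iso) == 0L) stop("MIG ", g, " has no scored isoforms")
    max(scores[iso])
  }, numeric(1L))
  out
}

# Evaluable held-out units: one row per held-out gene. SIGs are scored by
# their single isoform; MIGs by the max over their scored isoforms.
.evaluableUnits <- function(scores, genes, map, geneLabels) {
  sig <- intersect(sigGenes(map), genes)
  mig <- intersect(migGenes(map), genes)
  rows <- list()
  if (length(sig)) {
    iso <- vapply(sig, function(g) isoformsOf(map, g)[1L], character(1L))
    rows[[1L]] <- data.frame(gene = sig, type = "SIG",
      score = unname(scores[iso]), label = unname(geneLabels[sig]),
      stringsAsFactors = FALSE)
  }
  if (length(mig)) {
    ms <- migGeneScores(scores, map)
    ms <- ms[intersect(names(ms), mig)]
    rows[[2L]] <- data.frame(gene = names(ms), type = "MIG",
      score = unname(ms), label = unname(geneLabels[names(ms)]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.safeMetric <- function(fn, scores, labels) {
  if (length(scores) == 0L) return(NA_real_)
  tryCatch(fn(scores, labels), error = function(e) NA_real_)
}

#' Per-feature differential-expression screening
#'
#' For every feature (RNA-seq experiment), a Welch two-sample t-test of
#' the positive genes' expression values against the negative genes',
#' with Benjamini-Hochberg adjustment across features. Small q-values
#' flag experiments in which annotated and unannotated genes are
#' differentially expressed, i.e. features relevant to the function.
#'
#' @param task a [PredictionTask-class]; each class must hold at least
#'   two genes.
#' @return data.frame with columns `feature`, `t`, `p`, `q`.
#' @export
featureRelevanceTtest <- function(task) {
  pos <- task@yg == 1
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("each class needs at least two genes for the t-test")
  res <- vapply(seq_len(ncol(task@Xg)), function(j) {
    a <- task@Xg[pos, j]
    b <- task@Xg[!pos, j]
    out <- tryCatch({
      ht <- stats::t.test(a, b)
      c(unname(ht$statistic), ht$p.value)
    }, error = function(e) c(NaN, NaN))
    if (!all(is.finite(out))) {
      # degenerate (constant) feature: no evidence either way unless the
      # two class means actually differ
      out <- if (isTRUE(all.equal(mean(a), mean(b)))) c(0, 1) else c(Inf, 0)
    }
    out
  }, numeric(2L))
  data.frame(feature = colnames(task@Xg), t = res[1L, ], p = res[2L, ],
             q = stats::p.adjust(res[2L, ], method = "BH"),
             stringsAsFactors = FALSE)
}

#' Run the full prediction pipeline with outer cross-validation
#'
#' For each outer fold: the stochastic feature search ([runFrog()]) and
#' threshold scan ([selectSubset()]) run on the training genes only, the
#' predictor is fitted on the selected features, and the held-out genes'
#' isoforms are scored. Feature selection never sees held-out genes.
#' Held-out performance is reported at SIG level (SIG isoforms vs gene
#' labels), MIG level (max-aggregated gene scores vs labels), and pooled
#' (both unit sets together).
#'
#' @param geneExpr genes x features matrix (raw expression).
#' @param isoExpr isoforms x features matrix (raw expression).
#' @param map a [GeneIsoformMap-class].
#' @param annotations data.frame with `gene_id`, `term_id`.
#' @param termId the term to predict.
#' @param params a [FrogParams-class] for the feature search.
#' @param config a [DiplsConfig-class] for the predictor.
#' @param kOuter outer folds (default 5).
#' @param groups optional homolog-group data.frame (`gene_id`,
#'   `group_id`); grouped genes share a fold.
#' @param seed seed for the outer fold plan and per-fold search seeds.
#' @param selectFeatures if `FALSE`, skip the search and use all features
#'   (baseline variant).
#' @return List with elements `report` (per-fold metric data.frame),
#'   `means` (column means of the report over folds), `predictions`
#'   (data.frame: isoform_id, score, probability, fold), and
#'   `foldSubsets` (list of selected feature indices per fold).
#' @export
runPipeline <- function(geneExpr, isoExpr, map, annotations, termId,
                        params = frogParams(), config = diplsConfig(),
                        kOuter = 5L, groups = NULL, seed = 1L,
                        selectFeatures = TRUE) {
  task <- buildTask(geneExpr, isoExpr, map, annotations, termId)
  geneLabels <- stats::setNames(task@yg, rownames(task@Xg))
  folds <- groupKfold(rownames(task@Xg), groups, kOuter, seed)
  report <- NULL
  preds <- NULL
  foldSubsets <- vector("list", kOuter)
  for (f in seq_len(kOuter)) {
    trainGenes <- names(folds)[folds != f]
    testGenes <- names(folds)[folds == f]
    if (length(testGenes) == 0L) next
    trainTask <- .taskSubsetGenes(task, trainGenes)
    if (selectFeatures) {
      foldParams <- params
      foldParams@seed <- as.integer((params@seed + 7919 * f) %% 2147483629)
      fr <- runFrog(trainTask, foldParams, config)
      scan <- selectSubset(fr, trainTask, config,
                           folds = params@innerCvFolds,
                           foldSeed = foldParams@seed)
      subset <- scan@chosenSubset
      subTask <- applyFeatureSubset(trainTask, subset)
    } else {
      subset <- seq_len(ncol(task@Xg))
      subTask <- trainTask
    }
    foldSubsets[[f]] <- subset
    model <- fitDipls(subTask, .clampComponents(config, length(subset)))
    testIso <- mappedIsoforms(task@map)[task@map@gene %in% testGenes]
    rawRows <- .rawIsoformRows(task, testIso)[, sort(subset), drop = FALSE]
    scores <- predictScores(model, rawRows)
    units <- .evaluableUnits(scores, testGenes, task@map, geneLabels)
    isSig <- units$type == "SIG"
    report <- rbind(report, data.frame(fold = f,
      sigAuc = .safeMetric(aucScore, units$score[isSig], units$label[isSig]),
      sigAuprc = .safeMetric(auprcScore, units$score[isSig],
                             units$label[isSig]),
      migAuc = .safeMetric(aucScore, units$score[!isSig],
                           units$label[!isSig]),
      migAuprc = .safeMetric(auprcScore, units$score[!isSig],
                             units$label[!isSig]),
      pooledAuc = .safeMetric(aucScore, units$score, units$label),
      pooledAuprc = .safeMetric(auprcScore, units$score, units$label)))
    preds <- rbind(preds, data.frame(isoform_id = names(scores),
      score = unname(scores), fold = f, stringsAsFactors = FALSE))
  }
  preds$probability <- scoresToProbabilities(preds$score)
  preds <- preds[, c("isoform_id", "score", "probability", "fold")]
  list(report = report,
       means = colMeans(report[, -1L, drop = FALSE], na.rm = TRUE),
       predictions = preds, foldSubsets = foldSubsets)
}
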