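#' Extract one domain-aligned weight vector
#'
#' Solves for the projection direction w minimizing
#' \deqn{\|X_{src} - y_{src} w^T\|_F^2 +
#'       \lambda\,|\mathrm{var}(X_{src} w) - \mathrm{var}(X_{tgt} w)|,}
#' i.e. the PLS1 covariance objective on the (stacked) source domain plus
#' a penalty on the latent-score variance gap between source and target.
#' Because the absolute value is non-smooth, both branches are solved in
#' closed form — \eqn{w \propto (y^T y\, I \pm \lambda \Delta)^{-1}
#' X_{src}^T y} with \eqn{\Delta} the symmetrized difference of the two
#' domain covariance matrices — and the branch with the lower objective
#' value is kept. With `lambda = 0` this reduces to the ordinary PLS1
#' weight \eqn{w \propto X^T y}.
#'
#' @param Xsrc source matrix (rows = labeled units), column-centered.
#' @param ysrc response vector (labels or deflated residuals).
#' @param Xtgt target-domain matrix with the same columns, column-centered.
#' @param lambda domain-regularizer penalty, >= 0.
#' @return Weight vector of length `ncol(Xsrc)`, unit Euclidean norm.
#' @export
fitWeightVector <- function(Xsrc, ysrc, Xtgt, lambda) {
  if (nrow(Xsrc) != length(ysrc))
    stop("nrow(Xsrc) must equal length(ysrc)")
  if (ncol(Xsrc) != ncol(Xtgt))
    stop("Xsrc and Xtgt must have the same number of columns")
  if (lambda < 0) stop("lambda must be >= 0")
  if (all(Xsrc == 0)) stop("all-zero source matrix")
  xy <- as.vector(crossprod(Xsrc, ysrc))
  yss <- sum(ysrc^2)
  if (lambda == 0 || yss == 0) {
    w <- xy
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("degenerate weight vector (X'y = 0)")
    return(w / nrm)
  }
  Cs <- crossprod(Xsrc) / max(1L, nrow(Xsrc) - 1L)
  Ct <- crossprod(Xtgt) / max(1L, nrow(Xtgt) - 1L)
  .weightSolve(Cs, Ct, xy, yss, sum(Xsrc^2), lambda)
}

# Shared closed-form solver working purely on covariance-level pieces:
# Cs/Ct the (p x p) domain covariances, xy = Xsrc'y, yss = y'y, trX2 =
# ||Xsrc||_F^2 (only needed for the branch comparison). Both branches of
# the absolute-value regularizer are solved and the one with the lower
# true objective is kept; ||Xsrc - y w'||_F^2 expands to
# trX2 - 2 w'xy + yss w'w, so no n x p temporaries are formed.
.weightSolve <- function(Cs, Ct, xy, yss, trX2, lambda) {
  p <- length(xy)
  D <- Cs - Ct
  D <- (D + t(D)) / 2
  solveBranch <- function(sgn) {
    A <- diag(yss, p) + sgn * lambda * D
    tryCatch(solve(A, xy), error = function(e) {
      # near-singular branch: fall back to a tiny ridge
      solve(A + diag(1e-10 * yss, p), xy)
    })
  }
  objective <- function(w) {
    trX2 - 2 * sum(w * xy) + yss * sum(w^2) +
      lambda * abs(sum(w * (Cs %*% w)) - sum(w * (Ct %*% w)))
  }
  wPlus <- solveBranch(1)
  wMinus <- solveBranch(-1)
  w <- if (objective(wPlus) <= objective(wMinus)) wPlus else wMinus
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate weight vector (X'y = 0)")
  as.vector(w) / nrm
}

# Isoform training stack shared by the relabeling loop and the fit:
# rows of SIG isoforms and of negative-MIG isoforms, labeled by their gene.
.milBase <- function(task) {
  map <- task@map
  geneLabel <- stats::setNames(task@yg, rownames(task@Xg))
  sig <- sigGenes(map)
  mig <- migGenes(map)
  negMig <- mig[geneLabel[mig] == 0]
  keep <- map@gene %in% c(sig, negMig)
  ids <- map@isoform[keep]
  list(ids = ids,
       X = task@Xiso[ids, , drop = FALSE],
       y = as.numeric(geneLabel[map@gene[keep]]),
       posMig = mig[geneLabel[mig] == 1],
       posSigIso = map@isoform[map@gene %in% sig[geneLabel[sig] == 1]])
}

#' Multiple-instance relabeling of positive-MIG isoforms
#'
#' A positive multi-isoform gene guarantees only that at least one of its
#' isoforms carries the function. This loop resolves that ambiguity:
#' starting from the unambiguous isoform training set (SIG isoforms and
#' all isoforms of negative MIGs, labeled by their gene), it (1) extracts
#' a weight vector on the stacked gene + isoform training data, (2) builds
#' a reference distribution by projecting the positive-SIG isoform rows,
#' (3) scores every isoform of a positive MIG by the absolute distance of
#' its projection to the reference mean, (4) relabels the closest isoform
#' of each positive MIG as positive, and repeats until the selected set is
#' unchanged or the iteration cap is hit (then warns). Selection replaces
#' the previous sweep's choices, so each positive MIG contributes at most
#' one positive row.
#'
#' If the task has no positive SIGs the reference falls back to the
#' positive gene rows (with a warning); with no positive MIGs the loop
#' returns the base stack immediately.
#'
#' @param task a [PredictionTask-class].
#' @param config a [DiplsConfig-class] (`lambda`, `maxMilIterations`).
#' @return A [MilState-class] with the augmented training stack and the
#'   per-positive-MIG selected isoforms.
#' @export
milUpdate <- function(task, config = diplsConfig()) {
  base <- .milBase(task)
  if (length(base$posMig) == 0L)
    return(new("MilState", X = base$X, y = base$y, rowIds = base$ids,
               selected = character(), iterations = 1L, converged = TRUE))
  map <- task@map
  posMigIso <- lapply(base$posMig, function(g) isoformsOf(map, g))
  names(posMigIso) <- base$posMig
  usePosSig <- length(base$posSigIso) > 0L
  if (!usePosSig)
    warning("no positive SIGs; reference distribution built from positive gene rows")
  selected <- character()
  iter <- 0L
  converged <- FALSE
  # the base stack is fixed across sweeps; only the handful of selected
  # positive-MIG rows changes, so the solver's covariance pieces are
  # updated incrementally instead of rebuilt from the full row stack
  lambda <- config@lambda
  if (lambda > 0) {
    Sbase <- crossprod(task@Xg) + crossprod(base$X)
    Ct <- crossprod(task@Xiso) / max(1L, nrow(task@Xiso) - 1L)
    trBase <- sum(task@Xg^2) + sum(base$X^2)
  }
  xyBase <- as.vector(crossprod(task@Xg, task@yg)) +
    as.vector(crossprod(base$X, base$y))
  yssBase <- sum(task@yg^2) + sum(base$y^2)
  nBase <- nrow(task@Xg) + nrow(base$X)
  repeat {
    iter <- iter + 1L
    selRows <- task@Xiso[unname(selected), , drop = FALSE]
    xy <- xyBase + colSums(selRows)
    yss <- yssBase + length(selected)
    w0 <- if (lambda > 0) {
      Cs <- (Sbase + crossprod(selRows)) /
        max(1L, nBase + length(selected) - 1L)
      .weightSolve(Cs, Ct, xy, yss, trBase + sum(selRows^2), lambda)
    } else {
      nrm <- sqrt(sum(xy^2))
      if (nrm == 0) stop("degenerate weight vector (X'y = 0)")
      xy / nrm
    }
    refProj <- if (usePosSig)
      task@Xiso[base$posSigIso, , drop = FALSE] %*% w0
    else
      task@Xg[task@yg == 1, , drop = FALSE] %*% w0
    refMean <- mean(refProj)
    newSel <- vapply(posMigIso, function(iso) {
      proj <- as.vector(task@Xiso[iso, , drop = FALSE] %*% w0)
      iso[which.min(abs(proj - refMean))]
    }, character(1L))
    if (identical(unname(newSel), unname(selected)) &&
        length(newSel) == length(selected)) {
      converged <- TRUE
      break
    }
    selected <- newSel
    if (iter >= config@maxMilIterations) {
      warning("relabeling loop did not converge within ",
              config@maxMilIterations, " iterations")
      break
    }
  }
  new("MilState",
      X = rbind(base$X, task@Xiso[unname(selected), , drop = FALSE]),
      y = c(base$y, rep(1, length(selected))),
      rowIds = c(base$ids, unname(selected)),
      selected = selected, iterations = iter, converged = converged)
}

#' Fit the domain-invariant PLS predictor
#'
#' Runs the multiple-instance relabeling loop (if enabled), then extracts
#' `nComponents` latent variables. In component k the weight vector w_k is
#' fitted on the current deflated stack of gene rows and labeled isoform
#' rows against the isoform matrix as the target domain; the loading
#' p_k = X't/(t't) and inner coefficient q_k = y't/(t't) are computed from
#' the stacked source, and the source stack, the response, and the isoform
#' matrix (with its own scores t_iso against the shared loading) are
#' deflated. The regression vector is \eqn{b = W (P^T W)^{-1} q}.
#'
#' @param task a [PredictionTask-class].
#' @param config a [DiplsConfig-class].
#' @return A [DiplsModel-class].
#' @examples
#' sim <- simulateIsoformData(nSig = 30, nMig = 10, nFeatures = 8,
#'                            nInformative = 3, seed = 7)
#' task <- buildTask(sim$geneExpr, sim$isoExpr, sim$map, sim$annotations,
#'                   "T1")
#' fit <- fitDipls(task, diplsConfig(nComponents = 3))
#' head(predictScores(fit, sim$isoExpr))
#' @export
fitDipls <- function(task, config = diplsConfig()) {
  nf <- ncol(task@Xg)
  if (config@nComponents > nf)
    stop("nComponents (", config@nComponents,
         ") exceeds the number of features (", nf, ")")
  selected <- character()
  milIter <- 0L
  if (config@milEnabled) {
    mil <- milUpdate(task, config)
    X <- rbind(task@Xg, mil@X)
    y <- c(task@yg, mil@y)
    selected <- mil@selected
    milIter <- mil@iterations
  } else {
    X <- task@Xg
    y <- task@yg
  }
  Xi <- task@Xiso
  nk <- config@nComponents
  W <- P <- matrix(0, nf, nk, dimnames = list(colnames(task@Xg), NULL))
  q <- numeric(nk)
  for (k in seq_len(nk)) {
    w <- fitWeightVector(X, y, Xi, config@lambda)
    t <- as.vector(X %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12)
      stop("residual source matrix degenerate at component ", k,
           "; reduce nComponents")
    p <- as.vector(crossprod(X, t)) / tt
    qk <- sum(y * t) / tt
    X <- X - tcrossprod(t, p)
    y <- y - t * qk
    ti <- as.vector(Xi %*% w)
    Xi <- Xi - tcrossprod(ti, p)
    W[, k] <- w
    P[, k] <- p
    q[k] <- qk
  }
  PtW <- crossprod(P, W)
  if (rcond(PtW) < 1e-12)
    stop("P'W numerically singular; reduce nComponents")
  b <- as.vector(W %*% solve(PtW, q))
  new("DiplsModel", W = W, P = P, q = q, b = b,
      isoCenter = task@isoCenter, featureNames = colnames(task@Xg),
      config = config, selected = selected, milIterations = milIter)
}

#' Score isoforms with a fitted model
#'
#' Computes `ypred = (X - columnMeans) b` where the column means are the
#' isoform-domain means stored at fit time. Higher scores mean the isoform
#' is more likely to carry the function.
#'
#' @param model a [DiplsModel-class].
#' @param newdata raw (uncentered) isoforms x features matrix whose
#'   columns match the model's feature space.
#' @return Named numeric score vector aligned to the rows of `newdata`.
#' @export
predictScores <- function(model, newdata) {
  if (ncol(newdata) != length(model@b))
    stop("column mismatch: model has ", length(model@b),
         " features, newdata has ", ncol(newdata))
  if (!is.null(colnames(newdata)) && length(model@featureNames) &&
      !identical(colnames(newdata), model@featureNames))
    stop("feature names of newdata do not match the model")
  centered <- sweep(newdata, 2L, model@isoCenter, "-")
  stats::setNames(as.vector(centered %*% model@b), rownames(newdata))
}

#' Convert prediction scores to probabilities
#'
#' Scores are scaled to unit variance (sign and zero point preserved) and
#' passed through the two-class softmax with logits (s, -s):
#' \eqn{p = e^{s}/(e^{s} + e^{-s})}. A score of exactly 0 maps to 0.5, and
#' p > 0.5 if and only if the raw score is positive, so classifying at
#' p > 0.5 is equivalent to thresholding scores at 0.
#'
#' @param scores finite numeric score vector.
#' @return Probabilities in (0, 1), same names as `scores`.
#' @examples
#' scoresToProbabilities(c(a = -1, b = 0, c = 2))
#' @export
scoresToProbabilities <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  s <- stats::sd(scores)
  z <- if (isTRUE(s > 0)) scores / s else scores
  stats::plogis(2 * z)
}

#' Serialize a fitted model to a portable JSON file
#'
#' Stores W, P, q, b, the centering means, the configuration and the
#' selected positive-MIG isoforms; [readDiplsModel()] restores the model.
#'
#' @param model a [DiplsModel-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDiplsModel <- function(model, path) {
  obj <- list(
    W = unclass(model@W), P = unclass(model@P), q = model@q, b = model@b,
    isoCenter = model@isoCenter, featureNames = model@featureNames,
    config = list(nComponents = model@config@nComponents,
                  lambda = model@config@lambda,
                  maxMilIterations = model@config@maxMilIterations,
                  milEnabled = model@config@milEnabled),
    selected = as.list(model@selected),
    milIterations = model@milIterations)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDiplsModel
#' @return `readDiplsModel` returns the restored [DiplsModel-class].
#' @export
readDiplsModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- diplsConfig(obj$config$nComponents, obj$config$lambda,
                     obj$config$maxMilIterations, obj$config$milEnabled)
  sel <- unlist(obj$selected)
  if (is.null(sel)) sel <- character()
  W <- as.matrix(obj$W)
  rownames(W) <- obj$featureNames
  P <- as.matrix(obj$P)
  rownames(P) <- obj$featureNames
  new("DiplsModel", W = W, P = P, q = as.numeric(obj$q),
      b = as.numeric(obj$b),
      isoCenter = stats::setNames(as.numeric(obj$isoCenter),
                                  obj$featureNames),
      featureNames = as.character(obj$featureNames), config = cfg,
      selected = sel, milIterations = as.integer(obj$milIterations))
}
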