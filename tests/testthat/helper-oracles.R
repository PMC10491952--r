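# Independent reference implementations used only to generate expected
# values in tests; deliberately written as the textbook procedures, not
# via the package's own code paths.

# NIPALS PLS1: weight = X'y normalized, scores/loadings/deflation,
# predictions accumulated component-wise (never via b = W (P'W)^-1 q).
nipalsPls1 <- function(X, y, k) {
  Xd <- X
  yd <- y
  pred <- numeric(nrow(X))
  comps <- list()
  for (i in seq_len(k)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    tt <- sum(t^2)
    p <- crossprod(Xd, t) / tt
    q <- sum(yd * t) / tt
    pred <- pred + as.vector(t) * q
    Xd <- Xd - tcrossprod(as.vector(t), as.vector(p))
    yd <- yd - as.vector(t) * q
    comps[[i]] <- list(w = as.vector(w), p = as.vector(p), q = q)
  }
  list(fitted = pred, comps = comps)
}

# Score new rows with the NIPALS model by sequential deflation.
nipalsPredict <- function(comps, Xnew) {
  Xd <- Xnew
  pred <- numeric(nrow(Xnew))
  for (cmp in comps) {
    t <- Xd %*% cmp$w
    pred <- pred + as.vector(t) * cmp$q
    Xd <- Xd - tcrossprod(as.vector(t), cmp$p)
  }
  pred
}

# AUC by exhaustive pair enumeration with half credit for ties.
pairCountAuc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# AUPRC by exhaustive enumeration of distinct thresholds: precision at
# each recall change, summed stepwise.
enumAuprc <- function(scores, labels) {
  np <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0
  area <- 0
  for (th in ths) {
    called <- scores >= th
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / np
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}
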