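#' Simulate a paired gene/isoform expression dataset
#'
#' Generates data with the structure the predictor assumes: isoform
#' profiles are Gaussian noise around a common baseline; function-carrying
#' isoforms (all isoforms of positive SIGs, and exactly one planted
#' "responsible" isoform per positive MIG) get a mean shift of
#' `effectSize * noiseSd` on a planted set of informative features; the
#' remaining ("decoy") isoforms of positive MIGs draw from the negative
#' profile distribution, so the multiple-instance ground truth is
#' well-defined. Gene expression is the column-wise mean of the gene's
#' isoform rows, so the gene baseline does not depend on how many
#' isoforms a gene has (a sum would make isoform count, not function,
#' the dominant axis of gene-level variance). `domainShift` optionally
#' scales
#' the isoform matrix about its column means after gene rows are formed,
#' planting a latent-variance gap between the two domains.
#'
#' Everything is deterministic given `seed`.
#'
#' @param nSig,nMig numbers of single- and multi-isoform genes.
#' @param isoformsPerMig isoforms per MIG: a single integer >= 2, or a
#'   length-2 range sampled per gene.
#' @param nFeatures number of features (RNA-seq experiments).
#' @param nInformative number of informative features
#'   (<= `nFeatures`).
#' @param effectSize mean shift of informative features for
#'   function-carrying isoforms, in units of `noiseSd`.
#' @param noiseSd Gaussian noise standard deviation.
#' @param positiveFraction fraction of genes (per SIG/MIG stratum)
#'   annotated to the term, in (0, 1).
#' @param domainShift variance scaling factor of the isoform matrix
#'   (1 = none).
#' @param termId term id written into the annotation table.
#' @param seed RNG seed.
#' @return List with `geneExpr`, `isoExpr` (matrices), `map`
#'   ([GeneIsoformMap-class]), `annotations` (data.frame), and `truth`
#'   (list: `informative` feature ids, `responsible` named vector
#'   positive-MIG -> isoform, `positives` gene ids).
#' @examples
#' sim <- simulateIsoformData(nSig = 20, nMig = 10, nFeatures = 12,
#'                            nInformative = 4, seed = 1)
#' dim(sim$geneExpr); dim(sim$isoExpr)
#' @export
simulateIsoformData <- function(nSig = 100L, nMig = 50L,
                                isoformsPerMig = 3L, nFeatures = 50L,
                                nInformative = 10L, effectSize = 2,
                                noiseSd = 1, positiveFraction = 0.3,
                                domainShift = 1, termId = "T1",
                                seed = 1L) {
  stopifnot(nSig >= 1L, nMig >= 0L, nFeatures >= 1L,
            nInformative <= nFeatures, nInformative >= 0L,
            noiseSd > 0, positiveFraction > 0, positiveFraction < 1,
            domainShift > 0)
  if (length(isoformsPerMig) == 1L) isoformsPerMig <- rep(isoformsPerMig, 2L)
  if (isoformsPerMig[1L] < 2L) stop("MIGs need at least 2 isoforms")
  baseline <- 5
  withr::with_seed(as.integer(seed), {
    featIds <- sprintf("e%d", seq_len(nFeatures))
    sigIds <- sprintf("gs%d", seq_len(nSig))
    migIds <- if (nMig > 0L) sprintf("gm%d", seq_len(nMig)) else character()
    informative <- sort(sample.int(nFeatures, nInformative))
    nPosSig <- max(1L, round(positiveFraction * nSig))
    posSig <- sort(sample(sigIds, nPosSig))
    posMig <- if (nMig > 0L)
      sort(sample(migIds, max(1L, round(positiveFraction * nMig))))
    else character()
    isoRange <- seq(isoformsPerMig[1L], isoformsPerMig[2L])
    nIsoPerMig <- if (nMig > 0L) {
      if (length(isoRange) == 1L) rep(isoRange, nMig)
      else sample(isoRange, nMig, replace = TRUE)
    } else integer()
    mapGene <- c(sigIds, rep(migIds, nIsoPerMig))
    mapIso <- c(paste0(sigIds, ".i1"),
                unlist(lapply(seq_along(migIds), function(i)
                  paste0(migIds[i], ".i", seq_len(nIsoPerMig[i])))))
    nIso <- length(mapIso)
    Xiso <- matrix(stats::rnorm(nIso * nFeatures, baseline, noiseSd),
                   nrow = nIso, dimnames = list(mapIso, featIds))
    responsible <- stats::setNames(character(length(posMig)), posMig)
    for (g in posMig)
      responsible[g] <- sample(mapIso[mapGene == g], 1L)
    carriers <- c(paste0(posSig, ".i1"), unname(responsible))
    if (nInformative > 0L && length(carriers))
      Xiso[carriers, informative] <-
        Xiso[carriers, informative] + effectSize * noiseSd
    sums <- rowsum(Xiso, group = mapGene)
    Xg <- (sums / as.vector(table(mapGene)[rownames(sums)]))[
      c(sigIds, migIds), , drop = FALSE]
    if (domainShift != 1) {
      mu <- colMeans(Xiso)
      Xiso <- sweep(sweep(Xiso, 2L, mu, "-") * domainShift, 2L, mu, "+")
    }
    positives <- c(posSig, posMig)
    list(geneExpr = Xg, isoExpr = Xiso,
         map = GeneIsoformMap(mapGene, mapIso),
         annotations = data.frame(gene_id = positives,
                                  term_id = rep(termId, length(positives)),
                                  stringsAsFactors = FALSE),
         truth = list(informative = featIds[informative],
                      responsible = responsible, positives = positives))
  })
}
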