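# Small deterministic fixtures shared across test files.

# A tiny task built by hand: 4 SIGs + 2 MIGs (2 isoforms each), 3 features.
tinyTask <- function(posGenes = c("g1", "g5")) {
  genes <- paste0("g", 1:6)
  mapGene <- c("g1", "g2", "g3", "g4", "g5", "g5", "g6", "g6")
  mapIso <- c("g1.i1", "g2.i1", "g3.i1", "g4.i1",
              "g5.i1", "g5.i2", "g6.i1", "g6.i2")
  set.seed(42)
  Xiso <- matrix(rnorm(8 * 3, 5, 1), 8, 3,
                 dimnames = list(mapIso, c("e1", "e2", "e3")))
  Xg <- rowsum(Xiso, mapGene)[genes, ]
  ann <- data.frame(gene_id = posGenes, term_id = "T1")
  buildTask(Xg, Xiso, GeneIsoformMap(mapGene, mapIso), ann, "T1")
}

# A seeded random PLS task with no isoform structure beyond 1:1 SIGs,
# for comparing against the PLS1 oracle (nGenes x nFeatures).
randomSigTask <- function(nGenes = 50, nFeatures = 10, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  iso <- paste0(genes, ".i1")
  Xiso <- matrix(rnorm(nGenes * nFeatures), nGenes, nFeatures,
                 dimnames = list(iso, paste0("e", seq_len(nFeatures))))
  Xg <- Xiso
  rownames(Xg) <- genes
  y <- rep(0:1, length.out = nGenes)[sample.int(nGenes)]
  ann <- data.frame(gene_id = genes[y == 1], term_id = "T1")
  buildTask(Xg, Xiso, GeneIsoformMap(genes, iso), ann, "T1")
}

# Plain diPLS configuration: no isoform stacking, no relabeling loop.
plainConfig <- function(nComponents = 2, lambda = 0) {
  diplsConfig(nComponents = nComponents, lambda = lambda,
              milEnabled = FALSE)
}
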