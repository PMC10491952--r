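test_that("group-aware folds never split a homolog group and balance sizes", {
  # 10 singleton genes into 5 folds of 2
  plan <- groupKfold(paste0("g", 1:10), k = 5, seed = 1)
  expect_true(all(table(plan) == 2))
  # one 6-gene group among 20 genes stays together
  genes <- paste0("g", 1:20)
  grp <- data.frame(gene_id = genes[1:6], group_id = "h1")
  plan2 <- groupKfold(genes, grp, k = 5, seed = 2)
  expect_length(unique(plan2[genes[1:6]]), 1L)
  expect_error(groupKfold(paste0("g", 1:4), k = 5), "fewer groups")
  # property: across random group structures no group is ever split
  for (s in 1:25) {
    set.seed(s)
    n <- sample(12:40, 1)
    g <- paste0("g", seq_len(n))
    gid <- sample(paste0("h", 1:6), n, replace = TRUE)
    plan <- groupKfold(g, data.frame(gene_id = g, group_id = gid),
                       k = sample(2:4, 1), seed = s)
    expect_true(all(tapply(plan, gid, function(x) length(unique(x))) == 1))
  }
})

test_that("AUC matches exhaustive pair counting on random small instances", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  expect_equal(aucScore(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(aucScore(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 1, 0)), 1)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:20, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(aucScore(sc, lb), pairCountAuc(sc, lb))
  }
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(60)
  lb <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucScore(sc, lb), ref, tolerance = 1e-12)
})

test_that("AUPRC matches exhaustive threshold enumeration", {
  expect_equal(auprcScore(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auprcScore(rep(1, 8), c(1, 0, 0, 1, 0, 0, 0, 0)), 0.25)
  expect_error(auprcScore(1:3, c(0, 0, 0)), "positive")
  for (s in 1:100) {
    set.seed(200 + s)
    n <- sample(3:20, 1)
    sc <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    lb <- c(1, sample(0:1, n - 1, replace = TRUE))
    expect_equal(auprcScore(sc, lb), enumAuprc(sc, lb))
  }
})

test_that("MIG scores are the max over isoforms and order-invariant", {
  map <- GeneIsoformMap(c("g1", "g2", "g2", "g3", "g3", "g3"),
                        c("a", "b1", "b2", "c1", "c2", "c3"))
  sc <- c(a = 0.5, b1 = 0.2, b2 = 0.7, c1 = 0.1, c2 = 0.1, c3 = 0.1)
  ms <- migGeneScores(sc, map)
  expect_equal(ms, c(g2 = 0.7, g3 = 0.1))
  expect_equal(migGeneScores(sc[sample(names(sc))], map), ms)
  # a MIG with no scored isoforms is simply absent from the result
  ms2 <- migGeneScores(sc[c("a", "b1", "b2")], map)
  expect_identical(names(ms2), "g2")
})

test_that("per-feature t-test screening matches closed-form references", {
  set.seed(31)
  n <- 50
  genes <- paste0("g", seq_len(2 * n))
  iso <- paste0(genes, ".i1")
  X <- cbind(strong = c(rnorm(n, 10), rnorm(n, 0)),
             null = rnorm(2 * n),
             same = rep(1, 2 * n))
  rownames(X) <- iso
  Xg <- X
  rownames(Xg) <- genes
  ann <- data.frame(gene_id = genes[1:n], term_id = "T1")
  task <- buildTask(Xg, X, GeneIsoformMap(genes, iso), ann, "T1")
  tab <- featureRelevanceTtest(task)
  expect_lt(tab$q[tab$feature == "strong"], 1e-10)
  expect_gt(tab$q[tab$feature == "null"], 0.05)
  expect_equal(tab$p[tab$feature == "same"], 1)
  # agrees with stats::t.test directly
  ref <- t.test(X[1:n, "null"], X[(n + 1):(2 * n), "null"])
  expect_equal(tab$p[tab$feature == "null"], ref$p.value)
  # Benjamini-Hochberg hand check
  expect_equal(p.adjust(c(0.01, 0.02, 0.9), "BH"), c(0.03, 0.03, 0.9))
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
})

test_that("the pipeline is deterministic and leakage-guarded", {
  sim <- simulateIsoformData(nSig = 36, nMig = 12, nFeatures = 12,
                             nInformative = 4, effectSize = 2.5, seed = 21)
  pr <- frogParams(nIterations = 10L, seed = 5L)
  cfg <- diplsConfig(nComponents = 3)
  run1 <- suppressWarnings(runPipeline(sim$geneExpr, sim$isoExpr, sim$map,
    sim$annotations, "T1", pr, cfg, kOuter = 3, seed = 9))
  run2 <- suppressWarnings(runPipeline(sim$geneExpr, sim$isoExpr, sim$map,
    sim$annotations, "T1", pr, cfg, kOuter = 3, seed = 9))
  expect_identical(run1$report, run2$report)
  expect_identical(run1$predictions, run2$predictions)
  expect_true(all(unlist(run1$report[, -1]) >= 0 &
                    unlist(run1$report[, -1]) <= 1, na.rm = TRUE))
  # report means recompute from per-fold rows
  expect_equal(unname(run1$means["pooledAuc"]),
               mean(run1$report$pooledAuc, na.rm = TRUE))
  # every held-out isoform scored exactly once
  expect_setequal(run1$predictions$isoform_id, mappedIsoforms(sim$map))
  expect_false(anyDuplicated(run1$predictions$isoform_id) > 0)
})

test_that("feature selection for a fold ignores held-out gene content", {
  sim <- simulateIsoformData(nSig = 30, nMig = 10, nFeatures = 10,
                             nInformative = 3, effectSize = 2.5, seed = 14)
  task <- buildTask(sim$geneExpr, sim$isoExpr, sim$map, sim$annotations,
                    "T1")
  genes <- rownames(sim$geneExpr)
  folds <- groupKfold(genes, k = 3, seed = 4)
  trainGenes <- names(folds)[folds != 1]
  heldOut <- names(folds)[folds == 1]
  pr <- frogParams(nIterations = 8L, seed = 3L)
  cfg <- plainConfig(nComponents = 2)
  trainTask <- isopls:::.taskSubsetGenes(task, trainGenes)
  fr1 <- suppressWarnings(runFrog(trainTask, pr, cfg))
  # rebuild the dataset with held-out genes' values replaced by noise:
  # training-fold selection must not change
  set.seed(99)
  gE <- sim$geneExpr
  iE <- sim$isoExpr
  hoIso <- mappedIsoforms(sim$map)[sim$map@gene %in% heldOut]
  gE[heldOut, ] <- rnorm(length(heldOut) * ncol(gE), 5, 1)
  iE[hoIso, ] <- rnorm(length(hoIso) * ncol(iE), 5, 1)
  task2 <- buildTask(gE, iE, sim$map, sim$annotations, "T1")
  trainTask2 <- isopls:::.taskSubsetGenes(task2, trainGenes)
  fr2 <- suppressWarnings(runFrog(trainTask2, pr, cfg))
  expect_identical(selectionCounts(fr1), selectionCounts(fr2))
})

test_that("a training fold that loses a label class is an error", {
  sim <- simulateIsoformData(nSig = 12, nMig = 4, nFeatures = 6,
                             nInformative = 2, seed = 2)
  task <- buildTask(sim$geneExpr, sim$isoExpr, sim$map, sim$annotations,
                    "T1")
  negGenes <- rownames(sim$geneExpr)[task@yg == 0]
  expect_error(isopls:::.taskSubsetGenes(task, negGenes),
               "loses a label class")
})
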