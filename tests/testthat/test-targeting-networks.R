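test_that("bipartite construction drops isolated candidates", {
  u <- makeUniverse(c("m1", "m1", "m2"), c("G1", "G2", "G1"))
  bn <- buildBipartite(u, c("m1"), c("G1"))
  expect_identical(nrow(edges(bn)), 1L)
  expect_identical(mirnaNodes(bn), "m1")
  expect_identical(geneNodes(bn), "G1")

  bn2 <- buildBipartite(u, c("m1", "m2"), c("G1", "G2", "G_untargeted"))
  expect_false("G_untargeted" %in% geneNodes(bn2))

  full <- makeUniverse(rep(c("m1", "m2"), each = 3),
                       rep(c("G1", "G2", "G3"), 2))
  bn3 <- buildBipartite(full, c("m1", "m2"), c("G1", "G2", "G3"))
  expect_identical(nrow(edges(bn3)), 6L)
  expect_error(buildBipartite(u, character(), "G1"), "nonempty")
})

test_that("average neighbors equals 2E/V on degree-positive nodes", {
  u1 <- makeUniverse("m1", "G1")
  expect_equal(averageNeighbors(buildBipartite(u1, "m1", "G1")), 1.0)

  star <- makeUniverse(rep("m1", 4), paste0("G", 1:4))
  expect_equal(averageNeighbors(buildBipartite(star, "m1", paste0("G", 1:4))),
               1.6)

  for (a in 1:3) for (b in 1:4) {
    cb <- makeUniverse(rep(paste0("m", 1:a), each = b),
                       rep(paste0("G", 1:b), a))
    net <- buildBipartite(cb, paste0("m", 1:a), paste0("G", 1:b))
    expect_equal(averageNeighbors(net), 2 * a * b / (a + b))
  }
})

test_that("miRNA over-targeting p-values match exhaustive enumeration", {
  # hand case: N=10 expressed targetable, miRNA targets 5, 2 DE, both hit
  u <- makeUniverse(rep("m1", 5), paste0("G", 1:5))
  res <- mirnaOvertargeting(u, "m1", deSet = c("G1", "G2"),
                            expressed = paste0("G", 1:10))
  # population is restricted to targetable genes (G1..G5 here)
  expect_identical(res$table$N, 5L)

  # richer universe where every expressed gene is targetable
  withr::with_seed(42, {
    for (rep_ in 1:5) {
      N <- sample(6:12, 1)
      genes <- paste0("G", seq_len(N))
      anchor <- makeUniverse(rep("m0", N), genes)   # makes all genes targetable
      K <- sample(2:(N - 1), 1)
      tg <- sample(genes, K)
      n <- sample(2:(N - 1), 1)
      de <- sample(genes, n)
      u2 <- new("InteractionUniverse",
                edges = rbind(edges(anchor),
                              data.frame(mirna_id = "m1", gene_symbol = tg,
                                         status = "predicted", n_tools = 4L)),
                minTools = 4L)
      res2 <- mirnaOvertargeting(u2, "m1", de, genes)
      k <- length(intersect(tg, de))
      expect_equal(res2$table$p, hyperOracleEnum(k, N, K, n),
                   tolerance = 1e-12)
    }
  })

  # zero DE targets -> p = 1; miRNA without expressed targets is excluded
  res3 <- mirnaOvertargeting(u, c("m1", "mX"), deSet = "G9",
                             expressed = c(paste0("G", 1:5), "G9"))
  expect_error(mirnaOvertargeting(u, "m1", "not-expressed", "G1"), "subset")
  expect_identical(res3$excluded, "mX")
})

test_that("per-mRNA over-targeting swaps the sampling roles", {
  # 5-miRNA universe, 3 DE, gene targeted by all 3 DE miRNAs
  u <- makeUniverse(c(paste0("m", 1:5), paste0("m", 1:3)),
                    c(rep("Ganchor", 5), rep("G1", 3)))
  res <- mrnaOvertargeting(u, c("G1", "Gsolo"), mirnaDeSet = paste0("m", 1:3),
                           expressedMirnas = paste0("m", 1:5))
  expect_equal(res$table$p[res$table$gene_symbol == "G1"],
               1 / 10)                       # C(3,3)C(2,0)/C(5,3)
  # gene with <= 1 targeting miRNA excluded
  expect_true("Gsolo" %in% res$excluded)
  # no DE miRNAs among targeting set -> p = 1
  res2 <- mrnaOvertargeting(u, "G1", mirnaDeSet = c("m4", "m5")[0],
                            expressedMirnas = paste0("m", 1:5))
  expect_equal(res2$table$p, 1)
})

test_that("randomized nulls are exact when sampling the whole universe", {
  u <- makeUniverse(rep(c("m1", "m2"), each = 3),
                    rep(paste0("G", 1:3), 2))
  genes <- paste0("G", 1:3)
  obs <- averageNeighbors(buildBipartite(u, c("m1", "m2"), genes))
  ns <- randomizeNetworks(u, c("m1", "m2"), genes, geneSetSize = 3,
                          R = 20, seed = 1)
  expect_true(all(ns@meanDegree == obs))
  ns2 <- randomizeNetworks(u, c("m1", "m2"), genes, geneSetSize = 3,
                           R = 20, seed = 1)
  expect_identical(ns@meanDegree, ns2@meanDegree)
  expect_identical(ns@overtargetProp, ns2@overtargetProp)
  expect_error(randomizeNetworks(u, "m1", genes, 10, R = 5, seed = 1),
               "exceeds")
})

test_that("Monte Carlo null mean degree matches exhaustive enumeration", {
  # tiny universe: 6 genes, sample 3; compare against the average over all
  # C(6,3) = 20 subsets
  genes <- paste0("G", 1:6)
  ed <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2", "m3"),
    gene_symbol = c("G1", "G2", "G3", "G2", "G4", "G5"),
    status = "predicted", n_tools = 4L, stringsAsFactors = FALSE)
  u <- new("InteractionUniverse", edges = ed, minTools = 4L)
  mirs <- c("m1", "m2", "m3")
  subsets <- combn(6, 3)
  exact <- mean(apply(subsets, 2, function(idx) {
    gs <- genes[idx]
    keep <- ed$gene_symbol %in% gs
    if (!any(keep)) return(0)
    nE <- sum(keep)
    nV <- length(unique(ed$mirna_id[keep])) +
      length(unique(ed$gene_symbol[keep]))
    2 * nE / nV
  }))
  ns <- randomizeNetworks(u, mirs, genes, geneSetSize = 3, R = 10000,
                          seed = 3)
  se <- sd(ns@meanDegree) / sqrt(ns@R)
  expect_lt(abs(mean(ns@meanDegree) - exact), 3 * se)
})

test_that("published over-targeting proportions reject the null split", {
  pos <- proportionGofTest(38, 48, 0.49)
  expect_lt(pos$p, 1e-4)
  neg <- proportionGofTest(10, 41, 0.49)
  expect_lt(abs(neg$p - 0.0016) / 0.0016, 0.10)
})

test_that("network contrast report flags enrichment and round-trips", {
  d <- generateDataset(simConfig(nGenes = 400, nMirnas = 40,
    moduleSpecs = data.frame(module = c("M1", "M2"), size = c(60L, 50L),
                             traitCor = c(0.7, -0.7)),
    deFractionGenes = 110 / 400, overtargetEnrichment = 4,
    baselineEdgeProb = 0.04, seed = 2))
  mir <- callDE(fitModeratedT(d$mirna), 0.10)
  gene <- callDE(fitModeratedT(d$mrna), 0.01)
  expressed <- rownames(exprValues(d$mrna))
  tg <- targetableGenes(d$universe, expressed)
  run <- function(gs, lbl, nm) {
    list(network = buildBipartite(d$universe, mir$up, gs, label = lbl),
         null = randomizeNetworks(d$universe, mir$up, tg,
                                  length(intersect(gs, tg)), R = 100,
                                  seed = substreamSeed(2, nm)),
         ot = mirnaOvertargeting(d$universe, mir$up, gs, expressed))
  }
  pos <- run(gene$up, "positive", "p")
  neg <- run(gene$down, "negative", "n")
  rep_ <- networkContrastReport(pos$network, neg$network, pos$null, neg$null,
                                pos$ot, neg$ot)
  expect_identical(rep_$flag[rep_$network == "positive"], "enriched")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeTsv(rep_, tmp)
  back <- readTsv(tmp)
  expect_equal(back$mean_degree, rep_$mean_degree, tolerance = 1e-12)
  expect_identical(back$flag, rep_$flag)
})
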