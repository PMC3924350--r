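test_that("signed similarity maps correlation onto [0, 1]", {
  v <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),        # r = 1
             g3 = c(4, 3, 2, 1),        # r = -1 vs g1
             g4 = c(1, -1, -1, 1))      # r = 0 vs g1
  colnames(v) <- paste0("s", 1:4)
  S <- signedSimilarity(v)
  expect_equal(S["g1", "g2"], 1)
  expect_equal(S["g1", "g3"], 0)
  expect_equal(S["g1", "g4"], 0.5)
  expect_true(isSymmetric(unname(S)))
  expect_true(all(diag(S) == 1))

  vz <- rbind(v, g5 = rep(3, 4))
  expect_warning(S2 <- signedSimilarity(vz), "zero-variance")
  expect_false("g5" %in% rownames(S2))
})

test_that("soft adjacency is an elementwise monotone power", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  a <- softAdjacency(S, 12)
  expect_equal(a[1, 2], 0.5^12)
  expect_equal(a[1, 1], 1)
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(softAdjacency(s, 7)) >= 0))
  expect_error(softAdjacency(S, 0.5), "beta")
})

test_that("scale-free fit is exact on a power-law histogram", {
  # frequencies 64,16,4,1 at k = 1,2,4,8: slope -2 on the log-log plot
  k <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  fit <- scaleFreeFit(k)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(scaleFreeFit(rep(3, 50))$r2, 0)
})

test_that("scale-free fit is high for a preferential-attachment graph", {
  skip_if_not_installed("igraph")
  g <- withr::with_seed(8, igraph::sample_pa(400, m = 2, directed = FALSE))
  fit <- scaleFreeFit(igraph::degree(g))
  expect_gt(fit$r2, 0.8)
  expect_lt(fit$slope, 0)
})

test_that("soft-threshold selection honors the target and the grid", {
  skip_if_not_installed("igraph")
  # preferential-attachment adjacency: connectivity is scale-free, so the
  # smallest power already reaches the fit target
  g <- withr::with_seed(15, igraph::sample_pa(300, m = 2,
                                              directed = FALSE))
  S <- as.matrix(igraph::as_adjacency_matrix(g))
  diag(S) <- 1
  dimnames(S) <- list(paste0("g", 1:300), paste0("g", 1:300))
  res <- pickSoftThreshold(S, betaGrid = c(1, 2, 3), r2Target = 0.8)
  expect_gte(max(res$table$r2), 0.8)
  expect_identical(res$beta,
                   res$table$beta[min(which(res$table$r2 >= 0.8))])

  # expression data without scale-free structure: argmax fallback
  d <- generateDataset(simConfig(nGenes = 300, nMirnas = 20, seed = 4,
    moduleSpecs = data.frame(module = c("M1", "M2"), size = c(60L, 50L),
                             traitCor = c(0.7, -0.7)),
    deFractionGenes = 110 / 300))
  resF <- pickSoftThreshold(d$mrna, betaGrid = c(2, 6, 12),
                            r2Target = 0.999)
  expect_identical(resF$beta,
                   resF$table$beta[which.max(resF$table$r2)])
  one <- pickSoftThreshold(d$mrna, betaGrid = 12)
  expect_identical(one$beta, 12)
  expect_error(pickSoftThreshold(d$mrna, betaGrid = numeric()), "nonempty")
})

test_that("topological overlap matches hand and brute-force computations", {
  a <- matrix(c(1, 0.8, 0.6,
                0.8, 1, 0,
                0.6, 0, 1), 3, 3)
  tom <- topologicalOverlap(a)
  expect_equal(tom[2, 3], 0.48 / 1.6)
  expect_equal(tom[1, 2], 0.8 / 1.0)
  expect_true(all(diag(tom) == 1))

  for (s in 1:5) {
    a20 <- randomAdjacency(20, seed = s)
    expect_equal(topologicalOverlap(a20), tomOracle(a20), tolerance = 1e-12)
  }
  expect_error(topologicalOverlap(matrix(1:4, 2, 2)), "symmetric")
})

test_that("module detection separates clean blocks and handles edge cases", {
  d <- matrix(1, 40, 40)
  d[1:20, 1:20] <- 0
  d[21:40, 21:40] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:40)
  labels <- detectModules(d, minModuleSize = 10, cutHeight = 0.99)
  expect_identical(sort(unique(labels)), c("blue", "turquoise"))
  expect_identical(unname(table(labels)["turquoise"]), 20L)
  expect_false("grey" %in% labels)

  expect_warning(all_grey <- detectModules(d, minModuleSize = 100),
                 "exceeds")
  expect_true(all(all_grey == "grey"))
})

test_that("independent noise genes stay overwhelmingly grey", {
  for (s in 1:3) {
    v <- matrix(withr::with_seed(s, rnorm(600 * 32)), 600, 32,
                dimnames = list(paste0("g", 1:600), paste0("s", 1:32)))
    tom <- topologicalOverlap(softAdjacency(signedSimilarity(v), 12))
    labels <- detectModules(1 - tom, minModuleSize = 50, cutHeight = 0.99,
                            expr = v)
    expect_gte(mean(labels == "grey"), 0.9)
  }
})

test_that("module eigengenes are unit-norm first singular directions", {
  pm <- plantModules(60, data.frame(module = c("A", "B"),
                                    size = c(25L, 20L),
                                    traitCor = c(0.6, -0.4)),
                     nSamples = 16, noiseSd = 0.1, seed = 3)
  me <- moduleEigengenes(pm$values, pm$labels[pm$labels != "noise"])
  expect_identical(colnames(me), c("A", "B"))
  expect_equal(unname(colSums(me^2)), c(1, 1), tolerance = 1e-12)

  # independent eigen-decomposition oracle on the standardized submatrix
  genesA <- names(pm$labels)[pm$labels == "A"]
  Z <- t(scale(t(pm$values[genesA, ])))
  ev <- eigen(crossprod(Z), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(unname(me[, "A"])), abs(ev), tolerance = 1e-8)

  # sign convention: non-negative correlation with the average profile
  expect_gte(cor(me[, "A"], colMeans(Z)), 0)

  # identical genes: eigengene proportional to the shared profile
  ident <- matrix(rep(c(1, 5, 3, 2), times = 4), 4, 4, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  meI <- moduleEigengenes(ident, setNames(rep("A", 4), rownames(ident)))
  zshared <- as.numeric(scale(c(1, 5, 3, 2)))
  expect_equal(abs(cor(meI[, 1], zshared)), 1, tolerance = 1e-10)
})

test_that("eigengene projection variance dominates single-gene projections", {
  pm <- plantModules(30, data.frame(module = "A", size = 30L,
                                    traitCor = 0.5),
                     nSamples = 20, noiseSd = 0.3, seed = 6)
  Z <- t(scale(t(pm$values)))
  me <- moduleEigengenes(pm$values, pm$labels)
  varME <- sum((Z %*% me[, 1])^2)
  for (g in sample(rownames(Z), 5)) {
    u <- Z[g, ] / sqrt(sum(Z[g, ]^2))
    expect_gte(varME + 1e-10, sum((Z %*% u)^2))
  }
})

test_that("correlation p-values reproduce the published module table", {
  expect_equal(corPvalueStudent(0, 30), 1)
  expect_equal(corPvalueStudent(1, 30), 0)
  ref <- readTsv(extdata("module_trait_reference.tsv"))
  p <- corPvalueStudent(ref$r, 32)
  expect_true(all(abs(p - ref$p) / ref$p < 0.10))
  expect_error(corPvalueStudent(0.5, 2), "n >= 3")
})

test_that("trait statistics: GS, MM, module-trait and module-miRNA grids", {
  pm <- plantModules(80, data.frame(module = c("A", "B"),
                                    size = c(30L, 25L),
                                    traitCor = c(0.9, -0.5)),
                     nSamples = 32, noiseSd = 0.1, seed = 2)
  trait <- setNames(pm$trait, colnames(pm$values))
  me <- moduleEigengenes(pm$values, pm$labels[pm$labels != "noise"])
  # a pseudo-miRNA equal to module A's latent profile
  mir <- matrix(pm$latents[, "A"], 1, dimnames = list("mirX",
                                                      colnames(pm$values)))
  ms <- relateToTraits(pm$values, me, trait, mirnaProfiles = mir,
                       labels = pm$labels)

  # gene identical to the trait has |GS| = 1
  v2 <- rbind(pm$values, traitgene = trait)
  ms2 <- relateToTraits(v2, me, trait)
  expect_equal(abs(unname(geneSignificance(ms2)["traitgene"])), 1,
               tolerance = 1e-12)

  mt <- moduleTraitTable(ms)
  expect_gt(mt$r[mt$module == "A"], 0.7)
  expect_lt(mt$p[mt$module == "A"], 0.01)
  mg <- moduleMirnaTable(ms)
  expect_identical(nrow(mg), 2L)
  expect_true(mg$significant[mg$module == "A"])

  expect_error(relateToTraits(pm$values, me, trait[-1]), "missing")
})

test_that("planted trait correlation survives to the detected eigengene", {
  hit <- 0
  for (s in 1:10) {
    pm <- plantModules(120, data.frame(module = "A", size = 60L,
                                       traitCor = 0.9),
                       nSamples = 32, noiseSd = 0.1, seed = s)
    tom <- topologicalOverlap(softAdjacency(signedSimilarity(pm$values), 12))
    labels <- detectModules(1 - tom, minModuleSize = 30, cutHeight = 0.99,
                            expr = pm$values)
    mods <- setdiff(unique(labels), "grey")
    if (!length(mods)) next
    me <- moduleEigengenes(pm$values, labels)
    if (max(abs(cor(me, pm$trait))) >= 0.7) hit <- hit + 1
  }
  expect_gte(hit, 9)
})

test_that("module overlap is hypergeometric per cell and warns on mismatch", {
  labs <- setNames(rep(c("red", "blue"), c(6, 6)), paste0("g", 1:12))
  ov <- moduleOverlap(labs, labs)
  # identical assignments: diagonal cells carry the minimal p in their row
  for (m in c("red", "blue")) {
    rows <- ov[ov$module_a == m, ]
    expect_identical(rows$module_b[which.min(rows$p)], m)
  }
  # enumeration oracle on every cell
  for (i in seq_len(nrow(ov))) {
    expect_equal(ov$p[i],
                 hyperOracleEnum(ov$overlap[i], 12, ov$size_a[i],
                                 ov$size_b[i]),
                 tolerance = 1e-12)
  }
  labsB <- setNames(rep(c("m1", "m2"), c(5, 5)), paste0("g", 3:12))
  expect_warning(moduleOverlap(labs, labsB), "intersection")
})

test_that("random independent assignments are rarely significant", {
  sigRates <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      a <- setNames(sample(c("x", "y", "z"), 300, TRUE), paste0("g", 1:300))
      b <- setNames(sample(c("u", "v", "w"), 300, TRUE), paste0("g", 1:300))
    })
    ov <- moduleOverlap(a, b)
    mean(ov$adj_p < 0.10)
  }, numeric(1))
  expect_lte(mean(sigRates), 0.10)
})

test_that("hub extraction applies strict thresholds and finds the hub", {
  genes <- paste0("g", 1:4)
  labels <- setNames(rep("red", 4), genes)
  adj <- matrix(0.1, 4, 4, dimnames = list(genes, genes))
  adj["g1", "g2"] <- adj["g2", "g1"] <- 0.9
  adj["g1", "g3"] <- adj["g3", "g1"] <- 0.9
  diag(adj) <- 1
  ms <- new("ModuleSet", labels = labels,
            eigengenes = matrix(0, 2, 1, dimnames = list(NULL, "red")),
            membership = matrix(c(0.9, 0.8, 0.7, 0.5), 4, 1,
                                dimnames = list(genes, "red")),
            geneSignificance = setNames(c(0.9, 0.8, 0.8, 0.9), genes))
  res <- extractHubNetwork(ms, "red", adj)
  expect_false("g4" %in% res$genes$gene)   # MM exactly 0.5 -> excluded
  expect_identical(res$hub, "g1")
  expect_warning(none <- extractHubNetwork(ms, "red", adj, gsMin = 1),
                 "no gene")
  expect_identical(nrow(none$edges), 0L)
  expect_error(extractHubNetwork(ms, "chartreuse", adj), "not found")
})
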