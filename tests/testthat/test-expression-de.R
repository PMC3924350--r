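test_that("quantile normalization gives rank-wise means and is idempotent", {
  x <- makeExpr(cbind(c(1, 2, 3), c(2, 4, 6)), 1, 1)
  qn <- exprValues(quantileNormalize(x))
  expect_equal(unname(qn[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3, 4.5))

  same <- makeExpr(cbind(c(5, 1, 3), c(5, 1, 3)), 1, 1)
  expect_equal(exprValues(quantileNormalize(same)), exprValues(same))

  one <- makeExpr(matrix(c(3, 1, 2), 3, 1), 1, 0)
  expect_equal(exprValues(quantileNormalize(one)), exprValues(one))

  big <- makeExpr(matrix(withr::with_seed(1, rnorm(200)), 20, 10), 5, 5)
  once <- quantileNormalize(big)
  expect_equal(exprValues(quantileNormalize(once)), exprValues(once),
               tolerance = 1e-12)
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  v <- matrix(withr::with_seed(42, rnorm(300)), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  x <- makeExpr(v, 5, 5)
  mine <- exprValues(quantileNormalize(x))
  ref <- limma::normalizeQuantiles(v)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("scale normalization equalizes spread and aligns medians", {
  v <- withr::with_seed(3, matrix(rnorm(60, mean = 8), 20, 3))
  v[, 2] <- 2 * (v[, 1] - median(v[, 1])) + median(v[, 1])
  x <- makeExpr(v, 2, 1)
  sn <- exprValues(scaleNormalize(x))
  mads <- apply(sn, 2, mad)
  expect_equal(max(mads) / min(mads), 1, tolerance = 1e-12)
  # the x2-rescaled copy of column 1 is restored onto column 1
  expect_equal(unname(sn[, 2]), unname(sn[, 1]), tolerance = 1e-12)
  ident <- makeExpr(cbind(v[, 1], v[, 1]), 1, 1)
  expect_equal(exprValues(scaleNormalize(ident)), exprValues(ident),
               tolerance = 1e-12)
  flat <- makeExpr(cbind(v[, 1], rep(1, 20)), 1, 1)
  expect_error(scaleNormalize(flat), "zero-spread")
})

test_that("presence filter uses an inclusive boundary", {
  v <- matrix(0, 3, 32, dimnames = list(c("a", "b", "c"), sprintf("s%02d",
                                                                  1:32)))
  v["a", 1:24] <- 10      # 24/32 = 0.75, kept
  v["b", 1:23] <- 10      # 23/32, dropped
  v["c", ] <- 10
  x <- MirExpression(v, rep(c("treated", "control"), each = 16))
  kept <- rownames(exprValues(filterPresent(x, 0.75, noiseThreshold = 5)))
  expect_identical(kept, c("a", "c"))
  # fraction = 1 requires every sample above threshold
  kept1 <- rownames(exprValues(filterPresent(x, 1, noiseThreshold = 5)))
  expect_identical(kept1, "c")
})

test_that("replicate probes collapse to per-feature means", {
  v <- matrix(c(1, 2, 3, 4,       # feature F1, four replicates
                7, 7, 7, 7,       # feature F2
                1, 5),            # feature F3, two replicates
              10, 1, dimnames = list(paste0("p", 1:10), "s1"))
  v <- cbind(v, v)
  colnames(v) <- c("s1", "s2")
  map <- setNames(rep(c("F1", "F2", "F3"), c(4, 4, 2)), paste0("p", 1:10))
  x <- MirExpression(v, c("treated", "control"))
  out <- exprValues(collapseReplicates(x, map))
  expect_equal(unname(out[, 1]), c(2.5, 7, 3))
  expect_identical(rownames(out), c("F1", "F2", "F3"))
  expect_error(collapseReplicates(x, map[-1]), "unmapped")
})

test_that("variance prior recovery from a known scaled-F prior", {
  df <- 30
  s2 <- withr::with_seed(10, {
    1 * rchisq(5000, df) / df / (rchisq(5000, 4) / 4)
  })
  prior <- estimateVariancePrior(s2, df)
  expect_lt(abs(prior@d0 - 4) / 4, 0.2)
  expect_lt(abs(prior@s0sq - 1), 0.2)

  same <- estimateVariancePrior(rep(2, 100), df)
  expect_identical(same@d0, Inf)
  expect_equal(same@s0sq, 2, tolerance = 0.05)

  # more heterogeneity across genes -> smaller d0
  s2wide <- withr::with_seed(11, 1 * rchisq(5000, df) / df /
                               (rchisq(5000, 2) / 2))
  expect_lt(estimateVariancePrior(s2wide, df)@d0, prior@d0)
  expect_error(estimateVariancePrior(s2[1:5], df), ">= 10")
})

test_that("variance prior agrees with the limma reference fit", {
  skip_if_not_installed("limma")
  df <- 30
  s2 <- withr::with_seed(12, rchisq(2000, df) / df / (rchisq(2000, 6) / 6))
  mine <- estimateVariancePrior(s2, df)
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(mine@d0, ref$df2, tolerance = 0.05)
  expect_equal(mine@s0sq, ref$scale, tolerance = 0.05)
})

test_that("moderated t collapses to the classical pooled t at d0 = 0", {
  v <- matrix(withr::with_seed(5, rnorm(200, mean = 8, sd = 0.4)), 20, 10)
  dimnames(v) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10))
  x <- makeExpr(v, 6, 4)
  de <- fitModeratedT(x, prior = new("EBayesParams", d0 = 0, s0sq = 1))
  classical <- apply(v, 1, function(row) {
    t.test(row[1:6], row[7:10], var.equal = TRUE)$statistic
  })
  expect_equal(de$t[match(names(classical), de$feature_id)],
               unname(classical), tolerance = 1e-12)
})

test_that("moderated t at d0 = Inf uses the prior variance exactly", {
  v <- matrix(withr::with_seed(6, rnorm(120, sd = 0.3)), 12, 10)
  dimnames(v) <- list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:10))
  x <- makeExpr(v, 5, 5)
  s0 <- 0.25
  de <- fitModeratedT(x, prior = new("EBayesParams", d0 = Inf, s0sq = s0))
  m <- match(rownames(v), de$feature_id)
  lfc <- rowMeans(v[, 1:5]) - rowMeans(v[, 6:10])
  expect_equal(de$t[m], unname(lfc / sqrt(s0 * (1 / 5 + 1 / 5))),
               tolerance = 1e-12)
})

test_that("groups with equal means give logFC 0, t 0, p 1", {
  v <- matrix(rep(c(1, 2, 3, 4), each = 4), 1, byrow = FALSE)
  v <- rbind(c(1, 2, 1, 2, 1, 2, 1, 2))
  dimnames(v) <- list("g1", sprintf("s%d", 1:8))
  x <- makeExpr(v, 4, 4)
  de <- fitModeratedT(x, prior = new("EBayesParams", d0 = 0, s0sq = 1))
  expect_equal(de$logFC, 0)
  expect_equal(de$t, 0)
  expect_equal(de$p, 1)
  expect_error(fitModeratedT(makeExpr(v, 7, 1)), ">= 2 samples")
})

test_that("auto-prior moderated t matches limma given the same prior", {
  skip_if_not_installed("limma")
  v <- withr::with_seed(7, {
    sds <- runif(60, 0.15, 0.8)      # heteroscedastic so the prior df is
    matrix(rnorm(600, mean = 8, sd = rep(sds, 10)), 60, 10)  # finite
  })
  dimnames(v) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10))
  x <- makeExpr(v, 5, 5)
  design <- cbind(1, rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(v, design))
  refPrior <- new("EBayesParams", d0 = fit$df.prior,
                  s0sq = fit$s2.prior)
  de <- fitModeratedT(x, prior = refPrior)
  m <- match(rownames(v), de$feature_id)
  expect_equal(de$t[m], unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p[m], unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("DE calls use a strict threshold and split by direction", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    logFC = c(0.5, -0.5, 0.3, -0.1),
                    aveExp = 8, t = 1,
                    p = c(0.001, 0.002, 0.05, 0.9),
                    adj_p = c(0.004, 0.008, 0.10, 0.9),
                    direction = c("up", "down", "up", "down"),
                    stringsAsFactors = FALSE)
  calls <- callDE(tab, 0.10)
  expect_identical(calls$up, "a")            # "c" sits exactly at 0.10
  expect_identical(calls$down, "b")
  empty <- callDE(tab[0, ], 0.10)
  expect_identical(empty$up, character(0))
  expect_identical(empty$down, character(0))
})
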