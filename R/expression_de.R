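# Normalization and moderated differential expression for two-group
# log2-scale expression matrices. The moderated t follows the standard
# empirical-Bayes treatment: gene-wise sample variances are shrunk towards a
# scaled-F prior whose parameters (d0, s0^2) are estimated by moment matching
# on the log variances (trigamma inversion).

.replaceValues <- function(x, values) {
  se <- as(x, "SummarizedExperiment")
  SummarizedExperiment::assay(se, "log2") <- values
  new("MirExpression", se)
}

#' Quantile normalization
#'
#' After normalization every column has the identical sorted value vector:
#' the cross-sample rank-wise mean. Ties within a column receive the mean of
#' the normalized values they span. The operation is idempotent.
#'
#' @param x a \linkS4class{MirExpression} with >= 2 samples.
#' @return a normalized \linkS4class{MirExpression}.
#' @export
quantileNormalize <- function(x) {
  v <- exprValues(x)
  if (ncol(v) < 2) return(x)
  if (!all(is.finite(v))) {
    bad <- rownames(v)[!complete.cases(v) | rowSums(!is.finite(v)) > 0]
    stop("non-finite values in features: ", paste(head(bad, 5),
                                                  collapse = ", "))
  }
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(v)
  .replaceValues(x, out)
}

#' Scale normalization between arrays
#'
#' Columns are rescaled to a common spread (median absolute deviation equal
#' to the geometric mean of the per-column MADs) and their medians aligned to
#' the mean of the per-column medians.
#'
#' @param x a \linkS4class{MirExpression} with >= 2 samples.
#' @return a normalized \linkS4class{MirExpression}.
#' @export
scaleNormalize <- function(x) {
  v <- exprValues(x)
  if (ncol(v) < 2) return(x)
  meds <- apply(v, 2, median)
  mads <- apply(v, 2, mad)
  if (any(mads == 0))
    stop("zero-spread column(s): ",
         paste(colnames(v)[mads == 0], collapse = ", "))
  targetMad <- exp(mean(log(mads)))
  targetMed <- mean(meds)
  out <- sweep(sweep(v, 2, meds), 2, mads, "/") * targetMad + targetMed
  dimnames(out) <- dimnames(v)
  .replaceValues(x, out)
}

#' Filter features present over noise level
#'
#' Keeps features detected above \code{noiseThreshold} in at least
#' \code{fraction} of the samples (boundary inclusive).
#'
#' @param x a \linkS4class{MirExpression}.
#' @param fraction required presence fraction, in (0, 1]; default 0.75.
#' @param noiseThreshold log2 detection threshold.
#' @return the filtered \linkS4class{MirExpression}.
#' @export
filterPresent <- function(x, fraction = 0.75, noiseThreshold) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- exprValues(x)
  keep <- rowMeans(v > noiseThreshold) >= fraction
  x[keep, ]
}

#' Collapse replicate probes to one row per feature
#'
#' Replicate spots of the same feature are averaged (mean), an approximation
#' of modelling within-array replicate correlation explicitly.
#'
#' @param x a \linkS4class{MirExpression} whose rows are probes.
#' @param probeToFeature named character vector probe -> feature covering
#'   every probe.
#' @return a \linkS4class{MirExpression} with one row per feature, ordered by
#'   first occurrence.
#' @export
collapseReplicates <- function(x, probeToFeature) {
  v <- exprValues(x)
  feat <- probeToFeature[rownames(v)]
  if (anyNA(feat))
    stop("unmapped probes: ",
         paste(head(rownames(v)[is.na(feat)], 5), collapse = ", "))
  out <- rowsum(v, group = feat, reorder = FALSE) /
    as.vector(table(factor(feat, levels = unique(feat))))
  MirExpression(out, sampleGroups(x), consumption(x))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching of log sample variances under a scaled-F prior: the
#' excess spread of log variances over the theoretical sampling minimum
#' determines the prior degrees of freedom d0 via trigamma inversion;
#' \code{d0 = Inf} is returned when the observed spread does not exceed the
#' minimum (including the all-equal case).
#'
#' @param sampleVariances gene-wise sample variances (>= 10 values).
#' @param residualDf residual degrees of freedom of each variance (>= 1).
#' @return an \linkS4class{EBayesParams} object.
#' @export
estimateVariancePrior <- function(sampleVariances, residualDf) {
  s2 <- sampleVariances[is.finite(sampleVariances) & sampleVariances > 0]
  if (length(s2) < 10) stop("need >= 10 positive finite variances")
  if (residualDf < 1) stop("residualDf must be >= 1")
  z <- log(s2)
  ebar <- mean(z)
  vz <- var(z)
  excess <- vz - trigamma(residualDf / 2)
  if (!is.finite(excess) || excess <= 0) {
    # no inter-gene variance heterogeneity beyond sampling noise
    s0sq <- exp(ebar - digamma(residualDf / 2) + log(residualDf / 2))
    return(new("EBayesParams", d0 = Inf, s0sq = s0sq))
  }
  d0 <- 2 * .trigammaInverse(excess)
  s0sq <- exp(ebar - digamma(residualDf / 2) + log(residualDf / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  new("EBayesParams", d0 = d0, s0sq = s0sq)
}

# Newton inversion of the trigamma function on (0, Inf).
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group differential expression
#'
#' Per feature: logFC is the treated-minus-control mean difference, the
#' posterior variance is \code{(d0*s0^2 + df*s^2) / (d0 + df)}, and the
#' moderated t is referred to a t distribution with \code{d0 + df} degrees of
#' freedom (two-sided). With \code{d0 = 0} this is the classical pooled
#' two-sample t; with \code{d0 = Inf} the posterior variance is exactly
#' \code{s0^2}.
#'
#' @param x a \linkS4class{MirExpression}; both groups need >= 2 samples.
#' @param prior an \linkS4class{EBayesParams}, or \code{"auto"} (default) to
#'   estimate it from the data.
#' @return a DE table (data.frame): feature_id, logFC, aveExp, t, p, adj_p,
#'   direction; rows ordered by p.
#' @export
fitModeratedT <- function(x, prior = "auto") {
  v <- exprValues(x)
  grp <- sampleGroups(x)
  i1 <- which(grp == "treated"); i2 <- which(grp == "control")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  logFC <- m1 - m2
  ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (identical(prior, "auto"))
    prior <- estimateVariancePrior(s2, df)
  stopifnot(is(prior, "EBayesParams"))
  d0 <- prior@d0; s0sq <- prior@s0sq
  if (is.infinite(d0)) {
    s2post <- rep(s0sq, length(s2))
    dfTotal <- Inf
  } else {
    s2post <- (d0 * s0sq + df * s2) / (d0 + df)
    dfTotal <- d0 + df
  }
  tstat <- logFC / sqrt(s2post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = dfTotal)
  res <- data.frame(feature_id = rownames(v),
                    logFC = logFC,
                    aveExp = rowMeans(v),
                    t = tstat,
                    p = p,
                    adj_p = bhAdjust(p),
                    direction = ifelse(logFC >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p), , drop = FALSE]
}

#' Call differentially expressed features at an FDR threshold
#'
#' Strict inequality: features with BH-adjusted p exactly equal to the
#' threshold are excluded.
#'
#' @param deTable a DE table from \code{\link{fitModeratedT}}.
#' @param fdr FDR threshold in (0, 1).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDE <- function(deTable, fdr) {
  stopifnot(fdr > 0, fdr < 1)
  if (!nrow(deTable))
    return(list(up = character(), down = character()))
  sig <- deTable$adj_p < fdr
  list(up = deTable$feature_id[sig & deTable$direction == "up"],
       down = deTable$feature_id[sig & deTable$direction == "down"])
}
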