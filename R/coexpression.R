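# Signed weighted gene coexpression analysis, implemented from first
# principles: signed Pearson similarity, soft-threshold adjacency, scale-free
# fit for power selection, topological overlap, static-height module
# detection on average-linkage trees, module eigengenes via SVD, module
# membership (kME) and gene significance, module-trait / module-miRNA
# correlation statistics, module overlap between two networks, and hub
# subnetwork extraction.

#' Signed similarity matrix
#'
#' \code{S = (1 + cor) / 2}, mapping Pearson correlation from [-1, 1] to
#' [0, 1] so that anti-correlated genes are maximally dissimilar.
#' Zero-variance genes are dropped with a warning.
#'
#' @param x a \linkS4class{MirExpression} (>= 3 samples) or a numeric
#'   genes-x-samples matrix.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
signedSimilarity <- function(x) {
  v <- if (is(x, "MirExpression")) exprValues(x) else x
  if (ncol(v) < 3) stop("need >= 3 samples")
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s): ",
            paste(head(rownames(v)[sds == 0], 5), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  S <- (1 + cor(t(v))) / 2
  diag(S) <- 1
  S
}

#' Soft-threshold adjacency
#'
#' Elementwise power \code{a = S^beta}, emphasizing strong correlations and
#' suppressing weak ones on an exponential scale.
#'
#' @param S signed similarity matrix.
#' @param beta soft-threshold power (>= 1), default 12.
#' @return adjacency matrix.
#' @export
softAdjacency <- function(S, beta = 12) {
  stopifnot(beta >= 1)
  S^beta
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Connectivities are binned into \code{nBins} equal-width bins; the fit is
#' the R-squared of the regression of log10(frequency) on log10(mean
#' connectivity) over nonempty bins. Degenerate inputs (all connectivities
#' equal, or fewer than 3 usable bins) report R-squared 0.
#'
#' @param k vector of node connectivities.
#' @param nBins number of bins (default 10).
#' @return list with \code{r2} and \code{slope}.
#' @export
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(list(r2 = 0, slope = NA_real_))
  cuts <- cut(k, breaks = nBins)
  freq <- tapply(k, cuts, length)
  meanK <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(r2 = 0, slope = NA_real_))
  y <- log10(freq[ok])
  fit <- lm(y ~ log10(meanK[ok]))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  list(r2 = r2, slope = unname(coef(fit)[2]))
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power the whole-network connectivity
#' \code{k_i = sum_{j != i} a_ij} is computed and its scale-free fit
#' R-squared evaluated; the chosen power is the smallest one reaching
#' \code{r2Target}, or the power with maximal R-squared if none does.
#'
#' @param x a \linkS4class{MirExpression} or similarity matrix as accepted
#'   by \code{\link{signedSimilarity}}.
#' @param betaGrid candidate powers.
#' @param r2Target fit target (default 0.85).
#' @return list with \code{table} (data.frame: beta, r2, slope, mean_k) and
#'   \code{beta} (chosen power).
#' @export
pickSoftThreshold <- function(x, betaGrid = c(1:10, 12, 14, 16, 18, 20),
                              r2Target = 0.85) {
  if (!length(betaGrid)) stop("betaGrid must be nonempty")
  S <- if (is.matrix(x) && isSymmetric(unname(x))) x else signedSimilarity(x)
  tab <- do.call(rbind, lapply(betaGrid, function(b) {
    a <- softAdjacency(S, b)
    k <- colSums(a) - diag(a)
    fit <- scaleFreeFit(k)
    data.frame(beta = b, r2 = fit$r2, slope = fit$slope, mean_k = mean(k))
  }))
  hit <- which(tab$r2 >= r2Target)
  beta <- if (length(hit)) tab$beta[min(hit)] else tab$beta[which.max(tab$r2)]
  list(table = tab, beta = beta)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_{u != i,j} a_iu a_uj} and
#' \code{k_i = sum_{u != i} a_iu}; \code{TOM_ii = 1}. The dissimilarity used
#' for clustering is \code{1 - TOM}.
#'
#' @param a symmetric adjacency matrix (unit diagonal convention; the
#'   diagonal is excluded from connectivity sums).
#' @return the TOM matrix.
#' @export
topologicalOverlap <- function(a) {
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0                      # l_ij + extra i/j terms cancel via a0
  k <- rowSums(a0)
  minK <- outer(k, k, pmin)
  tom <- (L + a0) / (minK + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by static-height cutting of an average-linkage tree
#'
#' Genes are clustered by average linkage on the dissimilarity; branches
#' below \code{cutHeight} times the maximum merge height form candidate
#' clusters; clusters smaller than \code{minModuleSize} are assigned to
#' \code{"grey"}. When the expression matrix is supplied, a membership
#' cleanup follows: genes whose correlation with their module eigengene
#' falls below \code{minKME} in absolute value are reassigned to grey
#' (loosely attached genes join large branches through shared hub
#' neighborhoods in topological-overlap space even when their expression is
#' uncorrelated with the module). Module labels follow the size-ordered
#' color convention (turquoise, blue, brown, ...), ties broken by first
#' gene index.
#'
#' @param dissimilarity square matrix, typically \code{1 - TOM}.
#' @param minModuleSize minimum module size (default 100).
#' @param cutHeight fraction of the maximum merge height (default 0.99).
#' @param expr optional genes-x-samples matrix (or
#'   \linkS4class{MirExpression}) enabling the eigengene-membership cleanup.
#' @param minKME membership floor for the cleanup (default 0.45, about 2.5
#'   null standard deviations of a correlation at 32 samples).
#' @return named character vector gene -> module color.
#' @export
detectModules <- function(dissimilarity, minModuleSize = 100,
                          cutHeight = 0.99, expr = NULL, minKME = 0.45) {
  n <- nrow(dissimilarity)
  genes <- rownames(dissimilarity)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (minModuleSize > n) {
    warning("minModuleSize exceeds the number of genes; all genes grey")
    return(setNames(rep("grey", n), genes))
  }
  tree <- hclust(as.dist(dissimilarity), method = "average")
  h <- cutHeight * max(tree$height)
  cl <- cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- setNames(rep("grey", n), genes)
  if (length(keep)) {
    firstIdx <- vapply(keep, function(cid) min(which(cl == cid)), numeric(1))
    ord <- keep[order(-as.integer(sizes[keep]), firstIdx)]
    for (i in seq_along(ord)) {
      col <- if (i <= length(.MODULE_COLORS)) .MODULE_COLORS[i] else
        paste0("module", i)
      labels[cl == as.integer(ord[i])] <- col
    }
    if (!is.null(expr)) {
      v <- if (is(expr, "MirExpression")) exprValues(expr) else expr
      me <- moduleEigengenes(v[genes, , drop = FALSE], labels)
      for (m in colnames(me)) {
        members <- names(labels)[labels == m]
        kme <- as.vector(cor(t(v[members, , drop = FALSE]), me[, m]))
        labels[members[abs(kme) < minKME]] <- "grey"
      }
      # a module shrunk below the size floor dissolves entirely
      tab <- table(labels[labels != "grey"])
      labels[labels %in% names(tab)[tab < minModuleSize]] <- "grey"
    }
  }
  labels
}

#' Module eigengenes
#'
#' Per module, the first principal component across samples of the
#' per-gene standardized (z-scored) module submatrix, computed by SVD. Each
#' eigengene has unit norm; its sign is fixed so that its correlation with
#' the module's average standardized profile is non-negative.
#'
#' @param x a \linkS4class{MirExpression} or genes-x-samples matrix.
#' @param labels named character vector gene -> module (\code{"grey"}
#'   excluded).
#' @return numeric matrix samples x modules.
#' @export
moduleEigengenes <- function(x, labels) {
  v <- if (is(x, "MirExpression")) exprValues(x) else x
  mods <- setdiff(unique(labels), "grey")
  me <- sapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    sub <- v[genes, , drop = FALSE]
    Z <- t(scale(t(sub)))               # per-gene z-score across samples
    Z[!is.finite(Z)] <- 0
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    avg <- colMeans(Z)
    if (sum(e * avg) < 0) e <- -e
    e
  })
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(v), mods))
  me
}

#' Student-t p-value for a correlation coefficient
#'
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)}, two-sided p from a t
#' distribution with \code{n - 2} degrees of freedom. For |r| = 1 the
#' p-value 0 is returned (degenerate case).
#'
#' @param r correlation coefficient(s).
#' @param n sample size (>= 3).
#' @return two-sided p-value(s).
#' @export
corPvalueStudent <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  p <- numeric(length(r))
  degen <- abs(r) == 1
  tt <- r[!degen] * sqrt(n - 2) / sqrt(1 - r[!degen]^2)
  p[!degen] <- 2 * pt(-abs(tt), df = n - 2)
  p[degen] <- 0
  p
}

#' Module-trait and module-miRNA statistics
#'
#' Computes the signed gene significance GS (correlation of each gene with
#' the trait; reported absolute downstream), module membership
#' MM (correlation of each gene with each eigengene), the module-trait
#' correlation table, and the module-eigengene x miRNA-profile correlation
#' grid with BH FDR across the grid.
#'
#' @param x a \linkS4class{MirExpression} or genes-x-samples matrix.
#' @param me eigengene matrix from \code{\link{moduleEigengenes}}.
#' @param trait named numeric per-sample trait (e.g. consumption).
#' @param mirnaProfiles optional miRNAs-x-samples matrix of DE-miRNA
#'   expression.
#' @param labels named module assignment (used to populate the ModuleSet).
#' @param fdr flag threshold for the miRNA grid (default 0.10).
#' @return a \linkS4class{ModuleSet}.
#' @export
relateToTraits <- function(x, me, trait, mirnaProfiles = NULL,
                           labels = NULL, fdr = 0.10) {
  v <- if (is(x, "MirExpression")) exprValues(x) else x
  miss <- setdiff(colnames(v), names(trait))
  if (length(miss))
    stop("samples missing from trait: ", paste(miss, collapse = ", "))
  tr <- trait[colnames(v)]
  gs <- as.vector(cor(t(v), tr))
  names(gs) <- rownames(v)
  mm <- cor(t(v), me[colnames(v), , drop = FALSE])
  n <- ncol(v)
  mtr <- as.vector(cor(me[colnames(v), , drop = FALSE], tr))
  moduleTrait <- data.frame(module = colnames(me), r = mtr,
                            p = corPvalueStudent(mtr, n),
                            stringsAsFactors = FALSE)
  moduleMirna <- data.frame()
  if (!is.null(mirnaProfiles)) {
    missM <- setdiff(colnames(v), colnames(mirnaProfiles))
    if (length(missM))
      stop("samples missing from miRNA profiles: ",
           paste(missM, collapse = ", "))
    mp <- mirnaProfiles[, colnames(v), drop = FALSE]
    cc <- cor(me[colnames(v), , drop = FALSE], t(mp))
    grid <- expand.grid(module = rownames(cc), mirna = colnames(cc),
                        stringsAsFactors = FALSE)
    grid$r <- as.vector(cc)
    grid$p <- corPvalueStudent(grid$r, n)
    grid$adj_p <- bhAdjust(grid$p)
    grid$significant <- grid$adj_p < fdr
    moduleMirna <- grid
  }
  new("ModuleSet",
      labels = if (is.null(labels))
        setNames(rep(NA_character_, nrow(v)), rownames(v)) else labels,
      eigengenes = me, membership = mm, geneSignificance = gs,
      moduleTrait = moduleTrait, moduleMirna = moduleMirna)
}

#' Overlap of two module decompositions
#'
#' Cross-tabulates the assignments on the common gene set and tests each
#' cell with the upper-tail hypergeometric, BH-corrected across cells.
#'
#' @param labelsA,labelsB named module assignments.
#' @return data.frame: module_a, module_b, overlap, size_a, size_b, p,
#'   adj_p.
#' @export
moduleOverlap <- function(labelsA, labelsB) {
  common <- intersect(names(labelsA), names(labelsB))
  if (length(common) < length(labelsA) || length(common) < length(labelsB))
    warning("gene sets differ; restricting to the intersection (",
            length(common), " genes)")
  a <- labelsA[common]; b <- labelsB[common]
  N <- length(common)
  tab <- as.data.frame(table(module_a = a, module_b = b),
                       stringsAsFactors = FALSE)
  colnames(tab)[3] <- "overlap"
  sizeA <- table(a); sizeB <- table(b)
  tab$size_a <- as.integer(sizeA[tab$module_a])
  tab$size_b <- as.integer(sizeB[tab$module_b])
  tab$p <- hyperTailP(tab$overlap, N = N, K = tab$size_a, n = tab$size_b)
  tab$adj_p <- bhAdjust(tab$p)
  tab
}

#' Extract the hub subnetwork of a module
#'
#' Genes passing strict module-membership and gene-significance thresholds
#' (MM > mmMin and |GS| > gsMin) are kept; edges are weighted by adjacency,
#' the per-gene connectivity is the within-subnetwork adjacency row sum, and
#' the hub is the gene with maximal connectivity.
#'
#' @param moduleSet a \linkS4class{ModuleSet}.
#' @param module module color to extract.
#' @param adjacency full adjacency matrix (gene names on dimnames).
#' @param mmMin,gsMin strict thresholds (defaults 0.5).
#' @return list with \code{edges} (gene_a, gene_b, weight), \code{genes}
#'   (data.frame gene, connectivity), and \code{hub}; empty (with a warning)
#'   when no gene passes.
#' @export
extractHubNetwork <- function(moduleSet, module, adjacency,
                              mmMin = 0.5, gsMin = 0.5) {
  labels <- moduleLabels(moduleSet)
  if (!module %in% labels) stop("module '", module, "' not found")
  genes <- names(labels)[labels == module]
  mm <- moduleMembership(moduleSet)[genes, module]
  gs <- abs(geneSignificance(moduleSet)[genes])
  pass <- genes[mm > mmMin & gs > gsMin]
  if (!length(pass)) {
    warning("no gene passes MM > ", mmMin, " and GS > ", gsMin,
            " in module '", module, "'")
    return(list(edges = data.frame(gene_a = character(),
                                   gene_b = character(), weight = numeric(),
                                   stringsAsFactors = FALSE),
                genes = data.frame(gene = character(),
                                   connectivity = numeric(),
                                   stringsAsFactors = FALSE),
                hub = NA_character_))
  }
  sub <- adjacency[pass, pass, drop = FALSE]
  conn <- rowSums(sub) - diag(sub)
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  ed <- data.frame(gene_a = pass[pairs[, 1]], gene_b = pass[pairs[, 2]],
                   weight = sub[pairs], stringsAsFactors = FALSE)
  list(edges = ed,
       genes = data.frame(gene = pass, connectivity = unname(conn),
                          stringsAsFactors = FALSE),
       hub = pass[which.max(conn)])
}
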