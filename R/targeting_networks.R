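# Bipartite miRNA-mRNA targeting networks for correlated DE sets, their
# randomized null controls, and hypergeometric over-targeting tests.
#
# Conventions: only nodes with degree >= 1 are network members; the average
# number of neighbors is 2|E|/|V| over those members. The hypergeometric
# population for over-targeting is the set of expressed genes that appear as
# a target of at least one universe miRNA ("targetable" genes): genes absent
# from the universe can never be drawn as targets.

#' Build a bipartite targeting network
#'
#' Edges are the universe edges with both endpoints in the supplied sets;
#' candidates left without any edge are excluded from the node sets.
#'
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param mirnaSet character vector of miRNA IDs.
#' @param geneSet character vector of gene symbols.
#' @param label network label: \code{"positive"}, \code{"negative"} or
#'   \code{"random"}.
#' @return a \linkS4class{BipartiteNetwork}.
#' @export
buildBipartite <- function(universe, mirnaSet, geneSet, label = "positive") {
  if (!length(mirnaSet) || !length(geneSet))
    stop("mirnaSet and geneSet must be nonempty")
  ed <- edges(universe)
  keep <- ed$mirna_id %in% mirnaSet &
    tolower(ed$gene_symbol) %in% tolower(geneSet)
  e <- data.frame(mirna = ed$mirna_id[keep],
                  gene = ed$gene_symbol[keep], stringsAsFactors = FALSE)
  new("BipartiteNetwork",
      mirnaNodes = sort(unique(e$mirna)),
      geneNodes = sort(unique(e$gene)),
      edgeTable = e, label = label)
}

#' Average number of neighbors (mean degree)
#'
#' \code{2 * |edges| / |nodes|} over nodes with degree >= 1.
#'
#' @param network a nonempty \linkS4class{BipartiteNetwork}.
#' @return numeric mean degree.
#' @export
averageNeighbors <- function(network) {
  nNodes <- length(network@mirnaNodes) + length(network@geneNodes)
  if (nNodes == 0) stop("empty network")
  2 * nrow(edges(network)) / nNodes
}

# Logical incidence matrix of universe edges restricted to a miRNA set and
# the targetable-gene universe; rows = miRNAs, columns = genes.
.incidence <- function(universe, mirnaSet, genes) {
  ed <- edges(universe)
  ed <- ed[ed$mirna_id %in% mirnaSet, , drop = FALSE]
  m <- matrix(FALSE, length(mirnaSet), length(genes),
              dimnames = list(mirnaSet, genes))
  i <- match(ed$mirna_id, mirnaSet)
  j <- match(tolower(ed$gene_symbol), tolower(genes))
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- TRUE
  m
}

#' Targetable genes: expressed genes with at least one universe edge
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param expressed character vector of expressed gene symbols.
#' @return character vector (expressed casing preserved).
#' @export
targetableGenes <- function(universe, expressed) {
  expressed[tolower(expressed) %in% tolower(edges(universe)$gene_symbol)]
}

#' Per-miRNA over-targeting test
#'
#' For each miRNA with at least one expressed target, an upper-tail
#' hypergeometric test of whether its targets are over-represented in the DE
#' gene set. Population N = expressed targetable genes; successes n = DE
#' genes among them; draws K = the miRNA's expressed targets; observed k =
#' its DE targets. BH correction across tested miRNAs.
#'
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param mirnaSet miRNAs to test.
#' @param deSet DE gene set (subset of \code{expressed}).
#' @param expressed expressed gene symbols.
#' @param fdr over-targeting flag threshold (default 0.10).
#' @return list with \code{table} (data.frame: mirna_id, K, k, N, n, p,
#'   adj_p, overtargeting) and \code{excluded} (miRNAs with no expressed
#'   target).
#' @export
mirnaOvertargeting <- function(universe, mirnaSet, deSet, expressed,
                               fdr = 0.10) {
  if (!all(tolower(deSet) %in% tolower(expressed)))
    stop("deSet must be a subset of expressed")
  pool <- targetableGenes(universe, expressed)
  N <- length(pool)
  dePool <- pool[tolower(pool) %in% tolower(deSet)]
  n <- length(dePool)
  inc <- .incidence(universe, mirnaSet, pool)
  K <- rowSums(inc)
  k <- rowSums(inc[, tolower(pool) %in% tolower(dePool), drop = FALSE])
  tested <- K >= 1
  tab <- data.frame(mirna_id = mirnaSet[tested],
                    K = as.integer(K[tested]), k = as.integer(k[tested]),
                    N = N, n = n, stringsAsFactors = FALSE)
  tab$p <- hyperTailP(tab$k, N = N, K = tab$K, n = n)
  tab$adj_p <- bhAdjust(tab$p)
  tab$overtargeting <- tab$adj_p < fdr
  rownames(tab) <- NULL
  list(table = tab, excluded = mirnaSet[!tested])
}

#' Per-mRNA over-targeting test
#'
#' The symmetric test with roles swapped: for each gene targeted by more
#' than one miRNA, whether its targeting miRNAs are over-represented in the
#' DE miRNA set. Population N = expressed miRNAs present in the universe;
#' successes n = DE miRNAs among them; draws K = miRNAs targeting the gene.
#'
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param geneSet genes to test.
#' @param mirnaDeSet DE miRNA set.
#' @param expressedMirnas expressed miRNA IDs.
#' @param fdr flag threshold (default 0.10).
#' @return list with \code{table} and \code{excluded} (genes with <= 1
#'   targeting miRNA).
#' @export
mrnaOvertargeting <- function(universe, geneSet, mirnaDeSet, expressedMirnas,
                              fdr = 0.10) {
  ed <- edges(universe)
  pool <- expressedMirnas[expressedMirnas %in% unique(ed$mirna_id)]
  N <- length(pool)
  dePool <- intersect(pool, mirnaDeSet)
  n <- length(dePool)
  res <- lapply(geneSet, function(g) {
    mir <- intersect(ed$mirna_id[tolower(ed$gene_symbol) == tolower(g)], pool)
    c(K = length(mir), k = length(intersect(mir, dePool)))
  })
  K <- vapply(res, `[`, numeric(1), "K")
  k <- vapply(res, `[`, numeric(1), "k")
  tested <- K > 1
  tab <- data.frame(gene_symbol = geneSet[tested],
                    K = as.integer(K[tested]), k = as.integer(k[tested]),
                    N = N, n = n, stringsAsFactors = FALSE)
  tab$p <- hyperTailP(tab$k, N = N, K = tab$K, n = n)
  tab$adj_p <- bhAdjust(tab$p)
  tab$overtargeting <- tab$adj_p < fdr
  rownames(tab) <- NULL
  list(table = tab, excluded = geneSet[!tested])
}

#' Randomized control networks
#'
#' For each replicate, a gene set of the given size is sampled uniformly
#' without replacement from the gene universe, the bipartite network against
#' the fixed miRNA set is rebuilt, and the mean degree and over-targeting
#' proportion recorded. Deterministic under the seed.
#'
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param mirnaSet fixed miRNA set.
#' @param geneUniverse gene symbols to sample from (typically expressed,
#'   targetable genes).
#' @param geneSetSize sample size (the DE-set cardinality).
#' @param R number of replicates (default 1000).
#' @param seed integer seed.
#' @param fdr over-targeting flag threshold.
#' @return a \linkS4class{NullSummary}.
#' @export
randomizeNetworks <- function(universe, mirnaSet, geneUniverse, geneSetSize,
                              R = 1000, seed = 1, fdr = 0.10) {
  if (geneSetSize > length(geneUniverse))
    stop("geneSetSize exceeds the gene universe")
  R <- as.integer(R)
  inc <- .incidence(universe, mirnaSet, geneUniverse)
  Ktot <- rowSums(inc)
  N <- sum(colSums(inc) > 0)            # targetable genes in the universe
  pool <- which(colSums(inc) > 0)
  meanDeg <- numeric(R)
  otProp <- numeric(R)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(R)) {
      idx <- sample.int(ncol(inc), geneSetSize)
      sub <- inc[, idx, drop = FALSE]
      degMir <- rowSums(sub)
      degGene <- colSums(sub)
      nEdge <- sum(degMir)
      nNode <- sum(degMir > 0) + sum(degGene > 0)
      meanDeg[r] <- if (nNode > 0) 2 * nEdge / nNode else 0
      # over-targeting across the fixed miRNA set vs the sampled "DE" genes
      nDe <- sum(idx %in% pool)
      tested <- Ktot >= 1
      p <- hyperTailP(degMir[tested], N = N, K = Ktot[tested], n = nDe)
      otProp[r] <- if (any(tested)) mean(bhAdjust(p) < fdr) else 0
    }
  })
  new("NullSummary", meanDegree = meanDeg, overtargetProp = otProp,
      R = R, seed = as.integer(seed))
}

#' Observed-versus-null network contrast report
#'
#' Tabulates, for the positively and negatively correlated networks, the
#' observed mean degree against its randomized null (mean, sd, z), the
#' over-targeting proportions with goodness-of-fit tests against the null
#' proportion, and enrichment/depletion flags.
#'
#' @param positive,negative \linkS4class{BipartiteNetwork}s.
#' @param positiveNull,negativeNull matching \linkS4class{NullSummary}s.
#' @param positiveOvertarget,negativeOvertarget over-targeting tables from
#'   \code{\link{mirnaOvertargeting}}.
#' @return data.frame with one row per network.
#' @export
networkContrastReport <- function(positive, negative,
                                  positiveNull, negativeNull,
                                  positiveOvertarget, negativeOvertarget) {
  row <- function(net, null, ot) {
    obs <- averageNeighbors(net)
    nullMean <- mean(null@meanDegree)
    nullSd <- sd(null@meanDegree)
    nTested <- nrow(ot$table)
    kOt <- sum(ot$table$overtargeting)
    p0 <- mean(null@overtargetProp)
    gof <- if (nTested > 0 && p0 > 0 && p0 < 1)
      proportionGofTest(kOt, nTested, p0) else list(chi2 = NA_real_,
                                                    p = NA_real_)
    z <- if (isTRUE(nullSd > 0)) (obs - nullMean) / nullSd else NA_real_
    data.frame(network = net@label,
               mean_degree = obs,
               null_mean_degree = nullMean,
               null_sd_degree = nullSd,
               degree_z = z,
               n_mirnas_tested = nTested,
               n_overtargeting = kOt,
               overtarget_prop = if (nTested) kOt / nTested else NA_real_,
               null_overtarget_prop = p0,
               chi2 = gof$chi2,
               chi2_p = gof$p,
               flag = if (!is.finite(z)) "na" else if (z > 3) "enriched"
                      else if (z < -3) "depleted" else "null-like",
               stringsAsFactors = FALSE)
  }
  rbind(row(positive, positiveNull, positiveOvertarget),
        row(negative, negativeNull, negativeOvertarget))
}
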