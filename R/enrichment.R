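# Hypergeometric gene-set enrichment with BH correction, sharing the same
# hypergeometric kernel as the over-targeting and module-overlap tests.

#' Hypergeometric enrichment of a query set in a gene-set collection
#'
#' All counts are restricted to the universe. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query character vector of query genes (e.g. DE genes).
#' @param collection named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param universe character vector of background genes (e.g. all expressed
#'   genes after filtering).
#' @return data.frame: set, k (overlap), K (set size in universe), n (query
#'   size), N (universe), p, adj_p; ordered as in the collection.
#' @export
hypergeomEnrich <- function(query, collection, universe) {
  if (!length(universe)) stop("empty universe")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must be uniquely named")
  if (any(!lengths(collection)))
    stop("empty gene set(s): ",
         paste(names(collection)[!lengths(collection)], collapse = ", "))
  uni <- unique(tolower(universe))
  q <- unique(tolower(query))
  outside <- setdiff(q, uni)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    q <- intersect(q, uni)
  }
  N <- length(uni)
  n <- length(q)
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(unique(tolower(collection[[nm]])), uni)
    K <- length(set)
    k <- length(intersect(set, q))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = if (K > 0) hyperTailP(k, N = N, K = K, n = n) else 1,
               stringsAsFactors = FALSE)
  }))
  res$adj_p <- bhAdjust(res$p)
  rownames(res) <- NULL
  res
}

#' Enrichment of DE genes in each coexpression module
#'
#' Per module (grey included), the hypergeometric enrichment of the DE set,
#' BH-corrected across modules.
#'
#' @param labels named module assignment covering the universe.
#' @param deGenes character vector of DE genes.
#' @param universe character vector of background genes.
#' @return data.frame as from \code{\link{hypergeomEnrich}}, one row per
#'   module.
#' @export
deInModuleEnrichment <- function(labels, deGenes, universe) {
  miss <- setdiff(tolower(universe), tolower(names(labels)))
  if (length(miss))
    stop("labels do not cover the universe (", length(miss),
         " genes missing)")
  mods <- unique(labels)
  collection <- lapply(mods, function(m) names(labels)[labels == m])
  names(collection) <- mods
  hypergeomEnrich(deGenes, collection, universe)
}
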