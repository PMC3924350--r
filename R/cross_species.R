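# Cross-species comparison of DE miRNA-family and gene sets: deterministic
# overlap, Monte Carlo significance with the add-one empirical p-value, and
# direction concordance of common genes.

#' Overlap of two family sets
#'
#' @param familiesA,familiesB character vectors of family IDs (already
#'   converted to the species-neutral naming).
#' @return list with \code{overlap} (character vector) and \code{count}.
#' @export
familyOverlap <- function(familiesA, familiesB) {
  ov <- intersect(unique(familiesA), unique(familiesB))
  list(overlap = ov, count = length(ov))
}

#' Monte Carlo p-value for a set overlap
#'
#' R replicates draw a random subset of size \code{sizeA} without
#' replacement from the universe and count its overlap with a fixed subset
#' of size \code{sizeB}; the empirical p-value uses the add-one estimator
#' \code{(1 + #\{overlap >= observed\}) / (R + 1)}, so it is never zero and
#' never below \code{1/(R+1)}.
#'
#' @param observed observed overlap count.
#' @param sizeA,sizeB sizes of the two sets.
#' @param universeSize size of the sampling universe.
#' @param R number of simulations (default 10000).
#' @param seed integer seed.
#' @return list: observed_overlap, size_a, size_b, universe_size, mc_p, R,
#'   seed.
#' @export
montecarloOverlapP <- function(observed, sizeA, sizeB, universeSize,
                               R = 10000, seed = 1) {
  if (sizeA > universeSize || sizeB > universeSize)
    stop("set sizes exceed the universe")
  if (observed > min(sizeA, sizeB))
    stop("observed overlap exceeds min(sizeA, sizeB)")
  R <- as.integer(R)
  hits <- withr::with_seed(as.integer(seed), {
    # fixed subset = {1..sizeB}; overlap of a draw = #elements <= sizeB
    sum(vapply(seq_len(R), function(r)
      sum(sample.int(universeSize, sizeA) <= sizeB) >= observed,
      logical(1)))
  })
  list(observed_overlap = observed, size_a = sizeA, size_b = sizeB,
       universe_size = universeSize, mc_p = (1 + hits) / (R + 1),
       R = R, seed = as.integer(seed))
}

#' Cross-species gene-set overlap
#'
#' Symbols of list B are first converted through the homology map into the
#' taxon of list A, then intersected (case-insensitively); significance is
#' assessed by Monte Carlo over the mapped universe.
#'
#' @param deA DE symbols in the reference taxon.
#' @param deB DE symbols in the other taxon.
#' @param homology data.frame from \code{\link{readHomologyTsv}}.
#' @param fromTaxon taxon of \code{deB}; \code{toTaxon} taxon of \code{deA}.
#' @param toTaxon see above.
#' @param universe optional character vector of reference-taxon symbols used
#'   as the sampling universe; defaults to all \code{toTaxon} symbols in the
#'   homology table.
#' @param R,seed Monte Carlo settings.
#' @return list with \code{common} (character vector, reference casing) and
#'   \code{overlap} (as from \code{\link{montecarloOverlapP}}).
#' @export
geneOverlapCrossSpecies <- function(deA, deB, homology, fromTaxon, toTaxon,
                                    universe = NULL, R = 10000, seed = 1) {
  conv <- mapHomologs(deB, homology, fromTaxon, toTaxon)
  mappedB <- unique(tolower(conv$mapped))
  common <- deA[tolower(deA) %in% mappedB]
  if (is.null(universe))
    universe <- unique(tolower(
      homology$gene_symbol[homology$taxon_id == toTaxon]))
  u <- length(unique(tolower(universe)))
  sizeA <- length(unique(tolower(deA)))
  sizeB <- length(mappedB)
  if (length(common) == 0) {
    ov <- list(observed_overlap = 0L, size_a = sizeA, size_b = sizeB,
               universe_size = u, mc_p = 1, R = as.integer(R),
               seed = as.integer(seed))
  } else {
    ov <- montecarloOverlapP(length(common), sizeA, sizeB, u, R = R,
                             seed = seed)
  }
  list(common = common, overlap = ov)
}

#' Direction concordance of common DE genes
#'
#' @param common character vector of common genes.
#' @param dirsA,dirsB named character vectors (\code{"up"}/\code{"down"})
#'   covering every common gene.
#' @return list with \code{table} (per-gene directions and concordant flag)
#'   and \code{summary} (percent concordant/opposite, per-list up
#'   percentages); percentages are \code{NA} for an empty common set.
#' @export
directionConcordance <- function(common, dirsA, dirsB) {
  if (!length(common)) {
    return(list(table = data.frame(gene = character(),
                                   direction_a = character(),
                                   direction_b = character(),
                                   concordant = logical(),
                                   stringsAsFactors = FALSE),
                summary = c(pct_concordant = NA_real_,
                            pct_opposite = NA_real_,
                            pct_up_a = NA_real_, pct_up_b = NA_real_)))
  }
  da <- dirsA[common]; db <- dirsB[common]
  miss <- common[is.na(da) | is.na(db)]
  if (length(miss))
    stop("missing direction for gene(s): ",
         paste(head(miss, 5), collapse = ", "))
  conc <- da == db
  tab <- data.frame(gene = common, direction_a = unname(da),
                    direction_b = unname(db), concordant = unname(conc),
                    stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(pct_concordant = 100 * mean(conc),
                   pct_opposite = 100 * mean(!conc),
                   pct_up_a = 100 * mean(da == "up"),
                   pct_up_b = 100 * mean(db == "up")))
}
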