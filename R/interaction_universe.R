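# Construction of the miRNA-mRNA interaction universe from per-tool
# prediction tables plus validated interactions, and ID conversion helpers
# (miRNA family map, cross-species homology map). Gene symbols are compared
# case-insensitively throughout (human symbols are upper-case, mouse symbols
# title-case); original casing is preserved in outputs.

#' Build the consensus interaction universe
#'
#' A predicted edge is kept iff supported by at least \code{minTools}
#' distinct tools; validated edges are always kept. When a pair is both
#' predicted and validated, a single record is emitted with status
#' \code{"validated"} and the supporting-tool count preserved.
#'
#' @param predictedTables named list of data.frames (one per tool) with
#'   columns mirna_id, gene_symbol; names are the tool names.
#' @param validatedTable data.frame with columns mirna_id, gene_symbol.
#' @param minTools consensus threshold (default 4).
#' @return an \linkS4class{InteractionUniverse}.
#' @export
buildUniverse <- function(predictedTables, validatedTable, minTools = 4) {
  minTools <- as.integer(minTools)
  stopifnot(minTools >= 1)
  if (is.null(names(predictedTables)) ||
      anyDuplicated(names(predictedTables)))
    stop("predictedTables must be uniquely named by tool")
  checkEdges <- function(df, what) {
    need <- c("mirna_id", "gene_symbol")
    if (!all(need %in% colnames(df)))
      stop(what, ": malformed edge table, need columns mirna_id, gene_symbol")
    bad <- which(is.na(df$mirna_id) | is.na(df$gene_symbol) |
                   df$mirna_id == "" | df$gene_symbol == "")
    if (length(bad))
      stop(what, ": malformed edge rows at lines ",
           paste(head(bad, 10), collapse = ", "))
    df
  }
  pairKey <- function(df) paste(df$mirna_id, tolower(df$gene_symbol))

  perTool <- lapply(names(predictedTables), function(tool) {
    df <- checkEdges(predictedTables[[tool]], tool)
    unique(pairKey(df))
  })
  counts <- table(unlist(perTool))

  # representative casing: first appearance across tools then validated
  allPred <- do.call(rbind, lapply(predictedTables, function(df)
    df[, c("mirna_id", "gene_symbol")]))
  rep_ <- allPred[!duplicated(pairKey(allPred)), , drop = FALSE]
  rownames(rep_) <- pairKey(rep_)

  predKeys <- names(counts)[counts >= minTools]

  val <- checkEdges(validatedTable, "validated")
  val <- val[!duplicated(pairKey(val)), , drop = FALSE]
  valKeys <- pairKey(val)
  rownames(val) <- valKeys

  allKeys <- union(predKeys, valKeys)
  isVal <- allKeys %in% valKeys
  src <- ifelse(isVal & allKeys %in% rownames(val), "val", "pred")
  getRow <- function(key) {
    if (key %in% valKeys) val[key, c("mirna_id", "gene_symbol")]
    else rep_[key, c("mirna_id", "gene_symbol")]
  }
  if (length(allKeys)) {
    rows <- do.call(rbind, lapply(allKeys, getRow))
    nTools <- as.integer(counts[allKeys])
    nTools[is.na(nTools)] <- 0L
    ed <- data.frame(mirna_id = rows$mirna_id,
                     gene_symbol = rows$gene_symbol,
                     status = ifelse(isVal, "validated", "predicted"),
                     n_tools = nTools, stringsAsFactors = FALSE)
    ed <- ed[order(ed$mirna_id, tolower(ed$gene_symbol)), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(mirna_id = character(), gene_symbol = character(),
                     status = character(), n_tools = integer(),
                     stringsAsFactors = FALSE)
  }
  new("InteractionUniverse", edges = ed, minTools = minTools)
}

#' Derive a species-neutral family name from a miRNA ID
#'
#' Fallback used when a family map has no entry: strips the species prefix
#' (e.g. \code{mmu-}, \code{hsa-}, \code{rno-}), the arm suffix
#' (\code{-3p}/\code{-5p}), a trailing paralog letter, and lower-cases
#' \code{miR} to \code{mir} (\code{mmu-miR-101b-3p} -> \code{mir-101}).
#'
#' @param ids character vector of miRNA IDs.
#' @return character vector of derived family names.
#' @export
familyFromName <- function(ids) {
  # species prefix only when followed by a miR/let stem ("let-7" is a stem)
  x <- sub("^[a-z]{3,4}-(?=(miR|mir|let))", "", ids, perl = TRUE)
  x <- sub("-(3p|5p)$", "", x)
  x <- sub("^miR", "mir", x)
  x <- sub("^let", "let", x)
  sub("^(mir-[0-9]+|let-[0-9]+)[a-z]*(-[0-9]+)?$", "\\1", x)
}

#' Convert miRNA IDs to family IDs
#'
#' @param mirnaIds character vector of species-specific miRNA IDs.
#' @param familyMap named character vector mirna_id -> family_id.
#' @param fallback if TRUE, IDs missing from the map are converted with
#'   \code{\link{familyFromName}} instead of being reported unmapped.
#' @return list with \code{families} (distinct family IDs of mapped inputs)
#'   and \code{unmapped} (input IDs without a map entry).
#' @export
mapToFamilies <- function(mirnaIds, familyMap, fallback = FALSE) {
  hit <- familyMap[mirnaIds]
  unmapped <- mirnaIds[is.na(hit)]
  fams <- unname(hit[!is.na(hit)])
  if (fallback && length(unmapped)) {
    fams <- c(fams, familyFromName(unmapped))
    unmapped <- character()
  }
  list(families = unique(fams), unmapped = unmapped)
}

#' Count distinct family IDs in (mirna_id, family_id) rows
#' @param rows data.frame with a \code{family_id} column.
#' @return integer count of distinct families.
#' @export
countUniqueFamilies <- function(rows) {
  if (!nrow(rows)) return(0L)
  length(unique(rows$family_id))
}

#' Map gene symbols across species through a homology table
#'
#' Each input symbol is looked up (case-insensitively) in the
#' \code{fromTaxon} rows, and translated to the symbol(s) of its homology
#' group in \code{toTaxon}. Symbols without a group, or whose group has no
#' \code{toTaxon} member, are reported unmapped.
#'
#' @param symbols character vector of gene symbols.
#' @param homology data.frame from \code{\link{readHomologyTsv}}.
#' @param fromTaxon,toTaxon taxon IDs present in the table.
#' @return list with \code{mapped} (named character vector, input symbol ->
#'   target symbol; multi-target groups yield multiple entries) and
#'   \code{unmapped}.
#' @export
mapHomologs <- function(symbols, homology, fromTaxon, toTaxon) {
  if (!all(c(fromTaxon, toTaxon) %in% homology$taxon_id))
    stop("taxa not present in homology table")
  from <- homology[homology$taxon_id == fromTaxon, , drop = FALSE]
  to <- homology[homology$taxon_id == toTaxon, , drop = FALSE]
  grp <- from$homology_group_id[match(tolower(symbols),
                                      tolower(from$gene_symbol))]
  mappedList <- lapply(seq_along(symbols), function(i) {
    if (is.na(grp[i])) return(character())
    to$gene_symbol[to$homology_group_id == grp[i]]
  })
  nHit <- lengths(mappedList)
  mapped <- setNames(unlist(mappedList, use.names = FALSE),
                     rep(symbols, nHit))
  list(mapped = mapped, unmapped = symbols[nHit == 0])
}

#' Expressed targets of a miRNA in the universe
#'
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param mirnaId a miRNA ID.
#' @param expressedGenes character vector of expressed gene symbols.
#' @return character vector of targets (universe targets intersected with
#'   the expressed set, case-insensitively; expressed-set casing returned).
#' @export
targetsOf <- function(universe, mirnaId, expressedGenes) {
  tg <- edges(universe)
  tg <- tg$gene_symbol[tg$mirna_id == mirnaId]
  expressedGenes[tolower(expressedGenes) %in% tolower(tg)]
}
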