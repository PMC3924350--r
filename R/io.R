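# Readers and writers for the plain-text interchange formats: expression
# TSV (first column feature ID, remaining columns samples), trait TSV,
# per-tool prediction TSV, validated TSV, family map TSV, Homologene-style
# homology TSV, GMT gene sets, and one-ID-per-line lists.

#' Read an expression TSV
#'
#' First column is the feature ID; remaining columns are per-sample log2
#' intensities. Group labels (and the consumption trait) are supplied via a
#' trait table.
#'
#' @param path expression TSV path.
#' @param traits data.frame with columns \code{sample_id}, \code{group} and
#'   optionally \code{consumption} (as from \code{\link{readTraitTsv}}).
#' @return a \linkS4class{MirExpression} object.
#' @export
readExpressionTsv <- function(path, traits) {
  df <- readTsv(path)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  idx <- match(colnames(v), traits$sample_id)
  if (anyNA(idx))
    stop("samples missing from trait table: ",
         paste(colnames(v)[is.na(idx)], collapse = ", "))
  MirExpression(v, traits$group[idx],
                if ("consumption" %in% colnames(traits))
                  traits$consumption[idx] else NULL)
}

#' Read a per-sample trait TSV (sample_id, group, consumption)
#' @param path trait TSV path.
#' @return data.frame.
#' @export
readTraitTsv <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a miRNA-target edge TSV (mirna_id, gene_symbol, ...)
#' @param path edge TSV path.
#' @return data.frame with at least mirna_id and gene_symbol.
#' @export
readEdgeTsv <- function(path) {
  df <- readTsv(path)
  need <- c("mirna_id", "gene_symbol")
  if (!all(need %in% colnames(df))) {
    bad <- which(!need %in% colnames(df))
    stop("'", path, "': malformed edge table, missing column(s) ",
         paste(need[bad], collapse = ", "))
  }
  bad <- which(is.na(df$mirna_id) | is.na(df$gene_symbol) |
                 df$mirna_id == "" | df$gene_symbol == "")
  if (length(bad))
    stop("'", path, "': malformed edge rows at lines ",
         paste(bad + 1L, collapse = ", "))
  df
}

#' Read a miRNA family map TSV (mirna_id, family_id)
#' @param path family TSV path.
#' @return named character vector mirna_id -> family_id.
#' @export
readFamilyTsv <- function(path) {
  df <- readTsv(path)
  if (!all(c("mirna_id", "family_id") %in% colnames(df)))
    stop("family map must have columns mirna_id, family_id")
  if (any(df$family_id == "" | is.na(df$family_id)))
    stop("empty family IDs in '", path, "'")
  setNames(df$family_id, df$mirna_id)
}

#' Read a Homologene-style homology TSV
#'
#' Columns: homology_group_id, taxon_id, gene_symbol. A (taxon, symbol) pair
#' may appear in at most one group.
#' @param path homology TSV path.
#' @return data.frame.
#' @export
readHomologyTsv <- function(path) {
  df <- readTsv(path)
  need <- c("homology_group_id", "taxon_id", "gene_symbol")
  if (!all(need %in% colnames(df)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$taxon_id, tolower(df$gene_symbol))
  dup <- df[duplicated(key) &
              !duplicated(paste(key, df$homology_group_id)), , drop = FALSE]
  if (nrow(dup))
    stop("(taxon, symbol) pairs in multiple homology groups: ",
         paste(head(dup$gene_symbol, 5), collapse = ", "))
  df
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member symbols, tab-separated.
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Read a one-ID-per-line list file
#' @param path list file path.
#' @return character vector (empty lines dropped).
#' @export
readIdList <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write an interaction universe as TSV
#' @param universe an \linkS4class{InteractionUniverse}.
#' @param path output path.
#' @export
writeUniverseTsv <- function(universe, path) {
  writeTsv(edges(universe), path)
}

#' Read an interaction universe written by \code{writeUniverseTsv}
#' @param path universe TSV path.
#' @param minTools consensus threshold recorded on the object.
#' @return an \linkS4class{InteractionUniverse}.
#' @export
readUniverseTsv <- function(path, minTools = 4) {
  df <- readEdgeTsv(path)
  new("InteractionUniverse",
      edges = df[, c("mirna_id", "gene_symbol", "status", "n_tools")],
      minTools = as.integer(minTools))
}

#' Export a bipartite network as edge-list and node-attribute TSVs
#'
#' @param network a \linkS4class{BipartiteNetwork}.
#' @param edgePath,nodePath output paths.
#' @return invisibly, the two paths.
#' @export
writeNetworkTsv <- function(network, edgePath, nodePath) {
  e <- edges(network)
  e$status <- network@label
  writeTsv(e, edgePath)
  deg <- c(table(e$mirna)[network@mirnaNodes],
           table(e$gene)[network@geneNodes])
  nodes <- data.frame(
    node = c(network@mirnaNodes, network@geneNodes),
    type = rep(c("mirna", "gene"),
               c(length(network@mirnaNodes), length(network@geneNodes))),
    degree = as.integer(deg),
    stringsAsFactors = FALSE)
  writeTsv(nodes, nodePath)
  invisible(c(edgePath, nodePath))
}
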