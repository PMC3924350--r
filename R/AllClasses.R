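#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-"
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pt pchisq phyper rnorm runif rbinom sd var median mad
#'   quantile hclust cutree as.dist lm coef p.adjust setNames complete.cases
#'   trigamma digamma psigamma
#' @importFrom utils read.delim write.table head combn
NULL

.MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

.TOOL_NAMES <- c(
  "DIANA-microT", "MicroInspector", "miRanda", "MirTarget2", "miTarget",
  "NBmiRTar", "PicTar", "PITA", "RNA22", "RNAhybrid", "TargetScan"
)

#' Expression data container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' log2-scale expression assay together with the two-group design
#' (\code{treated}/\code{control}) and, optionally, the per-sample ethanol
#' consumption trait (g/kg per 3-h session) in \code{colData}.
#'
#' @slot .. inherited from SummarizedExperiment; the assay is named
#'   \code{"log2"}.
#' @export
setClass("MirExpression", contains = "SummarizedExperiment")

setValidity("MirExpression", function(object) {
  msg <- character()
  v <- SummarizedExperiment::assay(object)
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate feature IDs")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate sample IDs")
  if (!all(is.finite(v)))
    msg <- c(msg, "non-finite expression values")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(cd$group %in% c("treated", "control"))) {
    msg <- c(msg, "group labels must be 'treated' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MirExpression object
#'
#' @param values numeric matrix of log2 intensities, features in rows,
#'   samples in columns; dimnames required.
#' @param group character vector of \code{"treated"}/\code{"control"} labels,
#'   one per sample.
#' @param consumption optional numeric vector of ethanol consumption
#'   (g/kg/3h), one per sample.
#' @return A \linkS4class{MirExpression} object.
#' @export
MirExpression <- function(values, group, consumption = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have feature and sample names")
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             row.names = colnames(values))
  if (!is.null(consumption)) cd$consumption <- as.numeric(consumption)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values), colData = cd)
  new("MirExpression", se)
}

#' miRNA-mRNA interaction universe
#'
#' Composite of validated and multi-tool-predicted miRNA-target edges.
#' Each edge carries a provenance status and the number of prediction tools
#' supporting it; predicted edges must reach the consensus threshold.
#'
#' @slot edges data.frame with columns \code{mirna_id}, \code{gene_symbol},
#'   \code{status} (\code{"validated"}/\code{"predicted"}), \code{n_tools}.
#' @slot minTools consensus threshold used at construction.
#' @export
setClass("InteractionUniverse",
  representation(edges = "data.frame", minTools = "integer"),
  prototype(edges = data.frame(mirna_id = character(),
                               gene_symbol = character(),
                               status = character(),
                               n_tools = integer(),
                               stringsAsFactors = FALSE),
            minTools = 4L))

setValidity("InteractionUniverse", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("mirna_id", "gene_symbol", "status", "n_tools")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(e$mirna_id, tolower(e$gene_symbol))))
    msg <- c(msg, "duplicate (mirna_id, gene_symbol) pairs")
  if (!all(e$status %in% c("validated", "predicted")))
    msg <- c(msg, "status must be 'validated' or 'predicted'")
  if (any(e$n_tools < 0L | e$n_tools > 11L))
    msg <- c(msg, "n_tools must be in 0..11")
  if (any(e$status == "predicted" & e$n_tools < object@minTools))
    msg <- c(msg, "predicted edges below the consensus threshold")
  if (length(msg)) msg else TRUE
})

#' Bipartite miRNA-mRNA targeting network
#'
#' Only nodes with degree >= 1 are members of the node sets (isolated
#' candidates are excluded, matching the convention used when such networks
#' are drawn).
#'
#' @slot mirnaNodes,geneNodes character vectors of member nodes.
#' @slot edgeTable data.frame with columns \code{mirna}, \code{gene}.
#' @slot label one of \code{"positive"}, \code{"negative"}, \code{"random"}.
#' @export
setClass("BipartiteNetwork",
  representation(mirnaNodes = "character", geneNodes = "character",
                 edgeTable = "data.frame", label = "character"),
  prototype(mirnaNodes = character(), geneNodes = character(),
            edgeTable = data.frame(mirna = character(), gene = character(),
                                   stringsAsFactors = FALSE),
            label = "positive"))

setValidity("BipartiteNetwork", function(object) {
  e <- object@edgeTable
  msg <- character()
  if (!all(c("mirna", "gene") %in% colnames(e)))
    return("edgeTable must have columns mirna, gene")
  if (!all(e$mirna %in% object@mirnaNodes) ||
      !all(e$gene %in% object@geneNodes))
    msg <- c(msg, "edge endpoints outside node sets")
  if (!all(object@mirnaNodes %in% e$mirna) ||
      !all(object@geneNodes %in% e$gene))
    msg <- c(msg, "isolated nodes present (degree-0 nodes are not members)")
  if (!object@label %in% c("positive", "negative", "random"))
    msg <- c(msg, "label must be positive/negative/random")
  if (length(msg)) msg else TRUE
})

#' Null-model summary for randomized targeting networks
#'
#' @slot meanDegree per-replicate average number of neighbors.
#' @slot overtargetProp per-replicate proportion of tested miRNAs flagged as
#'   over-targeting (BH adj. p < fdr).
#' @slot R number of replicates; @slot seed RNG seed used.
#' @export
setClass("NullSummary",
  representation(meanDegree = "numeric", overtargetProp = "numeric",
                 R = "integer", seed = "integer"),
  prototype(R = 1L, seed = 1L))

setValidity("NullSummary", function(object) {
  if (object@R < 1L) return("R must be >= 1")
  if (length(object@meanDegree) != object@R)
    return("meanDegree must have one entry per replicate")
  TRUE
})

#' Coexpression module set
#'
#' Gene-to-module assignment plus derived statistics: module eigengenes
#' (samples x modules, unit-norm columns), module membership (kME),
#' signed gene significance, and module-trait / module-miRNA correlation
#' tables.
#'
#' @slot labels named character vector, gene -> module color
#'   (\code{"grey"} = unassigned).
#' @slot eigengenes numeric matrix samples x modules.
#' @slot membership numeric matrix genes x modules (kME).
#' @slot geneSignificance named numeric, signed correlation with the trait.
#' @slot moduleTrait data.frame (module, r, p).
#' @slot moduleMirna data.frame (module, mirna, r, p, adj_p, significant).
#' @export
setClass("ModuleSet",
  representation(labels = "character", eigengenes = "matrix",
                 membership = "matrix", geneSignificance = "numeric",
                 moduleTrait = "data.frame", moduleMirna = "data.frame"),
  prototype(labels = character(), eigengenes = matrix(numeric(), 0, 0),
            membership = matrix(numeric(), 0, 0),
            geneSignificance = numeric(),
            moduleTrait = data.frame(), moduleMirna = data.frame()))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) && length(object@labels))
    msg <- c(msg, "labels must be named by gene")
  if (length(object@membership) &&
      any(abs(object@membership) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "module membership outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic paired miRNA/mRNA dataset generator. Defaults
#' emulate a two-group brain expression study: 20 treated and 12 control
#' samples, small log2 fold changes in [0.15, 0.7], five planted coexpression
#' modules whose eigengenes correlate with the ethanol-consumption trait at
#' 0.63, 0.55, -0.63, -0.74 and 0, and a target universe in which upregulated
#' miRNAs over-target upregulated genes by an odds multiplier of 4.
#'
#' @export
setClass("SimConfig",
  representation(nTreated = "integer", nControl = "integer",
                 nGenes = "integer", nMirnas = "integer",
                 moduleSpecs = "data.frame",
                 deFractionGenes = "numeric", deFractionMirnas = "numeric",
                 upFractionMirnas = "numeric",
                 logfcRange = "numeric", noiseSd = "numeric",
                 overtargetEnrichment = "numeric",
                 baselineEdgeProb = "numeric", validatedFraction = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nTreated, object@nControl, object@nGenes, object@nMirnas)
  if (any(cnt <= 0L)) msg <- c(msg, "all counts must be > 0")
  ms <- object@moduleSpecs
  if (nrow(ms)) {
    if (!all(c("module", "size", "traitCor") %in% colnames(ms)))
      msg <- c(msg, "moduleSpecs needs columns module, size, traitCor")
    else {
      if (sum(ms$size) > object@nGenes)
        msg <- c(msg, "module sizes exceed n_genes")
      if (any(abs(ms$traitCor) > 1))
        msg <- c(msg, "trait correlations must lie in [-1, 1]")
      if (any(ms$size <= 0)) msg <- c(msg, "module sizes must be > 0")
    }
  }
  pr <- c(object@deFractionGenes, object@deFractionMirnas,
          object@upFractionMirnas, object@baselineEdgeProb,
          object@validatedFraction)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "proportions must lie in [0, 1]")
  if (length(object@logfcRange) != 2L ||
      object@logfcRange[1] > object@logfcRange[2])
    msg <- c(msg, "logfcRange must be an interval low <= high")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@overtargetEnrichment < 1)
    msg <- c(msg, "overtargetEnrichment must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot geneDe,mirnaDe named character vectors with levels
#'   \code{up}/\code{down}/\code{null} covering every feature.
#' @slot moduleLabels named character, gene -> module id or \code{"noise"}.
#' @slot trait named numeric, per-sample consumption (g/kg/3h).
#' @slot plantedEdges data.frame (mirna_id, gene_symbol) of universe edges.
#' @export
setClass("SyntheticTruth",
  representation(geneDe = "character", mirnaDe = "character",
                 moduleLabels = "character", trait = "numeric",
                 plantedEdges = "data.frame"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (!all(object@geneDe %in% c("up", "down", "null")))
    msg <- c(msg, "gene DE labels must be up/down/null")
  if (!all(object@mirnaDe %in% c("up", "down", "null")))
    msg <- c(msg, "miRNA DE labels must be up/down/null")
  if (is.null(names(object@trait)))
    msg <- c(msg, "trait must be named by sample")
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes variance prior
#'
#' Scaled-F prior for gene-wise variances: \code{d0} prior degrees of freedom
#' (may be \code{Inf}) and \code{s0sq} prior variance (log2^2 units).
#' @export
setClass("EBayesParams",
  representation(d0 = "numeric", s0sq = "numeric"),
  prototype(d0 = Inf, s0sq = 1))

setValidity("EBayesParams", function(object) {
  if (object@d0 < 0) return("d0 must be >= 0")
  if (object@s0sq <= 0) return("s0sq must be > 0")
  TRUE
})
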