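# Accessors and show methods for the S4 containers.

#' Edge table of an interaction universe or bipartite network
#' @param x an \linkS4class{InteractionUniverse} or
#'   \linkS4class{BipartiteNetwork}.
#' @return data.frame of edges.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname edges
#' @export
setMethod("edges", "InteractionUniverse", function(x) x@edges)

#' @rdname edges
#' @export
setMethod("edges", "BipartiteNetwork", function(x) x@edgeTable)

#' miRNA nodes of a bipartite network
#' @param x a \linkS4class{BipartiteNetwork}.
#' @export
setGeneric("mirnaNodes", function(x) standardGeneric("mirnaNodes"))
#' @rdname mirnaNodes
#' @export
setMethod("mirnaNodes", "BipartiteNetwork", function(x) x@mirnaNodes)

#' Gene nodes of a bipartite network
#' @param x a \linkS4class{BipartiteNetwork}.
#' @export
setGeneric("geneNodes", function(x) standardGeneric("geneNodes"))
#' @rdname geneNodes
#' @export
setMethod("geneNodes", "BipartiteNetwork", function(x) x@geneNodes)

#' Gene-to-module assignment of a ModuleSet
#' @param x a \linkS4class{ModuleSet}.
#' @return named character vector, gene -> module color.
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' Module eigengene matrix (samples x modules)
#' @param x a \linkS4class{ModuleSet}.
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname eigengenes
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)

#' Module membership (kME) matrix (genes x modules)
#' @param x a \linkS4class{ModuleSet}.
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
#' @rdname moduleMembership
#' @export
setMethod("moduleMembership", "ModuleSet", function(x) x@membership)

#' Signed gene significance (correlation with the trait)
#' @param x a \linkS4class{ModuleSet}.
#' @export
setGeneric("geneSignificance", function(x) standardGeneric("geneSignificance"))
#' @rdname geneSignificance
#' @export
setMethod("geneSignificance", "ModuleSet", function(x) x@geneSignificance)

#' Module-trait correlation table
#' @param x a \linkS4class{ModuleSet}.
#' @export
setGeneric("moduleTraitTable", function(x) standardGeneric("moduleTraitTable"))
#' @rdname moduleTraitTable
#' @export
setMethod("moduleTraitTable", "ModuleSet", function(x) x@moduleTrait)

#' Module-miRNA correlation table
#' @param x a \linkS4class{ModuleSet}.
#' @export
setGeneric("moduleMirnaTable", function(x) standardGeneric("moduleMirnaTable"))
#' @rdname moduleMirnaTable
#' @export
setMethod("moduleMirnaTable", "ModuleSet", function(x) x@moduleMirna)

#' Expression values of a MirExpression object
#' @param x a \linkS4class{MirExpression}.
#' @return log2 expression matrix.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' Sample group labels of a MirExpression object
#' @param x a \linkS4class{MirExpression}.
#' @export
sampleGroups <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x))
}

#' Per-sample ethanol consumption trait (g/kg/3h), if recorded
#' @param x a \linkS4class{MirExpression}.
#' @export
consumption <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"consumption" %in% colnames(cd)) return(NULL)
  setNames(as.numeric(cd$consumption), colnames(x))
}

setMethod("show", "InteractionUniverse", function(object) {
  e <- object@edges
  cat("InteractionUniverse with", nrow(e), "edges\n")
  cat("  miRNAs:", length(unique(e$mirna_id)),
      " genes:", length(unique(e$gene_symbol)), "\n")
  cat("  validated:", sum(e$status == "validated"),
      " predicted (>=", object@minTools, "tools):",
      sum(e$status == "predicted"), "\n")
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork (", object@label, "): ",
      length(object@mirnaNodes), " miRNAs, ",
      length(object@geneNodes), " genes, ",
      nrow(object@edgeTable), " edges\n", sep = "")
})

setMethod("show", "NullSummary", function(object) {
  cat("NullSummary over", object@R, "randomized networks (seed",
      object@seed, ")\n")
  cat("  mean degree: mean", round(mean(object@meanDegree), 3),
      "sd", round(sd(object@meanDegree), 3), "\n")
  if (length(object@overtargetProp))
    cat("  overtargeting proportion: mean",
        round(mean(object@overtargetProp), 3), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat("ModuleSet:", length(object@labels), "genes in",
      sum(names(tab) != "grey"), "modules (+grey)\n")
  print(tab)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTreated, "treated +", object@nControl,
      "control samples;", object@nGenes, "genes,", object@nMirnas,
      "miRNAs; seed", object@seed, "\n")
  if (nrow(object@moduleSpecs)) {
    cat("  modules:\n")
    print(object@moduleSpecs, row.names = FALSE)
  }
})
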