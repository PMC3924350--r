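# End-to-end orchestration: differential expression -> interaction universe
# -> targeting networks with randomized nulls -> coexpression modules ->
# enrichment, from a single configuration, with one master seed split into
# per-stage substreams and a machine-readable JSON report. Identical
# configuration and seed give a byte-identical report.

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param simulate a \linkS4class{SimConfig} (default: the standard
#'   synthetic configuration with the pipeline seed), or \code{NULL} to read
#'   all inputs from files.
#' @param inputs named list of file paths (used when \code{simulate} is
#'   NULL): \code{mirna_expr}, \code{mrna_expr}, \code{traits},
#'   \code{predicted} (named vector, one per tool), \code{validated},
#'   \code{family_map}.
#' @param mirnaFdr,geneFdr DE thresholds (defaults 0.10 and 0.01).
#' @param overtargetFdr,corrFdr flag thresholds (default 0.10).
#' @param minTools consensus threshold (default 4).
#' @param beta soft-threshold power (default 12).
#' @param minModuleSize minimum module size (default 50, scaled to the
#'   2000-gene synthetic dataset).
#' @param cutHeight tree cut height fraction (default 0.99).
#' @param nullReps randomized-network replicates (default 1000).
#' @param mcReps Monte Carlo overlap replicates (default 10000).
#' @return a pipeline configuration list.
#' @export
pipelineConfig <- function(seed = 1, simulate = simConfig(seed = seed),
                           inputs = list(),
                           mirnaFdr = 0.10, geneFdr = 0.01,
                           overtargetFdr = 0.10, corrFdr = 0.10,
                           minTools = 4, beta = 12, minModuleSize = 50,
                           cutHeight = 0.99, nullReps = 1000,
                           mcReps = 10000) {
  stopifnot(mirnaFdr > 0, mirnaFdr < 1, geneFdr > 0, geneFdr < 1,
            overtargetFdr > 0, overtargetFdr < 1)
  list(seed = as.integer(seed), simulate = simulate, inputs = inputs,
       mirnaFdr = mirnaFdr, geneFdr = geneFdr,
       overtargetFdr = overtargetFdr, corrFdr = corrFdr,
       minTools = minTools, beta = beta, minModuleSize = minModuleSize,
       cutHeight = cutHeight, nullReps = nullReps, mcReps = mcReps)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of \code{\link{pipelineConfig}}; a
#' \code{simulate:} block holds \code{\link{simConfig}} arguments.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding file keys.
#' @return a pipeline configuration list.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  simArgs <- y$simulate
  y$simulate <- NULL
  args <- y[intersect(names(y), names(formals(pipelineConfig)))]
  cfg <- do.call(pipelineConfig, args)
  cfg$simulate <- if (is.null(simArgs)) NULL else {
    if (!is.null(simArgs$moduleSpecs))
      simArgs$moduleSpecs <- as.data.frame(simArgs$moduleSpecs)
    do.call(simConfig, simArgs)
  }
  cfg
}

.loadInputs <- function(config) {
  if (!is.null(config$simulate)) return(generateDataset(config$simulate))
  inp <- config$inputs
  need <- c("mirna_expr", "mrna_expr", "traits", "validated")
  missing <- setdiff(need, names(inp))
  if (length(missing))
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  for (p in unlist(inp))
    if (!file.exists(p)) stop("input file not found: '", p, "'")
  traits <- readTraitTsv(inp$traits)
  predicted <- lapply(inp$predicted, readEdgeTsv)
  names(predicted) <- names(inp$predicted)
  list(mirna = readExpressionTsv(inp$mirna_expr, traits),
       mrna = readExpressionTsv(inp$mrna_expr, traits),
       traits = traits,
       universe = buildUniverse(predicted, readEdgeTsv(inp$validated),
                                minTools = config$minTools),
       truth = NULL, config = config$simulate)
}

#' Run the full integrative analysis pipeline
#'
#' Stages, in order: differential expression of miRNAs and genes, the
#' interaction universe, the positively and negatively correlated bipartite
#' networks with randomized nulls and over-targeting tests, signed
#' coexpression analysis with module-trait and module-miRNA statistics, and
#' DE-in-module enrichment. Every intermediate table is written as TSV under
#' \code{outDir}; the structured report is written as
#' \code{report.json}.
#'
#' @param config a pipeline configuration from \code{\link{pipelineConfig}}.
#' @param outDir output directory, created if missing.
#' @param quiet suppress progress messages.
#' @return the report, invisibly (also written to
#'   \code{file.path(outDir, "report.json")}).
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else .logMsg
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed
  data <- stage("load", .loadInputs(config))

  deMirna <- stage("de-mirna", fitModeratedT(data$mirna))
  deGene <- stage("de-gene", fitModeratedT(data$mrna))
  writeTsv(deMirna, file.path(outDir, "de_mirna.tsv"))
  writeTsv(deGene, file.path(outDir, "de_gene.tsv"))
  mirCalls <- callDE(deMirna, config$mirnaFdr)
  geneCalls <- callDE(deGene, config$geneFdr)

  universe <- data$universe
  writeUniverseTsv(universe, file.path(outDir, "universe.tsv"))
  expressed <- rownames(exprValues(data$mrna))
  expressedMir <- rownames(exprValues(data$mirna))

  net <- stage("networks", {
    res <- list()
    targetable <- targetableGenes(universe, expressed)
    for (side in c("positive", "negative")) {
      geneSet <- if (side == "positive") geneCalls$up else geneCalls$down
      if (!length(mirCalls$up) || !length(geneSet)) {
        res[[side]] <- NULL
        next
      }
      bn <- buildBipartite(universe, mirCalls$up, geneSet, label = side)
      ot <- mirnaOvertargeting(universe, mirCalls$up, geneSet, expressed,
                               fdr = config$overtargetFdr)
      nullSum <- randomizeNetworks(
        universe, mirCalls$up, targetable,
        geneSetSize = length(intersect(tolower(geneSet),
                                       tolower(targetable))),
        R = config$nullReps,
        seed = substreamSeed(seed, paste0("null-", side)),
        fdr = config$overtargetFdr)
      writeNetworkTsv(bn, file.path(outDir, paste0(side, "_edges.tsv")),
                      file.path(outDir, paste0(side, "_nodes.tsv")))
      writeTsv(ot$table, file.path(outDir, paste0(side, "_overtarget.tsv")))
      res[[side]] <- list(network = bn, overtarget = ot, null = nullSum)
    }
    res
  })

  contrast <- if (!is.null(net$positive) && !is.null(net$negative)) {
    ct <- networkContrastReport(net$positive$network, net$negative$network,
                                net$positive$null, net$negative$null,
                                net$positive$overtarget,
                                net$negative$overtarget)
    writeTsv(ct, file.path(outDir, "network_contrast.tsv"))
    ct
  } else NULL

  coex <- stage("coexpression", {
    S <- signedSimilarity(data$mrna)
    a <- softAdjacency(S, config$beta)
    tom <- topologicalOverlap(a)
    labels <- detectModules(1 - tom, minModuleSize = config$minModuleSize,
                            cutHeight = config$cutHeight, expr = data$mrna)
    me <- moduleEigengenes(data$mrna, labels)
    trait <- consumption(data$mrna)
    deMirProfiles <- exprValues(data$mirna)[
      intersect(c(mirCalls$up, mirCalls$down),
                rownames(exprValues(data$mirna))), , drop = FALSE]
    ms <- relateToTraits(data$mrna, me, trait,
                         mirnaProfiles = if (nrow(deMirProfiles))
                           deMirProfiles else NULL,
                         labels = labels, fdr = config$corrFdr)
    writeTsv(data.frame(gene = names(labels), module = unname(labels),
                        stringsAsFactors = FALSE),
             file.path(outDir, "module_labels.tsv"))
    writeTsv(data.frame(module = colnames(me), t(me), check.names = FALSE),
             file.path(outDir, "eigengenes.tsv"))
    writeTsv(moduleTraitTable(ms), file.path(outDir, "module_trait.tsv"))
    if (nrow(moduleMirnaTable(ms)))
      writeTsv(moduleMirnaTable(ms), file.path(outDir, "module_mirna.tsv"))
    list(moduleSet = ms, adjacency = a)
  })

  enrich <- stage("enrichment", {
    de <- c(geneCalls$up, geneCalls$down)
    if (length(de)) {
      tab <- deInModuleEnrichment(moduleLabels(coex$moduleSet), de,
                                  expressed)
      writeTsv(tab, file.path(outDir, "de_in_module.tsv"))
      tab
    } else NULL
  })

  mt <- moduleTraitTable(coex$moduleSet)
  mt <- mt[order(-abs(mt$r)), , drop = FALSE]
  report <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("miRcoNet")),
    thresholds = config[c("mirnaFdr", "geneFdr", "overtargetFdr", "corrFdr",
                          "minTools", "beta", "minModuleSize", "cutHeight",
                          "nullReps", "mcReps")],
    de = list(
      n_mirna_up = length(mirCalls$up), n_mirna_down = length(mirCalls$down),
      n_gene_up = length(geneCalls$up), n_gene_down = length(geneCalls$down)),
    universe = list(n_edges = nrow(edges(universe)),
                    n_validated = sum(edges(universe)$status == "validated")),
    networks = lapply(net, function(x) list(
      n_mirnas = length(mirnaNodes(x$network)),
      n_genes = length(geneNodes(x$network)),
      n_edges = nrow(edges(x$network)),
      mean_degree = averageNeighbors(x$network),
      null_mean_degree = mean(x$null@meanDegree),
      null_sd_degree = sd(x$null@meanDegree),
      null_reps = x$null@R,
      overtarget_prop = if (nrow(x$overtarget$table))
        mean(x$overtarget$table$overtargeting) else NA,
      n_tested = nrow(x$overtarget$table))),
    contrast = contrast,
    modules = list(
      n_modules = length(setdiff(unique(moduleLabels(coex$moduleSet)),
                                 "grey")),
      n_grey = sum(moduleLabels(coex$moduleSet) == "grey"),
      module_trait = mt),
    de_in_module = enrich)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  say("report written to ", file.path(outDir, "report.json"))
  invisible(report)
}

#' Human-readable summary of a pipeline report
#'
#' Every printed number is a projection of a report field; nothing is
#' recomputed at print time.
#'
#' @param report report list from \code{\link{runPipeline}} (or parsed from
#'   \code{report.json}).
#' @return character vector of summary lines, invisibly; also printed.
#' @export
summarizeReport <- function(report) {
  fmt <- function(x, d = 2) formatC(x, digits = d, format = "f")
  lines <- c(
    sprintf("Seed %s | miRcoNet %s", report$seed, report$package_version),
    sprintf("DE miRNAs: %d up / %d down; DE genes: %d up / %d down",
            report$de$n_mirna_up, report$de$n_mirna_down,
            report$de$n_gene_up, report$de$n_gene_down),
    sprintf("Universe: %d edges (%d validated)",
            report$universe$n_edges, report$universe$n_validated))
  if (!length(report$networks)) {
    lines <- c(lines, "No targeting networks built (empty DE sets)")
  } else {
    for (nm in names(report$networks)) {
      x <- report$networks[[nm]]
      lines <- c(lines, sprintf(
        "%s network: %d miRNAs x %d genes, %d edges; mean degree %s (null %s +/- %s); overtargeting %d/%d",
        nm, x$n_mirnas, x$n_genes, x$n_edges, fmt(x$mean_degree),
        fmt(x$null_mean_degree), fmt(x$null_sd_degree),
        round(x$overtarget_prop * x$n_tested), x$n_tested))
    }
  }
  ct <- report$contrast
  if (!is.null(ct)) {
    for (i in seq_len(nrow(as.data.frame(ct)))) {
      r <- as.data.frame(ct)[i, ]
      lines <- c(lines, sprintf(
        "%s vs null proportion %s: chi2 = %s, p = %.3g (%s)",
        r$network, fmt(r$null_overtarget_prop), fmt(r$chi2), r$chi2_p,
        r$flag))
    }
  }
  mt <- as.data.frame(report$modules$module_trait)
  lines <- c(lines, sprintf("Modules: %d (+%d grey genes)",
                            report$modules$n_modules, report$modules$n_grey))
  for (i in seq_len(nrow(mt)))
    lines <- c(lines, sprintf("  module %-10s trait r = %6s  p = %.3g",
                              mt$module[i], fmt(mt$r[i]), mt$p[i]))
  cat(lines, sep = "\n")
  invisible(lines)
}
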