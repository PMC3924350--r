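# Synthetic paired miRNA/mRNA dataset generator. The generator emulates a
# two-group (treated/control) brain expression study on the log2 scale:
# planted coexpression modules are eigengene-driven (shared latent profile
# plus independent noise), the per-sample trait is voluntary ethanol
# consumption (zero in controls), and the miRNA-target universe is enriched
# for edges between upregulated miRNAs and upregulated genes.
#
# Because the consumption trait is almost collinear with the group indicator
# (controls drink nothing), any module latent correlated with consumption
# necessarily carries a group-mean shift. Gene-level differential expression
# is therefore delivered *through* the module loadings: a DE gene in a module
# with trait correlation rho receives loading logFC / (|rho| * group gap of
# the standardized trait), so its expected treated-minus-control difference
# equals the planted logFC and truth labels are exactly consistent with the
# generative model. DE genes beyond the capacity of the trait-correlated
# modules are planted as scattered group-shift genes (these share the
# treatment covariate and are only used when de_fraction is raised above its
# default).

#' Default planted-module specification
#'
#' Five modules: two positively and two negatively correlated with the
#' consumption trait (correlations echoing the strong rows of a typical
#' module-trait table: 0.63, 0.55, -0.63, -0.74) plus one trait-neutral
#' module of pure coexpression.
#' @return data.frame with columns module, size, traitCor.
#' @export
defaultModuleSpecs <- function() {
  data.frame(module = c("M1", "M2", "M3", "M4", "M5"),
             size = c(180L, 140L, 120L, 110L, 110L),
             traitCor = c(0.63, 0.55, -0.63, -0.74, 0),
             stringsAsFactors = FALSE)
}

#' Construct a simulation configuration
#'
#' @param nTreated,nControl group sizes (defaults 20 and 12).
#' @param nGenes,nMirnas numbers of simulated features.
#' @param moduleSpecs data.frame (module, size, traitCor); see
#'   \code{\link{defaultModuleSpecs}}.
#' @param deFractionGenes target fraction of DE genes; the default equals the
#'   capacity of the trait-correlated modules (550/2000).
#' @param deFractionMirnas fraction of DE miRNAs.
#' @param upFractionMirnas fraction of DE miRNAs that are upregulated.
#' @param logfcRange interval of planted |log2 fold changes|.
#' @param noiseSd residual noise sd, log2 units.
#' @param overtargetEnrichment odds multiplier (>= 1) applied to the edge
#'   probability of (up-miRNA, up-gene) pairs.
#' @param baselineEdgeProb baseline miRNA-gene edge probability.
#' @param validatedFraction fraction of universe edges marked validated.
#' @param seed integer master seed.
#' @return a \linkS4class{SimConfig} object.
#' @export
simConfig <- function(nTreated = 20, nControl = 12, nGenes = 2000,
                      nMirnas = 150, moduleSpecs = defaultModuleSpecs(),
                      deFractionGenes = 0.275, deFractionMirnas = 0.3,
                      upFractionMirnas = 0.9,
                      logfcRange = c(0.15, 0.7), noiseSd = 0.1,
                      overtargetEnrichment = 4, baselineEdgeProb = 0.02,
                      validatedFraction = 0.1, seed = 1) {
  cfg <- new("SimConfig",
             nTreated = as.integer(nTreated), nControl = as.integer(nControl),
             nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
             moduleSpecs = moduleSpecs,
             deFractionGenes = deFractionGenes,
             deFractionMirnas = deFractionMirnas,
             upFractionMirnas = upFractionMirnas,
             logfcRange = as.numeric(logfcRange),
             noiseSd = noiseSd,
             overtargetEnrichment = overtargetEnrichment,
             baselineEdgeProb = baselineEdgeProb,
             validatedFraction = validatedFraction,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Latent profile with exact in-sample correlation rho to the standardized
# trait z: the raw normal draw is residualized against z and standardized,
# then mixed as rho*z + sqrt(1-rho^2)*e.
.latentWithCor <- function(z, rho) {
  n <- length(z)
  e <- rnorm(n)
  e <- e - mean(e)
  e <- e - z * sum(e * z) / sum(z * z)
  e <- e / sd(e)
  rho * z + sqrt(1 - rho^2) * e
}

#' Plant eigengene-driven coexpression modules
#'
#' Standalone module generator: a standard-normal trait is drawn, each module
#' receives a latent profile with the requested in-sample trait correlation,
#' and module genes are the latent profile scaled by gene-specific loadings
#' plus independent noise. Non-module genes are independent noise.
#'
#' @param nGenes total number of genes.
#' @param moduleSpecs data.frame (module, size, traitCor).
#' @param nSamples number of samples.
#' @param noiseSd residual noise sd (log2 units).
#' @param seed integer seed.
#' @return list with \code{values} (genes x samples), \code{labels} (named,
#'   \code{"noise"} for non-module genes), \code{trait}, and \code{latents}
#'   (samples x modules).
#' @export
plantModules <- function(nGenes, moduleSpecs, nSamples, noiseSd, seed = 1) {
  if (nrow(moduleSpecs) && sum(moduleSpecs$size) > nGenes)
    stop("module sizes exceed n_genes")
  withr::with_seed(as.integer(seed), {
    geneIds <- sprintf("Gene%04d", seq_len(nGenes))
    trait <- as.numeric(scale(rnorm(nSamples)))
    labels <- setNames(rep("noise", nGenes), geneIds)
    values <- matrix(rnorm(nGenes * nSamples, sd = max(noiseSd, 0)),
                     nGenes, nSamples,
                     dimnames = list(geneIds, sprintf("S%02d",
                                                     seq_len(nSamples))))
    latents <- matrix(numeric(), nSamples, 0)
    at <- 0L
    for (i in seq_len(nrow(moduleSpecs))) {
      sz <- moduleSpecs$size[i]
      rho <- moduleSpecs$traitCor[i]
      idx <- at + seq_len(sz)
      at <- at + sz
      E <- .latentWithCor(trait, rho)
      loadings <- runif(sz, 1.5, 2.5) * max(noiseSd, 1e-8)
      values[idx, ] <- values[idx, ] + loadings %o% E
      labels[idx] <- moduleSpecs$module[i]
      latents <- cbind(latents, E)
    }
    colnames(latents) <- moduleSpecs$module
    list(values = values, labels = labels, trait = trait, latents = latents)
  })
}

#' Generate a complete synthetic dataset
#'
#' Produces paired miRNA and mRNA expression objects, the per-sample trait
#' table, the planted interaction universe, and the ground truth. Identical
#' configurations (including the seed) give identical outputs; each
#' generation stage draws from its own named substream of the master seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{mirna}, \code{mrna}
#'   (\linkS4class{MirExpression}), \code{traits} (data.frame),
#'   \code{universe} (\linkS4class{InteractionUniverse}), \code{truth}
#'   (\linkS4class{SyntheticTruth}) and \code{config}.
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nT <- config@nTreated; nC <- config@nControl; n <- nT + nC
  sampleIds <- sprintf("S%02d", seq_len(n))
  group <- c(rep("treated", nT), rep("control", nC))
  seed <- config@seed

  cons <- withSubstream(seed, "trait", c(rnorm(nT, 4.92, 0.52), rep(0, nC)))
  names(cons) <- sampleIds
  z <- as.numeric(scale(cons))
  dz <- mean(z[group == "treated"]) - mean(z[group == "control"])

  geneIds <- sprintf("Gene%04d", seq_len(config@nGenes))
  mirIds <- sprintf("sim-miR-%03d", seq_len(config@nMirnas))

  ms <- config@moduleSpecs
  moduleLabels <- setNames(rep("noise", config@nGenes), geneIds)
  geneDe <- setNames(rep("null", config@nGenes), geneIds)
  geneLogfc <- setNames(rep(0, config@nGenes), geneIds)

  values <- withSubstream(seed, "expression", {
    mu <- runif(config@nGenes, 6, 13)
    X <- mu + matrix(rnorm(config@nGenes * n, sd = config@noiseSd),
                     config@nGenes, n)
    dimnames(X) <- list(geneIds, sampleIds)

    nDeTarget <- round(config@deFractionGenes * config@nGenes)
    responsive <- which(nrow(ms) > 0 & ms$traitCor != 0)
    capacity <- if (length(responsive)) sum(ms$size[responsive]) else 0L
    # per-module number of DE genes, filled proportionally
    deInModules <- if (capacity > 0)
      pmin(ms$size, round(ms$size * min(1, nDeTarget / capacity))) else
      integer(nrow(ms))
    deInModules[ms$traitCor == 0] <- 0L

    at <- 0L
    for (i in seq_len(nrow(ms))) {
      sz <- ms$size[i]; rho <- ms$traitCor[i]
      idx <- at + seq_len(sz); at <- at + sz
      E <- .latentWithCor(z, rho)
      moduleLabels[idx] <- ms$module[i]
      if (rho != 0) {
        nde <- deInModules[i]
        f <- runif(sz, config@logfcRange[1], config@logfcRange[2])
        loadings <- f / (abs(rho) * dz)
        if (nde < sz) {
          # weak, sub-detectable loadings for non-DE members
          weak <- (nde + 1L):sz
          loadings[weak] <- runif(length(weak), 0.2, 0.5) *
            config@logfcRange[1] / (abs(rho) * dz)
        }
        X[idx, ] <- X[idx, ] + loadings %o% E
        if (nde > 0) {
          deIdx <- idx[seq_len(nde)]
          geneDe[deIdx] <- if (rho > 0) "up" else "down"
          geneLogfc[deIdx] <- f[seq_len(nde)] * sign(rho)
        }
      } else {
        loadings <- runif(sz, 1.5, 2.5) * max(config@noiseSd, 1e-8)
        X[idx, ] <- X[idx, ] + loadings %o% E
      }
    }
    # scattered DE genes if the target exceeds module capacity
    nScatter <- max(0L, nDeTarget - sum(deInModules))
    if (nScatter > 0) {
      free <- which(moduleLabels == "noise")
      pick <- free[seq_len(min(nScatter, length(free)))]
      f <- runif(length(pick), config@logfcRange[1], config@logfcRange[2])
      sgn <- ifelse(runif(length(pick)) < 0.58, 1, -1)
      X[pick, ] <- X[pick, ] +
        (f * sgn) %o% as.numeric(group == "treated")
      geneDe[pick] <- ifelse(sgn > 0, "up", "down")
      geneLogfc[pick] <- f * sgn
    }
    X
  })

  mirnaDe <- setNames(rep("null", config@nMirnas), mirIds)
  mirValues <- withSubstream(seed, "mirna", {
    mu <- runif(config@nMirnas, 6, 13)
    M <- mu + matrix(rnorm(config@nMirnas * n, sd = config@noiseSd),
                     config@nMirnas, n)
    dimnames(M) <- list(mirIds, sampleIds)
    nDe <- round(config@deFractionMirnas * config@nMirnas)
    nUp <- round(config@upFractionMirnas * nDe)
    if (nDe > 0) {
      deIdx <- seq_len(nDe)
      f <- runif(nDe, config@logfcRange[1], config@logfcRange[2])
      sgn <- c(rep(1, nUp), rep(-1, nDe - nUp))
      M[deIdx, ] <- M[deIdx, ] + (f * sgn) %o% as.numeric(group == "treated")
      mirnaDe[deIdx] <- ifelse(sgn > 0, "up", "down")
    }
    M
  })

  universe <- withSubstream(seed, "edges", {
    upMir <- names(mirnaDe)[mirnaDe == "up"]
    upGene <- names(geneDe)[geneDe == "up"]
    p <- matrix(config@baselineEdgeProb, config@nMirnas, config@nGenes,
                dimnames = list(mirIds, geneIds))
    p[upMir, upGene] <- pmin(1, config@baselineEdgeProb *
                                  config@overtargetEnrichment)
    hit <- which(matrix(runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
    ed <- data.frame(mirna_id = mirIds[hit[, 1]],
                     gene_symbol = geneIds[hit[, 2]],
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$mirna_id, ed$gene_symbol), , drop = FALSE]
    validated <- runif(nrow(ed)) < config@validatedFraction
    nTools <- integer(nrow(ed))
    nTools[!validated] <- sample(4:11, sum(!validated), replace = TRUE,
                                 prob = 8:1)
    nTools[validated] <- sample(0:11, sum(validated), replace = TRUE,
                                prob = 12:1)
    ed$status <- ifelse(validated, "validated", "predicted")
    ed$n_tools <- nTools
    rownames(ed) <- NULL
    new("InteractionUniverse", edges = ed, minTools = 4L)
  })

  traits <- data.frame(sample_id = sampleIds, group = group,
                       consumption = round(as.numeric(cons), 3),
                       stringsAsFactors = FALSE)

  truth <- new("SyntheticTruth",
               geneDe = geneDe, mirnaDe = mirnaDe,
               moduleLabels = moduleLabels,
               trait = setNames(traits$consumption, sampleIds),
               plantedEdges = edges(universe)[, c("mirna_id", "gene_symbol")])

  list(mirna = MirExpression(mirValues, group, traits$consumption),
       mrna = MirExpression(values, group, traits$consumption),
       traits = traits,
       universe = universe,
       truth = truth,
       config = config)
}

#' Write a synthetic dataset as a bundle of plain-text fixture files
#'
#' Emits the expression TSVs, trait TSV, one prediction TSV per tool, a
#' validated-interaction TSV, a miRNA-family map covering every simulated
#' miRNA, and a toy mouse/human homology table. The per-tool files include
#' sub-consensus decoy predictions so that rebuilding the universe from the
#' files genuinely exercises the consensus filter. All files round-trip
#' losslessly through the package readers.
#'
#' @param dataset list returned by \code{\link{generateDataset}}.
#' @param dir output directory (created if missing).
#' @param toolNames names of the prediction tools (default: the 11 standard
#'   target-prediction programs).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtureBundle <- function(dataset, dir, toolNames = .TOOL_NAMES) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", dir, "'")
  }
  cfg <- dataset$config
  paths <- c()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    writeTsv(df, p)
    paths[[name]] <<- p
    p
  }

  exprDf <- function(x) {
    v <- exprValues(x)
    data.frame(feature_id = rownames(v), as.data.frame(v),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  emit(exprDf(dataset$mrna), "mrna_expression.tsv")
  emit(exprDf(dataset$mirna), "mirna_expression.tsv")
  emit(dataset$traits, "traits.tsv")

  ed <- edges(dataset$universe)
  withSubstream(cfg@seed, "fixtures", {
    # assign each edge its supporting tools
    toolAssign <- lapply(seq_len(nrow(ed)), function(i) {
      nt <- ed$n_tools[i]
      if (nt > 0) sample(toolNames, nt) else character()
    })
    # decoy predictions below the consensus threshold
    nDecoy <- max(10L, nrow(ed) %/% 5L)
    decoy <- data.frame(
      mirna_id = sample(rownames(exprValues(dataset$mirna)), nDecoy, TRUE),
      gene_symbol = sample(rownames(exprValues(dataset$mrna)), nDecoy, TRUE),
      stringsAsFactors = FALSE)
    decoy <- decoy[!paste(decoy$mirna_id, decoy$gene_symbol) %in%
                     paste(ed$mirna_id, ed$gene_symbol), , drop = FALSE]
    decoy <- decoy[!duplicated(paste(decoy$mirna_id, decoy$gene_symbol)), ,
                   drop = FALSE]
    decoyTools <- lapply(seq_len(nrow(decoy)),
                         function(i) sample(toolNames, sample(1:3, 1)))
    for (tool in toolNames) {
      keep <- vapply(toolAssign, function(s) tool %in% s, logical(1))
      dkeep <- vapply(decoyTools, function(s) tool %in% s, logical(1))
      tab <- rbind(ed[keep, c("mirna_id", "gene_symbol")],
                   decoy[dkeep, , drop = FALSE])
      tab <- tab[order(tab$mirna_id, tab$gene_symbol), , drop = FALSE]
      emit(tab, paste0("predicted_", gsub("[^A-Za-z0-9]", "", tool), ".tsv"))
    }
  })

  val <- ed[ed$status == "validated", c("mirna_id", "gene_symbol")]
  val$source <- "synthetic-validation"
  emit(val, "validated.tsv")

  mirIds <- rownames(exprValues(dataset$mirna))
  fam <- data.frame(mirna_id = mirIds,
                    family_id = paste0("mir-f",
                                       ((seq_along(mirIds) - 1L) %/% 3L) + 1L),
                    stringsAsFactors = FALSE)
  emit(fam, "family_map.tsv")

  geneIds <- rownames(exprValues(dataset$mrna))
  hom <- data.frame(
    homology_group_id = rep(paste0("H", seq_along(geneIds)), each = 2),
    taxon_id = rep(c(10090L, 9606L), length(geneIds)),
    gene_symbol = as.vector(rbind(geneIds, toupper(geneIds))),
    stringsAsFactors = FALSE)
  emit(hom, "homology.tsv")

  invisible(unlist(paths))
}
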