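#' Read an expression study from TSV files
#'
#' Expression file: first column the gene id, remaining columns one per
#' sample with a header row of sample ids. Metadata file: one row per sample
#' with a `sampleID` column (or rownames) and the covariate columns. Genes
#' are canonicalized to id-sorted order; categorical levels are normalized.
#'
#' @param expressionPath path to the expression TSV/CSV.
#' @param metadataPath path to the sample metadata TSV/CSV.
#' @param name study label.
#' @return an [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(expressionPath, metadataPath,
                                name = "study") {
  sepFor <- function(path) if (grepl("\\.csv$", path)) "," else "\t"
  em <- utils::read.delim(expressionPath, sep = sepFor(expressionPath),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(em) < 2)
    stopf("validation error: expression table needs a gene id column and samples")
  gids <- as.character(em[[1]])
  dup <- gids[duplicated(gids)]
  if (length(dup))
    stopf("validation error: duplicated gene id(s): %s",
          paste(utils::head(unique(dup), 5), collapse = ", "))
  m <- as.matrix(em[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gids
  if (anyNA(m)) {
    badRows <- rownames(m)[rowSums(is.na(m)) > 0]
    stopf("validation error: missing expression values in gene(s): %s",
          paste(utils::head(badRows, 5), collapse = ", "))
  }
  md <- utils::read.delim(metadataPath, sep = sepFor(metadataPath),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if ("sampleID" %in% colnames(md)) {
    rownames(md) <- as.character(md$sampleID)
    md$sampleID <- NULL
  }
  missing <- setdiff(colnames(m), rownames(md))
  if (length(missing))
    stopf("validation error: sample(s) in matrix but not metadata: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(rownames(md), colnames(m))
  if (length(extra))
    stopf("validation error: sample(s) in metadata but not matrix: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  md <- md[colnames(m), , drop = FALSE]
  ord <- order(rownames(m))
  ExpressionStudy(m[ord, , drop = FALSE], md, name = name)
}

#' Write stage outputs with deterministic formatting
#'
#' Writes each table as a TSV with a fixed column order and numeric columns
#' formatted to 9 significant digits, so identical inputs yield
#' byte-identical files.
#'
#' @param results named list of data.frames.
#' @param dir existing output directory.
#' @return data.frame manifest with `file` and `rows`.
#' @export
writeResults <- function(results, dir) {
  if (!dir.exists(dir))
    stopf("I/O error: directory does not exist: %s", dir)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stopf("results must be a named list of data.frames")
  files <- character(0); rows <- integer(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    out <- df
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
    fn <- paste0(nm, ".tsv")
    utils::write.table(out, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files <- c(files, fn)
    rows <- c(rows, nrow(df))
  }
  data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' The configuration supplies either paths for two real studies
#' (`study1: {expression: ..., metadata: ...}`, same for `study2`) or a
#' `sim:` block with [simConfig()] fields, plus the analysis options (see
#' [runPipeline()]). Exactly one input source must be present.
#'
#' @param path YAML file.
#' @return a named list usable as [runPipeline()] config.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    for (f in c("study1", "study2", "nSpecificDE", "covariateEffects"))
      if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
    cfg$sim <- do.call(simConfig, sim)
  }
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[%s] %s", stage, conditionMessage(e))
  })
}

#' Run the full two-study replication analysis
#'
#' End-to-end pipeline: per-study covariate-adjusted moderated-t
#' differential expression, cross-study overlap profiling and q2 selection,
#' sign-concordant consensus sets, Fisher p-value combination at the chosen
#' FDR level, optional gene-set enrichment of the UP and DOWN lists, and the
#' coupled-signature bioscalar analysis per study. All intermediate tables
#' are written when an output directory is given; the run is fully
#' reproducible given the seed.
#'
#' @param config named list (or [readPipelineConfig()] output) with either
#'   `study1`/`study2` path lists or a `sim` [simConfig()]; optional fields
#'   `covariates` (default batch, sex, age, anxiety), `ratioRule` (2),
#'   `pMax` (.05), `q2Method` ("credible"), `fdrLevel` (0.10), `nPerm` (0 =
#'   asymptotic only), `gmt` (path), `alpha` (.05), `standardize` (TRUE),
#'   `outDir`, `seed` (1).
#' @return a list summary: aligned gene count, `q2`, `noReplication` flag,
#'   consensus sizes, combined-test rejections, per-study coupling `r`,
#'   Cohen's d, AUC, tertile cutoff and specificity, the per-stage objects,
#'   and the output manifest when files were written.
#' @export
runPipeline <- function(config) {
  hasPaths <- !is.null(config$study1) || !is.null(config$study2)
  hasSim <- !is.null(config$sim)
  if (hasPaths && hasSim)
    stopf("config error: supply either study paths or a simulation config, not both")
  if (!hasPaths && !hasSim)
    stopf("config error: supply study paths or a simulation config")
  seed <- as.integer(config$seed %||% 1L)
  covariates <- config$covariates %||% c("batch", "sex", "age", "anxiety")
  ratioRule <- config$ratioRule %||% 2
  pMax <- config$pMax %||% 0.05
  q2Method <- config$q2Method %||% "credible"
  fdrLevel <- config$fdrLevel %||% 0.10
  nPerm <- config$nPerm %||% 0L
  outDir <- config$outDir

  truth <- NULL
  if (hasSim) {
    simCfg <- config$sim
    simCfg$seed <- seed
    message("simulating two studies (", simCfg$nGenes, " genes)")
    sim <- stageTry("simulate", generateTwoStudies(simCfg))
    studies <- list(sim$study1, sim$study2)
    truth <- sim$truth
  } else {
    studies <- stageTry("read", list(
      readExpressionStudy(config$study1$expression, config$study1$metadata,
                          name = "study1"),
      readExpressionStudy(config$study2$expression, config$study2$metadata,
                          name = "study2")))
  }

  common <- intersect(rownames(studies[[1]]), rownames(studies[[2]]))
  if (!length(common))
    stopf("[align] no genes shared between the studies")
  message("aligned ", length(common), " genes shared by both studies")
  studies <- lapply(studies, function(s) s[common, ])

  stats <- vector("list", 2)
  for (i in 1:2) {
    stats[[i]] <- stageTry("diffexpr", {
      design <- buildDesign(colData(studies[[i]]), covariates)
      fits <- fitGeneModels(studies[[i]], design)
      prior <- estimateVariancePrior(fits)
      st <- moderatedStatistics(fits, prior)
      if (nPerm > 0) {
        st@pPerm <- unname(permutationPvalues(
          studies[[i]], design, nPerm = nPerm,
          seed = splitSeed(seed, 400L + i), prior = prior))
      }
      st
    })
    message("study", i, ": ", sum(stats[[i]]@pValue <= 0.05),
            " genes at p <= .05")
  }

  profile <- stageTry("replicate", overlapProfile(
    pValues(stats[[1]]), pValues(stats[[2]]), pMax = pMax))
  q2 <- stageTry("replicate", selectQ2(
    profile, ratioRule = ratioRule, pMax = pMax, method = q2Method,
    seed = splitSeed(seed, 500L)))
  profile@q2 <- q2
  profile@ratioRule <- ratioRule

  combined <- stageTry("combine", fisherCombine(
    pValues(stats[[1]]), pValues(stats[[2]]), fdrLevel = fdrLevel))

  summary <- list(nGenes = length(common), q2 = q2,
                  noReplication = is.na(q2),
                  fisherRejected = sum(combined@rejected),
                  fdrLevel = fdrLevel, seed = seed)

  consensus <- NULL
  enrichment <- NULL
  bios <- list()
  if (!is.na(q2)) {
    consensus <- stageTry("consensus",
                          consensusSet(stats[[1]], stats[[2]], q2))
    summary$nConsensus <- length(upGenes(consensus)) +
      length(downGenes(consensus))
    summary$nUp <- length(upGenes(consensus))
    summary$nDown <- length(downGenes(consensus))
    summary$nDiscordant <- length(discordantGenes(consensus))
    message("consensus at q2 = ", signif(q2, 4), ": ", summary$nUp, " UP, ",
            summary$nDown, " DOWN, ", summary$nDiscordant, " discordant")

    if (!is.null(config$gmt)) {
      enrichment <- stageTry("enrich", {
        coll <- loadGeneSets(config$gmt, common)
        list(up = fisherEnrichment(upGenes(consensus), coll,
                                   alpha = config$alpha %||% 0.05),
             down = fisherEnrichment(downGenes(consensus), coll,
                                     alpha = config$alpha %||% 0.05))
      })
    }

    if (summary$nUp > 0 && summary$nDown > 0) {
      for (i in 1:2) {
        bios[[i]] <- stageTry("bioscalar", {
          sc <- signatureScores(studies[[i]], upGenes(consensus),
                                downGenes(consensus),
                                standardize = config$standardize %||% TRUE)
          line <- fitCouplingLine(sc)
          summarizeBioscalar(projectBioscalar(sc, line))
        })
        summary[[paste0("r", i)]] <- bios[[i]]@line@r
        summary[[paste0("cohensD", i)]] <- bios[[i]]@cohensD
        summary[[paste0("auc", i)]] <- bios[[i]]@auc
        summary[[paste0("cutoff", i)]] <- bios[[i]]@cutoff
        summary[[paste0("specificity", i)]] <- bios[[i]]@specificity
      }
    }
  } else {
    message("no replicated signal; downstream consensus stages skipped")
  }

  result <- list(summary = summary, stats = stats, profile = profile,
                 consensus = consensus, combined = combined,
                 enrichment = enrichment, bioscalar = bios, truth = truth)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    tables <- list(study1_stats = statsTable(stats[[1]]),
                   study2_stats = statsTable(stats[[2]]),
                   overlap_profile = profileTable(profile))
    if (!is.null(consensus)) {
      tables$consensus <- data.frame(
        geneID = c(upGenes(consensus), downGenes(consensus),
                   discordantGenes(consensus)),
        direction = rep(c("UP", "DOWN", "discordant"),
                        c(length(upGenes(consensus)),
                          length(downGenes(consensus)),
                          length(discordantGenes(consensus)))),
        stringsAsFactors = FALSE)
    }
    tables$combined <- data.frame(geneID = combined@geneIDs,
                                  X2 = combined@statistic,
                                  pValue = combined@pValue,
                                  qValue = combined@qValue,
                                  rejected = combined@rejected,
                                  stringsAsFactors = FALSE)
    if (!is.null(enrichment)) {
      tables$enrichment_up <- enrichment$up
      tables$enrichment_down <- enrichment$down
    }
    for (i in seq_along(bios)) {
      tables[[paste0("study", i, "_bioscalar")]] <- data.frame(
        sampleID = bios[[i]]@sampleIDs,
        group = as.character(bios[[i]]@group),
        bioscalar = bios[[i]]@bioscalar,
        inflamed = bios[[i]]@inflamed,
        stringsAsFactors = FALSE)
    }
    result$manifest <- stageTry("write", writeResults(tables, outDir))
  }
  result
}
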