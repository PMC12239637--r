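#' Pipeline run configuration
#'
#' Paths and thresholds for [runPipeline()]. When input paths are NULL the
#' \code{simulate} stage's outputs inside \code{outDir} are used, so
#' \code{runPipeline("all")} is self-contained.
#'
#' @param counts,samples,annotation,phenotypes optional input paths
#'   (counts TSV, sample sheet CSV, annotation TSV, phenotype CSV).
#' @param tpmFilter expressed-gene TPM threshold (default 2).
#' @param biasThreshold tau threshold (default 0.7).
#' @param zeroFloor detection floor in TPM (default 0.1).
#' @param qThreshold BH-adjusted significance cutoff (default 0.05).
#' @param patterns optional family-pattern TSV (see [readFamilyPatterns()]).
#' @param seed seed for the simulate stage.
#' @param synthetic optional [syntheticConfig()] overriding the default
#'   simulation design.
#' @param phenoConfig optional [phenotypeConfig()] for simulated assays.
#' @return list of class \code{"RunConfig"}.
#' @export
pipelineConfig <- function(counts = NULL, samples = NULL, annotation = NULL,
                           phenotypes = NULL, tpmFilter = 2,
                           biasThreshold = 0.7, zeroFloor = 0.1,
                           qThreshold = 0.05, patterns = NULL, seed = 1,
                           synthetic = NULL, phenoConfig = NULL) {
  .assertThat(tpmFilter >= 0 && biasThreshold >= 0 && biasThreshold <= 1 &&
                zeroFloor >= 0 && qThreshold > 0 && qThreshold <= 1,
              "thresholds out of range")
  structure(list(counts = counts, samples = samples, annotation = annotation,
                 phenotypes = phenotypes, tpmFilter = tpmFilter,
                 biasThreshold = biasThreshold, zeroFloor = zeroFloor,
                 qThreshold = qThreshold, patterns = patterns, seed = seed,
                 synthetic = synthetic, phenoConfig = phenoConfig),
            class = "RunConfig")
}

#' @noRd
.pipePath <- function(config, field, outDir, default, stageNeeded) {
  path <- config[[field]]
  if (is.null(path)) path <- file.path(outDir, default)
  if (!file.exists(path))
    stop("stage '", stageNeeded, "' requires file '", path,
         "'; run the upstream stage or point the config at an input",
         call. = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end to end. Each stage writes TSV/JSON artifacts
#' into \code{outDir} plus a run manifest (package version, thresholds,
#' seed, input checksums). Outputs are deterministic: two runs with the
#' same configuration and seed are byte-identical.
#'
#' Stages: \code{simulate} (synthetic counts, annotation, truth and
#' phenotypes), \code{normalize} (TPM, subtissue collapse, profiles,
#' expressed universe), \code{classify} (tau classification, summary
#' table, secondary-style domain comparison), \code{contrast}
#' (median-of-ratios planned contrasts), \code{families} (PME/PMEI
#' curation and reports), \code{phenotypes} (assay summaries and species
#' comparisons), \code{report} (assembled JSON summary), or \code{all}.
#'
#' @param stage one of the stage names above.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(stage = "all", outDir, config = pipelineConfig()) {
  stages <- c("simulate", "normalize", "classify", "contrast", "families",
              "phenotypes", "report")
  .assertThat(stage %in% c(stages, "all"),
              paste0("unknown stage '", stage, "'"))
  .assertThat(inherits(config, "RunConfig"),
              "config must come from pipelineConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages else stage
  for (s in todo) {
    t0 <- Sys.time()
    switch(s,
           simulate = .stageSimulate(outDir, config),
           normalize = .stageNormalize(outDir, config),
           classify = .stageClassify(outDir, config),
           contrast = .stageContrast(outDir, config),
           families = .stageFamilies(outDir, config),
           phenotypes = .stagePhenotypes(outDir, config),
           report = .stageReport(outDir, config))
    message(sprintf("[%s] done in %.1fs", s,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  .writeManifest(outDir, config)
  invisible(outDir)
}

#' @noRd
.stageSimulate <- function(outDir, config) {
  sc <- config$synthetic
  if (is.null(sc)) sc <- syntheticConfig(seed = config$seed)
  pc <- config$phenoConfig
  if (is.null(pc)) pc <- phenotypeConfig(seed = config$seed)
  sim <- generateExpression(sc)
  writeCounts(sim$counts, file.path(outDir, "counts.tsv"))
  utils::write.csv(sampleTable(sim$counts), file.path(outDir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(sim$annotation, file.path(outDir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeResultTable(sim$truth$table, file.path(outDir, "truth.tsv"))
  writePhenotypes(generatePhenotypes(pc), file.path(outDir, "phenotypes.csv"))
  invisible(NULL)
}

#' @noRd
.loadCounts <- function(outDir, config, stage) {
  countsPath <- .pipePath(config, "counts", outDir, "counts.tsv", stage)
  samplesPath <- .pipePath(config, "samples", outDir, "samples.csv", stage)
  readCounts(countsPath, samplesPath)
}

#' @noRd
.stageNormalize <- function(outDir, config) {
  tc <- .loadCounts(outDir, config, "normalize")
  collapsed <- collapseSubtissues(computeTpm(tc))
  mat <- SummarizedExperiment::assay(collapsed, "tpm")
  df <- data.frame(gene_id = rownames(mat), signif(mat, 10),
                   check.names = FALSE)
  utils::write.table(df, file.path(outDir, "tpm_collapsed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  profiles <- tissueProfiles(collapsed)
  universe <- filterExpressed(profiles, config$tpmFilter)
  writeLines(universe, file.path(outDir, "universe.txt"))
  wide <- do.call(cbind, lapply(profiles@species, function(sp)
    tissueMeans(profiles, sp)))
  colnames(wide) <- paste(rep(profiles@species, each = 3),
                          rep(.tissueLevels(), length(profiles@species)),
                          sep = "_")
  writeResultTable(data.frame(gene_id = rownames(wide), wide,
                              check.names = FALSE),
                   file.path(outDir, "profiles.tsv"))
  invisible(NULL)
}

## rebuild a collapsed TpmExperiment from the tpm_collapsed.tsv artifact
#' @noRd
.loadCollapsed <- function(outDir, config, stage) {
  path <- file.path(outDir, "tpm_collapsed.tsv")
  if (!file.exists(path))
    stop("stage '", stage, "' requires file '", path,
         "'; run the 'normalize' stage first", call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  parts <- strsplit(colnames(mat), ".", fixed = TRUE)
  st <- data.frame(sample_id = colnames(mat),
                   species = vapply(parts, `[`, "", 1),
                   tissue = vapply(parts, `[`, "", 2),
                   subtissue = "",
                   bio_rep = as.integer(sub("^r", "",
                                            vapply(parts, `[`, "", 3))),
                   stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = mat),
    colData = S4Vectors::DataFrame(st, row.names = st$sample_id))
  methods::new("TpmExperiment", se)
}

#' @noRd
.loadUniverse <- function(outDir, stage) {
  path <- file.path(outDir, "universe.txt")
  if (!file.exists(path))
    stop("stage '", stage, "' requires file '", path,
         "'; run the 'normalize' stage first", call. = FALSE)
  readLines(path)
}

#' @noRd
.stageClassify <- function(outDir, config) {
  profiles <- tissueProfiles(.loadCollapsed(outDir, config, "classify"))
  universe <- .loadUniverse(outDir, "classify")
  cl <- classifyGenes(profiles, universe,
                      biasThreshold = config$biasThreshold,
                      exprThreshold = config$tpmFilter,
                      zeroFloor = config$zeroFloor)
  writeResultTable(cl, file.path(outDir, "classifications.tsv"))
  tbl <- summarizeTable1(cl, profiles, exprThreshold = config$tpmFilter)
  writeResultTable(table1Report(tbl), file.path(outDir, "table1.tsv"))
  jsonlite::write_json(tbl, file.path(outDir, "table1.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  dc <- compareSecondaryStyleExpression(cl, profiles,
                                        exprFloor = config$tpmFilter,
                                        absentFloor = config$zeroFloor)
  writeResultTable(dc$per_gene, file.path(outDir, "domain_comparison.tsv"))
  jsonlite::write_json(dc[setdiff(names(dc), "per_gene")],
                       file.path(outDir, "domain_comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @noRd
.stageContrast <- function(outDir, config) {
  tc <- .loadCounts(outDir, config, "contrast")
  universe <- .loadUniverse(outDir, "contrast")
  res <- runPlannedContrasts(tc, universe, qThreshold = config$qThreshold)
  writeResultTable(res, file.path(outDir, "contrasts.tsv"))
  invisible(NULL)
}

#' @noRd
.stageFamilies <- function(outDir, config) {
  annPath <- .pipePath(config, "annotation", outDir, "annotation.tsv",
                       "families")
  clPath <- file.path(outDir, "classifications.tsv")
  if (!file.exists(clPath))
    stop("stage 'families' requires file '", clPath,
         "'; run the 'classify' stage first", call. = FALSE)
  ann <- readAnnotation(annPath)
  patterns <- if (is.null(config$patterns)) defaultFamilyPatterns()
              else readFamilyPatterns(config$patterns)
  assignments <- matchFamilyTerms(ann, patterns)
  writeResultTable(assignments, file.path(outDir, "families.tsv"))
  cl <- utils::read.delim(clPath, stringsAsFactors = FALSE)
  flags <- stats::setNames(
    cl$reproductive_specific[cl$species == cl$species[1]],
    cl$gene_id[cl$species == cl$species[1]])
  subsets <- reproductiveFamilySubset(assignments, flags)
  profiles <- tissueProfiles(.loadCollapsed(outDir, config, "families"))
  contrPath <- file.path(outDir, "contrasts.tsv")
  contrasts <- if (file.exists(contrPath))
    utils::read.delim(contrPath, stringsAsFactors = FALSE) else NULL
  reports <- lapply(subsets, familyExpressionReport, profiles = profiles,
                    contrasts = contrasts)
  for (fam in names(reports)) {
    if (nrow(reports[[fam]]$per_gene))
      writeResultTable(reports[[fam]]$per_gene,
                       file.path(outDir, paste0("family_", fam, "_genes.tsv")))
  }
  groups <- do.call(rbind, lapply(names(reports), function(fam) {
    gt <- reports[[fam]]$group_tests
    if (!nrow(gt)) return(NULL)
    cbind(family = fam, gt)
  }))
  if (!is.null(groups))
    writeResultTable(groups, file.path(outDir, "family_group_tests.tsv"))
  invisible(NULL)
}

#' @noRd
.stagePhenotypes <- function(outDir, config) {
  path <- .pipePath(config, "phenotypes", outDir, "phenotypes.csv",
                    "phenotypes")
  pt <- readPhenotypes(path)
  summaries <- summarizeAssays(pt)
  writeResultTable(summaries, file.path(outDir, "assay_summaries.tsv"))
  writeResultTable(speciesComparisonReport(summaries),
                   file.path(outDir, "species_comparison.tsv"))
  invisible(NULL)
}

#' @noRd
.stageReport <- function(outDir, config) {
  summary <- list()
  t1 <- file.path(outDir, "table1.json")
  if (file.exists(t1)) summary$table1 <- jsonlite::read_json(t1)
  dc <- file.path(outDir, "domain_comparison.json")
  if (file.exists(dc)) summary$domain_comparison <- jsonlite::read_json(dc)
  spPath <- file.path(outDir, "species_comparison.tsv")
  if (file.exists(spPath))
    summary$species_comparison <- utils::read.delim(spPath)
  .assertThat(length(summary) > 0,
              paste0("stage 'report' found no upstream artifacts in ",
                     outDir, "; run 'classify' and 'phenotypes' first"))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' @noRd
.writeManifest <- function(outDir, config) {
  inputs <- list.files(outDir, pattern = "\\.(tsv|csv|txt|json)$",
                       full.names = TRUE)
  inputs <- setdiff(inputs, file.path(outDir, "manifest.json"))
  sums <- tools::md5sum(sort(inputs))
  manifest <- list(
    package = "pollenTau",
    version = as.character(utils::packageVersion("pollenTau")),
    seed = config$seed,
    thresholds = list(tpm_filter = config$tpmFilter,
                      bias_threshold = config$biasThreshold,
                      zero_floor = config$zeroFloor,
                      q_threshold = config$qThreshold),
    checksums = as.list(stats::setNames(unname(sums), basename(names(sums)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
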