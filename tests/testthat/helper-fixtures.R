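# fixture builders shared across test files; everything is generated in code

toySampleTable <- function(ids, species = "SL", tissue = "style",
                           subtissue = "", bio_rep = seq_along(ids)) {
  data.frame(sample_id = ids, species = species, tissue = tissue,
             subtissue = subtissue, bio_rep = bio_rep,
             stringsAsFactors = FALSE)
}

toyTissueCounts <- function(counts, lengths = NULL, st = NULL) {
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  if (is.null(st)) st <- toySampleTable(colnames(counts))
  TissueCounts(counts, lengths, st)
}

# a minimal complete two-species design: 1 leaf + 1 pollen subtissue,
# nReps replicates per tissue (keeps profile tests fast)
fullDesignTable <- function(nReps = 2) {
  rows <- expand.grid(species = c("SL", "SP"),
                      tissue = c("leaf", "pollen", "style"),
                      bio_rep = seq_len(nReps), stringsAsFactors = FALSE)
  rows$subtissue <- ""
  rows$sample_id <- paste(rows$species, rows$tissue, rows$bio_rep, sep = ".")
  rows[, c("sample_id", "species", "tissue", "subtissue", "bio_rep")]
}

# TpmProfileSet straight from per-species tissue-mean matrices (replicate
# means equal to the tissue means), bypassing count simulation
profilesFromMeans <- function(meansBySpecies, nReps = 3) {
  geneIds <- rownames(meansBySpecies[[1]])
  tissues <- c("leaf", "pollen", "style")
  repMeans <- lapply(meansBySpecies, function(m) {
    stats::setNames(lapply(tissues, function(ti)
      matrix(m[, ti], nrow(m), nReps,
             dimnames = list(geneIds, paste0("r", seq_len(nReps))))),
      tissues)
  })
  methods::new("TpmProfileSet", geneIds = geneIds,
               species = names(meansBySpecies),
               tissueMeans = meansBySpecies, replicateMeans = repMeans)
}

meanMatrix <- function(..., geneIds = NULL) {
  m <- rbind(...)
  colnames(m) <- c("leaf", "pollen", "style")
  if (is.null(geneIds)) geneIds <- sprintf("g%03d", seq_len(nrow(m)))
  rownames(m) <- geneIds
  m
}

# syntheticConfig with planted set sizes scaled down so small n_genes
# designs stay feasible (defaults assume ~2000 genes)
smallSyntheticConfig <- function(n_genes, ...) {
  syntheticConfig(n_genes = n_genes,
                  n_secondary_higher_SP = 2, n_secondary_higher_SL = 1,
                  n_pme = 3, n_pmei = 2, n_reproductive_pme = 2, ...)
}

writeTempTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small in vitro / in vivo phenotype records built by hand
toyPhenotypeRow <- function(assay_type = "in_vitro", species = "SL",
                            donor_id = "d1", recipient_id = "",
                            tech_rep = 1, elapsed_h = 3,
                            style_length_um = NA_real_,
                            n_viable = 100L, n_germinated = 50L,
                            diameters = c(20, 21), tubes = c(300, 300)) {
  df <- data.frame(assay_type = assay_type, species = species,
                   donor_id = donor_id, recipient_id = recipient_id,
                   tech_rep = tech_rep, elapsed_h = elapsed_h,
                   style_length_um = style_length_um,
                   n_viable = n_viable, n_germinated = n_germinated,
                   stringsAsFactors = FALSE)
  df$pollen_diameters_um <- list(diameters)
  df$tube_lengths_um <- list(tubes)
  df
}
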