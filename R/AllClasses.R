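#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

#' TissueCounts: raw read counts with gene lengths and a sample design
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"counts"}
#' assay of non-negative integer read counts (genes x samples), per-gene
#' exonic lengths in \code{rowData()$gene_length}, and the sample design
#' (species, tissue, subtissue, biological replicate) in \code{colData()}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [TissueCounts()], [readCounts()], [computeTpm()]
#' @export
setClass("TissueCounts", contains = "SummarizedExperiment")

setValidity("TissueCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    else if (any(cnt != round(cnt)))
      msg <- c(msg, "counts must be integer-valued")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene IDs must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs must be present and unique")
  len <- SummarizedExperiment::rowData(object)$gene_length
  if (is.null(len) || any(is.na(len)) || any(len < 1))
    msg <- c(msg, "every gene needs a length >= 1 in rowData()$gene_length")
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "tissue", "subtissue", "bio_rep")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  } else {
    badSp <- setdiff(unique(cd$species), .speciesLevels())
    if (length(badSp))
      msg <- c(msg, paste0("unknown species label(s): ",
                           paste(badSp, collapse = ", "),
                           " (allowed: ", paste(.speciesLevels(), collapse = ", "), ")"))
    badTi <- setdiff(unique(cd$tissue), .tissueLevels())
    if (length(badTi))
      msg <- c(msg, paste0("unknown tissue label(s): ",
                           paste(badTi, collapse = ", "),
                           " (allowed: ", paste(.tissueLevels(), collapse = ", "), ")"))
    if (any(is.na(cd$bio_rep)) || any(cd$bio_rep < 1))
      msg <- c(msg, "bio_rep must be a positive integer")
    key <- paste(cd$species, cd$tissue, cd$subtissue, cd$bio_rep)
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicated (species, tissue, subtissue, bio_rep) ",
                           "combination: ", key[duplicated(key)][1]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TissueCounts object
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param geneLengths positive integer vector (bp), one per gene; names are
#'   matched against rownames of \code{counts} when present.
#' @param sampleTable data.frame with columns \code{sample_id}, \code{species}
#'   (\code{"SL"}/\code{"SP"}), \code{tissue} (\code{"leaf"}, \code{"pollen"},
#'   \code{"style"}), \code{subtissue} (free label, \code{""} or \code{NA} for
#'   none) and \code{bio_rep} (positive integer). One row per column of
#'   \code{counts}.
#' @return a validated [TissueCounts-class] object with samples ordered as in
#'   \code{counts}.
#' @examples
#' cm <- matrix(0:3, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' st <- data.frame(sample_id = c("s1", "s2"), species = "SL",
#'                  tissue = "style", subtissue = "", bio_rep = 1:2)
#' tc <- TissueCounts(cm, c(1000L, 500L), st)
#' @export
TissueCounts <- function(counts, geneLengths, sampleTable) {
  counts <- as.matrix(counts)
  .assertThat(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry gene IDs (rownames) and sample IDs (colnames)")
  if (!is.null(names(geneLengths))) {
    miss <- setdiff(rownames(counts), names(geneLengths))
    .assertThat(length(miss) == 0,
                paste0("no length for gene(s): ", paste(utils::head(miss, 5), collapse = ", ")))
    geneLengths <- geneLengths[rownames(counts)]
  }
  .assertThat(length(geneLengths) == nrow(counts),
              "geneLengths must have one entry per gene")
  st <- .normalizeSampleTable(sampleTable)
  .assertThat(!anyDuplicated(st$sample_id), paste0(
    "duplicated sample_id in sample table: ",
    paste(unique(st$sample_id[duplicated(st$sample_id)]), collapse = ", ")))
  miss <- setdiff(colnames(counts), st$sample_id)
  .assertThat(length(miss) == 0, paste0(
    "sample sheet is missing sample(s): ", paste(miss, collapse = ", ")))
  st <- st[match(colnames(counts), st$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(st, row.names = st$sample_id)
  rd <- S4Vectors::DataFrame(gene_length = as.integer(round(geneLengths)),
                             row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  methods::new("TissueCounts", se)
}

#' @noRd
.normalizeSampleTable <- function(st) {
  st <- as.data.frame(st)
  need <- c("sample_id", "species", "tissue", "bio_rep")
  miss <- setdiff(need, colnames(st))
  .assertThat(length(miss) == 0,
              paste0("sample table is missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(st$subtissue)) st$subtissue <- ""
  st$subtissue[is.na(st$subtissue)] <- ""
  st$sample_id <- as.character(st$sample_id)
  st$species <- as.character(st$species)
  st$tissue <- as.character(st$tissue)
  st$subtissue <- as.character(st$subtissue)
  st$bio_rep <- as.integer(st$bio_rep)
  st[need[!need %in% colnames(st)]] <- NULL
  st[, c("sample_id", "species", "tissue", "subtissue", "bio_rep")]
}

#' TpmExperiment: TPM values on the TissueCounts design
#'
#' A SummarizedExperiment with a single \code{"tpm"} assay. Columns are
#' either sequencing samples (as produced by [computeTpm()]) or
#' per-replicate pseudo-samples after subtissue averaging
#' (as produced by [collapseSubtissues()], where \code{subtissue} is
#' \code{""}).
#'
#' @export
setClass("TpmExperiment", contains = "SummarizedExperiment")

setValidity("TpmExperiment", function(object) {
  msg <- character()
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'tpm' is required")
  else {
    x <- SummarizedExperiment::assay(object, "tpm")
    if (any(is.na(x)) || any(x < 0))
      msg <- c(msg, "tpm values must be non-negative and non-missing")
    else {
      cs <- colSums(x)
      bad <- cs > 0 & abs(cs - 1e6) > 1e-3
      if (any(bad))
        msg <- c(msg, paste0("tpm column(s) do not sum to 1e6: ",
                             paste(colnames(x)[bad][seq_len(min(3, sum(bad)))],
                                   collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TpmProfileSet: per-gene, per-species tissue expression profiles
#'
#' Holds, for each species, the mean TPM of every gene in each of the three
#' tissues (leaf, pollen, style) together with the underlying per-replicate
#' means. Tissue means are the arithmetic mean of the replicate means.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot species character vector of species labels present.
#' @slot tissueMeans named list (by species) of genes x tissue matrices.
#' @slot replicateMeans named list (by species) of lists (by tissue) of
#'   genes x replicate matrices.
#' @seealso [tissueProfiles()], [tissueMeans()], [replicateMeans()]
#' @export
setClass("TpmProfileSet",
         representation(geneIds = "character",
                        species = "character",
                        tissueMeans = "list",
                        replicateMeans = "list"))

setValidity("TpmProfileSet", function(object) {
  msg <- character()
  for (sp in object@species) {
    tm <- object@tissueMeans[[sp]]
    if (is.null(tm) || !identical(rownames(tm), object@geneIds) ||
        !identical(colnames(tm), .tissueLevels())) {
      msg <- c(msg, paste0("tissueMeans[['", sp, "']] must be genes x ",
                           "(leaf, pollen, style)"))
      next
    }
    if (any(tm < 0)) msg <- c(msg, "tissue means must be >= 0")
    rm <- object@replicateMeans[[sp]]
    for (ti in .tissueLevels()) {
      if (!is.null(rm[[ti]])) {
        recomputed <- rowMeans(rm[[ti]])
        if (max(abs(recomputed - tm[, ti])) > 1e-6 * (1 + max(tm[, ti])))
          msg <- c(msg, paste0("tissue means of ", sp, "/", ti,
                               " do not equal the mean of replicate means"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TpmProfileSet-class compact display
#' @param object a TpmProfileSet.
#' @export
setMethod("show", "TpmProfileSet", function(object) {
  cat("TpmProfileSet with", length(object@geneIds), "genes,",
      "species:", paste(object@species, collapse = ", "), "\n")
  for (sp in object@species) {
    tm <- object@tissueMeans[[sp]]
    cat(" ", sp, "mean TPM by tissue:",
        paste(sprintf("%s=%.2f", colnames(tm), colMeans(tm)), collapse = " "),
        "\n")
  }
  invisible(NULL)
})

#' @describeIn TissueCounts-class compact display
#' @param object a TissueCounts.
#' @export
setMethod("show", "TissueCounts", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("TissueCounts:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  species:", paste(sort(unique(cd$species)), collapse = ", "),
      "| tissues:", paste(sort(unique(cd$tissue)), collapse = ", "), "\n")
  cat("  gene length range:",
      paste(range(SummarizedExperiment::rowData(object)$gene_length),
            collapse = "-"), "bp\n")
  invisible(NULL)
})
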