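#' TPM normalization
#'
#' Converts raw counts to transcripts per million: per sample, each gene's
#' count is divided by its length in kilobases to give a per-kilobase rate,
#' and rates are rescaled so that every sample sums to one million. A sample
#' with no reads yields an all-zero column rather than NaN.
#'
#' @param x a [TissueCounts-class] object.
#' @return a [TpmExperiment-class] with assay \code{"tpm"} on the same
#'   genes/samples and the same column design.
#' @examples
#' cm <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' st <- data.frame(sample_id = "s1", species = "SL", tissue = "style",
#'                  subtissue = "", bio_rep = 1)
#' tc <- TissueCounts(cm, c(1000L, 2000L), st)
#' SummarizedExperiment::assay(computeTpm(tc))  # 666666.7, 333333.3
#' @export
computeTpm <- function(x) {
  .assertThat(methods::is(x, "TissueCounts"), "x must be a TissueCounts")
  counts <- SummarizedExperiment::assay(x, "counts")
  kb <- geneLengths(x) / 1000
  rate <- counts / kb
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    rowData = SummarizedExperiment::rowData(x),
    colData = SummarizedExperiment::colData(x))
  methods::new("TpmExperiment", se)
}

#' Average subtissue samples within biological replicates
#'
#' Leaf profiles come from 7 developmental subtissues and pollen from 2
#' (ungerminated/germinated); for tissue-level analyses each (species,
#' tissue, biological replicate) is summarized as the unweighted arithmetic
#' mean of its subtissue TPM columns. Style samples, which have no
#' subtissues, pass through unchanged. TPM already removes sequencing depth,
#' so means are not depth-weighted.
#'
#' @param x a [TpmExperiment-class] from [computeTpm()].
#' @return a [TpmExperiment-class] with one pseudo-sample per (species,
#'   tissue, bio_rep), named \code{<species>.<tissue>.r<rep>}; column sums
#'   are no longer exactly 1e6 only through averaging of already-normalized
#'   columns (they remain 1e6 because the mean of columns each summing to
#'   1e6 sums to 1e6).
#' @export
collapseSubtissues <- function(x) {
  .assertThat(methods::is(x, "TpmExperiment"), "x must be a TpmExperiment")
  tpm <- SummarizedExperiment::assay(x, "tpm")
  cd <- sampleTable(x)
  key <- paste(cd$species, cd$tissue, cd$bio_rep, sep = ".")
  groups <- split(seq_len(ncol(tpm)), key)
  collapsed <- vapply(groups, function(idx) rowMeans(tpm[, idx, drop = FALSE]),
                      numeric(nrow(tpm)))
  meta <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  newNames <- paste0(meta[, 1], ".", meta[, 2], ".r", meta[, 3])
  colnames(collapsed) <- newNames
  st <- data.frame(sample_id = newNames, species = meta[, 1],
                   tissue = meta[, 2], subtissue = "",
                   bio_rep = as.integer(meta[, 3]),
                   stringsAsFactors = FALSE)
  ord <- order(st$species, match(st$tissue, .tissueLevels()), st$bio_rep)
  collapsed <- collapsed[, ord, drop = FALSE]
  st <- st[ord, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = collapsed),
    rowData = SummarizedExperiment::rowData(x),
    colData = S4Vectors::DataFrame(st, row.names = st$sample_id))
  methods::new("TpmExperiment", se)
}

#' Per-species tissue expression profiles
#'
#' Assembles, per gene and species, the replicate-level mean TPM for each
#' tissue and the tissue means (mean over biological replicates).
#'
#' @param x a collapsed [TpmExperiment-class] from [collapseSubtissues()]
#'   (one column per species/tissue/replicate).
#' @return a [TpmProfileSet-class].
#' @export
tissueProfiles <- function(x) {
  .assertThat(methods::is(x, "TpmExperiment"), "x must be a TpmExperiment")
  tpm <- SummarizedExperiment::assay(x, "tpm")
  cd <- sampleTable(x)
  speciesHere <- sort(unique(cd$species))
  tissueMeansL <- list()
  repMeansL <- list()
  for (sp in speciesHere) {
    missTi <- setdiff(.tissueLevels(), unique(cd$tissue[cd$species == sp]))
    .assertThat(length(missTi) == 0,
                paste0("species ", sp, " lacks tissue(s): ",
                       paste(missTi, collapse = ", "),
                       "; profiles require leaf, pollen and style"))
    repMeans <- list()
    tm <- matrix(0, nrow(tpm), length(.tissueLevels()),
                 dimnames = list(rownames(tpm), .tissueLevels()))
    for (ti in .tissueLevels()) {
      idx <- which(cd$species == sp & cd$tissue == ti)
      reps <- cd$bio_rep[idx]
      m <- tpm[, idx[order(reps)], drop = FALSE]
      colnames(m) <- paste0("r", sort(reps))
      repMeans[[ti]] <- m
      tm[, ti] <- rowMeans(m)
    }
    repMeansL[[sp]] <- repMeans
    tissueMeansL[[sp]] <- tm
  }
  methods::new("TpmProfileSet", geneIds = rownames(tpm),
               species = speciesHere, tissueMeans = tissueMeansL,
               replicateMeans = repMeansL)
}

#' Expressed-gene filter
#'
#' The analysis universe: genes whose mean TPM (across biological
#' replicates) is at or above \code{threshold} in at least one tissue of at
#' least one species. The comparison is inclusive (a tissue mean of exactly
#' 2 passes the default filter).
#'
#' @param profiles a [TpmProfileSet-class] covering the species of interest.
#' @param threshold minimum tissue-mean TPM (default 2).
#' @return character vector of gene IDs, in input order.
#' @export
filterExpressed <- function(profiles, threshold = 2) {
  .assertThat(methods::is(profiles, "TpmProfileSet"),
              "profiles must be a TpmProfileSet")
  best <- Reduce(pmax, lapply(profiles@species, function(sp)
    apply(tissueMeans(profiles, sp), 1, max)))
  profiles@geneIds[best >= threshold]
}
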