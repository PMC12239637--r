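#' Median-of-ratios size factors
#'
#' Per sample j, the size factor is the median over genes of
#' \eqn{count_{gj} / ref_g}, where \eqn{ref_g} is the geometric mean of
#' gene g across samples; genes with a zero count in any sample are
#' excluded from the reference. Normalized counts are counts divided by
#' the sample's factor.
#'
#' @param counts integer matrix (genes x samples) or a
#'   [TissueCounts-class] object.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(A = c(2, 4, 6), B = c(4, 8, 12))
#' rownames(m) <- paste0("g", 1:3)
#' sizeFactorsMedianOfRatios(m)  # 1/sqrt(2), sqrt(2)
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  if (methods::is(counts, "TissueCounts"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  allPos <- rowSums(counts == 0) == 0
  .assertThat(any(allPos),
              paste0("no gene has nonzero counts in every sample; ",
                     "median-of-ratios needs at least one (pseudo-reference ",
                     "fallback is disabled)"))
  logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
  sf <- apply(counts[allPos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logRef)))
  .assertThat(all(sf > 0), "size factors must be positive")
  sf
}

#' Normalize counts by size factors
#'
#' @param counts matrix or [TissueCounts-class].
#' @param sizeFactors named vector from [sizeFactorsMedianOfRatios()];
#'   computed if missing.
#' @return matrix of normalized counts.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  if (methods::is(counts, "TissueCounts"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(counts)
  sweep(counts, 2, sizeFactors, "/")
}

#' Two-group contrast test on normalized counts
#'
#' The per-gene species contrast: a Welch two-sample t test on
#' log2(normalized count + 1). This is a defined stand-in for a
#' negative-binomial GLM Wald test and is not equivalent to one; it tests
#' location shift on the log scale with unequal variances. When both groups
#' have zero variance and equal means, p is 1.
#'
#' @param a,b normalized counts for one gene in the two groups (>= 2
#'   samples each).
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff} on the
#'   log2 scale.
#' @export
contrastTest <- function(a, b) {
  welchT(log2(a + 1), log2(b + 1))
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m \, p_{(j)} / j)}, mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values (q-values), same order as input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' bhAdjust(c(0.005, 0.5))              # 0.01, 0.5
#' @export
bhAdjust <- function(p) {
  .assertThat(all(!is.na(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  scaled <- pmin(1, m * p[ord] / seq_len(m))
  q <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Planned between-species contrasts in pollen and style
#'
#' For every gene in the expressed universe, tests pollen expression
#' between species and style expression between species on
#' median-of-ratios-normalized counts (Welch on log2(normalized + 1),
#' including subtissue samples of the tissue). BH correction is applied
#' within each contrast family separately. Fold changes are
#' log2((mean_SP + 1) / (mean_SL + 1)) on normalized counts.
#'
#' @param x a [TissueCounts-class] object covering both species.
#' @param universe expressed gene IDs (see [filterExpressed()]).
#' @param qThreshold significance cutoff on the adjusted p (default 0.05),
#'   recorded in the \code{significant} column.
#' @return data.frame with one row per gene x contrast: \code{gene_id},
#'   \code{tissue}, \code{mean_norm_SL}, \code{mean_norm_SP},
#'   \code{log2fc}, \code{p}, \code{q}, \code{significant}.
#' @export
runPlannedContrasts <- function(x, universe, qThreshold = 0.05) {
  .assertThat(methods::is(x, "TissueCounts"), "x must be a TissueCounts")
  counts <- SummarizedExperiment::assay(x, "counts")
  norm <- normalizeCounts(counts)
  cd <- sampleTable(x)
  universe <- intersect(rownames(counts), universe)
  out <- lapply(c("pollen", "style"), function(ti) {
    idxSL <- which(cd$tissue == ti & cd$species == "SL")
    idxSP <- which(cd$tissue == ti & cd$species == "SP")
    .assertThat(length(idxSL) >= 2 && length(idxSP) >= 2,
                paste0("contrast in ", ti, " needs >= 2 samples per species"))
    a <- norm[universe, idxSP, drop = FALSE]
    b <- norm[universe, idxSL, drop = FALSE]
    p <- vapply(seq_along(universe), function(i)
      contrastTest(a[i, ], b[i, ])$p, numeric(1))
    meanSP <- rowMeans(a); meanSL <- rowMeans(b)
    data.frame(gene_id = universe, tissue = ti,
               mean_norm_SL = unname(meanSL), mean_norm_SP = unname(meanSP),
               log2fc = log2((meanSP + 1) / (meanSL + 1)),
               p = p, q = bhAdjust(p), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  res$significant <- res$q < qThreshold
  res
}

#' Top differentially expressed genes by TPM difference
#'
#' Within each of four categories (pollen-specific, style-specific,
#' pollen-biased, style-biased), ranks genes by the absolute difference in
#' the category tissue's mean TPM between species and returns the top k.
#' Biased categories include their specific subsets. Ordering is
#' deterministic; ties are broken by gene ID.
#'
#' @param classifications output of [classifyGenes()].
#' @param profiles the matching [TpmProfileSet-class].
#' @param k number of genes per category (default 10); categories with
#'   fewer genes return all of them with a warning.
#' @return data.frame: \code{category}, \code{rank}, \code{gene_id},
#'   \code{tissue}, \code{tpm_SL}, \code{tpm_SP}, \code{delta_tpm}
#'   (SP - SL), \code{abs_delta_tpm}.
#' @export
topDifferential <- function(classifications, profiles, k = 10) {
  cats <- list(pollen_specific = c("pollen", "specific"),
               style_specific = c("style", "specific"),
               pollen_biased = c("pollen", "biased"),
               style_biased = c("style", "biased"))
  rows <- lapply(names(cats), function(cat) {
    ti <- cats[[cat]][1]; level <- cats[[cat]][2]
    classes <- if (level == "biased") c("biased", "specific") else "specific"
    # a gene belongs to a category if it has that call in either species
    genes <- sort(unique(classifications$gene_id[
      classifications$class %in% classes &
        !is.na(classifications$focal_tissue) &
        classifications$focal_tissue == ti]))
    if (!length(genes)) return(NULL)
    sl <- tissueMeans(profiles, "SL")[genes, ti]
    sp <- tissueMeans(profiles, "SP")[genes, ti]
    d <- sp - sl
    df <- data.frame(category = cat, gene_id = genes, tissue = ti,
                     tpm_SL = unname(sl), tpm_SP = unname(sp),
                     delta_tpm = unname(d), abs_delta_tpm = abs(unname(d)),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$abs_delta_tpm, df$gene_id), ]
    if (nrow(df) < k)
      warning("category ", cat, " has only ", nrow(df), " gene(s) (< k = ",
              k, ")", call. = FALSE)
    df <- utils::head(df, k)
    df$rank <- seq_len(nrow(df))
    df[, c("category", "rank", "gene_id", "tissue", "tpm_SL", "tpm_SP",
           "delta_tpm", "abs_delta_tpm")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
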