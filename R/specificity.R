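#' The tau tissue-specificity index
#'
#' For a profile of mean expression values over N tissues,
#' \deqn{\tau = \sum_{i=1}^{N} (1 - \hat x_i) / (N - 1), \quad
#'       \hat x_i = x_i / \max_i(x_i).}
#' tau is 0 for perfectly uniform expression, 1 for expression confined to a
#' single tissue, and is invariant to rescaling the profile.
#'
#' @param x non-negative numeric vector of length >= 2 (one mean expression
#'   value per tissue), with at least one positive entry.
#' @return tau in [0, 1].
#' @examples
#' computeTau(c(1, 1, 1))   # 0
#' computeTau(c(5, 0, 0))   # 1
#' computeTau(c(10, 5, 5))  # 0.5
#' @export
computeTau <- function(x) {
  .assertThat(length(x) >= 2, "tau needs at least 2 tissues")
  .assertThat(all(x >= 0), "expression values must be non-negative")
  m <- max(x)
  .assertThat(m > 0, "tau is undefined for an all-zero profile")
  sum(1 - x / m) / (length(x) - 1)
}

## row-wise tau for a genes x tissues matrix; all-zero rows return NA
#' @noRd
.tauRows <- function(m) {
  mx <- apply(m, 1, max)
  tau <- rep(NA_real_, nrow(m))
  ok <- mx > 0
  tau[ok] <- rowSums(1 - m[ok, , drop = FALSE] / mx[ok]) / (ncol(m) - 1)
  tau
}

#' Classify genes by tissue bias and specificity
#'
#' Per species, each gene in the expressed universe is assigned a focal
#' tissue (the tissue of maximal mean TPM; ties broken in the fixed order
#' leaf, pollen, style) and a class: \code{"biased"} when tau >=
#' \code{biasThreshold}; \code{"specific"} when additionally the focal
#' tissue mean is >= \code{exprThreshold} TPM and every other tissue mean is
#' below \code{zeroFloor} (the practical form of tau = 1 under TPM
#' arithmetic); otherwise \code{"unbiased"}. Genes of the universe with an
#' all-zero profile in one species get class
#' \code{"unexpressed_in_species"} there and are excluded from that
#' species' counts. Specific genes are a subset of biased genes.
#'
#' @param profiles a [TpmProfileSet-class].
#' @param universe character vector of expressed gene IDs, from
#'   [filterExpressed()].
#' @param biasThreshold tau cutoff for tissue bias (default 0.7).
#' @param exprThreshold minimum focal-tissue TPM for a specific call
#'   (default 2).
#' @param zeroFloor TPM below which a tissue counts as not expressed
#'   (default 0.1).
#' @return data.frame with one row per gene x species: \code{gene_id},
#'   \code{species}, \code{tau}, \code{focal_tissue}, \code{class},
#'   \code{reproductive_specific}.
#' @export
classifyGenes <- function(profiles, universe, biasThreshold = 0.7,
                          exprThreshold = 2, zeroFloor = 0.1) {
  .assertThat(methods::is(profiles, "TpmProfileSet"),
              "profiles must be a TpmProfileSet")
  repro <- reproductiveSpecific(profiles, universe, threshold = exprThreshold)
  out <- lapply(profiles@species, function(sp) {
    tm <- tissueMeans(profiles, sp)[universe, , drop = FALSE]
    tau <- .tauRows(tm)
    focalIdx <- apply(tm, 1, which.max)  # first max: leaf < pollen < style
    focal <- .tissueLevels()[focalIdx]
    focalMean <- tm[cbind(seq_len(nrow(tm)), focalIdx)]
    otherMax <- apply(tm, 1, function(v) max(v[-which.max(v)]))
    cls <- rep("unbiased", nrow(tm))
    cls[!is.na(tau) & tau >= biasThreshold] <- "biased"
    cls[cls == "biased" & focalMean >= exprThreshold &
          otherMax < zeroFloor] <- "specific"
    cls[is.na(tau)] <- "unexpressed_in_species"
    focal[is.na(tau)] <- NA_character_
    data.frame(gene_id = universe, species = sp, tau = tau,
               focal_tissue = focal, class = cls,
               reproductive_specific = repro[universe],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reproductive-specific genes
#'
#' A gene is reproductive-specific when it passes the expressed filter, its
#' leaf tissue mean is below \code{threshold} TPM in both species, and its
#' pollen and/or style mean is >= \code{threshold} TPM in at least one
#' species.
#'
#' @param profiles a [TpmProfileSet-class] with both species.
#' @param universe expressed gene IDs.
#' @param threshold TPM cutoff (default 2); leaf must be strictly below it.
#' @return named logical vector over all genes in \code{profiles}.
#' @export
reproductiveSpecific <- function(profiles, universe, threshold = 2) {
  genes <- profiles@geneIds
  leafMax <- Reduce(pmax, lapply(profiles@species, function(sp)
    tissueMeans(profiles, sp)[, "leaf"]))
  reproMax <- Reduce(pmax, lapply(profiles@species, function(sp) {
    tm <- tissueMeans(profiles, sp)
    pmax(tm[, "pollen"], tm[, "style"])
  }))
  flag <- leafMax < threshold & reproMax >= threshold & genes %in% universe
  stats::setNames(flag, genes)
}

#' Tissue-level classification summary
#'
#' Counts, per species and tissue (plus a species-wide total), the genes
#' expressed in that tissue, the genes biased toward it, and the biased
#' genes that are tissue-specific.
#'
#' @param classifications output of [classifyGenes()].
#' @param profiles the [TpmProfileSet-class] the classifications came from.
#' @param exprThreshold TPM cutoff defining "expressed in a tissue"
#'   (default 2).
#' @return data.frame with columns \code{species}, \code{tissue} (three
#'   tissues plus \code{"total"}), \code{n_expressed}, \code{n_biased},
#'   \code{n_specific} and raw ratios \code{prop_biased} =
#'   n_biased/n_expressed and \code{prop_specific} = n_specific/n_biased
#'   (NA when n_biased is 0). Use [table1Report()] for the rounded
#'   presentation.
#' @export
summarizeTable1 <- function(classifications, profiles, exprThreshold = 2) {
  rows <- list()
  for (sp in sort(unique(classifications$species))) {
    cl <- classifications[classifications$species == sp, ]
    tm <- tissueMeans(profiles, sp)[cl$gene_id, , drop = FALSE]
    isBiased <- cl$class %in% c("biased", "specific")
    isSpecific <- cl$class == "specific"
    for (ti in .tissueLevels()) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, tissue = ti,
        n_expressed = sum(tm[, ti] >= exprThreshold),
        n_biased = sum(isBiased & cl$focal_tissue == ti, na.rm = TRUE),
        n_specific = sum(isSpecific & cl$focal_tissue == ti, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, tissue = "total",
      n_expressed = sum(apply(tm, 1, max) >= exprThreshold),
      n_biased = sum(isBiased), n_specific = sum(isSpecific),
      stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, rows)
  tbl$prop_biased <- ifelse(tbl$n_expressed > 0,
                            tbl$n_biased / tbl$n_expressed, NA_real_)
  tbl$prop_specific <- ifelse(tbl$n_biased > 0,
                              tbl$n_specific / tbl$n_biased, NA_real_)
  tbl
}

#' Reporting layer for the classification summary
#'
#' Computes the presentation proportions from counts: the proportion of
#' expressed genes that are tissue-biased and the proportion of biased
#' genes that are tissue-specific, rounded half up to 3 decimals (raw
#' ratios are retained by [summarizeTable1()] for JSON output).
#'
#' @param counts data.frame with columns \code{n_expressed},
#'   \code{n_biased}, \code{n_specific} (other columns pass through).
#' @return the input with \code{prop_biased} and \code{prop_specific}
#'   columns rounded half up to 3 decimals; \code{prop_specific} is NA when
#'   \code{n_biased} is 0.
#' @examples
#' table1Report(data.frame(n_expressed = 19667, n_biased = 6656,
#'                         n_specific = 2918))  # prop_biased 0.338
#' @export
table1Report <- function(counts) {
  .assertThat(all(c("n_expressed", "n_biased", "n_specific") %in%
                    colnames(counts)),
              "counts needs n_expressed, n_biased, n_specific")
  counts$prop_biased <- roundHalfUp(
    ifelse(counts$n_expressed > 0, counts$n_biased / counts$n_expressed,
           NA_real_), 3)
  counts$prop_specific <- roundHalfUp(
    ifelse(counts$n_biased > 0, counts$n_specific / counts$n_biased,
           NA_real_), 3)
  counts
}

#' Cross-species secondary style expression of pollen-biased genes
#'
#' For the union of genes called pollen-biased in at least one species,
#' compares style expression between species: a gene has secondary style
#' expression when its style tissue mean is >= \code{exprFloor} TPM in
#' either species; its direction is the species with the higher style mean
#' (exact ties are counted as neither and reported separately); and it is
#' absent from SL styles when its SL style mean is below \code{absentFloor}.
#'
#' @param classifications output of [classifyGenes()] covering both species.
#' @param profiles the matching [TpmProfileSet-class].
#' @param exprFloor TPM floor defining secondary expression (default 2).
#' @param absentFloor TPM floor below which a gene counts as not expressed
#'   at all in SL styles (default 0.1, the classification zero floor).
#' @return list with \code{per_gene} (data.frame: gene_id, style_SL,
#'   style_SP, secondary, direction, absent_SL) and counts
#'   \code{n_union}, \code{n_secondary}, \code{n_higher_SP},
#'   \code{n_higher_SL}, \code{n_ties}, \code{n_absent_SL_style}.
#' @export
compareSecondaryStyleExpression <- function(classifications, profiles,
                                            exprFloor = 2, absentFloor = 0.1) {
  isPollenBiased <- classifications$class %in% c("biased", "specific") &
    classifications$focal_tissue == "pollen"
  union <- sort(unique(classifications$gene_id[isPollenBiased]))
  styleSL <- tissueMeans(profiles, "SL")[union, "style"]
  styleSP <- tissueMeans(profiles, "SP")[union, "style"]
  secondary <- styleSL >= exprFloor | styleSP >= exprFloor
  direction <- ifelse(styleSP > styleSL, "SP",
                      ifelse(styleSL > styleSP, "SL", "tie"))
  direction[!secondary] <- NA_character_
  absentSL <- secondary & styleSL < absentFloor
  perGene <- data.frame(gene_id = union, style_SL = unname(styleSL),
                        style_SP = unname(styleSP), secondary = secondary,
                        direction = direction, absent_SL = absentSL,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_gene = perGene,
       n_union = length(union),
       n_secondary = sum(secondary),
       n_higher_SP = sum(direction == "SP", na.rm = TRUE),
       n_higher_SL = sum(direction == "SL", na.rm = TRUE),
       n_ties = sum(direction == "tie", na.rm = TRUE),
       n_absent_SL_style = sum(absentSL))
}

#' Directional split of secondary-expression counts
#'
#' The direction counts of a domain comparison partition its secondary
#' genes (no ties): given the total and one direction, the other is the
#' complement.
#'
#' @param n_secondary number of pollen-biased genes with secondary style
#'   expression.
#' @param n_higher_SP number with higher style expression in SP.
#' @return list with \code{n_higher_SP} and \code{n_higher_SL}.
#' @examples
#' domainDirectionCounts(482, 471)$n_higher_SL  # 11
#' @export
domainDirectionCounts <- function(n_secondary, n_higher_SP) {
  .assertThat(n_higher_SP <= n_secondary,
              "n_higher_SP cannot exceed n_secondary")
  list(n_higher_SP = n_higher_SP, n_higher_SL = n_secondary - n_higher_SP)
}

#' Sensitivity of classification counts to the tau threshold
#'
#' Re-runs the classification over a grid of tau thresholds and tabulates
#' biased-gene counts per species and tissue together with the
#' secondary-style direction counts, to check that inferences do not hinge
#' on the 0.7 convention.
#'
#' @param profiles a [TpmProfileSet-class].
#' @param universe expressed gene IDs.
#' @param thresholds numeric grid in [0.5, 1] (default every 0.05).
#' @param ... further arguments to [classifyGenes()].
#' @return data.frame with one row per threshold: biased counts per
#'   species/tissue (\code{n_biased_<sp>_<tissue>}), \code{n_secondary},
#'   \code{n_higher_SP}, \code{n_higher_SL}.
#' @export
thresholdSensitivity <- function(profiles, universe,
                                 thresholds = seq(0.5, 1, by = 0.05), ...) {
  rows <- lapply(thresholds, function(th) {
    cl <- classifyGenes(profiles, universe, biasThreshold = th, ...)
    row <- list(threshold = th)
    for (sp in profiles@species) {
      for (ti in .tissueLevels()) {
        row[[paste0("n_biased_", sp, "_", ti)]] <-
          sum(cl$species == sp & cl$class %in% c("biased", "specific") &
                !is.na(cl$focal_tissue) & cl$focal_tissue == ti)
      }
    }
    dc <- compareSecondaryStyleExpression(cl, profiles)
    row$n_secondary <- dc$n_secondary
    row$n_higher_SP <- dc$n_higher_SP
    row$n_higher_SL <- dc$n_higher_SL
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Between-species comparison of bias magnitude or expression level
#'
#' For the genes biased toward one tissue in each species, compares the
#' species' distributions of tau or of log10(focal-tissue TPM + 1) with a
#' Welch two-sample test.
#'
#' @param classifications output of [classifyGenes()].
#' @param profiles the matching [TpmProfileSet-class].
#' @param tissue the focal tissue ("leaf", "pollen" or "style").
#' @param metric \code{"tau"} or \code{"logtpm"}.
#' @return list with \code{mean_SL}, \code{mean_SP}, \code{difference}
#'   (SP - SL), \code{t}, \code{df}, \code{p} (NA when a group has fewer
#'   than 2 genes), and the group sizes.
#' @export
meanBiasContrast <- function(classifications, profiles, tissue,
                             metric = c("tau", "logtpm")) {
  metric <- match.arg(metric)
  .assertThat(tissue %in% .tissueLevels(), "unknown tissue")
  vals <- lapply(c("SL", "SP"), function(sp) {
    cl <- classifications[classifications$species == sp &
                            classifications$class %in% c("biased", "specific") &
                            !is.na(classifications$focal_tissue) &
                            classifications$focal_tissue == tissue, ]
    if (metric == "tau") cl$tau
    else log10(tissueMeans(profiles, sp)[cl$gene_id, tissue] + 1)
  })
  nSL <- length(vals[[1]]); nSP <- length(vals[[2]])
  res <- list(mean_SL = if (nSL) mean(vals[[1]]) else NA_real_,
              mean_SP = if (nSP) mean(vals[[2]]) else NA_real_,
              n_SL = nSL, n_SP = nSP)
  res$difference <- res$mean_SP - res$mean_SL
  if (nSL >= 2 && nSP >= 2) {
    wt <- welchT(vals[[2]], vals[[1]])
    res$t <- wt$t; res$df <- wt$df; res$p <- wt$p
  } else {
    res$t <- NA_real_; res$df <- NA_real_; res$p <- NA_real_
  }
  res
}
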