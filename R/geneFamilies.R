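#' Default PME/PMEI annotation search terms
#'
#' Case-insensitive substrings used to assign genes to the pectin
#' methylesterase (PME) and PME inhibitor (PMEI) families from their
#' functional descriptions. Inhibitor phrasing is the more specific and
#' takes precedence when both families match. The lists are configurable
#' because annotation vocabularies differ between releases.
#'
#' @return named list with character vectors \code{PME} and \code{PMEI}.
#' @export
defaultFamilyPatterns <- function() {
  list(PME = c("pectinesterase", "pectin methylesterase"),
       PMEI = c("pectinesterase inhibitor",
                "pectin methylesterase inhibitor",
                "invertase/pectin methylesterase inhibitor"))
}

#' Read family search terms from a file
#'
#' Two-column TSV \code{family<TAB>pattern}, one pattern per row.
#'
#' @param path path to the TSV.
#' @return named list of pattern vectors per family.
#' @export
readFamilyPatterns <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  .assertThat(all(c("family", "pattern") %in% colnames(df)),
              "pattern file needs columns family and pattern")
  split(df$pattern, df$family)
}

#' Assign genes to gene families by annotation keywords
#'
#' Pure function of the description string: a gene is assigned to a family
#' when any of the family's case-insensitive substrings occurs in its
#' functional description. A gene matching both PME and PMEI patterns is
#' assigned to PMEI (inhibitor phrasing is more specific). The substring
#' that fired is recorded verbatim.
#'
#' @param ann annotation data.frame from [readAnnotation()].
#' @param patterns named list of per-family substring vectors; the default
#'   is [defaultFamilyPatterns()]. PMEI patterns take precedence over PME.
#' @return data.frame: \code{gene_id}, \code{family} (\code{"PME"},
#'   \code{"PMEI"} or \code{"none"}), \code{matched_term}.
#' @export
matchFamilyTerms <- function(ann, patterns = defaultFamilyPatterns()) {
  .assertThat(length(patterns) > 0 && all(lengths(patterns) > 0),
              "patterns must be non-empty per family")
  desc <- tolower(ann$description)
  firstMatch <- function(pats) {
    hit <- rep(NA_character_, length(desc))
    for (p in pats) {
      idx <- is.na(hit) & grepl(tolower(p), desc, fixed = TRUE)
      hit[idx] <- p
    }
    hit
  }
  hits <- lapply(patterns, firstMatch)
  family <- rep("none", length(desc))
  matched <- rep(NA_character_, length(desc))
  # precedence: later entries override earlier ones only if more specific;
  # PMEI (inhibitor) wins over PME by contract
  order <- names(patterns)
  if (all(c("PME", "PMEI") %in% order)) order <- c("PME", setdiff(order, "PME"))
  for (fam in order) {
    idx <- !is.na(hits[[fam]])
    family[idx] <- fam
    matched[idx] <- hits[[fam]][idx]
  }
  data.frame(gene_id = ann$gene_id, family = family, matched_term = matched,
             stringsAsFactors = FALSE)
}

#' Reproductive-specific members of each gene family
#'
#' Intersects family assignments with the reproductive-specificity flag
#' (expressed at >= 2 TPM only in pollen and/or style, in both species; see
#' [reproductiveSpecific()]).
#'
#' @param assignments output of [matchFamilyTerms()].
#' @param reproductiveFlags named logical vector from
#'   [reproductiveSpecific()] (or the flag column of [classifyGenes()]
#'   output keyed by gene).
#' @return named list of gene-ID vectors per family (excluding
#'   \code{"none"}), sorted.
#' @export
reproductiveFamilySubset <- function(assignments, reproductiveFlags) {
  fams <- setdiff(unique(assignments$family), "none")
  out <- lapply(fams, function(fam) {
    genes <- assignments$gene_id[assignments$family == fam]
    sort(genes[genes %in% names(reproductiveFlags)[reproductiveFlags]])
  })
  stats::setNames(out, fams)
}

#' Expression report for a gene-family subset
#'
#' Per gene: tissue means in both species and, where contrast results are
#' supplied, the per-tissue species direction and adjusted p. Per family:
#' between-species comparisons of log10(TPM + 1) group means in style and
#' pollen (Welch test across genes).
#'
#' @param subset character vector of gene IDs (e.g. one element of
#'   [reproductiveFamilySubset()]), or a user-supplied watchlist of loci.
#' @param profiles a [TpmProfileSet-class].
#' @param contrasts optional output of [runPlannedContrasts()].
#' @return list with \code{per_gene} (data.frame) and \code{group_tests}
#'   (data.frame with one row per tissue in pollen/style: mean log-TPM per
#'   species, difference SP - SL, t, df, p; NA when fewer than 2 genes).
#' @export
familyExpressionReport <- function(subset, profiles, contrasts = NULL) {
  if (!length(subset))
    return(list(per_gene = data.frame(), group_tests = data.frame()))
  subset <- sort(subset)
  tmSL <- tissueMeans(profiles, "SL")[subset, , drop = FALSE]
  tmSP <- tissueMeans(profiles, "SP")[subset, , drop = FALSE]
  perGene <- data.frame(gene_id = subset,
                        leaf_SL = tmSL[, "leaf"], leaf_SP = tmSP[, "leaf"],
                        pollen_SL = tmSL[, "pollen"], pollen_SP = tmSP[, "pollen"],
                        style_SL = tmSL[, "style"], style_SP = tmSP[, "style"],
                        row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(contrasts)) {
    for (ti in c("pollen", "style")) {
      sub <- contrasts[contrasts$tissue == ti, ]
      idx <- match(subset, sub$gene_id)
      perGene[[paste0(ti, "_direction")]] <-
        ifelse(is.na(idx), NA_character_,
               ifelse(sub$log2fc[idx] > 0, "SP",
                      ifelse(sub$log2fc[idx] < 0, "SL", "tie")))
      perGene[[paste0(ti, "_q")]] <- sub$q[idx]
    }
  }
  groupTests <- do.call(rbind, lapply(c("pollen", "style"), function(ti) {
    a <- log10(tmSP[, ti] + 1)  # SP
    b <- log10(tmSL[, ti] + 1)  # SL
    if (length(subset) >= 2) {
      wt <- welchT(a, b)
      data.frame(tissue = ti, mean_log_SL = mean(b), mean_log_SP = mean(a),
                 diff_SP_minus_SL = wt$mean_diff, t = wt$t, df = wt$df,
                 p = wt$p, n = length(subset), stringsAsFactors = FALSE)
    } else {
      data.frame(tissue = ti, mean_log_SL = mean(b), mean_log_SP = mean(a),
                 diff_SP_minus_SL = mean(a) - mean(b), t = NA_real_,
                 df = NA_real_, p = NA_real_, n = length(subset),
                 stringsAsFactors = FALSE)
    }
  }))
  list(per_gene = perGene, group_tests = groupTests)
}
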