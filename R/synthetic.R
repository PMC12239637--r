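#' Configuration for the synthetic expression generator
#'
#' Builds a validated configuration mirroring the study design the package
#' analyses: 2 species x 3 tissues (leaf with 7 subtissues, pollen with 2,
#' style with none) x 3 biological replicates, gene classes with
#' controllable proportions, a set of pollen-biased genes with planted
#' secondary style expression in a chosen direction, planted PME/PMEI
#' annotations, and negative-binomial count noise.
#'
#' Class mean profiles (in relative TPM units, renormalized per species and
#' tissue at generation so a column of expected TPM sums to 1e6):
#' tissue-specific genes express \code{base_mean_tpm} in their focal tissue
#' and 0 elsewhere; tissue-biased genes express \code{base_mean_tpm} focally
#' and \code{base_mean_tpm / bias_ratio} in the other tissues (pollen-biased
#' genes carry their off-focal expression in leaf, with style 0, so that
#' secondary style expression is exactly the planted set); unbiased genes
#' are flat; silent genes are 0 everywhere. Planted secondary genes add
#' style expression of \code{base_mean_tpm / 5} in the higher species and
#' \code{base_mean_tpm / 20} (higher-SL direction) or 0 (higher-SP
#' direction, i.e. absent from SL styles) in the other.
#'
#' @param n_genes total genes (default 2000).
#' @param class_proportions named proportions over \code{leaf_specific},
#'   \code{pollen_specific}, \code{style_specific}, \code{leaf_biased},
#'   \code{pollen_biased}, \code{style_biased}, \code{unbiased},
#'   \code{silent}; must sum to 1.
#' @param n_secondary_higher_SP,n_secondary_higher_SL pollen-biased genes
#'   with planted secondary style expression per direction (defaults 40
#'   and 5).
#' @param n_pme,n_pmei,n_reproductive_pme planted family memberships
#'   (defaults 20, 8, 6): \code{n_reproductive_pme} PMEs sit on
#'   pollen-specific genes, remaining PMEs on leaf-biased genes, PMEIs on
#'   unbiased genes.
#' @param base_mean_tpm focal-tissue mean in relative TPM units
#'   (default 100).
#' @param bias_ratio focal:non-focal expression ratio for biased classes
#'   (default 10).
#' @param nb_dispersion negative-binomial dispersion alpha with variance
#'   mu + alpha mu^2; 0 gives deterministic rounded means (default 0.05).
#' @param library_sizes per-sample sequencing depths; default varies
#'   2-fold (1e6 to 2e6) across samples so size-factor code is exercised.
#' @param replicates biological replicates per tissue (default 3).
#' @param leaf_subtissues,pollen_subtissues subtissue counts (7 and 2).
#' @param gene_lengths optional vector of lengths (bp); default drawn
#'   log-uniform in [500, 5000] so TPM ordering differs from count ordering.
#' @param seed RNG seed (Mersenne-Twister).
#' @return list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_genes = 2000,
                            class_proportions = c(leaf_specific = 0.08,
                                                  pollen_specific = 0.08,
                                                  style_specific = 0.08,
                                                  leaf_biased = 0.12,
                                                  pollen_biased = 0.12,
                                                  style_biased = 0.12,
                                                  unbiased = 0.30,
                                                  silent = 0.10),
                            n_secondary_higher_SP = 40,
                            n_secondary_higher_SL = 5,
                            n_pme = 20, n_pmei = 8, n_reproductive_pme = 6,
                            base_mean_tpm = 100, bias_ratio = 10,
                            nb_dispersion = 0.05, library_sizes = NULL,
                            replicates = 3, leaf_subtissues = 7,
                            pollen_subtissues = 2, gene_lengths = NULL,
                            seed = 1) {
  classes <- c("leaf_specific", "pollen_specific", "style_specific",
               "leaf_biased", "pollen_biased", "style_biased",
               "unbiased", "silent")
  .assertThat(setequal(names(class_proportions), classes),
              paste0("class_proportions must name exactly: ",
                     paste(classes, collapse = ", ")))
  .assertThat(abs(sum(class_proportions) - 1) < 1e-8,
              "class proportions must sum to 1")
  .assertThat(nb_dispersion >= 0, "dispersion must be >= 0")
  counts <- floor(class_proportions[classes] * n_genes)
  counts["unbiased"] <- counts["unbiased"] + (n_genes - sum(counts))
  .assertThat(n_secondary_higher_SP + n_secondary_higher_SL <=
                counts["pollen_biased"],
              "planted secondary genes exceed the pollen_biased class size")
  .assertThat(n_reproductive_pme <= n_pme,
              "infeasible planting: n_reproductive_pme > n_pme")
  .assertThat(n_reproductive_pme <= counts["pollen_specific"],
              "not enough pollen_specific genes for reproductive PMEs")
  .assertThat(n_pme - n_reproductive_pme <= counts["leaf_biased"],
              "not enough leaf_biased genes for non-reproductive PMEs")
  .assertThat(n_pmei <= counts["unbiased"],
              "not enough unbiased genes for PMEIs")
  structure(list(n_genes = n_genes, class_counts = counts,
                 n_secondary_higher_SP = n_secondary_higher_SP,
                 n_secondary_higher_SL = n_secondary_higher_SL,
                 n_pme = n_pme, n_pmei = n_pmei,
                 n_reproductive_pme = n_reproductive_pme,
                 base_mean_tpm = base_mean_tpm, bias_ratio = bias_ratio,
                 nb_dispersion = nb_dispersion,
                 library_sizes = library_sizes,
                 replicates = replicates,
                 leaf_subtissues = leaf_subtissues,
                 pollen_subtissues = pollen_subtissues,
                 gene_lengths = gene_lengths, seed = seed),
            class = "SyntheticConfig")
}

#' @noRd
.syntheticDesign <- function(config) {
  rows <- list()
  for (sp in .speciesLevels()) {
    for (r in seq_len(config$replicates)) {
      for (s in seq_len(config$leaf_subtissues))
        rows[[length(rows) + 1L]] <- c(sp, "leaf", paste0("leaf_s", s), r)
      for (s in c("ungerminated", "germinated")[seq_len(config$pollen_subtissues)])
        rows[[length(rows) + 1L]] <- c(sp, "pollen", s, r)
      rows[[length(rows) + 1L]] <- c(sp, "style", "", r)
    }
  }
  st <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(st) <- c("species", "tissue", "subtissue", "bio_rep")
  st$bio_rep <- as.integer(st$bio_rep)
  st$sample_id <- paste0(st$species, ".", st$tissue,
                         ifelse(nzchar(st$subtissue),
                                paste0(".", st$subtissue), ""),
                         ".r", st$bio_rep)
  st[, c("sample_id", "species", "tissue", "subtissue", "bio_rep")]
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Draws a count matrix over the full study design from the configured
#' class profiles: per sample, expected counts are the sample's library
#' size distributed over genes proportionally to expected TPM times gene
#' length, and observed counts are negative-binomial around them
#' (variance mu + alpha mu^2); dispersion 0 yields rounded expected
#' counts. Annotations carry family-matching descriptions for planted
#' PME/PMEI genes. The generator verifies that noiseless classification of
#' the expected TPM profiles reproduces the planted class labels, so the
#' truth table is exact by construction.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with \code{counts} (a [TissueCounts-class]),
#'   \code{annotation} (data.frame), and \code{truth}: a list holding
#'   \code{table} (gene_id, class, secondary_direction, family,
#'   reproductive_specific) and \code{expected_tpm} (per species, genes x
#'   tissue matrices of expected TPM).
#' @export
generateExpression <- function(config) {
  .assertThat(inherits(config, "SyntheticConfig"),
              "config must come from syntheticConfig()")
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_genes
  geneIds <- sprintf("gene%05d", seq_len(n))
  classes <- rep(names(config$class_counts), config$class_counts)

  base <- config$base_mean_tpm
  off <- base / config$bias_ratio
  profileOf <- function(cls) switch(cls,
    leaf_specific   = c(base, 0, 0),
    pollen_specific = c(0, base, 0),
    style_specific  = c(0, 0, base),
    leaf_biased     = c(base, off, off),
    pollen_biased   = c(off, base, 0),
    style_biased    = c(off, off, base),
    unbiased        = c(base, base, base),
    silent          = c(0, 0, 0))
  prof <- t(vapply(classes, profileOf, numeric(3)))
  dimnames(prof) <- list(geneIds, .tissueLevels())
  tpmRel <- list(SL = prof, SP = prof)

  # planted secondary style expression on pollen-biased genes
  pbIdx <- which(classes == "pollen_biased")
  nSP <- config$n_secondary_higher_SP
  nSL <- config$n_secondary_higher_SL
  secondaryDir <- rep(NA_character_, n)
  if (nSP > 0) {
    idx <- pbIdx[seq_len(nSP)]
    tpmRel$SP[idx, "style"] <- base / 5
    tpmRel$SL[idx, "style"] <- 0       # absent from SL styles
    secondaryDir[idx] <- "SP"
  }
  if (nSL > 0) {
    idx <- pbIdx[nSP + seq_len(nSL)]
    tpmRel$SL[idx, "style"] <- base / 5
    tpmRel$SP[idx, "style"] <- base / 20
    secondaryDir[idx] <- "SL"
  }

  # expected TPM: renormalize each species x tissue column to sum 1e6
  expectedTpm <- lapply(tpmRel, function(m) sweep(m, 2, colSums(m), "/") * 1e6)

  # family planting
  family <- rep("none", n)
  psIdx <- which(classes == "pollen_specific")
  lbIdx <- which(classes == "leaf_biased")
  ubIdx <- which(classes == "unbiased")
  pmeIdx <- c(psIdx[seq_len(config$n_reproductive_pme)],
              lbIdx[seq_len(config$n_pme - config$n_reproductive_pme)])
  pmeiIdx <- ubIdx[seq_len(config$n_pmei)]
  family[pmeIdx] <- "PME"
  family[pmeiIdx] <- "PMEI"
  descriptions <- rep("hypothetical protein", n)
  descriptions[pmeIdx] <- "Pectin methylesterase"
  descriptions[pmeiIdx] <- "Invertase/pectin methylesterase inhibitor"
  annotation <- data.frame(gene_id = geneIds, description = descriptions,
                           stringsAsFactors = FALSE)

  reproductive <- classes %in% c("pollen_specific", "style_specific")

  .checkPlantedClasses(expectedTpm, classes)

  lengths <- config$gene_lengths
  if (is.null(lengths))
    lengths <- as.integer(round(exp(stats::runif(n, log(500), log(5000)))))
  .assertThat(length(lengths) == n, "gene_lengths must have one entry per gene")

  st <- .syntheticDesign(config)
  libs <- config$library_sizes
  if (is.null(libs)) libs <- round(seq(1e6, 2e6, length.out = nrow(st)))
  .assertThat(length(libs) == nrow(st),
              "library_sizes must have one entry per sample")

  counts <- matrix(0L, n, nrow(st), dimnames = list(geneIds, st$sample_id))
  alpha <- config$nb_dispersion
  for (j in seq_len(nrow(st))) {
    tpmCol <- expectedTpm[[st$species[j]]][, st$tissue[j]]
    w <- tpmCol * lengths
    mu <- libs[j] * w / sum(w)
    counts[, j] <- if (alpha == 0) as.integer(round(mu))
    else as.integer(stats::rnbinom(n, mu = mu, size = 1 / alpha))
  }

  truthTable <- data.frame(gene_id = geneIds, class = classes,
                           secondary_direction = secondaryDir,
                           family = family,
                           reproductive_specific = reproductive,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(counts = TissueCounts(counts, stats::setNames(lengths, geneIds), st),
       annotation = annotation,
       truth = list(table = truthTable, expected_tpm = expectedTpm,
                    config = config))
}

## noiseless feasibility check: classifying the expected profiles must
## reproduce the planted labels (default thresholds: 2 TPM, tau 0.7,
## floor 0.1)
#' @noRd
.checkPlantedClasses <- function(expectedTpm, classes) {
  for (sp in names(expectedTpm)) {
    m <- expectedTpm[[sp]]
    tau <- .tauRows(m)
    focalIdx <- apply(m, 1, which.max)
    focal <- .tissueLevels()[focalIdx]
    focalMean <- m[cbind(seq_len(nrow(m)), focalIdx)]
    otherMax <- apply(m, 1, function(v) max(v[-which.max(v)]))
    derived <- ifelse(is.na(tau), "silent",
               ifelse(tau >= 0.7 & focalMean >= 2 & otherMax < 0.1,
                      paste0(focal, "_specific"),
               ifelse(tau >= 0.7, paste0(focal, "_biased"), "unbiased")))
    bad <- which(derived != classes)
    .assertThat(length(bad) == 0,
                paste0("infeasible config: planted class '", classes[bad[1]],
                       "' is classified as '", derived[bad[1]],
                       "' on the expected ", sp, " profile"))
  }
  invisible(TRUE)
}

#' Configuration for the synthetic phenotype generator
#'
#' Planted species means and variance components for the pollen-tube
#' assays: growth rate per donor = species mean + a normal donor effect;
#' each record adds residual noise; tube lengths scatter around rate x
#' elapsed hours. Defaults emulate faster in vitro growth in SL (with
#' larger among-donor variance there) and faster in vivo growth in SP with
#' longer SP styles and a matched proportion of the style traversed.
#'
#' @param donors pollen donors (biological replicates) per species
#'   (default 5).
#' @param tech_reps in vitro technical replicates per donor (default 5).
#' @param recipients,repeats in vivo recipients per donor and repeats per
#'   combination (defaults 3 and 2).
#' @param invitro_rate_mean,invitro_donor_sd,invitro_resid_sd in vitro
#'   growth rate components, um/h (named per species where applicable).
#' @param invivo_rate_mean,invivo_donor_sd,invivo_resid_sd in vivo growth
#'   rate components, um/h.
#' @param tube_sd per-tube length scatter (um).
#' @param n_tubes_invitro,n_tubes_invivo tubes measured per record.
#' @param germination_rate per-species germination probability.
#' @param n_viable_mean expected viable pollen per in vitro image.
#' @param diameter_mean,diameter_sd pollen diameter components (um).
#' @param style_length_mean,style_length_sd style length components (um).
#' @param elapsed_invitro_h culture time (default 3 h).
#' @param elapsed_invivo_range_h collection window after pollination
#'   (default 5 to 7 h).
#' @param seed RNG seed.
#' @return list of class \code{"PhenotypeConfig"}.
#' @export
phenotypeConfig <- function(donors = 5, tech_reps = 5, recipients = 3,
                            repeats = 2,
                            invitro_rate_mean = c(SL = 100, SP = 70),
                            invitro_donor_sd = c(SL = 15, SP = 5),
                            invitro_resid_sd = 8,
                            invivo_rate_mean = c(SL = 280, SP = 420),
                            invivo_donor_sd = 40, invivo_resid_sd = 60,
                            tube_sd = 30, n_tubes_invitro = 10,
                            n_tubes_invivo = 5,
                            germination_rate = c(SL = 0.5, SP = 0.5),
                            n_viable_mean = 200,
                            diameter_mean = c(SL = 20, SP = 25),
                            diameter_sd = 1.5,
                            style_length_mean = c(SL = 8000, SP = 12000),
                            style_length_sd = c(SL = 400, SP = 600),
                            elapsed_invitro_h = 3,
                            elapsed_invivo_range_h = c(5, 7),
                            seed = 1) {
  .assertThat(all(invitro_rate_mean > 0) && all(invivo_rate_mean > 0) &&
                all(style_length_mean > 0) && all(diameter_mean > 0),
              "planted means must be positive")
  structure(as.list(environment()), class = "PhenotypeConfig")
}

#' Generate a synthetic pollen-tube phenotype table
#'
#' In vitro: \code{donors x tech_reps} records per species, each with
#' \code{n_tubes_invitro} tube lengths, pollen diameters, and viable /
#' germinated counts. In vivo: \code{donors x recipients x repeats}
#' records per species, each with \code{n_tubes_invivo} tube lengths and a
#' style length; elapsed time varies within the configured window. With
#' all SDs zero, every biological-replicate growth rate equals its planted
#' species mean.
#'
#' @param config a [phenotypeConfig()] object.
#' @return a validated phenotype data.frame (see [readPhenotypes()]).
#' @export
generatePhenotypes <- function(config) {
  .assertThat(inherits(config, "PhenotypeConfig"),
              "config must come from phenotypeConfig()")
  set.seed(config$seed, kind = "Mersenne-Twister")
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  for (sp in .speciesLevels()) {
    donorIds <- sprintf("%s_d%d", sp, seq_len(config$donors))
    dEffVitro <- stats::rnorm(config$donors, 0, config$invitro_donor_sd[[sp]])
    dEffVivo <- stats::rnorm(config$donors, 0, config$invivo_donor_sd)
    for (d in seq_len(config$donors)) {
      for (tr in seq_len(config$tech_reps)) {
        rate <- config$invitro_rate_mean[[sp]] + dEffVitro[d] +
          stats::rnorm(1, 0, config$invitro_resid_sd)
        el <- config$elapsed_invitro_h
        tubes <- pmax(1, rate * el +
                        stats::rnorm(config$n_tubes_invitro, 0,
                                     config$tube_sd))
        nv <- max(1L, stats::rpois(1, config$n_viable_mean))
        ng <- stats::rbinom(1, nv, config$germination_rate[[sp]])
        diam <- pmax(0.1, stats::rnorm(10, config$diameter_mean[[sp]],
                                       config$diameter_sd))
        addRow(assay_type = "in_vitro", species = sp,
               donor_id = donorIds[d], recipient_id = "",
               tech_rep = tr, elapsed_h = el, style_length_um = NA_real_,
               n_viable = nv, n_germinated = ng,
               pollen_diameters_um = list(diam),
               tube_lengths_um = list(tubes))
      }
      for (r in seq_len(config$recipients)) {
        for (rep2 in seq_len(config$repeats)) {
          rate <- config$invivo_rate_mean[[sp]] + dEffVivo[d] +
            stats::rnorm(1, 0, config$invivo_resid_sd)
          el <- stats::runif(1, config$elapsed_invivo_range_h[1],
                             config$elapsed_invivo_range_h[2])
          tubes <- pmax(1, rate * el +
                          stats::rnorm(config$n_tubes_invivo, 0,
                                       config$tube_sd))
          styleLen <- max(1, stats::rnorm(1,
                                          config$style_length_mean[[sp]],
                                          config$style_length_sd[[sp]]))
          addRow(assay_type = "in_vivo", species = sp,
                 donor_id = donorIds[d],
                 recipient_id = sprintf("%s_r%d", sp, r),
                 tech_rep = rep2, elapsed_h = el,
                 style_length_um = styleLen,
                 n_viable = NA_integer_, n_germinated = NA_integer_,
                 pollen_diameters_um = list(numeric(0)),
                 tube_lengths_um = list(tubes))
        }
      }
    }
  }
  pt <- do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(assay_type = r$assay_type, species = r$species,
                     donor_id = r$donor_id, recipient_id = r$recipient_id,
                     tech_rep = r$tech_rep, elapsed_h = r$elapsed_h,
                     style_length_um = r$style_length_um,
                     n_viable = r$n_viable, n_germinated = r$n_germinated,
                     stringsAsFactors = FALSE)
    df$pollen_diameters_um <- r$pollen_diameters_um
    df$tube_lengths_um <- r$tube_lengths_um
    df
  }))
  rownames(pt) <- NULL
  validatePhenotypes(pt)
}

#' Recovery of ground truth by the pipeline
#'
#' Scores pipeline outputs against a generator truth table: per-species
#' classification accuracy over genes the truth marks expressed,
#' confusion counts for the secondary style-expression direction, and
#' recall/precision of the planted family memberships.
#'
#' @param classifications output of [classifyGenes()].
#' @param truth the \code{truth} element of [generateExpression()] output.
#' @param domainComparison optional output of
#'   [compareSecondaryStyleExpression()].
#' @param familySubsets optional output of [reproductiveFamilySubset()];
#'   scored against planted reproductive family members.
#' @param assignments optional output of [matchFamilyTerms()]; scored
#'   against planted family labels.
#' @return list with \code{class_accuracy} (named per species),
#'   \code{n_scored}, and (when the optional inputs are given)
#'   \code{direction_confusion}, \code{direction_accuracy},
#'   \code{family_scores}, \code{reproductive_family_scores}.
#' @export
recoveryReport <- function(classifications, truth, domainComparison = NULL,
                           familySubsets = NULL, assignments = NULL) {
  tt <- truth$table
  expressed <- tt$gene_id[tt$class != "silent"]
  truthLabel <- stats::setNames(tt$class, tt$gene_id)
  acc <- vapply(sort(unique(classifications$species)), function(sp) {
    cl <- classifications[classifications$species == sp &
                            classifications$gene_id %in% expressed, ]
    predicted <- ifelse(cl$class == "unbiased", "unbiased",
                 ifelse(cl$class == "unexpressed_in_species", "silent",
                        paste0(cl$focal_tissue, "_",
                               ifelse(cl$class == "specific", "specific",
                                      "biased"))))
    mean(predicted == truthLabel[cl$gene_id])
  }, numeric(1))
  out <- list(class_accuracy = acc, n_scored = length(expressed))
  if (!is.null(domainComparison)) {
    pg <- domainComparison$per_gene
    truthDir <- stats::setNames(tt$secondary_direction, tt$gene_id)
    callDir <- stats::setNames(ifelse(pg$secondary, pg$direction,
                                      NA_character_), pg$gene_id)
    planted <- names(truthDir)[!is.na(truthDir)]
    out$direction_confusion <- as.data.frame(table(
      truth = truthDir[planted], called = callDir[planted], useNA = "ifany"))
    out$direction_accuracy <- mean(!is.na(callDir[planted]) &
                                     callDir[planted] == truthDir[planted])
  }
  if (!is.null(assignments)) {
    fams <- setdiff(unique(tt$family), "none")
    out$family_scores <- do.call(rbind, lapply(fams, function(fam) {
      truthSet <- tt$gene_id[tt$family == fam]
      callSet <- assignments$gene_id[assignments$family == fam]
      data.frame(family = fam,
                 recall = length(intersect(truthSet, callSet)) /
                   max(1, length(truthSet)),
                 precision = length(intersect(truthSet, callSet)) /
                   max(1, length(callSet)),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(familySubsets)) {
    out$reproductive_family_scores <- do.call(rbind, lapply(
      names(familySubsets), function(fam) {
        truthSet <- tt$gene_id[tt$family == fam & tt$reproductive_specific]
        callSet <- familySubsets[[fam]]
        data.frame(family = fam,
                   recall = length(intersect(truthSet, callSet)) /
                     max(1, length(truthSet)),
                   precision = length(intersect(truthSet, callSet)) /
                     max(1, length(callSet)),
                   stringsAsFactors = FALSE)
      }))
  }
  out
}
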