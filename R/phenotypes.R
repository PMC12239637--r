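#' Welch two-sample t test (closed form)
#'
#' Unequal-variance t statistic \eqn{t = (\bar a - \bar b) /
#' \sqrt{s_a^2/n_a + s_b^2/n_b}} with Welch–Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate inputs follow a fixed
#' contract: when both groups have zero variance, p is 1 for equal means
#' and 0 otherwise (|t| infinite).
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param pooled use the pooled-variance (classical) t test instead of
#'   Welch. Default FALSE.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff}
#'   (mean(a) - mean(b)).
#' @export
welchT <- function(a, b, pooled = FALSE) {
  .assertThat(length(a) >= 2 && length(b) >= 2,
              "each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0) (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)) else NA_real_
  }
  if (se == 0) {
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = df, p = if (md == 0) 1 else 0, mean_diff = md))
  }
  t <- md / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = md)
}

#' Two-sided variance-ratio (F) test
#'
#' \eqn{F = s_a^2 / s_b^2} compared against the F distribution with
#' \eqn{(n_a - 1, n_b - 1)} degrees of freedom; the two-sided p doubles the
#' smaller tail.
#'
#' @param a,b numeric vectors with at least 2 values each; \code{b} must
#'   not be constant.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
varianceRatioTest <- function(a, b) {
  .assertThat(length(a) >= 2 && length(b) >= 2,
              "each group needs at least 2 values")
  vb <- stats::var(b)
  .assertThat(vb > 0, "denominator group has zero variance")
  f <- stats::var(a) / vb
  df1 <- length(a) - 1; df2 <- length(b) - 1
  lower <- stats::pf(f, df1, df2)
  list(F = f, df1 = df1, df2 = df2, p = min(1, 2 * min(lower, 1 - lower)))
}

#' One-way analysis of variance (closed form)
#'
#' Standard between/within decomposition: \eqn{F = (SSB/(k-1)) /
#' (SSW/(n-k))}. Groups of size 1 are dropped with a warning. Degenerate
#' contract when SSW = 0: F is Inf and p is 0 when SSB > 0; F is 0 and p is
#' 1 when SSB = 0.
#'
#' @param values numeric vector of observations.
#' @param groups grouping labels, same length as \code{values} (e.g.
#'   biological replicate within a species); an optional blocking factor
#'   such as assay date can be passed as the grouping instead.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}, and the
#'   number of groups used.
#' @export
onewayAnova <- function(values, groups) {
  .assertThat(length(values) == length(groups),
              "values and groups must have the same length")
  groups <- as.character(groups)
  sizes <- table(groups)
  single <- names(sizes)[sizes < 2]
  if (length(single)) {
    warning("dropping group(s) of size 1: ",
            paste(single, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% single)
    values <- values[keep]; groups <- groups[keep]
  }
  k <- length(unique(groups))
  .assertThat(k >= 2, "one-way ANOVA needs at least 2 groups of size >= 2")
  n <- length(values)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0) {
    if (ssb > 0) return(list(F = Inf, df1 = df1, df2 = df2, p = 0, k = k))
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, k = k))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       k = k)
}

#' Summarize pollen-tube assay records to biological replicates
#'
#' Computes per-record metrics and then averages technical replicates
#' within each (species, donor, assay type), yielding one row per
#' biological replicate (pollen donor). In vitro records give germination
#' rate (n_germinated / n_viable), mean pollen diameter, mean tube length
#' over the measured tubes, and growth rate = mean tube length / elapsed
#' hours. In vivo records give the mean of the 5 longest tubes (fewer with
#' a warning), the corresponding growth rate, style length, and the
#' proportion of the style traversed; in vivo rates use each record's own
#' elapsed time.
#'
#' @param pt phenotype data.frame as returned by [readPhenotypes()] or
#'   [generatePhenotypes()].
#' @return data.frame with one row per (species, donor_id, assay_type):
#'   \code{germination_rate}, \code{mean_diameter_um},
#'   \code{mean_tube_length_um}, \code{growth_rate_um_per_h},
#'   \code{style_length_um}, \code{prop_style} (NA where not applicable),
#'   and \code{n_records} averaged.
#' @export
summarizeAssays <- function(pt) {
  pt <- validatePhenotypes(pt)
  meanTop5 <- function(v) {
    if (length(v) < 5)
      warning("in vivo record with fewer than 5 tubes; using all ",
              length(v), call. = FALSE)
    mean(sort(v, decreasing = TRUE)[seq_len(min(5, length(v)))])
  }
  recLen <- numeric(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    tl <- pt$tube_lengths_um[[i]]
    .assertThat(length(tl) >= 1,
                paste0("record ", i, " has no tube lengths"))
    recLen[i] <- if (pt$assay_type[i] == "in_vivo") meanTop5(tl) else mean(tl)
  }
  rec <- data.frame(
    species = pt$species, donor_id = as.character(pt$donor_id),
    assay_type = pt$assay_type,
    germination_rate = ifelse(pt$assay_type == "in_vitro" &
                                !is.na(pt$n_viable) & pt$n_viable > 0,
                              pt$n_germinated / pt$n_viable, NA_real_),
    mean_diameter_um = vapply(pt$pollen_diameters_um, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    mean_tube_length_um = recLen,
    growth_rate_um_per_h = recLen / pt$elapsed_h,
    style_length_um = ifelse(pt$assay_type == "in_vivo",
                             pt$style_length_um, NA_real_),
    stringsAsFactors = FALSE)
  rec$prop_style <- ifelse(rec$assay_type == "in_vivo",
                           rec$mean_tube_length_um / rec$style_length_um,
                           NA_real_)
  if (any(rec$prop_style > 1, na.rm = TRUE))
    message(sum(rec$prop_style > 1, na.rm = TRUE),
            " in vivo record(s) with tubes beyond the style end ",
            "(prop_style > 1); kept")
  key <- interaction(rec$species, rec$donor_id, rec$assay_type, drop = TRUE)
  agg <- do.call(rbind, lapply(split(rec, key), function(g) {
    data.frame(species = g$species[1], donor_id = g$donor_id[1],
               assay_type = g$assay_type[1],
               germination_rate = mean(g$germination_rate),
               mean_diameter_um = mean(g$mean_diameter_um),
               mean_tube_length_um = mean(g$mean_tube_length_um),
               growth_rate_um_per_h = mean(g$growth_rate_um_per_h),
               style_length_um = mean(g$style_length_um),
               prop_style = mean(g$prop_style),
               n_records = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$assay_type, agg$species, agg$donor_id), ]
  rownames(agg) <- NULL
  agg
}

#' Species comparison panel for pollen-tube phenotypes
#'
#' Runs the standard panel of between-species tests on biological-replicate
#' values: in vitro growth rate, germination rate and pollen diameter; in
#' vivo growth rate, style length and proportion of style traversed (Welch
#' two-sample tests, direction reported as SP - SL); plus a variance-ratio
#' test on in vitro growth rates (SL variance over SP variance).
#'
#' @param summaries output of [summarizeAssays()].
#' @param pooled use pooled-variance t tests instead of Welch.
#' @return data.frame with one row per metric: \code{metric},
#'   \code{assay_type}, \code{mean_SL}, \code{mean_SP}, \code{diff_SP_minus_SL},
#'   \code{statistic}, \code{df}, \code{p}.
#' @export
speciesComparisonReport <- function(summaries, pooled = FALSE) {
  panel <- list(
    c("growth_rate_um_per_h", "in_vitro"),
    c("germination_rate", "in_vitro"),
    c("mean_diameter_um", "in_vitro"),
    c("growth_rate_um_per_h", "in_vivo"),
    c("style_length_um", "in_vivo"),
    c("prop_style", "in_vivo"))
  rows <- lapply(panel, function(it) {
    metric <- it[1]; assay <- it[2]
    sl <- summaries[summaries$assay_type == assay & summaries$species == "SL",
                    metric]
    sp <- summaries[summaries$assay_type == assay & summaries$species == "SP",
                    metric]
    sl <- sl[!is.na(sl)]; sp <- sp[!is.na(sp)]
    if (length(sl) >= 2 && length(sp) >= 2) {
      wt <- welchT(sp, sl, pooled = pooled)
      data.frame(metric = metric, assay_type = assay, test = "welch_t",
                 mean_SL = mean(sl), mean_SP = mean(sp),
                 diff_SP_minus_SL = wt$mean_diff, statistic = wt$t,
                 df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    } else {
      data.frame(metric = metric, assay_type = assay, test = "welch_t",
                 mean_SL = if (length(sl)) mean(sl) else NA_real_,
                 mean_SP = if (length(sp)) mean(sp) else NA_real_,
                 diff_SP_minus_SL = NA_real_, statistic = NA_real_,
                 df = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  slRate <- summaries[summaries$assay_type == "in_vitro" &
                        summaries$species == "SL", "growth_rate_um_per_h"]
  spRate <- summaries[summaries$assay_type == "in_vitro" &
                        summaries$species == "SP", "growth_rate_um_per_h"]
  if (length(slRate) >= 2 && length(spRate) >= 2 && stats::var(spRate) > 0) {
    vt <- varianceRatioTest(slRate, spRate)
    out <- rbind(out, data.frame(
      metric = "growth_rate_variance", assay_type = "in_vitro",
      test = "variance_ratio_F",
      mean_SL = stats::var(slRate), mean_SP = stats::var(spRate),
      diff_SP_minus_SL = stats::var(spRate) - stats::var(slRate),
      statistic = vt$F, df = vt$df1, p = vt$p, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
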