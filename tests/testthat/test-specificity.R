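test_that("tau matches hand-derived values, is scale invariant, rejects bad input", {
  expect_equal(computeTau(c(1, 1, 1)), 0)
  expect_equal(computeTau(c(5, 0, 0)), 1)
  expect_equal(computeTau(c(10, 5, 5)), 0.5)
  expect_equal(computeTau(c(100, 50, 0)), 0.75)
  x <- c(7, 3, 1.5)
  expect_equal(computeTau(1000 * x), computeTau(x))
  expect_error(computeTau(c(0, 0, 0)), "all-zero")
  expect_error(computeTau(5), "at least 2")
  expect_error(computeTau(c(-1, 2, 3)), "non-negative")
})

test_that("row-wise tau agrees with the scalar formula over random profiles", {
  set.seed(101)
  m <- matrix(runif(3000, 0, 500), 1000, 3,
              dimnames = list(sprintf("g%04d", 1:1000),
                              c("leaf", "pollen", "style")))
  m[17, ] <- 0  # all-zero row must give NA
  got <- pollenTau:::.tauRows(m)
  want <- vapply(seq_len(nrow(m)), function(i) {
    if (all(m[i, ] == 0)) NA_real_ else computeTau(m[i, ])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(is.na(got[17]))
})

test_that("classification applies thresholds, zero floor, and the tie order", {
  m <- meanMatrix(
    c(0,    100, 0),      # gA: specific pollen
    c(1,    100, 0),      # gB: biased (off-focal 1 >= zero floor)
    c(0.05, 100, 0.09),   # gC: specific (others below 0.1)
    c(0,    1.9, 0),      # gD: biased only (focal mean < 2 TPM)
    c(50,   50,  50),     # gE: unbiased
    c(100,  100, 0),      # gF: tau 0.5, tie -> focal leaf
    c(0,    0,   0))      # gG: unexpressed in this species
  prof <- profilesFromMeans(list(SL = m, SP = m))
  cl <- classifyGenes(prof, universe = rownames(m))
  sl <- cl[cl$species == "SL", ]
  rownames(sl) <- sl$gene_id
  expect_identical(sl[c("g001", "g002", "g003", "g004", "g005", "g006",
                        "g007"), "class"],
                   c("specific", "biased", "specific", "biased", "unbiased",
                     "unbiased", "unexpressed_in_species"))
  expect_identical(sl["g006", "focal_tissue"], "leaf")  # first max wins
  expect_true(is.na(sl["g007", "focal_tissue"]))
  expect_equal(sl["g001", "tau"], 1)
  # specific genes are always a subset of biased-or-specific genes
  expect_true(all(sl$class[sl$class == "specific"] %in%
                    c("biased", "specific")))
})

test_that("reproductive-specific needs leaf silence in both species", {
  means <- list(
    SL = meanMatrix(c(0,   50, 0),   # repro: pollen high, leaf silent
                    c(1.9, 0,  30),  # repro: leaf below 2 in both
                    c(2.0, 40, 0),   # leaf at threshold in SL -> not repro
                    c(0,   1,  1),   # never reaches 2 in pollen/style
                    c(0,   90, 0)),  # repro in SL only -> still repro
    SP = meanMatrix(c(0,   60, 0),
                    c(1.5, 25, 0),
                    c(0,   40, 0),
                    c(0,   1.9, 0),
                    c(1,   0,  0)))
  prof <- profilesFromMeans(means)
  uni <- filterExpressed(prof, 2)
  flag <- reproductiveSpecific(prof, uni)
  expect_identical(unname(flag[c("g001", "g002", "g003", "g004", "g005")]),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("classification summary proportions reproduce published ratios", {
  counts <- data.frame(
    label = c("SL_total_biased", "SP_total_biased", "SL_style_biased",
              "SP_style_biased", "SL_pollen_secondary", "SL_total_specific"),
    n_expressed = c(19667, 19589, 1132, 1027, 1711, 19667),
    n_biased = c(6656, 7055, 681, 340, 645, 6656),
    n_specific = c(0, 0, 0, 0, 0, 2918))
  rep <- table1Report(counts)
  expect_equal(rep$prop_biased, c(0.338, 0.360, 0.602, 0.331, 0.377, 0.338))
  expect_equal(rep$prop_specific[6], 0.438)
  expect_equal(rep$prop_specific[1:5], rep(0, 5))  # n_biased > 0, none specific
})

test_that("summarizeTable1 counts agree with direct tallies", {
  sim <- generateExpression(smallSyntheticConfig(n_genes = 400,
                                                 nb_dispersion = 0, seed = 7))
  prof <- tissueProfiles(collapseSubtissues(computeTpm(sim$counts)))
  uni <- filterExpressed(prof)
  cl <- classifyGenes(prof, uni)
  tbl <- summarizeTable1(cl, prof)
  slPollen <- tbl[tbl$species == "SL" & tbl$tissue == "pollen", ]
  direct <- sum(cl$species == "SL" & cl$focal_tissue == "pollen" &
                  cl$class %in% c("biased", "specific"), na.rm = TRUE)
  expect_identical(slPollen$n_biased, direct)
  expect_true(all(tbl$n_specific <= tbl$n_biased))
  expect_true(all(tbl$n_biased <= tbl$n_expressed))
  expect_equal(slPollen$prop_biased, slPollen$n_biased / slPollen$n_expressed)
})

test_that("secondary style comparison counts each direction and absences", {
  means <- list(
    SL = meanMatrix(c(0, 100, 0),    c(0, 100, 3),
                    c(0, 100, 0.05), c(0, 100, 2),
                    c(10, 10, 10)),
    SP = meanMatrix(c(0, 100, 5),    c(0, 100, 1),
                    c(0, 100, 0.05), c(0, 100, 2),
                    c(0, 100, 4)))
  prof <- profilesFromMeans(means)
  cl <- classifyGenes(prof, universe = sprintf("g%03d", 1:5))
  dc <- compareSecondaryStyleExpression(cl, prof)
  expect_identical(dc$n_union, 5L)         # union over either species
  expect_identical(dc$n_secondary, 4L)     # g003 stays below 2 TPM
  expect_identical(dc$n_higher_SP, 1L)     # g001
  expect_identical(dc$n_higher_SL, 2L)     # g002 and g005 (SL style 10 > 4)
  expect_identical(dc$n_ties, 1L)          # g004
  expect_identical(dc$n_absent_SL_style, 1L)  # g001: SL style 0
  expect_identical(dc$n_secondary,
                   dc$n_higher_SP + dc$n_higher_SL + dc$n_ties)
})

test_that("direction counts are complements of the secondary total", {
  dd <- domainDirectionCounts(482, 471)
  expect_identical(dd$n_higher_SL, 11)
  expect_error(domainDirectionCounts(10, 11), "exceed")
})

test_that("planted secondary directions are recovered from noisy counts", {
  sim <- generateExpression(syntheticConfig(seed = 11))  # 2000 genes, NB noise
  prof <- tissueProfiles(collapseSubtissues(computeTpm(sim$counts)))
  uni <- filterExpressed(prof)
  cl <- classifyGenes(prof, uni)
  dc <- compareSecondaryStyleExpression(cl, prof)
  expect_identical(dc$n_higher_SP, 40L)
  expect_identical(dc$n_higher_SL, 5L)
  rec <- recoveryReport(cl, sim$truth, domainComparison = dc)
  expect_true(all(rec$class_accuracy >= 0.97))
  expect_gte(rec$direction_accuracy, 0.97)
})

test_that("biased counts shrink monotonically with the tau threshold", {
  sim <- generateExpression(smallSyntheticConfig(n_genes = 400,
                                                 nb_dispersion = 0, seed = 13))
  prof <- tissueProfiles(collapseSubtissues(computeTpm(sim$counts)))
  uni <- filterExpressed(prof)
  sens <- thresholdSensitivity(prof, uni)
  cols <- grep("^n_biased_", colnames(sens), value = TRUE)
  for (cc in cols) expect_true(all(diff(sens[[cc]]) <= 0))
  # at tau threshold 1 only single-tissue genes remain biased; in the
  # noiseless generator those are exactly the specific calls
  cl <- classifyGenes(prof, uni)
  strict <- sens[sens$threshold == 1, ]
  for (sp in c("SL", "SP")) {
    nSpecific <- sum(cl$species == sp & cl$class == "specific")
    nStrict <- sum(unlist(strict[paste0("n_biased_", sp, "_",
                                        c("leaf", "pollen", "style"))]))
    expect_identical(nStrict, nSpecific)
  }
})

test_that("meanBiasContrast detects a planted shift in tau and in level", {
  tauSL <- seq(0.72, 0.92, length.out = 200)
  tauSP <- tauSL + 0.05
  uFrom <- function(tau) 100 * (1 - tau)  # profile (u, 100, u) has this tau
  mkMeans <- function(tau) {
    m <- cbind(leaf = uFrom(tau), pollen = 100, style = uFrom(tau))
    rownames(m) <- sprintf("g%03d", seq_along(tau))
    m
  }
  prof <- profilesFromMeans(list(SL = mkMeans(tauSL), SP = mkMeans(tauSP)))
  cl <- classifyGenes(prof, universe = sprintf("g%03d", 1:200))
  res <- meanBiasContrast(cl, prof, "pollen", metric = "tau")
  expect_equal(res$difference, 0.05, tolerance = 1e-10)
  expect_lt(res$p, 1e-6)

  # level metric: SP pollen 10x SL -> difference of 1 on log10(TPM + 1),
  # up to the +1 offset
  m2SL <- meanMatrix(c(0, 99, 0), c(0, 999, 0), c(0, 9999, 0))
  m2SP <- m2SL * 10; m2SP[m2SP == 0] <- 0
  rownames(m2SP) <- rownames(m2SL)
  prof2 <- profilesFromMeans(list(SL = m2SL, SP = m2SP))
  cl2 <- classifyGenes(prof2, universe = rownames(m2SL))
  res2 <- meanBiasContrast(cl2, prof2, "pollen", metric = "logtpm")
  expect_equal(res2$difference, mean(log10(c(991, 9991, 99991)) -
                                       log10(c(100, 1000, 10000))),
               tolerance = 1e-12)

  # degenerate group sizes yield NA statistics, not an error
  m3 <- meanMatrix(c(0, 100, 0))
  prof3 <- profilesFromMeans(list(SL = m3, SP = m3))
  cl3 <- classifyGenes(prof3, universe = "g001")
  res3 <- meanBiasContrast(cl3, prof3, "pollen", metric = "tau")
  expect_true(is.na(res3$p))
  expect_equal(res3$difference, 0)
})
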