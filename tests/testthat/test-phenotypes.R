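test_that("welchT matches stats::t.test in both variance modes", {
  set.seed(50)
  a <- rnorm(8, 10, 2); b <- rnorm(13, 9, 5)
  got <- welchT(a, b)
  ref <- t.test(a, b)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$mean_diff, mean(a) - mean(b), tolerance = 1e-12)
  gotP <- welchT(a, b, pooled = TRUE)
  refP <- t.test(a, b, var.equal = TRUE)
  expect_equal(gotP$t, unname(refP$statistic), tolerance = 1e-10)
  expect_equal(gotP$df, unname(refP$parameter), tolerance = 1e-10)
  expect_equal(gotP$p, refP$p.value, tolerance = 1e-10)
})

test_that("welchT degenerate contracts are fixed", {
  expect_equal(welchT(c(5, 5), c(5, 5))$p, 1)
  expect_equal(welchT(c(5, 5), c(5, 5))$t, 0)
  d <- welchT(c(7, 7), c(5, 5))
  expect_identical(d$t, Inf)
  expect_equal(d$p, 0)
  expect_identical(welchT(c(3, 3), c(5, 5))$t, -Inf)
  expect_error(welchT(1, c(2, 3)), "at least 2")
})

test_that("variance-ratio test matches var.test and the worked example", {
  got <- varianceRatioTest(c(0, 10), c(4, 6))
  expect_equal(got$F, 25)  # var 50 over var 2
  ref0 <- var.test(c(0, 10), c(4, 6))
  expect_equal(got$p, ref0$p.value, tolerance = 1e-12)
  set.seed(51)
  a <- rnorm(12, 0, 3); b <- rnorm(9, 0, 1)
  got2 <- varianceRatioTest(a, b)
  ref <- var.test(a, b)
  expect_equal(got2$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got2$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(got2$df1, got2$df2), c(11, 8))
  expect_error(varianceRatioTest(a, c(2, 2, 2)), "zero variance")
})

test_that("one-way ANOVA matches anova(lm) and honors its contracts", {
  set.seed(52)
  g <- rep(c("d1", "d2", "d3", "d4"), times = c(5, 5, 4, 6))
  y <- rnorm(length(g), ave(seq_along(g), g), 1)
  got <- onewayAnova(y, g)
  ref <- anova(lm(y ~ factor(g)))
  expect_equal(got$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), as.numeric(ref$Df[1:2]))
  # singleton groups are dropped, not silently pooled
  expect_warning(res <- onewayAnova(c(y, 99), c(g, "d5")), "d5")
  expect_equal(res$F, got$F, tolerance = 1e-10)
  # degenerate contracts
  zeroWithin <- onewayAnova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_identical(zeroWithin$F, Inf)
  expect_equal(zeroWithin$p, 0)
  flat <- onewayAnova(rep(3, 6), rep(c("a", "b", "c"), 2))
  expect_identical(flat$F, 0)
  expect_equal(flat$p, 1)
})

test_that("in vivo records use the mean of the 5 longest tubes", {
  tubes <- seq(900, 100, by = -100)  # 9 tubes
  row <- toyPhenotypeRow(assay_type = "in_vivo", recipient_id = "r1",
                         elapsed_h = 1, style_length_um = 12000,
                         n_viable = NA, n_germinated = NA,
                         diameters = numeric(0), tubes = tubes)
  s <- summarizeAssays(row)
  expect_equal(s$mean_tube_length_um, 700)  # mean(900, 800, 700, 600, 500)
  expect_equal(s$growth_rate_um_per_h, 700)
  expect_equal(s$prop_style, 700 / 12000)
  # tube order must not matter
  row2 <- row; row2$tube_lengths_um <- list(sample(tubes))
  expect_equal(summarizeAssays(row2)$mean_tube_length_um, 700)
  # fewer than 5 tubes: use all, with a warning
  short <- row; short$tube_lengths_um <- list(c(400, 600))
  expect_warning(sShort <- summarizeAssays(short), "fewer than 5")
  expect_equal(sShort$mean_tube_length_um, 500)
})

test_that("technical replicates average to one biological replicate", {
  r1 <- toyPhenotypeRow(tech_rep = 1, elapsed_h = 1, tubes = c(90, 90),
                        n_viable = 100L, n_germinated = 40L)
  r2 <- toyPhenotypeRow(tech_rep = 2, elapsed_h = 1, tubes = c(110, 110),
                        n_viable = 100L, n_germinated = 60L)
  s <- summarizeAssays(rbind(r1, r2))
  expect_identical(nrow(s), 1L)
  expect_equal(s$growth_rate_um_per_h, 100)  # mean(90, 110)
  expect_equal(s$germination_rate, 0.5)      # mean(0.4, 0.6)
  expect_identical(s$n_records, 2L)
  # growth summaries are monotone in tube length
  r3 <- r2; r3$tube_lengths_um <- list(c(150, 150))
  s2 <- summarizeAssays(rbind(r1, r3))
  expect_gt(s2$growth_rate_um_per_h, s$growth_rate_um_per_h)
})

test_that("zero-noise phenotype generation yields the planted differences exactly", {
  cfg <- phenotypeConfig(invitro_donor_sd = c(SL = 0, SP = 0),
                         invitro_resid_sd = 0, invivo_donor_sd = 0,
                         invivo_resid_sd = 0, tube_sd = 0, diameter_sd = 0,
                         style_length_sd = c(SL = 0, SP = 0), seed = 6)
  s <- summarizeAssays(generatePhenotypes(cfg))
  rep <- speciesComparisonReport(s)
  pick <- function(metric, assay)
    rep[rep$metric == metric & rep$assay_type == assay, ]
  vitro <- pick("growth_rate_um_per_h", "in_vitro")
  expect_equal(vitro$diff_SP_minus_SL, -30)  # 70 - 100
  expect_equal(vitro$p, 0)                   # zero variance, unequal means
  vivo <- pick("growth_rate_um_per_h", "in_vivo")
  expect_equal(vivo$diff_SP_minus_SL, 140)   # 420 - 280
  style <- pick("style_length_um", "in_vivo")
  expect_equal(style$diff_SP_minus_SL, 4000)
})

test_that("the comparison panel reproduces the planted sign reversal", {
  cfg <- phenotypeConfig(seed = 3)
  s <- summarizeAssays(generatePhenotypes(cfg))
  expect_identical(nrow(s[s$assay_type == "in_vitro", ]), 10L)  # 5 donors x 2
  rep <- speciesComparisonReport(s)
  vitro <- rep[rep$metric == "growth_rate_um_per_h" &
                 rep$assay_type == "in_vitro", ]
  vivo <- rep[rep$metric == "growth_rate_um_per_h" &
                rep$assay_type == "in_vivo", ]
  expect_lt(vitro$diff_SP_minus_SL, 0)  # SL grows faster in culture
  expect_lt(vitro$p, 0.05)
  expect_gt(vivo$diff_SP_minus_SL, 0)   # SP grows faster in the style
  expect_lt(vivo$p, 0.05)
  style <- rep[rep$metric == "style_length_um", ]
  expect_gt(style$diff_SP_minus_SL, 0)
  expect_lt(style$p, 0.05)
  vr <- rep[rep$test == "variance_ratio_F", ]
  expect_identical(nrow(vr), 1L)
  expect_gt(vr$statistic, 1)  # SL donor variance planted larger
})

test_that("donor ANOVA detects a planted between-donor effect", {
  set.seed(53)
  donors <- rep(paste0("d", 1:5), each = 5)
  spread <- rnorm(5, 0, 20)        # between-donor sd 20
  y <- 100 + spread[as.integer(factor(donors))] + rnorm(25, 0, 8)
  res <- onewayAnova(y, donors)
  ref <- anova(lm(y ~ factor(donors)))
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_lt(res$p, 0.01)
})

test_that("a 4x variance ratio is detectable at 20 donors per species", {
  set.seed(54)
  hits <- vapply(1:200, function(i) {
    sl <- rnorm(20, 100, 15)  # variance 225
    sp <- rnorm(20, 70, 7.5)  # variance 56.25, ratio 4
    varianceRatioTest(sl, sp)$p < 0.05
  }, logical(1))
  # theoretical power ~0.81; allow Monte Carlo spread
  expect_gt(mean(hits), 0.70)
  expect_lt(mean(hits), 0.92)
})
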