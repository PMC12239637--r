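test_that("median-of-ratios size factors match the worked example", {
  cm <- matrix(c(2L, 4L, 6L, 4L, 8L, 12L), 3,
               dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- sizeFactorsMedianOfRatios(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_identical(names(sf), c("A", "B"))
})

test_that("size factors scale with depth and ignore all-zero genes", {
  set.seed(30)
  cm <- matrix(rpois(400, 50) + 1L, 100, 4,
               dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  sf <- sizeFactorsMedianOfRatios(cm)
  # doubling one sample's counts doubles its factor relative to the others
  # (the geometric-mean reference rescales, so only ratios are identified)
  cm2 <- cm; cm2[, 2] <- cm[, 2] * 2L
  sf2 <- sizeFactorsMedianOfRatios(cm2)
  expect_equal(unname(sf2[2] / sf2[1]), unname(2 * sf[2] / sf[1]),
               tolerance = 1e-12)
  expect_equal(unname(sf2[3] / sf2[4]), unname(sf[3] / sf[4]),
               tolerance = 1e-12)
  # equal columns give unit factors
  eq <- cbind(a = cm[, 1], b = cm[, 1])
  expect_equal(unname(sizeFactorsMedianOfRatios(eq)), c(1, 1))
  # a gene zero in any sample cannot anchor the reference
  noRef <- matrix(c(0L, 5L, 3L, 0L), 2,
                  dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(sizeFactorsMedianOfRatios(noRef), "nonzero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(31)
  mu <- outer(exp(rnorm(300, 4, 1)), c(0.5, 1, 1.5, 2, 3))
  cm <- matrix(rpois(length(mu), mu), nrow(mu),
               dimnames = list(sprintf("g%03d", seq_len(nrow(mu))),
                               paste0("s", 1:5)))
  ours <- sizeFactorsMedianOfRatios(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("normalizeCounts divides by the factors", {
  cm <- matrix(c(2L, 4L, 6L, 4L, 8L, 12L), 3,
               dimnames = list(paste0("g", 1:3), c("A", "B")))
  norm <- normalizeCounts(cm)
  expect_equal(norm[, "A"], norm[, "B"], tolerance = 1e-12)
  expect_equal(unname(norm["g1", "A"]), 2 * sqrt(2), tolerance = 1e-12)
})

test_that("BH adjustment reproduces hand-worked examples", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bhAdjust(0.03), 0.03)
  # order of the input must not matter beyond the mapping back
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(bhAdjust(p), rep(0.04, 4))
})

test_that("BH agrees with p.adjust and the step-up definition on random input", {
  set.seed(32)
  p <- runif(500)^2
  q <- bhAdjust(p)
  expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
  # brute-force step-up: q_i = min over p_j >= p_i of m * p_j / rank_j
  m <- length(p)
  r <- rank(p, ties.method = "first")
  brute <- vapply(seq_len(m), function(i)
    min(1, min((m * p / r)[p >= p[i]])), numeric(1))
  expect_equal(q, brute, tolerance = 1e-14)
  # adjusted values preserve the ordering of the raw p-values
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= p) && all(q <= 1))
})

test_that("contrastTest is a Welch t on log2(x + 1)", {
  a <- c(10, 12, 14); b <- c(3, 4, 5)
  got <- contrastTest(a, b)
  ref <- t.test(log2(a + 1), log2(b + 1))
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # identical constant groups: no evidence, p = 1
  expect_equal(contrastTest(c(5, 5, 5), c(5, 5, 5))$p, 1)
})

test_that("planned contrasts recover a planted 4x style difference", {
  set.seed(21)
  nNull <- 200; nUp <- 50; n <- nNull + nUp
  genes <- sprintf("g%03d", 1:n)
  st <- expand.grid(species = c("SL", "SP"), tissue = c("pollen", "style"),
                    bio_rep = 1:3, stringsAsFactors = FALSE)
  st$subtissue <- ""
  st$sample_id <- paste(st$species, st$tissue, st$bio_rep, sep = ".")
  mu <- matrix(100, n, nrow(st), dimnames = list(genes, st$sample_id))
  up <- genes[(nNull + 1):n]
  mu[up, st$species == "SP" & st$tissue == "style"] <- 400
  cm <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.02),
               n, nrow(st), dimnames = dimnames(mu))
  tc <- TissueCounts(cm, rep(1000L, n),
                     st[, c("sample_id", "species", "tissue", "subtissue",
                            "bio_rep")])
  res <- runPlannedContrasts(tc, genes)
  sty <- res[res$tissue == "style", ]
  expect_gte(mean(sty$significant[sty$gene_id %in% up]), 0.75)
  expect_true(all(sty$log2fc[sty$gene_id %in% up & sty$significant] > 0))
  expect_lte(mean(sty$significant[!sty$gene_id %in% up]), 0.03)
  # the pollen contrast is all-null here: BH keeps rejections near zero and
  # the raw p-values are approximately calibrated
  pol <- res[res$tissue == "pollen", ]
  expect_lte(mean(pol$significant), 0.03)
  expect_lte(mean(pol$p < 0.05),
             0.05 + 2 * sqrt(0.05 * 0.95 / nrow(pol)))
  expect_equal(res$q, unlist(tapply(res$p, res$tissue,
                                    p.adjust, method = "BH",
                                    simplify = FALSE)[c("pollen", "style")],
                             use.names = FALSE))
})

test_that("topDifferential ranks by |delta TPM| with deterministic ties", {
  means <- list(
    SL = meanMatrix(c(0, 100, 0), c(0, 50, 0), c(0, 400, 0), c(0, 10, 0.5)),
    SP = meanMatrix(c(0, 300, 0), c(0, 50, 0), c(0, 100, 0), c(0, 210, 0.5)))
  prof <- profilesFromMeans(means)
  cl <- classifyGenes(prof, universe = sprintf("g%03d", 1:4))
  w <- capture_warnings(top <- topDifferential(cl, prof, k = 10))
  expect_length(w, 2)  # both pollen categories are shorter than k;
                       # the empty style categories stay silent
  expect_match(w, "only", all = TRUE)
  ps <- top[top$category == "pollen_specific", ]
  # g003 has |delta| 300, g001 200 (specific both), g004 is biased-only in SP
  expect_identical(ps$gene_id[1:2], c("g003", "g001"))
  expect_equal(ps$delta_tpm[1:2], c(-300, 200))
  pb <- top[top$category == "pollen_biased", ]
  expect_true("g004" %in% pb$gene_id)          # biased includes specific
  expect_true(all(diff(pb$abs_delta_tpm) <= 0))
  expect_identical(pb$rank, seq_len(nrow(pb)))
  # exact tie on |delta|: gene ID breaks it
  tie <- list(SL = meanMatrix(c(0, 10, 0), c(0, 30, 0)),
              SP = meanMatrix(c(0, 30, 0), c(0, 10, 0)))
  profT <- profilesFromMeans(tie)
  clT <- classifyGenes(profT, universe = c("g001", "g002"))
  topT <- suppressWarnings(topDifferential(clT, profT, k = 2))
  expect_identical(topT$gene_id[topT$category == "pollen_specific"],
                   c("g001", "g002"))
})
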