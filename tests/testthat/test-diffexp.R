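test_that("normalization factors are neutral for equal or scaled samples", {
  set.seed(71)
  cnt <- matrix(rpois(2000, 100), 1000, 2,
                dimnames = list(NULL, c("a", "b")))
  cnt[, 2] <- cnt[, 1]
  expect_equal(unname(normalization_factors(cnt)), c(1, 1), tolerance = 1e-6)
  # pure depth: sample b is an exact doubling of a
  cnt[, 2] <- 2 * cnt[, 1]
  expect_equal(unname(normalization_factors(cnt)), c(1, 1), tolerance = 1e-6)
  expect_error(normalization_factors(cnt[, 1, drop = FALSE]), "2 samples")
})

test_that("planted composition bias is recovered near the analytic factor", {
  set.seed(72)
  n <- 5000
  base <- exp(runif(n, log(50), log(500)))
  up <- seq_len(n) <= n * 0.1          # 10% of genes 8-fold up in sample b
  mu_a <- base
  mu_b <- base * ifelse(up, 8, 1)
  cnt <- cbind(a = rpois(n, mu_a), b = rpois(n, mu_b))
  f <- normalization_factors(cnt)
  # analytic: after trimming, M of the 90% unchanged genes is
  # -log2(lib_b / lib_a); the factor ratio recovers that depth distortion
  lib_ratio <- sum(mu_b) / sum(mu_a)
  expected_b_over_a <- 1 / lib_ratio
  expect_equal(unname(f[["b"]] / f[["a"]]), expected_b_over_a,
               tolerance = 0.05)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)
})

test_that("log2-CPM applies the pseudo-count and effective library size", {
  cnt <- matrix(c(100, 200), 1, 2, dimnames = list("f", c("a", "b")))
  y <- log2_cpm(cnt, lib_sizes = c(1e6, 1e6), norm_factors = c(1, 2))
  expect_equal(y[1, 1], log2(100.5))
  expect_equal(y[1, 2], log2(200.5 / 2))
})

test_that("expression filters use inclusive class-specific cutoffs", {
  lib <- c(1e6, 1e6)
  # mean log2-cpm exactly 0.5: count + 0.5 = 2^0.5
  c_at <- 2^0.5 - 0.5
  c_below <- 2^0.49 - 0.5
  cnt <- matrix(c(c_at, c_at, c_below, c_below), 2, 2, byrow = TRUE,
                dimnames = list(c("at", "below"), c("a", "b")))
  keep <- filter_features(cnt, "gene", lib)
  expect_true(keep[["at"]])
  expect_false(keep[["below"]])
  # the ECR class applies the 4.5 cutoff
  c_ecr <- 2^4.5 - 0.5
  cnt2 <- matrix(c(c_ecr, c_ecr, c_at, c_at), 2, 2, byrow = TRUE,
                 dimnames = list(c("hi", "lo"), c("a", "b")))
  keep2 <- filter_features(cnt2, "ECR", lib)
  expect_true(keep2[["hi"]])
  expect_false(keep2[["lo"]])
  expect_false(filter_features(matrix(0, 1, 2, dimnames = list("z", c("a", "b"))),
                               "gene", lib))
  expect_error(filter_features(cnt, "promoter", lib), "unknown feature class")
})

test_that("swapping the contrast direction negates every log2FC", {
  set.seed(73)
  cnt <- matrix(rpois(600, 200), 100, 6,
                dimnames = list(sprintf("f%03d", 1:100), sprintf("s%d", 1:6)))
  design <- data.frame(sample_id = colnames(cnt),
                       treatment = rep(c("A", "B"), each = 3))
  lib <- colSums(cnt)
  fwd <- differential_expression(cnt, design, c("A", "B"), lib)
  rev <- differential_expression(cnt, design, c("B", "A"), lib)
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p, rev$p)
  expect_error(differential_expression(cnt, design, c("A", "C"), lib),
               "at least 2 samples")
})

test_that("log2FC estimates agree with an independent limma fit", {
  set.seed(74)
  cnt <- matrix(rnbinom(300 * 6, mu = 150, size = 20), 300, 6,
                dimnames = list(sprintf("f%03d", 1:300), sprintf("s%d", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  cnt[1:30, grp == "B"] <- rnbinom(30 * 3, mu = 600, size = 20)
  design <- data.frame(sample_id = colnames(cnt), treatment = grp)
  lib <- colSums(cnt)
  nf <- normalization_factors(cnt)
  mine <- differential_expression(cnt, design, c("A", "B"), lib, nf)
  y <- log2_cpm(cnt, lib, nf)
  mm <- stats::model.matrix(~ 0 + factor(grp))
  colnames(mm) <- c("A", "B")
  fit <- limma::lmFit(y, mm)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(B - A, levels = mm))
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, number = Inf, sort.by = "none")
  expect_equal(mine$log2fc, unname(tab$logFC), tolerance = 1e-10)
  expect_gt(cor(rank(mine$p), rank(tab$P.Value)), 0.99)
})

test_that("interaction coefficient equals group-mean arithmetic exactly", {
  # noiseless counts: per-genotype constant expression
  groups <- rep(c("WT/WT", "KO/WT", "WT/KO", "KO/KO"), each = 3)
  design <- data.frame(sample_id = sprintf("s%d", 1:12),
                       hnRNPC = sub("/.*", "", groups),
                       ADAR = sub(".*/", "", groups))
  lib <- rep(1e6, 12)
  vals <- c("WT/WT" = 100, "KO/WT" = 200, "WT/KO" = 150, "KO/KO" = 1200)
  cnt <- matrix(vals[groups], 2, 12, byrow = TRUE,
                dimnames = list(c("f1", "f2"), design$sample_id))
  cnt[2, ] <- 50  # flat feature
  it <- interaction_test(cnt, design, lib, prior_df = 4)
  m <- log2(vals + 0.5)
  want <- (m[["KO/KO"]] - m[["WT/KO"]]) - (m[["KO/WT"]] - m[["WT/WT"]])
  expect_equal(it$interaction[1], unname(want), tolerance = 1e-10)
  expect_equal(it$interaction[2], 0, tolerance = 1e-10)
  expect_error(interaction_test(cnt[, 1:9], design[1:9, ], lib[1:9]),
               "missing genotype")
})

test_that("intron-gene decoupling computes deltas and classes", {
  intron_de <- data.frame(feature_id = c("i1", "i2"), log2fc = c(3.0, 2.0),
                          p_adjust = c(0.001, 0.001))
  gene_de <- data.frame(feature_id = c("gA", "gB"), log2fc = c(0.2, 2.0),
                        p_adjust = c(0.5, 0.001))
  map <- c(i1 = "gA", i2 = "gB")
  dec <- intron_gene_decoupling(intron_de, gene_de, map)
  expect_equal(dec$delta, c(2.8, 0))
  expect_equal(dec$class, c("decoupled", "transcription-driven"))
  expect_error(intron_gene_decoupling(intron_de, gene_de, c(i1 = "gA")),
               "unmapped")
})

test_that("regulated-intron selection scans all per-day comparisons", {
  d1 <- data.frame(feature_id = c("i1", "i2"), log2fc = c(2.5, 0.5),
                   p_adjust = c(0.001, 0.5))
  d2 <- data.frame(feature_id = c("i1", "i2"), log2fc = c(0.1, 2.1),
                   p_adjust = c(0.9, 0.005))
  hit <- select_regulated_introns(list(d1, d2))
  expect_equal(hit, c(TRUE, TRUE))
  expect_equal(select_regulated_introns(list(d1)), c(TRUE, FALSE))
})

test_that("rpkm follows the definition and the expression floor", {
  cnt <- matrix(100, 1, 1, dimnames = list("f", "s"))
  expect_equal(rpkm(cnt, 1000, 1e7, 1)[1, 1], 10)
  expect_equal(rpkm(cnt, 2000, 1e7, 1)[1, 1], 5)
  expect_error(rpkm(cnt, 0, 1e7, 1), "positive")
  rk <- matrix(c(10, 10, 3, 10), 2, 2, byrow = TRUE,
               dimnames = list(c("ok", "low"), c("s1", "s2")))
  ex <- expressed_in_all_conditions(rk, c(s1 = "C1", s2 = "C2"), min_rpkm = 4)
  expect_true(ex[["ok"]])
  expect_false(ex[["low"]])
})

test_that("library rescaling of one sample leaves log2FCs invariant", {
  set.seed(75)
  cnt <- matrix(rpois(100 * 6, 300), 100, 6,
                dimnames = list(sprintf("f%03d", 1:100), sprintf("s%d", 1:6)))
  design <- data.frame(sample_id = colnames(cnt),
                       treatment = rep(c("A", "B"), each = 3))
  lib <- colSums(cnt)
  de1 <- differential_expression(cnt, design, c("A", "B"), lib,
                                 normalization_factors(cnt))
  cnt2 <- cnt
  cnt2[, 3] <- cnt[, 3] * 4
  de2 <- differential_expression(cnt2, design, c("A", "B"), colSums(cnt2),
                                 normalization_factors(cnt2))
  # multiplying all counts of one sample by a constant is pure depth;
  # the 0.5 pseudo-count breaks exact equality only marginally
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 0.02)
})
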