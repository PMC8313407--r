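make_splice_clusters <- function(keys, counts, sig = NULL) {
  path <- tempfile()
  mat <- counts
  rownames(mat) <- keys
  utils::write.table(mat, path, sep = " ", quote = FALSE, col.names = NA)
  sig_path <- NULL
  if (!is.null(sig)) {
    sig_path <- tempfile()
    utils::write.table(sig, sig_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  read_splice_tables(path, sig_path)
}

test_that("intron row keys parse and significance joins are partial", {
  counts <- matrix(c(10, 20, 30, 40), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  sc <- make_splice_clusters(c("chr1:200:400:clu_7", "chr1:200:900:clu_7"),
                             counts,
                             sig = data.frame(cluster = "clu_7", p = 0.02,
                                              p_adjust = 0.04))
  expect_equal(sc$introns$chrom, c("chr1", "chr1"))
  expect_equal(sc$introns$start, c(200, 200))
  expect_equal(sc$introns$end, c(400, 900))
  expect_equal(sc$introns$cluster_id, c("clu_7", "clu_7"))
  expect_equal(sc$cluster_p$p, 0.02)
  # a cluster absent from the significance table keeps p = NA
  sc2 <- make_splice_clusters(c("chr1:1:2:clu_1", "chr1:1:3:clu_1"), counts,
                              sig = data.frame(cluster = "clu_9", p = 0.5,
                                               p_adjust = 0.5))
  expect_true(is.na(sc2$cluster_p$p))
  expect_error(
    make_splice_clusters(c("chr1:200:clu_7", "chr1:1:2:clu_1"), counts),
    "malformed")
})

test_that("splice tables round trip through the synthetic generator", {
  spec <- sim_spec(n_genes = 8, n_editing_clusters = 4, seed = 12,
                   n_structures = 4)
  dir <- tempfile()
  ds <- generate_dataset(spec, dir)
  sc <- read_splice_tables(file.path(dir, "splice_counts.txt"))
  expect_equal(unname(sc$counts), unname(ds$counts$splice_counts))
  expect_equal(rownames(sc$counts), rownames(ds$counts$splice_counts))
})

test_that("relative splice-site use matches the aggregation identity", {
  counts <- matrix(c(30, 70), 2, 1, dimnames = list(NULL, "s1"))
  sc <- make_splice_clusters(c("chr1:100:400:clu_1", "chr1:100:900:clu_1"),
                             counts)
  use <- relative_splice_site_use(sc, c(s1 = "CTRL"))
  start_use <- use[use$side == "start", ]
  end_use <- use[use$side == "end", ]
  expect_equal(start_use$CTRL, 1.0)         # both introns share start 100
  expect_equal(end_use$CTRL[end_use$site == 400], 0.3)
  expect_equal(end_use$CTRL[end_use$site == 900], 0.7)
})

test_that("relative uses sum to one per side and fold changes are ratios", {
  set.seed(21)
  counts <- matrix(rpois(12, 50), 3, 4,
                   dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  keys <- c("chr1:10:50:clu_1", "chr1:10:80:clu_1", "chr1:20:80:clu_1")
  sc <- make_splice_clusters(keys, counts)
  cond <- c(a1 = "CTRL", a2 = "CTRL", b1 = "KO", b2 = "KO")
  use <- relative_splice_site_use(sc, cond, contrast = c("CTRL", "KO"))
  for (side in c("start", "end")) {
    sub <- use[use$side == side, ]
    expect_equal(sum(sub$CTRL), 1)
    expect_equal(sum(sub$KO), 1)
  }
  expect_equal(use$fold_change, use$KO / use$CTRL)
})

test_that("CLIP proximity uses the 50-nt window on interval distance", {
  peaks <- genomic_intervals("chr1", 10060, 10100, ".")
  r <- annotate_clip_proximity("chr1", 10030, peaks, max_gap = 50)
  expect_equal(r$distance, 30)
  expect_true(r$proximal)
  r51 <- annotate_clip_proximity("chr1", 10009, peaks, max_gap = 50)
  expect_equal(r51$distance, 51)
  expect_false(r51$proximal)
  inside <- annotate_clip_proximity("chr1", 10070, peaks, max_gap = 50)
  expect_equal(inside$distance, 0)
  none <- annotate_clip_proximity("chr2", 10, peaks, max_gap = 50)
  expect_true(is.na(none$distance))
  expect_false(none$proximal)
})

test_that("the G-test reproduces the textbook statistic and null identity", {
  # identical proportions -> G = 0, p = 1
  expect_equal(ecrscan:::g_test_2group(c(30, 70), c(60, 140)), 1)
  # hand-worked 2x2 table
  o1 <- c(25, 75); o2 <- c(50, 50)
  p_pool <- (o1 + o2) / 200
  e1 <- 100 * p_pool; e2 <- 100 * p_pool
  g <- 2 * (sum(o1 * log(o1 / e1)) + sum(o2 * log(o2 / e2)))
  expect_equal(ecrscan:::g_test_2group(o1, o2),
               pchisq(g, df = 1, lower.tail = FALSE))
  # zero totals in one group are undefined
  expect_true(is.na(ecrscan:::g_test_2group(c(0, 0), c(10, 10))))
})

test_that("differential clusters exclude singletons and adjust with BH", {
  keys <- c("chr1:1:5:clu_1", "chr1:1:9:clu_1", "chr1:50:99:clu_2")
  counts <- rbind(c(90, 10), c(10, 90), c(100, 100))
  dimnames(counts) <- list(NULL, c("a", "b"))
  sc <- make_splice_clusters(keys, counts)
  sc <- differential_splice_clusters(sc, c(a = "CTRL", b = "KO"),
                                     c("CTRL", "KO"))
  p1 <- sc$cluster_p$p[sc$cluster_p$cluster_id == "clu_1"]
  expect_lt(p1, 1e-10)
  expect_true(is.na(sc$cluster_p$p[sc$cluster_p$cluster_id == "clu_2"]))
  expect_equal(sc$cluster_p$p_adjust,
               p.adjust(sc$cluster_p$p, method = "BH"))
})

test_that("externally supplied significance values take precedence", {
  counts <- matrix(c(90, 10, 10, 90), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  sc <- make_splice_clusters(c("chr1:1:5:clu_1", "chr1:1:9:clu_1"), counts,
                             sig = data.frame(cluster = "clu_1", p = 0.77,
                                              p_adjust = 0.77))
  kept <- differential_splice_clusters(sc, c(a = "CTRL", b = "KO"),
                                       c("CTRL", "KO"))
  expect_equal(kept$cluster_p$p, 0.77)
  forced <- differential_splice_clusters(sc, c(a = "CTRL", b = "KO"),
                                         c("CTRL", "KO"), overwrite = TRUE)
  expect_lt(forced$cluster_p$p, 0.01)
})

test_that("cluster stratification keys off splice-site repeat overlap", {
  repeats <- genomic_intervals("chr1", c(90, 1090), c(120, 1120), "+",
                               name = c("AluSx", "L1MA4"))
  keys <- c("chr1:100:500:clu_1", "chr1:100:600:clu_1",   # start in Alu
            "chr1:1100:1500:clu_2", "chr1:1100:1600:clu_2", # start in L1
            "chr1:5000:5500:clu_3", "chr1:5000:5600:clu_3") # nothing
  counts <- matrix(rep(c(60, 40), 3), 6, 2,
                   dimnames = list(NULL, c("a", "b")))
  sc <- make_splice_clusters(keys, counts)
  sc$cluster_p$p <- c(1e-5, 0.5, 0.5)
  sc$cluster_p$p_adjust <- c(3e-5, 0.5, 0.5)
  strat <- stratify_clusters(sc, repeats, cutoffs = c(0.001, 0.05))
  cls <- strat$classes
  expect_equal(cls$class[cls$cluster_id == "clu_1"], "Alu")
  expect_equal(cls$class[cls$cluster_id == "clu_2"], "non-Alu RE")
  expect_equal(cls$class[cls$cluster_id == "clu_3"], "no RE")
  alu_row <- strat$fractions[strat$fractions$class == "Alu" &
                               strat$fractions$cutoff == 0.001, ]
  expect_equal(alu_row$fraction, 1)
  # invariance to repeat record order
  strat2 <- stratify_clusters(sc, repeats[2:1, ], cutoffs = c(0.001, 0.05))
  expect_equal(strat2$classes[order(strat2$classes$cluster_id), ],
               cls[order(cls$cluster_id), ])
})

test_that("gene overlap fraction counts genes touching significant spans", {
  genes <- genomic_intervals("chr1", c(0, 5000), c(2000, 7000), "+",
                             gene_id = c("gA", "gB"))
  keys <- c("chr1:100:500:clu_1", "chr1:100:900:clu_1")
  counts <- matrix(c(90, 10, 10, 90), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  sc <- make_splice_clusters(keys, counts)
  sc$cluster_p$p_adjust <- 0.005
  ov <- gene_splice_overlap(genes, sc, p_cutoff = 0.01)
  expect_equal(ov$genes$overlaps, c(TRUE, FALSE))
  expect_equal(ov$fraction, 0.5)
  # a cutoff no cluster reaches flags nothing
  expect_equal(gene_splice_overlap(genes, sc, p_cutoff = 1e-6)$fraction, 0)
})
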