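test_that("site frequency folds sequencing errors into the reference", {
  # sense: G is the edit, T/C fold into the reference
  r <- compute_site_frequency(80, 5, 10, 5, "+")
  expect_equal(r$edit, 10)
  expect_equal(r$reference, 90)
  expect_equal(r$frequency, 0.10)
  # antisense: C is the edit (genome space), A/G fold into the reference
  r2 <- compute_site_frequency(0, 10, 0, 90, "-")
  expect_equal(r2$edit, 10)
  expect_equal(r2$reference, 90)
  expect_equal(r2$frequency, 0.10)
  # zero coverage reports frequency 0, not NA
  expect_equal(compute_site_frequency(0, 0, 0, 0, "+")$frequency, 0)
  expect_error(compute_site_frequency(1, 1, 1, 1, "."), "strand")
  expect_error(compute_site_frequency(-1, 0, 0, 0, "+"), "non-negative")
})

test_that("primary filter applies all clauses in at least one WT sample", {
  grid <- expand.grid(freq = c(0.049, 0.05, 0.10, 0.95, 0.951),
                      reads = c(9, 10), score = c(0.49, 0.5),
                      pass = c(TRUE, FALSE), snp = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sites <- make_sites(freq = matrix(g$freq), total = matrix(g$reads),
                        score = matrix(g$score), pass = matrix(g$pass),
                        snp = g$snp)
    kept <- nrow(primary_site_filter(sites, "s1")$meta) == 1
    want <- !g$snp && g$pass && g$score >= 0.5 && g$reads >= 10 &&
      g$freq >= 0.05 && g$freq <= 0.95
    expect_equal(kept, want, info = paste(g, collapse = "/"))
  }
})

test_that("primary filter needs only one qualifying WT sample", {
  sites <- make_sites(freq = matrix(c(0.97, 0.10), 1),
                      total = matrix(c(50, 20), 1))
  expect_equal(nrow(primary_site_filter(sites, c("s1", "s2"))$meta), 1)
  # restricted to the failing sample alone, the site drops
  expect_equal(nrow(primary_site_filter(sites, "s1")$meta), 0)
  expect_error(primary_site_filter(sites, character(0)), "non-empty")
})

test_that("gap clustering matches the worked example and edge cases", {
  cl <- cluster_sites("chr1", "+", c(100, 140, 190, 250), max_gap = 50)
  expect_equal(cl, c(1, 1, 1, 2))  # gaps 40, 50 join; 60 splits
  expect_equal(cluster_sites("chr1", "+", 42, 50), 1L)
  expect_equal(cluster_sites("chr1", "+", c(150, 100), 50), c(1L, 1L))
  expect_error(cluster_sites(c("chr1", "chr2"), "+", c(1, 2), 50),
               "single chromosome")
})

test_that("gap clustering equals the transitive-closure oracle", {
  set.seed(52)
  for (trial in 1:30) {
    n <- sample(2:80, 1)
    pos <- sort(sample(0:5000, n))
    cl <- cluster_sites("chr1", "+", pos, max_gap = 50)
    expect_equal(cl, oracle_cluster(pos, 50))
  }
})

test_that("secondary filter requires one fully qualifying treatment triplet", {
  design <- data.frame(sample_id = sprintf("s%d", 1:6),
                       treatment = rep(c("T1", "T2"), each = 3))
  ok <- make_sites(freq = matrix(c(0.06, 0.12, 0.15, 0, 0, 0), 1),
                   total = matrix(c(12, 30, 11, 0, 0, 0), 1))
  expect_equal(nrow(secondary_site_filter(ok, design)$meta), 1)
  # two-samples->=0.10 clause fails: frequencies (0.06, 0.08, 0.09)
  low <- make_sites(freq = matrix(c(0.06, 0.08, 0.09, 0, 0, 0), 1),
                    total = matrix(c(20, 20, 20, 0, 0, 0), 1))
  expect_equal(nrow(secondary_site_filter(low, design)$meta), 0)
  # a missing sample counts as zero reads, failing its triplet
  missing <- make_sites(freq = matrix(c(0.12, 0.15, 0, 0, 0, 0), 1),
                        total = matrix(c(30, 30, 0, 0, 0, 0), 1))
  expect_equal(nrow(secondary_site_filter(missing, design)$meta), 0)
  bad_design <- data.frame(sample_id = sprintf("s%d", 1:5),
                           treatment = c("T1", "T1", "T1", "T2", "T2"))
  expect_error(secondary_site_filter(ok, bad_design), "exactly 3")
})

test_that("boundary grid of the secondary filter matches clause logic", {
  design <- data.frame(sample_id = c("s1", "s2", "s3"), treatment = "T1")
  for (f1 in c(0.049, 0.05, 0.10)) {
    for (f3 in c(0.05, 0.10, 0.951)) {
      for (r in c(9, 10)) {
        freq <- c(f1, 0.10, f3)
        sites <- make_sites(freq = matrix(freq, 1),
                            total = matrix(rep(r, 3), 1))
        kept <- nrow(secondary_site_filter(sites, design)$meta) == 1
        want <- all(freq >= 0.05) && sum(freq >= 0.10) >= 2 && r >= 10
        expect_equal(kept, want, info = sprintf("%g/%g/%d", f1, f3, r))
      }
    }
  }
})

test_that("final clustering drops small clusters together with their sites", {
  pos5 <- c(0, 40, 80, 120, 160)
  pos4 <- 1000 + c(0, 40, 80, 120)
  sites <- make_sites(freq = matrix(0.2, 9, 1), total = matrix(50, 9, 1),
                      pos = c(pos5, pos4))
  fin <- finalize_clusters(sites)
  expect_equal(nrow(fin$clusters), 1)
  expect_equal(fin$clusters$n_sites, 5)
  expect_equal(nrow(fin$sites$meta), 5)
  expect_true(all(fin$sites$meta$pos %in% pos5))
})

test_that("removing a bridging site splits and can doom both halves", {
  # 7 sites chained by 40-nt gaps; the middle one is removed upstream,
  # leaving two 3-site clusters, both below the 5-site rule
  pos <- seq(0, by = 40, length.out = 7)
  sites <- make_sites(freq = matrix(0.2, 6, 1), total = matrix(50, 6, 1),
                      pos = pos[-4])
  # the two halves are 120 nt apart (gap 80 > 50) after the bridge is gone
  fin <- finalize_clusters(sites)
  expect_equal(nrow(fin$clusters), 0)
  expect_equal(nrow(fin$sites$meta), 0)
  expect_equal(nrow(finalize_clusters(make_sites(matrix(0.2, 1, 1),
                                                 matrix(50, 1, 1)))$clusters),
               0)
})

test_that("ECR construction pads, clamps and merges by >=1 bp overlap", {
  cl <- genomic_intervals("chr1", c(5000, 6500), c(5100, 6600), "+",
                          cluster_id = c("c1", "c2"), n_sites = c(5, 5))
  e <- build_ecrs(cl)
  expect_equal(nrow(e$ecrs), 1)
  expect_equal(e$ecrs$start, 4000)
  expect_equal(e$ecrs$end, 7600)
  expect_equal(sort(e$membership$cluster_id), c("c1", "c2"))
  # gap of exactly 2000: padded intervals abut without shared base
  cl2 <- genomic_intervals("chr1", c(1000, 3100), c(1100, 3200), "+",
                           cluster_id = c("c1", "c2"), n_sites = c(5, 5))
  e2 <- build_ecrs(cl2)
  expect_equal(nrow(e2$ecrs), 2)
  # pad clamps at zero near the chromosome start
  cl3 <- genomic_intervals("chr1", 300, 400, "+", cluster_id = "c1",
                           n_sites = 5)
  expect_equal(build_ecrs(cl3)$ecrs$start, 0)
})

test_that("clusters share an ECR iff chained gaps stay under twice the pad", {
  set.seed(61)
  for (trial in 1:20) {
    n <- sample(2:12, 1)
    starts <- sort(sample(seq(0, 1e6, by = 10), n))
    cl <- genomic_intervals("chr1", starts, starts + 100, "+",
                            cluster_id = sprintf("c%02d", seq_len(n)),
                            n_sites = 5)
    e <- build_ecrs(cl)
    gaps <- starts[-1] - (starts[-n] + 100)
    expected_groups <- cumsum(c(1, as.integer(gaps >= 2000)))
    member <- e$membership[match(cl$cluster_id, e$membership$cluster_id), ]
    expect_equal(length(unique(member$ecr_id)), max(expected_groups))
    same <- outer(expected_groups, expected_groups, "==")
    got <- outer(member$ecr_id, member$ecr_id, "==")
    expect_true(all(same == got))
  }
})

test_that("pooled editing is a ratio of summed counts, not mean of ratios", {
  sites <- make_sites(freq = matrix(c(0.1, 0.2), 2, 1),
                      total = matrix(c(50, 50), 2, 1))
  one <- average_editing(sites, site_group = c("g", "g"))
  expect_equal(one$frequency, 15 / 100)
  mix <- make_sites(freq = matrix(c(0.1, 0.5), 2, 1),
                    total = matrix(c(10, 100), 2, 1))
  pooled <- average_editing(mix, site_group = c("g", "g"))
  expect_equal(pooled$frequency, 51 / 110, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pooled$frequency, 0.30)))
  zero <- average_editing(make_sites(matrix(0, 1, 1), matrix(0, 1, 1)))
  expect_equal(zero$frequency, 0)
  expect_true(zero$no_reads)
})

test_that("tightening thresholds never grows the retained-site set", {
  set.seed(83)
  n <- 200
  m <- 3
  design <- data.frame(sample_id = sprintf("s%d", 1:3), treatment = "T1")
  sites <- make_sites(freq = matrix(runif(n * m, 0, 0.5), n, m),
                      total = matrix(rpois(n * m, 15), n, m),
                      score = matrix(runif(n * m), n, m),
                      pass = matrix(runif(n * m) > 0.2, n, m),
                      pos = sort(sample(0:20000, n)))
  base_p <- pipeline_params()
  loose1 <- primary_site_filter(sites, "s1", base_p)
  loose <- secondary_site_filter(loose1, design, base_p)
  for (tweak in list(list(min_coverage = 20), list(freq_min = 0.08),
                     list(min_caller_score = 0.8), list(freq_high = 0.2))) {
    tight_p <- do.call(pipeline_params, tweak)
    t1 <- primary_site_filter(sites, "s1", tight_p)
    tight <- secondary_site_filter(t1, design, tight_p)
    loose_keys <- paste(loose$meta$chrom, loose$meta$pos)
    tight_keys <- paste(tight$meta$chrom, tight$meta$pos)
    expect_true(all(tight_keys %in% loose_keys),
                info = paste(names(tweak), collapse = ","))
  }
})

test_that("the display read filter subsets without altering retention", {
  sites <- make_sites(freq = matrix(0.2, 4, 2),
                      total = matrix(c(30, 5, 30, 30, 30, 30, 5, 30), 4, 2))
  keep <- reporting_site_filter(sites, c("s1", "s2"), min_reads = 10)
  expect_equal(keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(sites$meta), 4)  # untouched
  expect_error(reporting_site_filter(sites, "nope"), "unknown sample")
})
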