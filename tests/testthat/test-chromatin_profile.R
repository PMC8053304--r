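test_that("binned profiles standardize depth and respect window geometry", {
  # uniform coverage: every bin is bin_size * standard_total / total_tags
  len <- 20000L
  tr <- signal_track(list(chrA = rep(1, len)))
  sites <- genomic_sites("chrA", c(5000L, 9000L))
  pm <- binned_profile(tr, sites, window_half = 1000L, bin_size = 10L,
                       standard_total = 2e5)
  expect_equal(dim(pm), c(2L, 200L))
  expect_true(all(pm == 10 * 2e5 / len))
  # scaling coverage by any c > 0 leaves the matrix unchanged
  tr7 <- signal_track(list(chrA = rep(7, len)))
  pm7 <- binned_profile(tr7, sites, 1000L, 10L, 2e5)
  expect_equal(unclass(pm7), unclass(pm))
  # out-of-range windows are dropped with a warning
  s2 <- genomic_sites("chrA", c(5L, 5000L))
  expect_warning(pm2 <- binned_profile(tr, s2, 1000L, 10L, 2e5), "dropped")
  expect_equal(nrow(pm2), 1L)
  expect_equal(attr(pm2, "dropped"), "site_1")
  expect_error(binned_profile(tr, sites, 1000L, 7L), "divide")
  expect_error(binned_profile(signal_track(list(chrA = rep(0, len))),
                              sites), "zero total")
})

test_that("average profiles are column means, permutation-invariant", {
  m <- make_profile_matrix(rbind(a = rep(0, 200), b = 1:200))
  expect_equal(as.numeric(average_profile(m)), (1:200) / 2)
  expect_equal(as.numeric(average_profile(m[c(2, 1), ])),
               as.numeric(average_profile(m)))
  expect_equal(as.numeric(average_profile(m["b", , drop = FALSE])),
               as.numeric(1:200))
  expect_error(average_profile(m[0, , drop = FALSE]), "empty")
})

test_that("feature matrix is depth-invariant and z-scored per mark", {
  len <- 30000L
  set.seed(7)
  base <- pmax(0, rnorm(len, 1, 0.1))
  tr <- signal_track(list(chrA = base))
  tr2 <- signal_track(list(chrA = base * 5))  # deeper library, same shape
  sites <- genomic_sites("chrA", seq(3000L, 27000L, by = 3000L))
  f1 <- site_feature_matrix(list(m = tr), sites)
  f2 <- site_feature_matrix(list(m = tr2), sites)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(mean(f1[, "m"]), 0, tolerance = 1e-12)
  expect_equal(sd(f1[, "m"]), 1, tolerance = 1e-12)
  # single site: z-scores are zero by convention
  f3 <- site_feature_matrix(list(m = tr), sites[3])
  expect_equal(as.numeric(f3), 0)
  # zero-variance mark skipped with a warning
  flat <- signal_track(list(chrA = rep(2, len)))
  expect_warning(site_feature_matrix(list(flat = flat), sites),
                 "zero-variance")
  # planted two-block structure survives the transform
  blocky <- rep(0.01, len)
  for (p in seq(3000L, 12000L, by = 3000L))
    blocky[(p - 500):(p + 500)] <- 5
  fb <- site_feature_matrix(list(m = signal_track(list(chrA = blocky))),
                            sites)
  expect_true(min(fb[1:4, 1]) > max(fb[5:9, 1]))
})

test_that("seeded k-means recovers planted groups and reports the best restart", {
  set.seed(11)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), 4, 2, byrow = TRUE)
  truth <- rep(1:4, each = 25)
  x <- centers[truth, ] + matrix(rnorm(200, sd = 0.5), 100, 2)
  rownames(x) <- paste0("s", 1:100)
  km <- kmeans_cluster(x, k = 4, seed = 5, n_restarts = 25)
  expect_gte(mclust::adjustedRandIndex(km$labels, truth), 0.95)
  expect_equal(km$objective, min(km$restart_objectives))
  expect_identical(km, kmeans_cluster(x, k = 4, seed = 5, n_restarts = 25))
  # labels ordered by descending cluster size
  expect_true(all(diff(as.integer(table(km$labels))) <= 0))
  expect_equal(unique(kmeans_cluster(x, k = 1, seed = 1,
                                     n_restarts = 2)$labels), 1L)
  # duplicated rows land in one cluster
  dup <- x[rep(1, 10), ]
  rownames(dup) <- paste0("d", 1:10)
  km2 <- kmeans_cluster(rbind(x, dup), k = 4, seed = 5, n_restarts = 25)
  expect_equal(length(unique(km2$labels[paste0("d", 1:10)])), 1L)
  expect_error(kmeans_cluster(x, k = 0), ">= 1")
  expect_error(kmeans_cluster(x[1:3, ], k = 4), "exceeds")
})

test_that("accessibility calls are summit-in-interval with half-open BED edges", {
  acc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  inside <- genomic_sites("chr1", 150L)
  expect_true(classify_accessibility(inside, acc)$accessible[[1]])
  # half-open on disk: BED end position itself is outside
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)  # 0-based [100, 200) = 1-based 101..200
  bed <- rtracklayer::import(f, format = "BED")
  at_end <- genomic_sites("chr1", 201L)
  expect_false(classify_accessibility(at_end, bed)$accessible[[1]])
  expect_true(classify_accessibility(genomic_sites("chr1", 200L),
                                     bed)$accessible[[1]])
  # empty interval set -> fraction 0; absent chromosome warns
  expect_equal(classify_accessibility(inside,
                                      GenomicRanges::GRanges())$fraction, 0)
  expect_warning(
    res <- classify_accessibility(genomic_sites("chrZ", 10L), acc),
    "absent")
  expect_false(res$accessible[[1]])
})

test_that("annotation precedence is promoter > exon > intron > intergenic", {
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 20000),
                               strand = "+", tx_id = "t1")
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(10000, 15000),
                                                c(11000, 16000)),
                               strand = "+", tx_id = c("t1", "t1"))
  gm <- gene_model(tx, ex)
  sites <- genomic_sites(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    c(9500L, 10500L, 13000L, 25000L, 100L))
  ann <- annotate_sites(sites, gm)
  expect_equal(unname(ann$category),
               c("promoter", "exonic", "intronic", "intergenic",
                 "intergenic"))
  expect_equal(sum(ann$fractions), 1)
  # exon beyond promoter reach is exonic; minus-strand promoter is at the end
  ann2 <- annotate_sites(genomic_sites("chr1", 15500L), gm)
  expect_equal(unname(ann2$category), "exonic")
  txm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 20000),
                                strand = "-", tx_id = "t1")
  gmm <- gene_model(txm, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(10000, 10500), strand = "-", tx_id = "t1"))
  ann3 <- annotate_sites(genomic_sites("chr1", 20500L), gmm)
  expect_equal(unname(ann3$category), "promoter")
  # malformed transcript (exon outside span) is skipped with a warning
  bad_ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9500),
                                   tx_id = "t1")
  expect_warning(gene_model(tx, bad_ex), "malformed")
})

test_that("site-set comparison partitions both sets exactly once", {
  a <- genomic_sites(rep("chr1", 3), c(1000L, 2000L, 3000L))
  expect_equal(compare_site_sets(a, a)$n_shared_a, 3L)
  b <- genomic_sites(rep("chr2", 3), c(1000L, 2000L, 3000L))
  cmp <- compare_site_sets(a, b)
  expect_equal(cmp$n_shared_a, 0L)
  expect_equal(cmp$n_a_only + cmp$n_shared_a, 3L)
  expect_equal(cmp$n_b_only + cmp$n_shared_b, 3L)
  # boundary: summits 99 bp apart are shared at match_dist 100
  near <- genomic_sites("chr1", 1099L)
  expect_equal(compare_site_sets(a, near, 100L)$n_shared_b, 1L)
  far <- genomic_sites("chr1", 1101L)
  expect_equal(compare_site_sets(a, far, 100L)$n_shared_b, 0L)
  expect_error(compare_site_sets(a, b, -5), ">= 0")
})

test_that("signal delta flags the peak-valley-peak acetylation shape", {
  nb <- 200
  ctr <- seq(-995, 995, by = 10)
  flatm <- make_profile_matrix(rbind(rep(1, nb)))
  expect_false(signal_delta(flatm, flatm)$pvp)
  expect_equal(signal_delta(flatm, flatm)$delta, rep(0, nb))
  # flanking maxima at +/-200 bp at twice the central level -> flagged
  shape <- 1 + exp(-(ctr - 200)^2 / (2 * 80^2)) +
    exp(-(ctr + 200)^2 / (2 * 80^2))
  pvp <- make_profile_matrix(rbind(shape))
  expect_true(signal_delta(flatm, pvp)$pvp)
  # uniform elevation has no valley
  expect_false(signal_delta(flatm, make_profile_matrix(rbind(rep(3, nb))))$pvp)
  expect_error(signal_delta(flatm, make_profile_matrix(rbind(rep(1, 100)),
                                                       500L, 10L)),
               "geometry")
})

test_that("profile matrices survive a TSV round trip", {
  sim <- small_chromatin_sim()
  pm <- binned_profile(sim$tracks$MNase, sim$sites[1:10],
                       standard_total = 1e9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, f)
  back <- read_profile_matrix(f)
  expect_equal(unclass(back)[, ], unclass(pm)[, ], tolerance = 1e-10)
  expect_equal(attr(back, "window_half"), attr(pm, "window_half"))
  expect_equal(attr(back, "bin_size"), attr(pm, "bin_size"))
})
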