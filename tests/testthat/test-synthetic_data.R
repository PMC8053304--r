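test_that("titration counts honor the no-binding and complete-shift limits", {
  lib <- default_library()
  # zero concentration, zero floor: no supershift reads at all
  m0 <- binding_model(theta0 = 0)
  cfg0 <- emsa_sim_config(lib, m0, concentrations = 0,
                          reads_per_band = 5000, seed = 51)
  bct0 <- simulate_titration(cfg0)
  expect_equal(sum(bct0$lanes[[1]]$supershift), 0)
  expect_equal(sum(bct0$lanes[[1]]$nucleosome), 5000)
  # saturated template vanishes from the unshifted band
  msat <- binding_model(kd_high = 1e-15, theta0 = 0, d_star = 0, s = 1)
  cfgs <- emsa_sim_config(lib, msat, concentrations = 1e-3,
                          reads_per_band = 5000, seed = 52)
  bcts <- simulate_titration(cfgs)
  high_edge <- bcts$lanes[[1]]$nucleosome[c("H66", "H71", "H81")]
  expect_true(all(high_edge == 0))
  # counts are non-negative integers at the configured depth, reproducibly
  cfg <- emsa_sim_config(lib, reads_per_band = 2000, seed = 53)
  b1 <- simulate_titration(cfg)
  expect_identical(b1, simulate_titration(cfg))
  for (lane in b1$lanes) for (band in lane) {
    expect_true(all(band >= 0))
    expect_equal(sum(band), 2000)
  }
  expect_error(emsa_sim_config(lib, reads_per_band = 0), "depth")
  expect_error(emsa_sim_config(lib, error_rate = 0.3), "error rate")
})

test_that("simulated band reads reproduce the count table through assignment", {
  lib <- default_library()
  cfg <- emsa_sim_config(lib, reads_per_band = 400, seed = 54)
  bct <- simulate_titration(cfg)
  # error-free paired reads are exact substrings and invert exactly
  rd <- simulate_reads(bct, lib, error_rate = 0, seed = 55)
  one <- rd$lanes[[1]]$nucleosome
  i <- which(one$template == "H66")[1]
  expect_equal(one$r1[i], substr(lib$sequence[lib$id == "H66"], 1, 150))
  back <- reads_to_counts(rd, lib)
  expect_equal(back$input, bct$input)
  for (ln in names(bct$lanes))
    expect_equal(back$lanes[[ln]], bct$lanes[[ln]])
  expect_equal(sum(unlist(attr(back, "unassigned"))), 0L)
  # at 1% error nearly all reads still come home
  rd2 <- simulate_reads(bct, lib, error_rate = 0.01, seed = 56)
  b2 <- reads_to_counts(rd2, lib)
  agree <- sum(pmin(b2$input, bct$input)) / sum(bct$input)
  expect_gte(agree, 0.99)
  expect_error(simulate_reads(bct, lib, read_len = 500), "exceeds")
  # same seed, same reads
  expect_identical(rd, simulate_reads(bct, lib, error_rate = 0, seed = 55))
})

test_that("FASTQ export round-trips through Biostrings", {
  lib <- default_library()
  cfg <- emsa_sim_config(lib, reads_per_band = 50, seed = 57)
  rd <- simulate_reads(simulate_titration(cfg), lib, error_rate = 0,
                       seed = 58)
  d <- withr::local_tempdir()
  paths <- write_band_fastq(rd, d, "band")
  expect_true(all(file.exists(paths)))
  r1 <- Biostrings::readDNAStringSet(
    file.path(d, "band_input_R1.fastq"), format = "fastq")
  expect_equal(unname(as.character(r1)), rd$input$r1)
})

test_that("the chromatin generator plants the structure the pipeline assumes", {
  sim <- small_chromatin_sim()
  truth <- sim$truth
  # group-d sites: baseline-only marks, outside accessible intervals
  d_sites <- sim$sites[sim$sites$group == "d"]
  acc <- classify_accessibility(d_sites, sim$accessible)
  expect_equal(acc$n_accessible, 0L)
  k27 <- binned_profile(sim$tracks$H3K27ac, d_sites)
  a27 <- binned_profile(sim$tracks$H3K27ac,
                        sim$sites[sim$sites$group == "a"])
  expect_lt(max(average_profile(k27)) * 3, max(average_profile(a27)))
  # accessibility fraction is exact at zero noise
  expect_equal(classify_accessibility(sim$sites, sim$accessible)$fraction,
               truth$accessible_fraction)
  # tracks are non-negative everywhere
  for (tr in sim$tracks)
    expect_true(all(vapply(tr$coverage, function(x)
      min(S4Vectors::runValue(x)) >= 0, logical(1))))
  # nucleosome dyads displaced 50-60 bp, random side
  expect_true(all(abs(truth$nuc_offset) >= 50 & abs(truth$nuc_offset) <= 60))
  expect_true(any(truth$nuc_offset > 0) && any(truth$nuc_offset < 0))
  # same seed: bit-identical regeneration
  sim2 <- simulate_chromatin(sim$config)
  expect_equal(sim2$truth, truth)
  expect_equal(sim2$tracks$MNase$total_tags, sim$tracks$MNase$total_tags)
  expect_identical(as.numeric(sim2$tracks$H3K4me3$coverage[[1]]),
                   as.numeric(sim$tracks$H3K4me3$coverage[[1]]))
})

test_that("generator round trip: oriented occupancy peaks sit 50-60 bp out", {
  sim <- small_chromatin_sim()
  pm <- binned_profile(sim$tracks$MNase, sim$sites, standard_total = 1e9)
  oc <- orient_cluster(pm, k = 2, seed = 61)
  for (j in 1:2) {
    pk <- occupancy_peak_offset(oc$means[j, ], 1000, 10)
    expect_false(pk$undefined)
    expect_gte(abs(pk$offset), 50 - 5)  # within one bin of the planted range
    expect_lte(abs(pk$offset), 60 + 5)
  }
})

test_that("planted acetylation gains yield the PVP call only at bound sites", {
  sim <- small_chromatin_sim()
  before <- binned_profile(sim$tracks$H3K27ac, sim$sites)
  after <- binned_profile(sim$tracks$H3K27ac_after, sim$sites)
  dl <- signal_delta(before, after)
  expect_true(dl$pvp)
  expect_gte(max(dl$delta), 0)
  # unbound (cell-line-B-only) control sites show no planted change
  bonly <- sim$sites_b[(sim$truth$n_shared + 1):length(sim$sites_b)]
  dl0 <- signal_delta(binned_profile(sim$tracks$H3K27ac, bonly),
                      binned_profile(sim$tracks$H3K27ac_after, bonly))
  expect_false(dl0$pvp)
  # depth standardization rescales the whole track, so the control delta
  # is a flat offset with no peak-valley-peak shape
  expect_lt(diff(range(dl0$delta)), 0.02 * max(dl0$avg_after))
})
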