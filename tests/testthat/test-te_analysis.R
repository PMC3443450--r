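test_that("binning lays ceil(length/bin) bins per CG, half-open", {
  # 25 cM CG -> 3 bins; marker at exactly 10 falls in bin 2
  map <- map_from_positions(list(c(0, 10, 25)),
                            systems = list(rep("RT", 3)))
  b <- bin_markers(map, bin_cm = 10)
  expect_equal(b$n_bins, 3)
  expect_equal(b$counts, c(1L, 1L, 1L))
  # terminal marker on an exact multiple stays in the last bin
  map2 <- map_from_positions(list(c(0, 10, 20)),
                             systems = list(rep("RT", 3)))
  b2 <- bin_markers(map2, bin_cm = 10)
  expect_equal(b2$n_bins, 2)
  expect_equal(b2$counts, c(1L, 2L))
  # non-target markers are not counted
  map3 <- map_from_positions(list(c(0, 10, 25)),
                             systems = list(c("RT", "AFLP", "RT")))
  expect_equal(bin_markers(map3, bin_cm = 10)$counts, c(1L, 0L, 1L))
  expect_error(bin_markers(linkage_map(list(),
                                       data.frame(marker_id = character(0),
                                                  system = character(0),
                                                  cross_type = character(0)))),
               "empty map")
})

test_that("uniform placement gives Poisson-dispersed bin counts", {
  cfg <- sim_config(n_individuals = 10, n_chromosomes = 10,
                    chr_length_cM = 100,
                    marker_counts = matrix(c(0, 0, 0, 0, 0, 0, 20, 20, 16),
                                           3, byrow = TRUE),
                    te_clusters = list(n_clusters = 0,
                                       markers_per_cluster = 0,
                                       spacing_cM = 1),
                    seed = 121)
  disp <- replicate(200, {
    pl <- sdmap:::.place_te(cfg, mode = "null")
    counts <- integer(0)
    for (chr in 1:10) {
      pos <- pl$position_cM[pl$chrom == chr]
      counts <- c(counts, tabulate(floor(pos / 10) + 1L, nbins = 10L))
    }
    stats::var(counts) / mean(counts)
  })
  expect_equal(mean(disp), 1, tolerance = 0.05)
})

test_that("the Poisson goodness-of-fit matches a hand-computed oracle", {
  # a 484-bin map with counts 0/1/2/3 in 436/41/6/1 bins
  counts <- rep(0:3, c(436, 41, 6, 1))
  g <- poisson_gof(counts)
  lambda <- 56 / 484
  expect_equal(g$lambda, lambda)
  expect_equal(g$df, 2L)  # 4 classes - 1 - 1 estimated parameter
  expd <- 484 * lambda^(0:3) * exp(-lambda) / factorial(0:3)
  chi2 <- sum((c(436, 41, 6, 1) - expd)^2 / expd)
  expect_equal(g$chi2, chi2, tolerance = 1e-9)
  expect_equal(g$p_value, pchisq(chi2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(poisson_gof(rep(0:1, c(9, 1))), "count classes")
})

test_that("pooling merges the sparse tail into a >=K class", {
  counts <- rep(0:3, c(436, 41, 6, 1))
  g <- poisson_gof(counts, pool = TRUE)
  expect_lt(nrow(g$classes), 4)
  expect_gte(min(g$classes$expected), 1)
  expect_equal(sum(g$classes$observed), 484)
})

test_that("cluster calling uses strict adjacent gaps within CGs", {
  map <- map_from_positions(list(c(10, 12, 16.64, 30, 35)),
                            systems = list(rep("RT", 5)))
  cl <- call_clusters(map, max_gap_cm = 5)
  expect_equal(nrow(cl), 1)  # gaps 2.00, 4.64 cluster; 13.36 and 5.0 break
  expect_equal(cl$n_markers, 3)
  expect_equal(cl$span_cM, 6.64, tolerance = 1e-9)
  # a gap of exactly 5 cM does not cluster
  map2 <- map_from_positions(list(c(10, 15)),
                             systems = list(rep("RT", 2)))
  expect_equal(nrow(call_clusters(map2, max_gap_cm = 5)), 0)
})

test_that("cluster calls ignore interleaved non-target markers", {
  pos <- c(0, 1.5, 2, 3.5)
  map_a <- map_from_positions(list(pos),
                              systems = list(c("RT", "AFLP", "RT", "RT")))
  map_b <- map_from_positions(list(pos[c(1, 3, 4)]),
                              systems = list(rep("RT", 3)))
  ca <- call_clusters(map_a)
  cb <- call_clusters(map_b)
  expect_equal(ca$n_markers, cb$n_markers)
  expect_equal(ca$span_cM, cb$span_cM)
})

test_that("planted clusters are recovered from the true map", {
  cfg <- sim_config(n_individuals = 10, n_chromosomes = 10,
                    chr_length_cM = 100,
                    marker_counts = matrix(c(5, 5, 2, 0, 0, 0, 20, 20, 16),
                                           3, byrow = TRUE),
                    te_clusters = list(n_clusters = 6,
                                       markers_per_cluster = 3,
                                       spacing_cM = 2),
                    seed = 122)
  sim <- simulate_population(cfg)
  map <- map_from_truth(sim$truth)
  cl <- call_clusters(map, max_gap_cm = 5)
  truth <- as.data.frame(sim$truth)
  planted <- truth[!is.na(truth$cluster), ]
  for (cid in unique(planted$cluster)) {
    members <- planted$marker_id[planted$cluster == cid]
    # every planted trio appears inside one called cluster
    hit <- vapply(cl$markers, function(s)
      all(members %in% strsplit(s, ",", fixed = TRUE)[[1]]), logical(1))
    expect_true(any(hit))
  }
})

test_that("copy numbers divide fragments by combinations (half-up)", {
  cn <- copy_number(357, 6)
  expect_equal(cn$estimate_raw, 59.5)
  expect_equal(cn$estimate_rounded, 60L)
  expect_equal(copy_number(324, 6)$estimate_rounded, 54L)
  cn316 <- copy_number(316, 6)
  expect_equal(round(cn316$estimate_raw, 2), 52.67)
  expect_equal(cn316$estimate_rounded, 53L)
  expect_error(copy_number(0, 6))
})

test_that("copy number is exact under perfect detection", {
  prof <- simulate_nbs_profiles(nbs_config(true_copy_number = 60,
                                           n_combinations = 6,
                                           detection_prob = 1,
                                           polymorphism_rate = 0,
                                           seed = 123))
  expect_equal(copy_number(prof$total_fragments, 6)$estimate_rounded, 60L)
  expect_equal(copy_number(prof$total_parent1, 6)$estimate_rounded, 60L)
})
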