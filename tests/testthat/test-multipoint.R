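test_that("the Kosambi map function and its inverse are exact", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(1.5 / 0.5))
  expect_equal(round(kosambi(0.25), 3), 27.465)
  for (r in seq(0, 0.49, by = 0.01)) {
    expect_equal(kosambi_inv(kosambi(r)), r, tolerance = 1e-12)
  }
  # strictly increasing and never below the naive 100 r cM
  r <- seq(0.001, 0.499, by = 0.001)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 100 * r))
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi_inv(-1), ">= 0")
})

test_that("the 2-locus HMM equals the two-point likelihood", {
  set.seed(91)
  classes <- list(
    list(cls = "D1xD1", cross = c("D1", "D1")),
    list(cls = "D2xD2", cross = c("D2", "D2")),
    list(cls = "CxC", cross = c("C", "C")),
    list(cls = "D1xC", cross = c("D1", "C")),
    list(cls = "D2xC", cross = c("D2", "C")))
  for (cc in classes) {
    for (ph in sdmap:::phases_for_class(cc$cls)) {
      for (r in runif(10, 0.01, 0.49)) {
        p <- joint_pattern_probs(cc$cls, ph, r)
        counts <- as.vector(stats::rmultinom(1, 100, p))
        # lay the counts out as two marker rows
        y1 <- rep(c(1L, 1L, 0L, 0L), counts)
        y2 <- rep(c(1L, 0L, 1L, 0L), counts)
        info <- data.frame(
          marker_id = c("A", "B"), system = "AFLP",
          parent1 = ifelse(cc$cross %in% c("D1", "C"), "present", "absent"),
          parent2 = ifelse(cc$cross %in% c("D2", "C"), "present", "absent"))
        tab <- marker_table(sprintf("I%03d", seq_along(y1)), info,
                            rbind(y1, y2))
        comp <- sdmap:::phase_components(cc$cls, ph)
        # a C marker's phase in a parent the pair cannot constrain is
        # arbitrary for the 2-locus likelihood; fix it at 1
        flip <- function(x) ifelse(is.na(x), 1L,
                                   ifelse(x == "repulsion", 0L, 1L))
        phases <- list(
          phase_p1 = c(ifelse(cc$cross[1] %in% c("D1", "C"), 1L, NA)[1],
                       if (cc$cross[2] %in% c("D1", "C")) flip(comp[1])
                       else NA_integer_),
          phase_p2 = c(ifelse(cc$cross[1] %in% c("D2", "C"), 1L, NA)[1],
                       if (cc$cross[2] %in% c("D2", "C")) flip(comp[2])
                       else NA_integer_))
        ll_hmm <- hmm_loglik(c("A", "B"), tab, phases, r)
        ll_tp <- sdmap:::pair_loglik(cc$cls, ph, r, counts[1], counts[2],
                                     counts[3], counts[4])
        expect_equal(ll_hmm, ll_tp, tolerance = 1e-9)
      }
    }
  }
})

test_that("free recombination factorizes and all-missing individuals drop out", {
  sim <- sim_chromosome(n = 50, pos = c(0, 10, 20),
                        cross = c("D1", "D2", "C"), seed = 92,
                        shuffle = FALSE)
  tab <- sim$table
  phases <- list(phase_p1 = c(1L, NA, 1L), phase_p2 = c(NA, 1L, 1L))
  ll_joint <- hmm_loglik(sim$ids, tab, phases, c(0.5, 0.5))
  ll_sep <- sum(vapply(seq_along(sim$ids), function(j)
    hmm_loglik(sim$ids[j], tab,
               list(phase_p1 = phases$phase_p1[j],
                    phase_p2 = phases$phase_p2[j]), numeric(0)),
    numeric(1)))
  expect_equal(ll_joint, ll_sep, tolerance = 1e-9)

  # masking one individual entirely adds exactly zero log-likelihood
  tab2 <- tab
  tab2$geno[, 1] <- NA_integer_
  ll_masked <- hmm_loglik(sim$ids, tab2, phases, c(0.1, 0.2))
  tab3 <- marker_table(tab$individuals[-1],
                       tab$info, tab$geno[, -1, drop = FALSE])
  ll_dropped <- hmm_loglik(sim$ids, tab3, phases, c(0.1, 0.2))
  expect_equal(ll_masked, ll_dropped, tolerance = 1e-9)
})

test_that("EM recovers interval recombination fractions", {
  # two D1 markers at rf 0.10, large n
  set.seed(93)
  n <- 1e4
  r <- 0.10
  a1 <- rbinom(n, 1, 0.5)
  a2 <- bitwXor(a1, rbinom(n, 1, r))
  info <- data.frame(marker_id = c("A", "B"), system = "AFLP",
                     parent1 = "present", parent2 = "absent")
  tab <- marker_table(sprintf("I%05d", 1:n), info,
                      rbind(as.integer(a1), as.integer(a2)))
  fit <- em_rfs(c("A", "B"), tab,
                list(phase_p1 = c(1L, 1L), phase_p2 = c(NA, NA)))
  expect_lt(abs(fit$rfs - r), 0.01)

  # a perfectly co-segregating pair collapses to rf ~ 0
  tab0 <- marker_table(sprintf("I%05d", 1:n), info,
                       rbind(as.integer(a1), as.integer(a1)))
  fit0 <- em_rfs(c("A", "B"), tab0,
                 list(phase_p1 = c(1L, 1L), phase_p2 = c(NA, NA)))
  expect_lt(fit0$rfs, 1e-3)
})

test_that("EM matches a 2-D grid oracle on a 3-marker chain", {
  sim <- sim_chromosome(n = 150, pos = c(0, 8, 20),
                        cross = c("D1", "C", "D2"), seed = 94,
                        shuffle = FALSE)
  idx <- match(sim$ids, sim$table$info$marker_id)
  g <- sim$table$geno[idx, ]
  phases <- list(phase_p1 = c(1L, 1L, NA), phase_p2 = c(NA, 1L, 1L))
  fit <- em_rfs(sim$ids, sim$table, phases,
                config = ordering_config(em_tol = 1e-9, em_maxit = 2000))
  # oracle: coarse grid then local refinement around the best cell
  grid <- seq(0.005, 0.30, by = 0.005)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (r1 in grid) for (r2 in grid) {
    ll <- oracle_chain3_loglik(g, c("D1", "C", "D2"),
                               phases$phase_p1, phases$phase_p2, r1, r2)
    if (ll > best_ll) { best_ll <- ll; best <- c(r1, r2) }
  }
  fine1 <- seq(best[1] - 0.005, best[1] + 0.005, by = 5e-4)
  fine2 <- seq(best[2] - 0.005, best[2] + 0.005, by = 5e-4)
  for (r1 in fine1) for (r2 in fine2) {
    ll <- oracle_chain3_loglik(g, c("D1", "C", "D2"),
                               phases$phase_p1, phases$phase_p2, r1, r2)
    if (ll > best_ll) { best_ll <- ll; best <- c(r1, r2) }
  }
  expect_lt(max(abs(fit$rfs - best)), 1e-3)
  expect_gte(fit$loglik, best_ll - 1e-6)
})

test_that("EM log-likelihood is monotone over iterations", {
  sim <- sim_chromosome(n = 120, pos = c(0, 10, 25, 30),
                        cross = c("D1", "D1", "C", "D2"), seed = 95,
                        shuffle = FALSE)
  phases <- list(phase_p1 = c(1L, 1L, 1L, NA),
                 phase_p2 = c(NA, NA, 1L, 1L))
  lls <- vapply(1:12, function(it) {
    suppressWarnings(em_rfs(sim$ids, sim$table, phases,
                            r_init = rep(0.4, 3),
                            config = ordering_config(em_tol = 1e-12,
                                                     em_maxit = it))$loglik)
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
})

test_that("exhaustive ordering recovers a 3-marker chain", {
  hits <- 0L
  for (k in 1:30) {
    sim <- sim_chromosome(n = 188, pos = c(0, 10, 20),
                          cross = c("D1", "D1", "D1"), seed = 9500 + k)
    f <- filter_sdm(sim$table)
    pr <- all_pairs(f, sim$table)
    ocg <- compare_orders(sim$ids, sim$table, pr)
    got <- match(ocg$markers, sim$ids)
    if (identical(got, 1:3) || identical(got, 3:1)) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.95)
})

test_that("reversing an order leaves the likelihood unchanged", {
  sim <- sim_chromosome(n = 150, pos = c(0, 10, 18, 30),
                        cross = c("D1", "C", "D2", "D1"), seed = 96,
                        shuffle = FALSE)
  f <- filter_sdm(sim$table)
  pr <- all_pairs(f, sim$table)
  prep <- sdmap:::prepare_cg(sim$ids, sim$table, pr)
  cfg <- ordering_config()
  f1 <- sdmap:::eval_order(prep, 1:4, cfg, em = TRUE, final = TRUE)
  f2 <- sdmap:::eval_order(prep, 4:1, cfg, em = TRUE, final = TRUE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$rfs, rev(f2$rfs), tolerance = 1e-4)
})

test_that("sequential insertion orders collinear markers", {
  sim <- sim_chromosome(n = 188, pos = seq(0, 60, by = 10),
                        cross = rep("D1", 7), seed = 97)
  f <- filter_sdm(sim$table)
  pr <- all_pairs(f, sim$table)
  ocg <- order_seq(sim$ids, sim$table, pr)
  expect_setequal(ocg$markers, sim$ids)
  expect_equal(length(ocg$markers), length(unique(ocg$markers)))
  got <- match(ocg$markers, sim$ids)
  if (got[1] > got[length(got)]) got <- rev(got)
  expect_identical(got, seq_along(sim$ids))
})

test_that("small groups go through exhaustive search automatically", {
  sim <- sim_chromosome(n = 100, pos = c(0, 12, 24),
                        cross = c("D1", "D1", "D1"), seed = 98)
  f <- filter_sdm(sim$table)
  pr <- all_pairs(f, sim$table)
  expect_error(compare_orders(sim$ids, sim$table, pr,
                              ordering_config(exhaustive_max = 2)),
               "order_seq")
  ocg <- order_seq(sim$ids, sim$table, pr)  # delegates to compare_orders
  expect_equal(length(ocg$markers), 3)
})

test_that("ripple fixes a local swap and never lowers the likelihood", {
  sim <- sim_chromosome(n = 188, pos = seq(0, 50, by = 10),
                        cross = rep("D1", 6), seed = 99, shuffle = FALSE)
  f <- filter_sdm(sim$table)
  pr <- all_pairs(f, sim$table)
  prep <- sdmap:::prepare_cg(sim$ids, sim$table, pr)
  cfg <- ordering_config()
  true_fit <- sdmap:::finalize_cg(prep, 1:6, cfg, "true")
  # perturb: swap two adjacent markers
  swapped <- sdmap:::finalize_cg(prep, c(1, 3, 2, 4, 5, 6), cfg, "swapped")
  rippled <- ripple(swapped, sim$table, pr)
  expect_gte(rippled$loglik, swapped$loglik - 1e-9)
  got <- match(rippled$markers, sim$ids)
  if (got[1] > got[length(got)]) got <- rev(got)
  expect_identical(got, 1:6)
  # an already-optimal order is left alone
  again <- ripple(true_fit, sim$table, pr)
  expect_identical(again$markers, true_fit$markers)
})

test_that("ordered groups derive positions strictly from the rfs", {
  sim <- sim_chromosome(n = 100, pos = c(0, 15, 30),
                        cross = rep("D1", 3), seed = 100)
  f <- filter_sdm(sim$table)
  pr <- all_pairs(f, sim$table)
  ocg <- compare_orders(sim$ids, sim$table, pr)
  expect_equal(ocg$positions, c(0, cumsum(kosambi(ocg$rfs))))
  expect_equal(ocg$length_cM, max(ocg$positions))
})
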