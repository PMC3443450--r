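mk_cg <- function(name, markers, len = 50) {
  m <- length(markers)
  rfs <- if (m > 1) rep(kosambi_inv(len / max(m - 1, 1)), m - 1) else numeric(0)
  new_ordered_cg(name, markers, rep("D1", m), rep(1L, m),
                 rep(NA_integer_, m), rfs)
}

test_that("SSR locus codes strip the allele size", {
  expect_equal(ssr_locus_of("ESTB94279", loci = c("ESTB94", "ESTB100")),
               "ESTB94")
  expect_equal(ssr_locus_of("CV22140", loci = "CV22"), "CV22")
  # without a declared locus list the maximal trailing integer is the size
  expect_equal(ssr_locus_of("CV22140"), "CV")
  expect_error(ssr_locus_of("E35M47510"), "not an EST-SSR")
  expect_error(ssr_locus_of("E35M47510", loci = "ESTB94"), "not an EST-SSR")
})

test_that("CGs sharing two loci form a core group, one locus is putative", {
  cgs <- list(
    A = mk_cg("A", c("ESTB94279", "ESTB100240", "x1"), len = 80),
    B = mk_cg("B", c("ESTB94261", "ESTB100255", "x2"), len = 60),
    C = mk_cg("C", c("ESTB94250", "x3"), len = 40),
    D = mk_cg("D", c("x4", "x5"), len = 30))
  loci <- c(ESTB94279 = "ESTB94", ESTB100240 = "ESTB100",
            ESTB94261 = "ESTB94", ESTB100255 = "ESTB100",
            ESTB94250 = "ESTB94")
  hg <- assemble_hgs(cgs, loci, min_shared = 2)
  tab <- hg$table
  expect_equal(tab$hg[tab$cg == "A"], "I")
  expect_equal(tab$status[tab$cg == "A"], "core")
  expect_equal(tab$status[tab$cg == "B"], "core")
  expect_equal(tab$hg[tab$cg == "C"], "I")
  expect_equal(tab$status[tab$cg == "C"], "putative")
  expect_equal(tab$hg[tab$cg == "D"], "U")
  # within-HG naming by length descending; leftovers are U-k
  expect_equal(tab$new_name[tab$cg == "A"], "I-1")
  expect_equal(tab$new_name[tab$cg == "B"], "I-2")
  expect_equal(tab$new_name[tab$cg == "D"], "U-1")
  # every CG appears exactly once
  expect_setequal(tab$cg, names(cgs))
  expect_equal(anyDuplicated(tab$cg), 0L)
})

test_that("a duplicated locus within one CG is not homeology evidence", {
  cgs <- list(
    A = mk_cg("A", c("CV01100", "CV01120", "CV02100")),
    B = mk_cg("B", c("x1", "x2")))
  loci <- c(CV01100 = "CV01", CV01120 = "CV01", CV02100 = "CV02")
  hg <- assemble_hgs(cgs, loci)
  expect_true(all(hg$table$hg == "U"))
  expect_length(hg$evidence, 0)
})

test_that("raising min_shared never merges homeology groups", {
  cgs <- list(
    A = mk_cg("A", c("CV01100", "CV02100", "CV03100")),
    B = mk_cg("B", c("CV01110", "CV02110", "x1")),
    C = mk_cg("C", c("CV03120", "CV04100", "x2")),
    D = mk_cg("D", c("CV03130", "CV04110", "x3")))
  loci <- setNames(substr(grep("^CV", unlist(lapply(cgs, `[[`, "markers")),
                               value = TRUE), 1, 4),
                   grep("^CV", unlist(lapply(cgs, `[[`, "markers")),
                        value = TRUE))
  lo <- assemble_hgs(cgs, loci, min_shared = 1)
  hi <- assemble_hgs(cgs, loci, min_shared = 2)
  hg_of <- function(x) setNames(x$table$hg, x$table$cg)
  lo_hg <- hg_of(lo)
  hi_hg <- hg_of(hi)
  # at min_shared = 1 the single CV03 link chains everything into one HG;
  # at 2 it splits into {A, B} and {C, D}
  expect_equal(length(unique(lo_hg)), 1)
  expect_equal(hi_hg[["A"]], hi_hg[["B"]])
  expect_equal(hi_hg[["C"]], hi_hg[["D"]])
  expect_true(hi_hg[["A"]] != hi_hg[["C"]])
  # any pair split at min_shared = 1 must remain split at 2
  for (p in combn(names(cgs), 2, simplify = FALSE)) {
    if (lo_hg[p[1]] != lo_hg[p[2]] || lo_hg[p[1]] == "U") {
      expect_true(hi_hg[p[1]] != hi_hg[p[2]] || hi_hg[p[1]] == "U")
    }
  }
})

test_that("HGs are numbered by size and cores merge transitively", {
  cgs <- list(
    A = mk_cg("A", c("CV01100", "CV02100")),
    B = mk_cg("B", c("CV01110", "CV02110")),
    C = mk_cg("C", c("CV02120", "CV03100")),  # chains A-B to C via >= 2
    X = mk_cg("X", sprintf("x%d", 1:6)),
    Y = mk_cg("Y", c("CV09100", "CV08100")),
    Z = mk_cg("Z", c("CV09110", "CV08110")))
  ids <- grep("^CV", unlist(lapply(cgs, `[[`, "markers")), value = TRUE)
  loci <- setNames(substr(ids, 1, 4), ids)
  # C shares CV02 with A and B but only one locus with each -> putative;
  # make it core with B through a second shared locus
  cgs$C <- mk_cg("C", c("CV02120", "CV01120"))
  ids <- grep("^CV", unlist(lapply(cgs, `[[`, "markers")), value = TRUE)
  loci <- setNames(substr(ids, 1, 4), ids)
  hg <- assemble_hgs(cgs, loci)
  tab <- hg$table
  # A, B, C form the largest HG (6 markers) -> "I"; Y, Z -> "II"
  expect_equal(unique(tab$hg[tab$cg %in% c("A", "B", "C")]), "I")
  expect_equal(unique(tab$hg[tab$cg %in% c("Y", "Z")]), "II")
  expect_equal(tab$hg[tab$cg == "X"], "U")
})

test_that("simulated homeology groups are recovered end to end", {
  cfg <- sim_config(n_individuals = 150, n_chromosomes = 4,
                    chr_length_cM = 60,
                    marker_counts = matrix(c(8, 8, 4, 10, 10, 6, 0, 0, 0),
                                           3, byrow = TRUE),
                    te_clusters = list(n_clusters = 0,
                                       markers_per_cluster = 0,
                                       spacing_cM = 1),
                    n_hgs = 2, ssr_pool_size = 3,
                    missing_rate = 0, error_rate = 0, seed = 111)
  sim <- simulate_population(cfg)
  truth <- as.data.frame(sim$truth)
  cgs <- list()
  for (chr in unique(truth$chrom)) {
    p <- truth[truth$chrom == chr, ]
    cgs[[paste0("chr", chr)]] <- new_ordered_cg(
      paste0("chr", chr), p$marker_id, p$cross_type, p$phase_p1,
      p$phase_p2,
      if (nrow(p) > 1) kosambi_inv(diff(p$position_cM)) else numeric(0))
  }
  ssr <- truth$system == "EST_SSR"
  loci <- setNames(truth$locus[ssr], truth$marker_id[ssr])
  hg <- assemble_hgs(cgs, loci)
  # chromosomes 1/3 and 2/4 share locus pools (cycled into 2 groups)
  hg_of <- setNames(hg$table$hg, hg$table$cg)
  expect_equal(hg_of[["chr1"]], hg_of[["chr3"]])
  expect_equal(hg_of[["chr2"]], hg_of[["chr4"]])
  expect_true(hg_of[["chr1"]] != hg_of[["chr2"]])
})
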