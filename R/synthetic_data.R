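#' Simulation configuration for an outcrossed F1 population
#'
#' Defaults emulate the study conditions the package is validated against:
#' 188 F1 individuals from a single biparental cross, 730 single-dose
#' markers in the observed system-by-cross-type proportions (AFLP / EST-SSR /
#' retrotransposon fingerprint), spread over many short chromosomes so that
#' co-segregation groups have the handful-to-tens of markers seen in
#' polyploid maps, and a clustered placement of the retrotransposon markers.
#'
#' @param n_individuals F1 population size.
#' @param n_chromosomes number of chromosomes (one per parental homolog pair
#'   under the single-dose, bivalent-pairing model).
#' @param chr_length_cM genetic length(s) in cM, recycled over chromosomes.
#'   Both parental meioses share one length (integrated-map convention).
#' @param marker_counts 3 x 3 integer matrix of marker numbers, rows
#'   `AFLP`, `EST_SSR`, `RT`, columns `D1`, `D2`, `C`.
#' @param te_clusters list with `n_clusters`, `markers_per_cluster` and
#'   `spacing_cM` (within-cluster adjacent gaps are drawn strictly below
#'   this value) controlling clustered placement of RT markers.
#' @param n_hgs number of homo(eo)logy groups the chromosomes are cycled
#'   into; EST-SSR markers on chromosomes of the same group share locus
#'   codes, which is what lets [assemble_hgs()] recover the groups.  `0`
#'   gives every SSR marker its own locus.
#' @param ssr_pool_size number of distinct SSR locus codes per homeology
#'   group.
#' @param missing_rate per-call probability that a progeny score is masked
#'   to missing.
#' @param error_rate per-call probability that a progeny score is flipped.
#' @param distortion optional data frame (`marker_id`, `bias`) of markers
#'   whose band-transmission probability is forced to `bias` instead of the
#'   Mendelian expectation (generated unlinked; used to exercise the
#'   segregation filter).
#' @param seed integer seed; identical seeds give identical simulations.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 188,
                       n_chromosomes = 46,
                       chr_length_cM = 105,
                       marker_counts = default_marker_counts(),
                       te_clusters = list(n_clusters = 6,
                                          markers_per_cluster = 3,
                                          spacing_cM = 2),
                       n_hgs = 7,
                       ssr_pool_size = 4,
                       missing_rate = 0.03,
                       error_rate = 0.01,
                       distortion = NULL,
                       seed = NULL) {
  stopifnot(is_count(n_individuals), n_individuals >= 2,
            is_count(n_chromosomes), n_chromosomes >= 1,
            is_prob(missing_rate), is_prob(error_rate),
            is_count(n_hgs), is_count(ssr_pool_size), ssr_pool_size >= 1)
  chr_length_cM <- rep_len(as.numeric(chr_length_cM), n_chromosomes)
  if (any(chr_length_cM < 0)) stop_("chromosome lengths must be >= 0")
  marker_counts <- as.matrix(marker_counts)
  if (!identical(dim(marker_counts), c(3L, 3L)))
    stop_("marker_counts must be a 3 x 3 matrix (systems x cross types)")
  dimnames(marker_counts) <- list(c("AFLP", "EST_SSR", "RT"),
                                  c("D1", "D2", "C"))
  if (any(marker_counts < 0) || any(marker_counts != floor(marker_counts)))
    stop_("marker_counts must be non-negative integers")
  tc <- te_clusters
  stopifnot(is_count(tc$n_clusters),
            is_count(tc$markers_per_cluster),
            is.numeric(tc$spacing_cM), tc$spacing_cM > 0)
  if (tc$n_clusters * tc$markers_per_cluster > sum(marker_counts["RT", ]))
    stop_("TE cluster settings ask for more clustered markers than RT markers exist")
  if (!is.null(distortion)) {
    distortion <- as.data.frame(distortion)
    stopifnot(all(c("marker_id", "bias") %in% names(distortion)),
              all(distortion$bias >= 0 & distortion$bias <= 1))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_chromosomes = as.integer(n_chromosomes),
                 chr_length_cM = chr_length_cM,
                 marker_counts = marker_counts,
                 te_clusters = tc,
                 n_hgs = as.integer(n_hgs),
                 ssr_pool_size = as.integer(ssr_pool_size),
                 missing_rate = missing_rate,
                 error_rate = error_rate,
                 distortion = distortion,
                 seed = seed),
            class = "sim_config")
}

#' Marker numbers per system and cross type used by default
#'
#' The default single-dose marker counts: 197/192/146 AFLP, 41/60/29
#' EST-SSR and 23/32/10 retrotransposon-fingerprint markers for cross types
#' D1/D2/C (730 markers in total).
#'
#' @return A 3 x 3 integer matrix.
#' @export
default_marker_counts <- function() {
  matrix(c(197L, 192L, 146L,
           41L, 60L, 29L,
           23L, 32L, 10L),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("AFLP", "EST_SSR", "RT"), c("D1", "D2", "C")))
}

#' Place retrotransposon markers on the simulated genome
#'
#' In `"clustered"` mode, `n_clusters` clusters of `markers_per_cluster`
#' markers are dropped at uniform positions with every within-cluster
#' adjacent gap drawn strictly below `spacing_cM`; remaining RT markers are
#' placed i.i.d. uniform.  In `"null"` mode all RT markers are uniform --
#' the null hypothesis of the Poisson clustering test.
#'
#' @param config a [sim_config()]; its seed (if any) is applied.
#' @param mode `"clustered"` or `"null"`; defaults to clustered unless the
#'   configured number of clusters is zero.
#' @return Data frame with columns `chrom`, `position_cM`, `cluster`
#'   (cluster index or `NA`).
#' @export
place_te_markers <- function(config, mode = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  .place_te(config, mode)
}

.place_te <- function(config, mode = NULL) {
  tc <- config$te_clusters
  n_rt <- sum(config$marker_counts["RT", ])
  if (is.null(mode)) mode <- if (tc$n_clusters > 0) "clustered" else "null"
  mode <- match.arg(mode, c("clustered", "null"))
  L <- config$chr_length_cM
  out <- data.frame(chrom = integer(0), position_cM = numeric(0),
                    cluster = integer(0))
  n_clustered <- 0L
  if (mode == "clustered" && tc$n_clusters > 0) {
    k <- tc$markers_per_cluster
    span_max <- tc$spacing_cM * (k - 1)
    eligible <- which(L > span_max)
    if (length(eligible) == 0)
      stop_("cluster span exceeds every chromosome length")
    for (cl in seq_len(tc$n_clusters)) {
      chrom <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      start <- runif(1, 0, L[chrom] - span_max)
      gaps <- runif(k - 1, 0, tc$spacing_cM)
      pos <- start + cumsum(c(0, gaps))
      out <- rbind(out, data.frame(chrom = chrom, position_cM = pos,
                                   cluster = cl))
    }
    n_clustered <- tc$n_clusters * k
  }
  n_free <- n_rt - n_clustered
  if (n_free > 0) {
    chrom <- sample.int(config$n_chromosomes, n_free, replace = TRUE,
                        prob = pmax(L, 1e-12))
    out <- rbind(out, data.frame(chrom = chrom,
                                 position_cM = runif(n_free) * L[chrom],
                                 cluster = NA_integer_))
  }
  out[order(out$chrom, out$position_cM), , drop = FALSE]
}

rt_codes <- function() {
  as.vector(outer(c("AI", "DI", "SI", "RI"),
                  c("sIvSI", "sIvGR", "sIvLI", "sIvLII"), paste0))
}

# assign unique fragment sizes within each code so marker ids never collide
name_markers <- function(codes, lo, hi) {
  sizes <- integer(length(codes))
  for (code in unique(codes)) {
    idx <- which(codes == code)
    sizes[idx] <- sort(sample(seq(lo, hi), length(idx)))
  }
  paste0(codes, sizes)
}

#' Simulate an F1 outcross population of single-dose markers
#'
#' Each individual receives, per chromosome, one gamete from each parent.
#' A gamete is a two-homolog meiosis with crossovers as a no-interference
#' (Poisson, rate 1 per 100 cM) process, realized at the marker positions
#' as the equivalent Markov switch chain (switch probability between
#' adjacent markers = Haldane recombination fraction of the gap).  Band
#' presence follows the single-dose model: a D1 marker shows a band iff
#' parent 1 transmits the homolog carrying it, D2 likewise for parent 2,
#' and a C marker iff either parent transmits its band-carrying homolog.
#' Genotyping error then flips each call with probability `error_rate` and
#' missingness masks it with probability `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `table` (a [marker_table()]; row order is
#'   randomized so the truth does not leak into the input) and `truth` (a
#'   `true_map`: per-chromosome placements with phases plus the transmitted
#'   parental homolog -- the gamete truth -- for every individual).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$n_individuals
  L <- config$chr_length_cM
  mc <- config$marker_counts

  # --- placements ------------------------------------------------------
  te <- .place_te(config)
  n_rt <- sum(mc["RT", ])
  plc <- list()
  for (sys in c("AFLP", "EST_SSR")) {
    n <- sum(mc[sys, ])
    if (n == 0) next
    chrom <- sample.int(config$n_chromosomes, n, replace = TRUE,
                        prob = pmax(L, 1e-12))
    plc[[sys]] <- data.frame(chrom = chrom, position_cM = runif(n) * L[chrom],
                             cluster = NA_integer_, system = sys)
  }
  if (n_rt > 0) {
    te$system <- "RT"
    plc[["RT"]] <- te
  }
  plc <- do.call(rbind, plc)

  # cross types within each system, in random placement order
  ct <- character(nrow(plc))
  for (sys in rownames(mc)) {
    idx <- which(plc$system == sys)
    idx <- idx[sample.int(length(idx))]
    ct[idx] <- rep(colnames(mc), times = mc[sys, ])
  }
  plc$cross_type <- ct
  plc$phase_p1 <- ifelse(plc$cross_type %in% c("D1", "C"),
                         sample(0:1, nrow(plc), replace = TRUE), NA_integer_)
  plc$phase_p2 <- ifelse(plc$cross_type %in% c("D2", "C"),
                         sample(0:1, nrow(plc), replace = TRUE), NA_integer_)

  # --- names and SSR locus codes --------------------------------------
  plc$locus <- NA_character_
  aflp_idx <- which(plc$system == "AFLP")
  if (length(aflp_idx)) {
    combos <- sprintf("E%dM%d", 32:53, 47:68)
    codes <- rep_len(combos, length(aflp_idx))
    plc$locus[aflp_idx] <- NA
    plc$marker_id <- NA_character_
    plc$marker_id[aflp_idx] <- name_markers(codes, 60, 700)
  } else {
    plc$marker_id <- NA_character_
  }
  ssr_idx <- which(plc$system == "EST_SSR")
  if (length(ssr_idx)) {
    if (config$n_hgs > 0) {
      hg_of_chrom <- rep_len(seq_len(config$n_hgs), config$n_chromosomes)
      n_loci <- config$n_hgs * config$ssr_pool_size
      locus_codes <- sprintf("CV%03d", seq_len(n_loci))
      pools <- split(locus_codes,
                     rep(seq_len(config$n_hgs), each = config$ssr_pool_size))
      hg <- hg_of_chrom[plc$chrom[ssr_idx]]
      plc$locus[ssr_idx] <- vapply(hg, function(h) {
        p <- pools[[h]]
        if (length(p) == 1) p else sample(p, 1)
      }, character(1))
    } else {
      plc$locus[ssr_idx] <- sprintf("CV%03d", seq_along(ssr_idx))
    }
    plc$marker_id[ssr_idx] <- name_markers(plc$locus[ssr_idx], 80, 400)
  }
  rt_idx <- which(plc$system == "RT")
  if (length(rt_idx)) {
    codes <- rep_len(rt_codes()[1:6], length(rt_idx))
    plc$marker_id[rt_idx] <- name_markers(codes, 100, 999)
  }

  # --- meiosis and band calls -----------------------------------------
  plc <- plc[order(plc$chrom, plc$position_cM), , drop = FALSE]
  rownames(plc) <- NULL
  geno <- matrix(NA_integer_, nrow(plc), N)
  gametes <- vector("list", config$n_chromosomes)
  for (chr in seq_len(config$n_chromosomes)) {
    idx <- which(plc$chrom == chr)
    if (length(idx) == 0) next
    pos <- plc$position_cM[idx]
    d <- diff(pos)
    theta <- 0.5 * (1 - exp(-2 * d / 100))  # Haldane, no interference
    a <- sim_gamete(N, theta)
    b <- sim_gamete(N, theta)
    dimnames(a) <- dimnames(b) <- list(NULL, plc$marker_id[idx])
    gametes[[chr]] <- list(a = a, b = b)
    for (j in seq_along(idx)) {
      i <- idx[j]
      band <- switch(plc$cross_type[i],
                     D1 = as.integer(a[, j] == plc$phase_p1[i]),
                     D2 = as.integer(b[, j] == plc$phase_p2[i]),
                     C = as.integer(a[, j] == plc$phase_p1[i] |
                                      b[, j] == plc$phase_p2[i]))
      geno[i, ] <- band
    }
  }

  # forced transmission bias: distorted markers are generated unlinked
  if (!is.null(config$distortion)) {
    for (k in seq_len(nrow(config$distortion))) {
      i <- match(config$distortion$marker_id[k], plc$marker_id)
      if (is.na(i)) stop_("distortion names unknown marker '",
                          config$distortion$marker_id[k], "'")
      geno[i, ] <- rbinom(N, 1, config$distortion$bias[k])
    }
  }

  if (config$error_rate > 0) {
    flip <- matrix(runif(length(geno)) < config$error_rate, nrow(geno))
    geno[flip] <- 1L - geno[flip]
  }
  if (config$missing_rate > 0) {
    geno[matrix(runif(length(geno)) < config$missing_rate, nrow(geno))] <-
      NA_integer_
  }

  info <- data.frame(
    marker_id = plc$marker_id,
    system = plc$system,
    parent1 = ifelse(plc$cross_type %in% c("D1", "C"), "present", "absent"),
    parent2 = ifelse(plc$cross_type %in% c("D2", "C"), "present", "absent"),
    stringsAsFactors = FALSE
  )
  individuals <- sprintf("F1_%03d", seq_len(N))

  # randomize row order so downstream stages cannot read the truth off it
  ord <- sample.int(nrow(plc))
  tab <- marker_table(individuals, info[ord, , drop = FALSE],
                      geno[ord, , drop = FALSE])

  chromosomes <- lapply(seq_len(config$n_chromosomes), function(chr) {
    p <- plc[plc$chrom == chr,
             c("marker_id", "position_cM", "cross_type", "system",
               "phase_p1", "phase_p2", "locus", "cluster")]
    rownames(p) <- NULL
    list(length_cM = L[chr], placements = p)
  })
  truth <- structure(list(chromosomes = chromosomes, gametes = gametes,
                          config = config),
                     class = "true_map")
  list(table = tab, truth = truth)
}

# transmitted-homolog indicator at each marker: Markov chain equivalent to
# thinning the crossover point process at the marker positions
sim_gamete <- function(N, theta) {
  m <- length(theta) + 1L
  h <- matrix(0L, N, m)
  h[, 1] <- rbinom(N, 1, 0.5)
  for (j in seq_along(theta)) {
    sw <- rbinom(N, 1, theta[j])
    h[, j + 1] <- bitwXor(h[, j], sw)
  }
  h
}

#' @export
print.true_map <- function(x, ...) {
  n <- vapply(x$chromosomes, function(ch) nrow(ch$placements), integer(1))
  cat("true_map:", length(x$chromosomes), "chromosomes,", sum(n),
      "markers, total", sum(vapply(x$chromosomes, `[[`, numeric(1),
                                   "length_cM")), "cM\n")
  invisible(x)
}

#' Flatten a simulation truth to a data frame
#'
#' @param x a `true_map`.
#' @param ... unused.
#' @return Data frame of placements with a `chrom` column.
#' @export
as.data.frame.true_map <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$chromosomes), function(chr) {
    p <- x$chromosomes[[chr]]$placements
    if (nrow(p) == 0) return(NULL)
    cbind(chrom = chr, p)
  }))
}

#' Configuration for simulated retrotransposon fingerprint profiles
#'
#' @param true_copy_number genomic copy number of the target element.
#' @param n_combinations number of restriction-enzyme x primer combinations
#'   fingerprinted.
#' @param detection_prob probability that a combination detects a given
#'   copy as a scorable band.
#' @param polymorphism_rate probability that a detected copy is absent from
#'   one given parent is `polymorphism_rate / 2` (each parent
#'   independently).
#' @param seed integer seed.
#' @return A validated list of class `nbs_config`.
#' @export
nbs_config <- function(true_copy_number = 60, n_combinations = 6,
                       detection_prob = 1, polymorphism_rate = 0,
                       seed = NULL) {
  stopifnot(is_count(true_copy_number), true_copy_number >= 1,
            is_count(n_combinations), n_combinations >= 1,
            is_prob(detection_prob), detection_prob > 0,
            is_prob(polymorphism_rate))
  structure(list(true_copy_number = as.integer(true_copy_number),
                 n_combinations = as.integer(n_combinations),
                 detection_prob = detection_prob,
                 polymorphism_rate = polymorphism_rate,
                 seed = seed),
            class = "nbs_config")
}

#' Simulate per-combination fingerprint band counts
#'
#' Each enzyme-primer combination detects each of the `true_copy_number`
#' element copies independently with probability `detection_prob`; a
#' detected copy is then absent from a given parent with probability
#' `polymorphism_rate / 2` (independently per parent).
#'
#' @param config an [nbs_config()].
#' @return List with `band_counts` (per combination), `parent1_counts`,
#'   `parent2_counts`, and their totals.
#' @export
simulate_nbs_profiles <- function(config) {
  stopifnot(inherits(config, "nbs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$n_combinations
  C <- config$true_copy_number
  q <- config$polymorphism_rate / 2
  band <- p1 <- p2 <- integer(k)
  for (j in seq_len(k)) {
    det <- runif(C) < config$detection_prob
    band[j] <- sum(det)
    p1[j] <- sum(det & runif(C) >= q)
    p2[j] <- sum(det & runif(C) >= q)
  }
  list(band_counts = band, parent1_counts = p1, parent2_counts = p2,
       total_fragments = sum(band),
       total_parent1 = sum(p1), total_parent2 = sum(p2))
}

#' Build the exact linkage map implied by a simulation truth
#'
#' Turns a `true_map` into a [linkage_map()] whose co-segregation groups
#' are the simulated chromosomes at their true positions and phases.
#' Useful for testing map-level statistics in isolation from estimation.
#'
#' @param truth a `true_map` from [simulate_population()].
#' @return A [linkage_map()].
#' @export
map_from_truth <- function(truth) {
  stopifnot(inherits(truth, "true_map"))
  cgs <- list()
  k <- 0
  for (chr in seq_along(truth$chromosomes)) {
    p <- truth$chromosomes[[chr]]$placements
    if (nrow(p) < 1) next
    k <- k + 1
    pos <- p$position_cM - p$position_cM[1]
    rfs <- if (nrow(p) > 1) kosambi_inv(diff(pos)) else numeric(0)
    cgs[[sprintf("CG%02d", k)]] <- new_ordered_cg(
      name = sprintf("CG%02d", k),
      markers = p$marker_id,
      cross_type = p$cross_type,
      phase_p1 = p$phase_p1,
      phase_p2 = p$phase_p2,
      rfs = rfs,
      loglik = NA_real_)
  }
  sys <- as.data.frame(truth)
  linkage_map(cgs, info = data.frame(marker_id = sys$marker_id,
                                     system = sys$system,
                                     cross_type = sys$cross_type))
}
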