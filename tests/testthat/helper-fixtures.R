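# Shared fixture builders: everything is generated in code at test time.

# tiny hand-built marker table
toy_table <- function() {
  info <- data.frame(
    marker_id = c("E35M47510", "ESTB94279", "DIsIvLI385"),
    system = c("AFLP", "EST_SSR", "RT"),
    parent1 = c("present", "present", "absent"),
    parent2 = c("absent", "present", "present")
  )
  geno <- rbind(c(1L, 0L, 1L, NA),
                c(1L, 1L, 0L, 1L),
                c(0L, 1L, 1L, 1L))
  marker_table(c("I1", "I2", "I3", "I4"), info, geno)
}

# simulate one chromosome directly at given marker positions/types; no
# genotyping error, returns the table plus the true layout
sim_chromosome <- function(n = 188, pos, cross, system = NULL, seed = 1,
                           shuffle = TRUE) {
  set.seed(seed)
  m <- length(pos)
  system <- system %||% rep("AFLP", m)
  theta <- if (m > 1) 0.5 * (1 - exp(-2 * diff(pos) / 100)) else numeric(0)
  a <- sdmap:::sim_gamete(n, theta)
  b <- sdmap:::sim_gamete(n, theta)
  p1 <- ifelse(cross %in% c("D1", "C"), 1L, NA_integer_)
  p2 <- ifelse(cross %in% c("D2", "C"), 1L, NA_integer_)
  geno <- matrix(NA_integer_, m, n)
  for (j in seq_len(m)) {
    geno[j, ] <- switch(cross[j],
                        D1 = as.integer(a[, j] == p1[j]),
                        D2 = as.integer(b[, j] == p2[j]),
                        C = as.integer(a[, j] == p1[j] | b[, j] == p2[j]))
  }
  ids <- sprintf("M%02d", seq_len(m))
  info <- data.frame(
    marker_id = ids, system = system,
    parent1 = ifelse(cross %in% c("D1", "C"), "present", "absent"),
    parent2 = ifelse(cross %in% c("D2", "C"), "present", "absent"))
  ord <- if (shuffle) sample(m) else seq_len(m)
  tab <- marker_table(sprintf("I%03d", seq_len(n)), info[ord, , drop = FALSE],
                      geno[ord, , drop = FALSE])
  list(table = tab, ids = ids, pos = pos, cross = cross,
       gametes = list(a = a, b = b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default-shaped simulation config for pipeline-level tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_individuals = 150, n_chromosomes = 4, chr_length_cM = 70,
             marker_counts = matrix(c(8, 8, 5, 3, 3, 2, 2, 2, 1),
                                    nrow = 3, byrow = TRUE),
             te_clusters = list(n_clusters = 1, markers_per_cluster = 3,
                                spacing_cM = 2),
             n_hgs = 2, ssr_pool_size = 3,
             missing_rate = 0.02, error_rate = 0.005, seed = seed, ...)
}

# a linkage map built directly from given positions (one or more CGs)
map_from_positions <- function(cg_positions, systems = NULL,
                               cross = NULL) {
  cgs <- list()
  info <- list()
  for (k in seq_along(cg_positions)) {
    pos <- cg_positions[[k]]
    nm <- sprintf("CG%02d", k)
    ids <- sprintf("%s_M%02d", nm, seq_along(pos))
    sys <- if (is.null(systems)) rep("AFLP", length(pos)) else systems[[k]]
    ct <- if (is.null(cross)) rep("D1", length(pos)) else cross[[k]]
    rfs <- if (length(pos) > 1) kosambi_inv(diff(pos)) else numeric(0)
    cgs[[nm]] <- new_ordered_cg(nm, ids, ct,
                                phase_p1 = rep(1L, length(pos)),
                                phase_p2 = rep(NA_integer_, length(pos)),
                                rfs = rfs)
    info[[nm]] <- data.frame(marker_id = ids, system = sys, cross_type = ct)
  }
  linkage_map(cgs, do.call(rbind, info))
}
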