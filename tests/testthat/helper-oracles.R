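# Independent oracles used across the suite.

# Brute-force joint band-pattern probabilities: enumerate the four
# transmission states per locus pair (a = parent-1 homolog transmitted,
# b = parent-2 homolog), each parent recombinant with probability r,
# and map transmissions to bands through the single-dose rules.
oracle_joint_probs <- function(pair_class, phase, r) {
  comp <- function(x) if (is.na(x) || x == "coupling") 0L else 1L
  types <- switch(pair_class,
                  D1xD1 = c("D1", "D1"), D2xD2 = c("D2", "D2"),
                  CxC = c("C", "C"), D1xC = c("D1", "C"),
                  D2xC = c("D2", "C"), D1xD2 = c("D1", "D2"))
  # marker 1 carries its band on homolog 1 of each informative parent;
  # marker 2 flips per relative-phase component
  if (pair_class == "CxC") {
    pc <- strsplit(phase, "-", fixed = TRUE)[[1]]
    m2 <- c(1L - comp(pc[1]), 1L - comp(pc[2]))
  } else if (pair_class %in% c("D1xD1", "D1xC")) {
    m2 <- c(1L - comp(phase), 1L)
  } else if (pair_class %in% c("D2xD2", "D2xC")) {
    m2 <- c(1L, 1L - comp(phase))
  } else {
    m2 <- c(1L, 1L)
  }
  band <- function(type, p1, p2, a, b) {
    switch(type,
           D1 = as.integer(a == p1),
           D2 = as.integer(b == p2),
           C = as.integer(a == p1 | b == p2))
  }
  out <- setNames(numeric(4), c("p11", "p10", "p01", "p00"))
  for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
    pr <- 0.25 * (if (a1 == a2) 1 - r else r) * (if (b1 == b2) 1 - r else r)
    y1 <- band(types[1], 1L, 1L, a1, b1)
    y2 <- band(types[2], m2[1], m2[2], a2, b2)
    key <- paste0("p", y1, y2)
    out[key] <- out[key] + pr
  }
  out
}

# grid-search ML recombination fraction for one pair; searches all
# admissible phases unless one is fixed
oracle_rf_grid <- function(pair_class, counts, step = 1e-6, phase = NULL) {
  grid <- seq(0, 0.5, by = step)
  phases <- phase %||% sdmap:::phases_for_class(pair_class)
  best <- list(loglik = -Inf)
  for (ph in phases) {
    p <- sdmap:::pair_probs(pair_class, ph, grid)
    ll <- sdmap:::xlogp(counts[1], p$p11) + sdmap:::xlogp(counts[2], p$p10) +
      sdmap:::xlogp(counts[3], p$p01) + sdmap:::xlogp(counts[4], p$p00)
    k <- which.max(ll)
    if (ll[k] > best$loglik + 1e-12)
      best <- list(rf = grid[k], phase = ph, loglik = ll[k])
  }
  best
}

# independent 3-locus likelihood: direct sum over the 4^3 transmission
# paths, written as explicit base-R matrix products (no scaling, none of
# the package's compiled code)
oracle_chain3_loglik <- function(geno, cross, p1, p2, r1, r2) {
  a_state <- c(0L, 0L, 1L, 1L)
  b_state <- c(0L, 1L, 0L, 1L)
  trans_mat <- function(r) {
    outer(1:4, 1:4, function(s, t)
      ifelse(a_state[s] == a_state[t], 1 - r, r) *
        ifelse(b_state[s] == b_state[t], 1 - r, r))
  }
  emit_mat <- function(j) {
    bandp <- switch(cross[j],
                    D1 = as.numeric(a_state == p1[j]),
                    D2 = as.numeric(b_state == p2[j]),
                    C = as.numeric(a_state == p1[j] | b_state == p2[j]))
    y <- geno[j, ]
    E <- matrix(1, length(y), 4)
    E[which(y == 1L), ] <- matrix(bandp, sum(y == 1L, na.rm = TRUE), 4,
                                  byrow = TRUE)
    E[which(y == 0L), ] <- matrix(1 - bandp, sum(y == 0L, na.rm = TRUE), 4,
                                  byrow = TRUE)
    E
  }
  E1 <- emit_mat(1); E2 <- emit_mat(2); E3 <- emit_mat(3)
  v <- (0.25 * E1) %*% trans_mat(r1)
  v <- (v * E2) %*% trans_mat(r2)
  sum(log(rowSums(v * E3)))
}
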