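#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction to a map distance,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centiMorgans, allowing for positive
#' interference; `kosambi_inv()` inverts it, `r = tanh(d / 50) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return Distances in cM, or recombination fractions.
#' @export
kosambi <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop_("r must be in [0, 0.5) (distance diverges at 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop_("d must be >= 0")
  tanh(d / 50) / 2
}

#' Ordering configuration for multipoint map construction
#'
#' @param exhaustive_max largest group size ordered by exhaustive search
#'   over all orders ([compare_orders()]).
#' @param frame_size size of the seed frame used by [order_seq()].
#' @param ripple_window window size for [ripple()].
#' @param em_tol EM convergence tolerance on the log-likelihood.
#' @param em_maxit maximum EM iterations.
#' @param insertion_lod_threshold log10-likelihood gap below which an
#'   insertion position is considered ambiguous and the marker is force-
#'   placed (flagged) rather than safely ordered.
#' @return List of class `ordering_config`.
#' @export
ordering_config <- function(exhaustive_max = 6, frame_size = 5,
                            ripple_window = 4, em_tol = 1e-6,
                            em_maxit = 200, insertion_lod_threshold = 3) {
  stopifnot(exhaustive_max >= 2, frame_size >= 2, ripple_window >= 2,
            em_tol > 0, em_maxit >= 1, insertion_lod_threshold >= 0)
  structure(list(exhaustive_max = as.integer(exhaustive_max),
                 frame_size = as.integer(frame_size),
                 ripple_window = as.integer(ripple_window),
                 em_tol = em_tol, em_maxit = as.integer(em_maxit),
                 insertion_lod_threshold = insertion_lod_threshold),
            class = "ordering_config")
}

# ---- four-state transmission HMM -------------------------------------
# states are the pair (a, b) of transmitted homologs, a for parent 1 and
# b for parent 2, in the fixed order (0,0), (0,1), (1,0), (1,1); the
# forward and EM kernels live in src/hmm.cpp
STATE_A <- c(0L, 0L, 1L, 1L)
STATE_B <- c(0L, 1L, 0L, 1L)

# deterministic band indicator per state for one marker
band_states <- function(cross_type, phase_p1, phase_p2) {
  switch(cross_type,
         D1 = as.numeric(STATE_A == phase_p1),
         D2 = as.numeric(STATE_B == phase_p2),
         C = as.numeric(STATE_A == phase_p1 | STATE_B == phase_p2),
         stop_("cannot build emissions for cross type '", cross_type, "'"))
}

# m x 4 band-state matrix for an ordered marker set
bs_matrix <- function(cross_type, phase_p1, phase_p2) {
  t(vapply(seq_along(cross_type), function(j)
    band_states(cross_type[j], phase_p1[j], phase_p2[j]), numeric(4)))
}

#' Multipoint log-likelihood of an ordered marker set
#'
#' Forward-algorithm log-likelihood of the observed band patterns under the
#' four-state transmission HMM: the hidden state at each locus is the pair
#' of homologs transmitted by the two parents, transitions between adjacent
#' loci factorize over parents with one shared recombination fraction per
#' interval, the initial distribution is uniform (1/4), and emissions are
#' the deterministic single-dose band rules (missing scores emit 1).
#'
#' @param markers marker ids in map order.
#' @param table a [marker_table()].
#' @param phases list or data frame with `phase_p1`, `phase_p2` (0/1 or
#'   `NA`) per marker, in `markers` order.
#' @param rfs interval recombination fractions, length
#'   `length(markers) - 1`, each in `[0, 0.5]`.
#' @return The total log-likelihood (summed over individuals).
#' @export
hmm_loglik <- function(markers, table, phases, rfs) {
  stopifnot(inherits(table, "marker_table"), length(markers) >= 1,
            length(rfs) == length(markers) - 1L)
  if (length(rfs) && (any(rfs < 0) || any(rfs > 0.5)))
    stop_("rfs must be in [0, 0.5]")
  idx <- match(markers, table$info$marker_id)
  if (anyNA(idx)) stop_("unknown markers: ",
                        paste(markers[is.na(idx)], collapse = ", "))
  cross <- cross_types_of(table)[idx]
  bs <- bs_matrix(cross, phases$phase_p1, phases$phase_p2)
  hmm_forward_cpp(table$geno[idx, , drop = FALSE], bs, rfs)
}

cross_types_of <- function(table) {
  vapply(seq_len(nrow(table$info)), function(i)
    classify_cross_type(table$info$parent1[i],
                        table$info$parent2[i])$cross_type,
    character(1))
}

# Baum-Welch wrapper around the compiled kernel; per-interval M-step pools
# the expected recombination events of both parental meioses
em_core <- function(geno, bs, r_init, tol = 1e-6, maxit = 200) {
  fit <- hmm_em_cpp(geno, bs, clamp(r_init, 1e-4, 0.49), tol, maxit)
  fit$rfs <- as.numeric(fit$rfs)
  fit
}

#' EM estimation of interval recombination fractions
#'
#' Baum-Welch estimation for a fixed marker order and fixed phases: the
#' E-step computes the expected number of recombination events per interval
#' and per parent under the four-state HMM posterior, and the M-step sets
#' each interval's shared recombination fraction to (expected parent-1
#' recombinants + expected parent-2 recombinants) / (2N).  The
#' log-likelihood is non-decreasing across iterations.
#'
#' @inheritParams hmm_loglik
#' @param r_init initial interval recombination fractions (clamped to
#'   `[1e-4, 0.49]`).
#' @param config an [ordering_config()] supplying `em_tol` and `em_maxit`.
#' @return List with `rfs`, `loglik`, `converged` (FALSE means the
#'   iteration cap was hit) and `n_iter`.
#' @export
em_rfs <- function(markers, table, phases, r_init = NULL,
                   config = ordering_config()) {
  stopifnot(inherits(table, "marker_table"), length(markers) >= 2)
  idx <- match(markers, table$info$marker_id)
  if (anyNA(idx)) stop_("unknown markers")
  cross <- cross_types_of(table)[idx]
  bs <- bs_matrix(cross, phases$phase_p1, phases$phase_p2)
  r_init <- r_init %||% rep(0.25, length(markers) - 1L)
  fit <- em_core(table$geno[idx, , drop = FALSE], bs, r_init,
                 config$em_tol, config$em_maxit)
  if (!fit$converged)
    warning("EM did not converge in ", config$em_maxit, " iterations")
  fit
}

# ---- per-group preparation and phase propagation ---------------------

# precompute symmetric pair matrices over the group's markers: rf, LOD and
# the per-parent relative phase (0 = coupling, 1 = repulsion, NA = not
# informative for that parent)
prepare_cg <- function(markers, table, pairs) {
  idx <- match(markers, table$info$marker_id)
  if (anyNA(idx)) stop_("unknown markers: ",
                        paste(markers[is.na(idx)], collapse = ", "))
  m <- length(markers)
  rfm <- lodm <- matrix(NA_real_, m, m)
  ph1 <- ph2 <- matrix(NA_integer_, m, m)
  sel <- which(pairs$marker_a %in% markers & pairs$marker_b %in% markers)
  i <- match(pairs$marker_a[sel], markers)
  j <- match(pairs$marker_b[sel], markers)
  ij <- cbind(i, j)
  ji <- cbind(j, i)
  rel <- function(x) ifelse(is.na(x), NA_integer_,
                            ifelse(x == "repulsion", 1L, 0L))
  rfm[ij] <- rfm[ji] <- pairs$rf[sel]
  lodm[ij] <- lodm[ji] <- pairs$LOD[sel]
  ph1[ij] <- ph1[ji] <- rel(pairs$phase_p1[sel])
  ph2[ij] <- ph2[ji] <- rel(pairs$phase_p2[sel])
  # phase-resolution strength per parent: D-type pairs pin the relative
  # phase sharply, C x C pairs barely distinguish it at small r (at r = 0
  # coupling-repulsion and repulsion-repulsion coincide)
  st1 <- st2 <- matrix(NA_real_, m, m)
  cls <- pairs$pair_class[sel]
  st1[ij] <- st1[ji] <- ifelse(cls %in% c("D1xD1", "D1xC"), 2,
                               ifelse(cls == "CxC", 1, NA))
  st2[ij] <- st2[ji] <- ifelse(cls %in% c("D2xD2", "D2xC"), 2,
                               ifelse(cls == "CxC", 1, NA))
  list(markers = markers,
       cross = cross_types_of(table)[idx],
       geno = table$geno[idx, , drop = FALSE],
       rfm = rfm, lodm = lodm, ph1 = ph1, ph2 = ph2,
       st1 = st1, st2 = st2)
}

# absolute 0/1 phases per marker along an order, propagated per parent
# from the two-point relative phases; each marker is anchored on the
# highest-LOD previously placed marker whose pair resolves the phase in
# that parent, and the first informative marker of each parent sets the
# (arbitrary) reference
assign_phases_idx <- function(prep, ord) {
  m <- length(ord)
  p1 <- p2 <- rep(NA_integer_, m)
  prev1 <- prev2 <- integer(0)  # positions (in ord) already phased per parent
  for (j in seq_len(m)) {
    oj <- ord[j]
    if (prep$cross[oj] %in% c("D1", "C")) {
      if (length(prev1) == 0) {
        p1[j] <- 1L
      } else {
        ok <- ord[prev1]
        rel <- prep$ph1[ok, oj]
        score <- prep$st1[ok, oj] * 1e6 + prep$lodm[ok, oj]
        usable <- which(!is.na(rel) & !is.na(score))
        if (length(usable) == 0) {
          p1[j] <- 1L
        } else {
          k <- usable[which.max(score[usable])]
          p1[j] <- bitwXor(p1[prev1[k]], rel[k])
        }
      }
      prev1 <- c(prev1, j)
    }
    if (prep$cross[oj] %in% c("D2", "C")) {
      if (length(prev2) == 0) {
        p2[j] <- 1L
      } else {
        ok <- ord[prev2]
        rel <- prep$ph2[ok, oj]
        score <- prep$st2[ok, oj] * 1e6 + prep$lodm[ok, oj]
        usable <- which(!is.na(rel) & !is.na(score))
        if (length(usable) == 0) {
          p2[j] <- 1L
        } else {
          k <- usable[which.max(score[usable])]
          p2[j] <- bitwXor(p2[prev2[k]], rel[k])
        }
      }
      prev2 <- c(prev2, j)
    }
  }
  list(phase_p1 = p1, phase_p2 = p2)
}

adjacent_r_init <- function(prep, ord) {
  m <- length(ord)
  if (m < 2) return(numeric(0))
  r <- prep$rfm[cbind(ord[-m], ord[-1])]
  r[is.na(r)] <- 0.25
  clamp(r, 1e-4, 0.49)
}

# em = TRUE fits interval rfs by EM; during order search a coarser
# tolerance/iteration cap is enough to rank candidate orders (final =
# TRUE restores the configured precision); em = FALSE only evaluates the
# likelihood at plug-in two-point rfs (cheap screening)
eval_order <- function(prep, ord, config, em = TRUE, final = FALSE) {
  ph <- assign_phases_idx(prep, ord)
  g <- prep$geno[ord, , drop = FALSE]
  bs <- bs_matrix(prep$cross[ord], ph$phase_p1, ph$phase_p2)
  r0 <- adjacent_r_init(prep, ord)
  if (em) {
    tol <- if (final) config$em_tol else max(config$em_tol, 1e-4)
    maxit <- if (final) config$em_maxit else min(config$em_maxit, 50L)
    fit <- em_core(g, bs, r0, tol, maxit)
    list(ord = ord, phases = ph, rfs = fit$rfs, loglik = fit$loglik,
         converged = fit$converged)
  } else {
    list(ord = ord, phases = ph, rfs = r0,
         loglik = hmm_forward_cpp(g, bs, r0), converged = NA)
  }
}

permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = n - k)
    }
  }
  out
}

# all orders up to reversal, in deterministic lexicographic order
unique_orders <- function(n) {
  if (n <= 2) return(list(seq_len(n)))
  perms <- permutations(n)
  perms <- perms[vapply(perms, function(p) p[1] < p[n], logical(1))]
  keys <- vapply(perms, paste, character(1), collapse = ",")
  perms[order(keys)]
}

# candidate phase flips for one marker (its own components only)
phase_flips <- function(cross, p1, p2) {
  switch(cross,
         D1 = list(c(1L - p1, p2)),
         D2 = list(c(p1, 1L - p2)),
         C = list(c(1L - p1, p2), c(p1, 1L - p2), c(1L - p1, 1L - p2)))
}

# post-hoc likelihood re-check of each marker's phases: the two-point
# anchoring can mis-call weakly identified components (C x C pairs at
# small r), which the multipoint likelihood resolves
polish_phases <- function(g, cross, ph, rfs) {
  m <- length(cross)
  bs <- bs_matrix(cross, ph$phase_p1, ph$phase_p2)
  ll <- hmm_forward_cpp(g, bs, rfs)
  for (pass in 1:3) {
    changed <- FALSE
    for (j in seq_len(m)) {
      for (alt in phase_flips(cross[j], ph$phase_p1[j], ph$phase_p2[j])) {
        ph2 <- ph
        ph2$phase_p1[j] <- alt[1]
        ph2$phase_p2[j] <- alt[2]
        bs2 <- bs_matrix(cross, ph2$phase_p1, ph2$phase_p2)
        ll2 <- hmm_forward_cpp(g, bs2, rfs)
        if (ll2 > ll + 1e-6) {
          ph <- ph2
          ll <- ll2
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ph
}

finalize_cg <- function(prep, ord, config, name, ambiguous = character(0)) {
  ph <- assign_phases_idx(prep, ord)
  g <- prep$geno[ord, , drop = FALSE]
  cross <- prep$cross[ord]
  r0 <- adjacent_r_init(prep, ord)
  pre <- em_core(g, bs_matrix(cross, ph$phase_p1, ph$phase_p2), r0,
                 max(config$em_tol, 1e-4), min(config$em_maxit, 50L))
  ph <- polish_phases(g, cross, ph, pre$rfs)
  fit <- em_core(g, bs_matrix(cross, ph$phase_p1, ph$phase_p2), pre$rfs,
                 config$em_tol, config$em_maxit)
  new_ordered_cg(name = name,
                 markers = prep$markers[ord],
                 cross_type = cross,
                 phase_p1 = ph$phase_p1,
                 phase_p2 = ph$phase_p2,
                 rfs = fit$rfs,
                 loglik = fit$loglik,
                 converged = isTRUE(fit$converged),
                 ambiguous = ambiguous)
}

#' An ordered co-segregation group
#'
#' Container for a multipoint-ordered co-segregation group: markers with
#' cross types and phases, interval recombination fractions, cumulative
#' Kosambi positions (starting at 0) and the multipoint log-likelihood.
#'
#' @param name group name.
#' @param markers marker ids in map order.
#' @param cross_type,phase_p1,phase_p2 per-marker annotations.
#' @param rfs interval recombination fractions (`length(markers) - 1`).
#' @param loglik multipoint log-likelihood.
#' @param converged logical EM convergence flag.
#' @param ambiguous ids of markers whose placement was forced (ambiguous
#'   insertion in [order_seq()]).
#' @return Object of class `ordered_cg`.
#' @export
new_ordered_cg <- function(name, markers, cross_type, phase_p1, phase_p2,
                           rfs, loglik = NA_real_, converged = TRUE,
                           ambiguous = character(0)) {
  m <- length(markers)
  stopifnot(length(cross_type) == m, length(rfs) == max(m - 1L, 0L))
  if (length(rfs) && (any(rfs < 0) || any(rfs >= 0.5)))
    rfs <- clamp(rfs, 0, 0.5 - 1e-9)
  positions <- c(0, cumsum(kosambi(rfs)))
  structure(list(name = name, markers = markers, cross_type = cross_type,
                 phase_p1 = phase_p1, phase_p2 = phase_p2, rfs = rfs,
                 positions = positions,
                 length_cM = if (m) positions[m] else 0,
                 loglik = loglik, converged = converged,
                 ambiguous = ambiguous),
            class = "ordered_cg")
}

#' @export
print.ordered_cg <- function(x, ...) {
  cat(sprintf("ordered_cg %s: %d markers, %.2f cM, loglik %.2f\n",
              x$name, length(x$markers), x$length_cM, x$loglik))
  invisible(x)
}

#' Exhaustive multipoint ordering of a small group
#'
#' Evaluates every marker order (up to reversal) with EM-fitted interval
#' recombination fractions and returns the order with the highest
#' multipoint log-likelihood (deterministic lexicographic tie-break).
#'
#' @param markers marker ids of the group (at most
#'   `config$exhaustive_max`).
#' @param table a [marker_table()].
#' @param pairs the [all_pairs()] estimates (source of phases and starting
#'   values).
#' @param config an [ordering_config()].
#' @param name name for the resulting group.
#' @return An `ordered_cg`.
#' @export
compare_orders <- function(markers, table, pairs, config = ordering_config(),
                           name = "CG") {
  m <- length(markers)
  if (m < 2) stop_("need at least 2 markers")
  if (m > config$exhaustive_max)
    stop_("group has ", m, " markers (> exhaustive_max = ",
          config$exhaustive_max, "); use order_seq()")
  prep <- prepare_cg(markers, table, pairs)
  best <- NULL
  for (ord in unique_orders(m)) {
    fit <- eval_order(prep, ord, config, em = TRUE)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  finalize_cg(prep, best$ord, config, name)
}

#' Sequential multipoint ordering of a large group
#'
#' Orders groups too large for exhaustive search: a seed frame of the
#' `frame_size` markers with the highest within-group LOD connectivity is
#' ordered exhaustively, then the remaining markers are inserted one at a
#' time at their likelihood-best position.  Candidate positions are
#' screened with plug-in two-point recombination fractions and the two best
#' are refitted by EM; a marker whose best and second-best refitted
#' positions differ by less than `insertion_lod_threshold` log10 units is
#' force-placed and flagged ambiguous.
#'
#' @inheritParams compare_orders
#' @return An `ordered_cg` (ambiguous placements listed in
#'   `$ambiguous`).
#' @export
order_seq <- function(markers, table, pairs, config = ordering_config(),
                      name = "CG") {
  m <- length(markers)
  if (m <= config$exhaustive_max)
    return(compare_orders(markers, table, pairs, config, name))
  prep <- prepare_cg(markers, table, pairs)
  lodsum <- marker_lod_sums(markers, pairs)
  frame <- order(-lodsum, markers)[seq_len(config$frame_size)]
  rest <- setdiff(order(-lodsum, markers), frame)
  sub_cfg <- config
  sub_cfg$exhaustive_max <- max(config$exhaustive_max, config$frame_size)
  best <- NULL
  for (ord in unique_orders(length(frame))) {
    fit <- eval_order(prep, frame[ord], config, em = TRUE)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  cur <- best$ord
  ambiguous <- character(0)
  for (k in rest) {
    cand <- lapply(seq_len(length(cur) + 1L), function(pos)
      append(cur, k, after = pos - 1L))
    cheap <- vapply(cand, function(o)
      eval_order(prep, o, config, em = FALSE)$loglik, numeric(1))
    top2 <- order(-cheap)[seq_len(min(2L, length(cheap)))]
    fits <- lapply(top2, function(i) eval_order(prep, cand[[i]], config,
                                                em = TRUE))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    pick <- which.max(lls)
    if (length(lls) > 1 &&
        (max(lls) - min(lls)) / log(10) < config$insertion_lod_threshold)
      ambiguous <- c(ambiguous, prep$markers[k])
    cur <- fits[[pick]]$ord
  }
  finalize_cg(prep, cur, config, name, ambiguous = ambiguous)
}

marker_lod_sums <- function(markers, pairs) {
  sel <- pairs$marker_a %in% markers & pairs$marker_b %in% markers &
    !is.na(pairs$LOD)
  lod <- c(pairs$LOD[sel], pairs$LOD[sel])
  who <- c(pairs$marker_a[sel], pairs$marker_b[sel])
  out <- setNames(rep(0, length(markers)), markers)
  agg <- tapply(lod, who, sum)
  out[names(agg)] <- agg
  out
}

#' Ripple refinement of a marker order
#'
#' Slides a window along the order, tries all permutations of the markers
#' inside it (screened with plug-in two-point recombination fractions,
#' best candidate refitted by EM) and accepts any strict multipoint
#' log-likelihood improvement, repeating until a full pass changes
#' nothing.  The log-likelihood never decreases.
#'
#' @param ordered an `ordered_cg`.
#' @inheritParams compare_orders
#' @param window window size.
#' @return An `ordered_cg` (same markers, possibly better order).
#' @export
ripple <- function(ordered, table, pairs, window = NULL,
                   config = ordering_config()) {
  stopifnot(inherits(ordered, "ordered_cg"))
  window <- window %||% config$ripple_window
  m <- length(ordered$markers)
  if (m < 3 || window < 2) return(ordered)
  window <- min(window, m)
  prep <- prepare_cg(ordered$markers, table, pairs)
  cur <- seq_len(m)
  cur_fit <- eval_order(prep, cur, config, em = TRUE)
  max_passes <- 25L
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (start in seq_len(m - window + 1L)) {
      slots <- start:(start + window - 1L)
      cands <- list()
      for (p in permutations(window)) {
        if (identical(p, seq_len(window))) next
        o <- cur
        o[slots] <- cur[slots][p]
        cands[[length(cands) + 1L]] <- o
      }
      cheap <- vapply(cands, function(o)
        eval_order(prep, o, config, em = FALSE)$loglik, numeric(1))
      fit <- eval_order(prep, cands[[which.max(cheap)]], config, em = TRUE)
      if (fit$loglik > cur_fit$loglik + 1e-9) {
        cur <- fit$ord
        cur_fit <- fit
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  finalize_cg(prep, cur, config, ordered$name, ambiguous = ordered$ambiguous)
}

#' Order every co-segregation group of a partition
#'
#' Dispatches each group to [compare_orders()] (size up to
#' `exhaustive_max`) or [order_seq()] and refines with [ripple()].
#'
#' @param partition a [co_segregation_groups()] result.
#' @inheritParams compare_orders
#' @return Named list of `ordered_cg` objects.
#' @export
order_cgs <- function(partition, table, pairs, config = ordering_config()) {
  stopifnot(inherits(partition, "cg_partition"))
  out <- list()
  for (nm in names(partition$groups)) {
    mk <- partition$groups[[nm]]
    ocg <- if (length(mk) <= config$exhaustive_max)
      compare_orders(mk, table, pairs, config, name = nm)
    else
      order_seq(mk, table, pairs, config, name = nm)
    out[[nm]] <- ripple(ocg, table, pairs, config = config)
  }
  out
}
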