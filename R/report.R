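#' Map-level summary statistics
#'
#' Computes the standard descriptive statistics of an integrated map:
#' linked/unlinked marker counts, number of co-segregation groups, total
#' length, marker density (total length / linked markers), CG length range
#' and mean, largest adjacent-marker gap, linked counts per cross type,
#' the number of integrated CGs (containing markers from both parents),
#' and -- when the segregation filter is supplied -- the mapped proportion
#' of single-dose markers per system.  Values are kept at full precision;
#' rounding happens only in the print method (2 decimals for cM, 1 for
#' percentages).
#'
#' @param map a [linkage_map()].
#' @param filter optional [filter_sdm()] result for mapped-proportion and
#'   unlinked-marker accounting.
#' @return Object of class `map_summary`.
#' @export
map_summary <- function(map, filter = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  if (length(map$cgs) == 0) stop_("empty map")
  asn <- map$assignments
  lens <- vapply(map$cgs, `[[`, numeric(1), "length_cM")
  gaps <- unlist(lapply(map$cgs, function(cg)
    if (length(cg$positions) > 1) diff(cg$positions) else numeric(0)))
  n_linked <- nrow(asn)
  per_type <- vapply(c("D1", "D2", "C"), function(ct)
    sum(asn$cross_type == ct), integer(1))
  integrated <- vapply(map$cgs, function(cg)
    any(cg$cross_type == "D1") && any(cg$cross_type == "D2"), logical(1))
  out <- list(
    n_linked_markers = n_linked,
    n_unlinked = NA_integer_,
    n_cgs = length(map$cgs),
    total_length_cM = sum(lens),
    density_cM = sum(lens) / n_linked,
    cg_length_min = min(lens),
    cg_length_max = max(lens),
    cg_length_mean = sum(lens) / length(lens),
    max_adjacent_gap_cM = if (length(gaps)) max(gaps) else 0,
    linked_per_cross_type = per_type,
    n_integrated_cgs = sum(integrated),
    mapped_proportion = NULL
  )
  if (!is.null(filter)) {
    res <- filter$results
    kept <- res$marker_id[res$kept]
    out$n_unlinked <- length(setdiff(kept, asn$marker))
    systems <- c("AFLP", "EST_SSR", "RT")
    sdm <- vapply(systems, function(s)
      sum(res$kept & res$system == s), integer(1))
    linked <- vapply(systems, function(s)
      sum(asn$system == s), integer(1))
    out$mapped_proportion <- ifelse(sdm > 0, linked / sdm, NA_real_)
    names(out$mapped_proportion) <- systems
  }
  structure(out, class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Map summary\n")
  cat(sprintf("  linked markers: %d (D1 %d, D2 %d, C %d)\n",
              x$n_linked_markers, x$linked_per_cross_type[["D1"]],
              x$linked_per_cross_type[["D2"]],
              x$linked_per_cross_type[["C"]]))
  if (!is.na(x$n_unlinked))
    cat(sprintf("  unlinked markers: %d\n", x$n_unlinked))
  cat(sprintf("  CGs: %d (%d integrated), total %.2f cM, density %.2f cM/marker\n",
              x$n_cgs, x$n_integrated_cgs, x$total_length_cM, x$density_cM))
  cat(sprintf("  CG length: %.2f-%.2f cM (mean %.2f), largest gap %.2f cM\n",
              x$cg_length_min, x$cg_length_max, x$cg_length_mean,
              x$max_adjacent_gap_cM))
  if (!is.null(x$mapped_proportion)) {
    p <- x$mapped_proportion * 100
    cat(sprintf("  mapped proportion: AFLP %.1f%%, EST-SSR %.1f%%, RT %.1f%%\n",
                p[["AFLP"]], p[["EST_SSR"]], p[["RT"]]))
  }
  invisible(x)
}

#' Run the full mapping pipeline on a simulated population
#'
#' Simulates a population (or accepts a marker table), then runs
#' segregation filtering, two-point estimation, co-segregation grouping,
#' multipoint ordering, homo(eo)logy-group assembly, retrotransposon
#' clustering analyses and the map summary.  With `out_dir` set, each
#' stage writes a TSV artifact (`segregation.tsv`, `twopoint.tsv`,
#' `groups.tsv`, `map.tsv`, `hgs.tsv`, `te_clusters.tsv`,
#' `summary.tsv`).  All randomness flows from the configuration seed, so
#' identical seeds give identical outputs.
#'
#' @param x a [sim_config()] (the population is simulated, and SSR locus
#'   codes are taken from the truth) or a [marker_table()].
#' @param out_dir optional output directory for the TSV artifacts.
#' @param nbs optional [nbs_config()]; when given, fingerprint profiles
#'   are simulated and copy numbers estimated.
#' @param alpha_global family-wise level for the segregation filter.
#' @param lod_min,rf_max grouping thresholds.
#' @param ordering an [ordering_config()].
#' @param min_shared core threshold for [assemble_hgs()].
#' @param bin_cm,max_gap_cm retrotransposon analysis parameters.
#' @param ssr_loci declared SSR locus codes (only needed for marker-table
#'   input whose locus codes end in digits).
#' @return List of class `sdmap_pipeline` with every stage's result:
#'   `table`, `truth` (simulation input only), `filter`, `pairs`,
#'   `graph`, `partition`, `map`, `assembly`, `bins`, `poisson`,
#'   `clusters`, `copy_number`, `summary`.
#' @export
run_pipeline <- function(x, out_dir = NULL, nbs = NULL,
                         alpha_global = 0.05, lod_min = 6, rf_max = 0.35,
                         ordering = ordering_config(), min_shared = 2,
                         bin_cm = 10, max_gap_cm = 5, ssr_loci = NULL) {
  truth <- NULL
  if (inherits(x, "sim_config")) {
    sim <- simulate_population(x)
    table <- sim$table
    truth <- sim$truth
    flat <- as.data.frame(truth)
    ssr <- flat$system == "EST_SSR" & !is.na(flat$locus)
    locus_map <- setNames(flat$locus[ssr], flat$marker_id[ssr])
  } else if (inherits(x, "marker_table")) {
    table <- x
    locus_map <- build_locus_map(table$info, loci = ssr_loci)
  } else {
    stop_("x must be a sim_config or a marker_table")
  }

  filter <- filter_sdm(table, alpha_global = alpha_global)
  if (sum(filter$results$kept) < 2) stop_("stage segregation: < 2 markers kept")
  pairs <- all_pairs(filter, table)
  graph <- build_linkage_graph(pairs, lod_min = lod_min, rf_max = rf_max)
  partition <- co_segregation_groups(graph)
  if (length(partition$groups) == 0) stop_("stage grouping: no linked groups")
  cgs <- order_cgs(partition, table, pairs, config = ordering)
  assembly <- assemble_hgs(cgs, locus_map, min_shared = min_shared)
  cgs <- rename_cgs(cgs, assembly)
  hg_table <- data.frame(cg = assembly$table$new_name, hg = assembly$table$hg,
                         status = assembly$table$status,
                         stringsAsFactors = FALSE)
  info <- data.frame(marker_id = filter$results$marker_id,
                     system = filter$results$system,
                     cross_type = filter$results$cross_type,
                     stringsAsFactors = FALSE)
  map <- linkage_map(cgs, info, hg_table = hg_table)

  bins <- bin_markers(map, target_system = "RT", bin_cm = bin_cm)
  poisson <- tryCatch(poisson_gof(bins), error = function(e) NULL)
  clusters <- call_clusters(map, target_system = "RT",
                            max_gap_cm = max_gap_cm)
  cn <- NULL
  if (!is.null(nbs)) {
    prof <- simulate_nbs_profiles(nbs)
    cn <- list(profiles = prof,
               total = copy_number(prof$total_fragments, nbs$n_combinations),
               parent1 = copy_number(prof$total_parent1, nbs$n_combinations),
               parent2 = copy_number(prof$total_parent2, nbs$n_combinations))
  }
  summary <- map_summary(map, filter)

  out <- structure(list(table = table, truth = truth, filter = filter,
                        pairs = pairs, graph = graph, partition = partition,
                        map = map, assembly = assembly, bins = bins,
                        poisson = poisson, clusters = clusters,
                        copy_number = cn, summary = summary),
                   class = "sdmap_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.sdmap_pipeline <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$poisson))
    cat(sprintf("RT clustering: chi2 = %.2f, p = %.3g; %d clusters called\n",
                x$poisson$chi2, x$poisson$p_value, nrow(x$clusters)))
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

write_pipeline_artifacts <- function(pipe, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(pipe$filter$results, p("segregation.tsv"))
  write_tsv(as.data.frame(pipe$pairs), p("twopoint.tsv"))
  groups <- rbind(pipe$partition$assignments,
                  if (length(pipe$partition$unlinked))
                    data.frame(marker = pipe$partition$unlinked,
                               cg = "unlinked"))
  write_tsv(groups, p("groups.tsv"))
  export_map_text(pipe$map, p("map.tsv"), format = "tsv")
  write_tsv(pipe$assembly$table, p("hgs.tsv"))
  write_tsv(pipe$clusters, p("te_clusters.tsv"))
  s <- pipe$summary
  kv <- list(
    n_linked_markers = s$n_linked_markers,
    n_unlinked = s$n_unlinked,
    n_cgs = s$n_cgs,
    total_length_cM = s$total_length_cM,
    density_cM = s$density_cM,
    cg_length_min = s$cg_length_min,
    cg_length_max = s$cg_length_max,
    cg_length_mean = s$cg_length_mean,
    max_adjacent_gap_cM = s$max_adjacent_gap_cM,
    n_integrated_cgs = s$n_integrated_cgs,
    linked_D1 = s$linked_per_cross_type[["D1"]],
    linked_D2 = s$linked_per_cross_type[["D2"]],
    linked_C = s$linked_per_cross_type[["C"]],
    poisson_p = if (is.null(pipe$poisson)) NA else pipe$poisson$p_value,
    n_te_clusters = nrow(pipe$clusters)
  )
  if (!is.null(s$mapped_proportion)) {
    kv$mapped_AFLP <- s$mapped_proportion[["AFLP"]]
    kv$mapped_EST_SSR <- s$mapped_proportion[["EST_SSR"]]
    kv$mapped_RT <- s$mapped_proportion[["RT"]]
  }
  if (!is.null(pipe$copy_number)) {
    kv$copy_number <- pipe$copy_number$total$estimate_rounded
    kv$copy_number_parent1 <- pipe$copy_number$parent1$estimate_rounded
    kv$copy_number_parent2 <- pipe$copy_number$parent2$estimate_rounded
  }
  write_tsv(data.frame(key = names(kv),
                       value = vapply(kv, function(v)
                         format(v, digits = 12), character(1))),
            p("summary.tsv"))
  invisible(out_dir)
}
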