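#' Build the two-point linkage graph
#'
#' Markers are the nodes; an undirected edge joins two markers whose
#' two-point estimate is informative, reaches `LOD >= lod_min` and has
#' `rf <= rf_max`.  D1 x D2 pairs carry no two-point information and never
#' form an edge -- their groups can only be joined through C-type bridge
#' markers.
#'
#' @param estimates a [all_pairs()] result.
#' @param lod_min minimum LOD score (default 6).
#' @param rf_max maximum recombination fraction (default 0.35).
#' @return A list of class `linkage_graph` with `nodes`, `edges` (data
#'   frame) and the thresholds.
#' @export
build_linkage_graph <- function(estimates, lod_min = 6, rf_max = 0.35) {
  stopifnot(is.data.frame(estimates))
  nodes <- sort(unique(c(estimates$marker_a, estimates$marker_b)))
  keep <- estimates$pair_class != "D1xD2" &
    !is.na(estimates$LOD) & !is.na(estimates$rf) &
    estimates$LOD >= lod_min & estimates$rf <= rf_max
  edges <- estimates[keep, c("marker_a", "marker_b", "rf", "LOD"),
                     drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, lod_min = lod_min,
                 rf_max = rf_max),
            class = "linkage_graph")
}

#' @export
print.linkage_graph <- function(x, ...) {
  cat("linkage_graph:", length(x$nodes), "markers,", nrow(x$edges),
      sprintf("edges (LOD >= %g, rf <= %g)\n", x$lod_min, x$rf_max))
  invisible(x)
}

#' Co-segregation groups from the linkage graph
#'
#' Connected components of the linkage graph.  Markers in no edge are
#' reported as unlinked and excluded from ordering.  Groups are returned in
#' a deterministic order -- by marker count descending, then by the
#' lexicographically smallest member -- so the partition is independent of
#' input order.
#'
#' @param graph a [build_linkage_graph()] result.
#' @return List of class `cg_partition`: `groups` (named list of marker id
#'   vectors, provisional names `CG01`, ...), `unlinked` (character
#'   vector), `assignments` (data frame marker -> group).
#' @export
co_segregation_groups <- function(graph) {
  stopifnot(inherits(graph, "linkage_graph"))
  linked <- sort(unique(c(graph$edges$marker_a, graph$edges$marker_b)))
  unlinked <- setdiff(graph$nodes, linked)
  groups <- list()
  if (length(linked)) {
    ig <- igraph::graph_from_data_frame(
      graph$edges[, c("marker_a", "marker_b")],
      directed = FALSE,
      vertices = data.frame(name = linked))
    comp <- igraph::components(ig)
    groups <- split(names(comp$membership), comp$membership)
    groups <- lapply(groups, sort)
    ord <- order(-lengths(groups),
                 vapply(groups, `[[`, character(1), 1))
    groups <- groups[ord]
    names(groups) <- sprintf("CG%02d", seq_along(groups))
  }
  assignments <- data.frame(
    marker = unlist(groups, use.names = FALSE),
    cg = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
  structure(list(groups = groups, unlinked = unlinked,
                 assignments = assignments),
            class = "cg_partition")
}

#' @export
print.cg_partition <- function(x, ...) {
  cat("cg_partition:", length(x$groups), "co-segregation groups,",
      length(x$unlinked), "unlinked markers\n")
  if (length(x$groups))
    cat("group sizes:", paste(lengths(x$groups), collapse = " "), "\n")
  invisible(x)
}
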