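SSR_PREFIXES <- c("ESTA", "ESTB", "ESTC", "CV")

#' Locus code of an EST-SSR marker
#'
#' Strips the trailing allele size from an EST-SSR marker name and returns
#' the locus code (`ESTA`, `ESTB`, `ESTC` or `CV` families).  Because
#' locus codes may themselves end in digits (locus `ESTB94`, allele 279,
#' marker `ESTB94279`), a declared locus list resolves the split; without
#' one the maximal trailing integer is taken as the allele size.
#'
#' @param marker_id marker name (optionally `D1-`/`D2-`/`C-` prefixed).
#' @param loci optional character vector of declared locus codes.
#' @return The locus code.
#' @export
ssr_locus_of <- function(marker_id, loci = NULL) {
  p <- parse_marker_name(marker_id, loci = loci)
  code <- p$system_code
  ok <- if (!is.null(loci)) code %in% loci
        else any(startsWith(code, SSR_PREFIXES))
  if (!ok)
    stop_("'", marker_id, "' is not an EST-SSR marker (code '", code, "')")
  code
}

#' Map mapped EST-SSR markers to locus codes
#'
#' @param info marker info data frame (`marker_id`, `system`).
#' @param loci optional declared locus codes passed to [ssr_locus_of()].
#' @return Named character vector, marker id -> locus code, for the
#'   EST-SSR markers.
#' @export
build_locus_map <- function(info, loci = NULL) {
  ids <- info$marker_id[info$system == "EST_SSR"]
  setNames(vapply(ids, ssr_locus_of, character(1), loci = loci), ids)
}

#' Assemble co-segregation groups into homo(eo)logous groups
#'
#' CGs sharing at least `min_shared` distinct EST-SSR locus codes are core
#' members of one homo(eo)logous group (transitively: a locus chain through
#' several CG pairs merges their groups); CGs sharing a single locus with a
#' group's core are attached as putative members.  Groups are numbered with
#' Roman numerals by total marker count descending; within a group, CGs are
#' renamed `<HG>-k` by genetic length descending; CGs in no group become
#' `U-k`, also by length descending.
#'
#' @param cgs named list of `ordered_cg` objects.
#' @param locus_map named character vector (marker id -> SSR locus code),
#'   e.g. from [build_locus_map()] or the simulation truth.
#' @param min_shared minimum number of distinct shared loci for core
#'   membership (default 2).
#' @return Object of class `hg_assembly`: `table` (one row per CG:
#'   original and new name, HG, core/putative/unassigned status, length,
#'   marker count, shared loci) and `evidence` (shared loci per CG pair
#'   within a group).
#' @export
assemble_hgs <- function(cgs, locus_map, min_shared = 2) {
  stopifnot(is.list(cgs), min_shared >= 1)
  if (length(cgs) && is.null(names(cgs)))
    names(cgs) <- vapply(cgs, `[[`, character(1), "name")
  cg_names <- names(cgs)
  n <- length(cgs)
  # distinct locus codes per CG (within-CG duplications count once and
  # never create self-evidence)
  cg_loci <- lapply(cgs, function(cg)
    sort(unique(unname(locus_map[intersect(cg$markers, names(locus_map))]))))
  shared <- function(i, j) intersect(cg_loci[[i]], cg_loci[[j]])

  core_edges <- data.frame(from = character(0), to = character(0))
  evidence <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        s <- shared(i, j)
        if (length(s) >= 1)
          evidence[[paste(cg_names[i], cg_names[j], sep = " ~ ")]] <- s
        if (length(s) >= min_shared)
          core_edges <- rbind(core_edges,
                              data.frame(from = cg_names[i], to = cg_names[j]))
      }
    }
  }
  core_members <- unique(c(core_edges$from, core_edges$to))
  groups <- list()
  if (length(core_members)) {
    ig <- igraph::graph_from_data_frame(core_edges, directed = FALSE,
                                        vertices = data.frame(name = sort(core_members)))
    comp <- igraph::components(ig)
    groups <- lapply(split(names(comp$membership), comp$membership),
                     function(cg) list(core = sort(cg), putative = character(0)))
  }
  # putative attachment: one shared locus with the union of a group's core
  if (length(groups)) {
    core_loci <- lapply(groups, function(g)
      sort(unique(unlist(cg_loci[g$core]))))
    for (nm in setdiff(cg_names, core_members)) {
      hits <- vapply(core_loci, function(cl)
        length(intersect(cg_loci[[nm]], cl)), integer(1))
      if (any(hits >= 1)) {
        pick <- which.max(hits)  # ties: first (largest-core-first ordering below)
        groups[[pick]]$putative <- c(groups[[pick]]$putative, nm)
      }
    }
  }
  n_markers <- vapply(cgs, function(cg) length(cg$markers), integer(1))
  len <- vapply(cgs, `[[`, numeric(1), "length_cM")
  names(n_markers) <- names(len) <- cg_names
  if (length(groups)) {
    total <- vapply(groups, function(g)
      sum(n_markers[c(g$core, g$putative)]), numeric(1))
    ord <- order(-total, vapply(groups, function(g) g$core[1], character(1)))
    groups <- groups[ord]
    names(groups) <- as.character(as.roman(seq_along(groups)))
  }
  rows <- list()
  for (hg in names(groups)) {
    g <- groups[[hg]]
    members <- c(g$core, g$putative)
    status <- c(rep("core", length(g$core)),
                rep("putative", length(g$putative)))
    o <- order(-len[members], -n_markers[members], members)
    members <- members[o]
    status <- status[o]
    for (k in seq_along(members)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cg = members[k], new_name = paste0(hg, "-", k), hg = hg,
        status = status[k], length_cM = len[members[k]],
        n_markers = n_markers[members[k]],
        loci = paste(cg_loci[[members[k]]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  assigned <- vapply(rows, `[[`, character(1), "cg")
  un <- setdiff(cg_names, assigned)
  un <- un[order(-len[un], -n_markers[un], un)]
  for (k in seq_along(un)) {
    rows[[length(rows) + 1L]] <- data.frame(
      cg = un[k], new_name = paste0("U-", k), hg = "U",
      status = "unassigned", length_cM = len[un[k]],
      n_markers = n_markers[un[k]],
      loci = paste(cg_loci[[un[k]]], collapse = ","),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, evidence = evidence,
                 min_shared = min_shared),
            class = "hg_assembly")
}

#' @export
print.hg_assembly <- function(x, ...) {
  hgs <- setdiff(unique(x$table$hg), "U")
  cat("hg_assembly:", length(hgs), "homo(eo)logous groups,",
      sum(x$table$hg == "U"), "unassigned CGs\n")
  print(x$table[, c("cg", "new_name", "status", "length_cM", "n_markers")],
        row.names = FALSE)
  invisible(x)
}

#' Apply homo(eo)logy-group names to ordered CGs
#'
#' Renames each `ordered_cg` with its `<HG>-k` / `U-k` name from an
#' [assemble_hgs()] result and returns the renamed list in final name
#' order (HG groups first, then unassigned, each as ordered in the
#' assembly table).
#'
#' @param cgs named list of `ordered_cg` objects (original names).
#' @param assembly an `hg_assembly`.
#' @return Named list of renamed `ordered_cg` objects.
#' @export
rename_cgs <- function(cgs, assembly) {
  stopifnot(inherits(assembly, "hg_assembly"))
  tab <- assembly$table
  out <- list()
  for (k in seq_len(nrow(tab))) {
    cg <- cgs[[tab$cg[k]]]
    cg$name <- tab$new_name[k]
    out[[cg$name]] <- cg
  }
  out
}
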