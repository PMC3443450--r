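#' An integrated linkage map
#'
#' The set of ordered co-segregation groups, their homo(eo)logy-group
#' assignments (when assembled) and a flat marker table of positions.
#'
#' @param cgs named list of [new_ordered_cg()] objects.
#' @param info data frame with columns `marker_id`, `system`,
#'   `cross_type` covering every mapped marker.
#' @param hg_table optional data frame (`cg`, `hg`, `status`) from
#'   [assemble_hgs()]; CGs without a row get homeology group `"U"`.
#' @return Object of class `linkage_map` with elements `cgs`,
#'   `assignments` and `hg_table`.
#' @export
linkage_map <- function(cgs, info, hg_table = NULL) {
  stopifnot(is.list(cgs))
  if (length(cgs) && is.null(names(cgs)))
    names(cgs) <- vapply(cgs, `[[`, character(1), "name")
  for (cg in cgs) stopifnot(inherits(cg, "ordered_cg"))
  hg_of <- function(cg_name) {
    if (is.null(hg_table)) return("U")
    i <- match(cg_name, hg_table$cg)
    if (is.na(i)) "U" else hg_table$hg[i]
  }
  rows <- lapply(cgs, function(cg) {
    idx <- match(cg$markers, info$marker_id)
    if (anyNA(idx))
      stop_("markers missing from info: ",
            paste(cg$markers[is.na(idx)], collapse = ", "))
    data.frame(marker = cg$markers,
               cg = cg$name,
               hg = hg_of(cg$name),
               position_cM = cg$positions,
               system = info$system[idx],
               cross_type = info$cross_type[idx],
               stringsAsFactors = FALSE)
  })
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), cg = character(0), hg = character(0),
               position_cM = numeric(0), system = character(0),
               cross_type = character(0))
  rownames(assignments) <- NULL
  structure(list(cgs = cgs, assignments = assignments, hg_table = hg_table),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  lens <- vapply(x$cgs, `[[`, numeric(1), "length_cM")
  cat(sprintf("linkage_map: %d markers in %d CGs, %.2f cM total\n",
              nrow(x$assignments), length(x$cgs), sum(lens)))
  invisible(x)
}
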