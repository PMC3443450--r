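#' Marker score tables
#'
#' A `marker_table` holds dominant (presence/absence) scores for a set of
#' markers over the two parents and the F1 progeny of an outcrossed
#' biparental population.  Scores are stored as an integer matrix with
#' values `1` (band present), `0` (band absent) and `NA` (missing), one row
#' per marker, one column per individual.  Parental scores and the marker
#' system (`"AFLP"`, `"EST_SSR"` or `"RT"` for retrotransposon-anchored
#' fingerprints) travel in the `info` data frame.
#'
#' @param individuals character vector of individual identifiers (length
#'   >= 2, no duplicates).
#' @param info data frame with columns `marker_id`, `system`, `parent1`,
#'   `parent2`.  Parental scores use the same coding as progeny scores:
#'   `"present"`, `"absent"` or `"missing"`.
#' @param geno integer matrix of 1/0/NA scores, markers x individuals.
#'
#' @return An object of class `marker_table`: a list with elements
#'   `individuals`, `info` and `geno`.
#' @seealso [read_marker_table()], [write_marker_table()]
#' @export
marker_table <- function(individuals, info, geno) {
  individuals <- as.character(individuals)
  if (length(individuals) < 2)
    stop_("a marker table needs at least 2 individuals")
  if (anyDuplicated(individuals))
    stop_("duplicated individual ids")
  need <- c("marker_id", "system", "parent1", "parent2")
  if (!all(need %in% names(info)))
    stop_("info must have columns ", paste(need, collapse = ", "))
  info <- as.data.frame(info)[, need]
  info$marker_id <- as.character(info$marker_id)
  if (anyDuplicated(info$marker_id))
    stop_("duplicated marker ids: ",
          paste(unique(info$marker_id[duplicated(info$marker_id)]), collapse = ", "))
  bad <- !info$system %in% c("AFLP", "EST_SSR", "RT")
  if (any(bad))
    stop_("unknown marker system: ", paste(unique(info$system[bad]), collapse = ", "))
  for (p in c("parent1", "parent2")) {
    bad <- !info[[p]] %in% c("present", "absent", "missing")
    if (any(bad)) stop_("invalid ", p, " score")
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(info))
    stop_("geno and info disagree on the number of markers")
  if (ncol(geno) != length(individuals))
    stop_("geno has ", ncol(geno), " columns for ", length(individuals),
          " declared individuals")
  if (!all(geno %in% c(0L, 1L, NA_integer_)))
    stop_("scores must be 1, 0 or NA")
  dimnames(geno) <- list(info$marker_id, individuals)
  structure(list(individuals = individuals, info = info, geno = geno),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat("marker_table:", nrow(x$geno), "markers x", length(x$individuals),
      "individuals\n")
  print(table(system = x$info$system))
  invisible(x)
}

#' @export
dim.marker_table <- function(x) dim(x$geno)

score_to_int <- c("1" = 1L, "0" = 0L, "-" = NA_integer_)
score_to_word <- c("1" = "present", "0" = "absent", "-" = "missing")
word_to_score <- c(present = "1", absent = "0", missing = "-")

#' Read a marker score table
#'
#' Reads the tab-separated marker table dialect used throughout the package:
#' a header line `#individuals:` followed by one tab-separated individual id
#' per field, then one line per marker with fields
#' `marker_id`, `system`, `parent1`, `parent2`, and one score per
#' individual.  Scores are coded `1` (band present), `0` (absent) and `-`
#' (missing); parental scores use the same codes.
#'
#' @param path path to the file.
#' @param dialect currently only `"tsv"`.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_("line 1: empty file")
  head_f <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (head_f[[1]] != "#individuals:")
    stop_("line 1: malformed header, expected '#individuals:'")
  individuals <- head_f[-1]
  if (length(individuals) < 2)
    stop_("line 1: fewer than 2 individuals declared")
  n <- length(individuals)
  body <- lines[-1]
  if (length(body) == 0) stop_("line 2: no marker rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  len <- lengths(fields)
  bad <- which(len != n + 4L)
  if (length(bad))
    stop_("line ", bad[[1]] + 1L, ": expected ", n + 4L, " fields, found ",
          len[bad[[1]]])
  m <- do.call(rbind, fields)
  scores <- m[, -(1:4), drop = FALSE]
  unknown <- which(!scores %in% names(score_to_int))
  if (length(unknown)) {
    idx <- arrayInd(unknown[[1]], dim(scores))
    stop_("line ", idx[1, 1] + 1L, ": unknown score code '",
          scores[unknown[[1]]], "'")
  }
  for (j in 3:4) {
    unk <- !m[, j] %in% names(score_to_word)
    if (any(unk))
      stop_("line ", which(unk)[[1]] + 1L, ": unknown parental score code '",
            m[which(unk)[[1]], j], "'")
  }
  if (anyDuplicated(m[, 1]))
    stop_("line ", which(duplicated(m[, 1]))[[1]] + 1L, ": duplicate marker id '",
          m[duplicated(m[, 1]), 1][[1]], "'")
  geno <- matrix(score_to_int[scores], nrow = nrow(m))
  info <- data.frame(
    marker_id = m[, 1],
    system = m[, 2],
    parent1 = unname(score_to_word[m[, 3]]),
    parent2 = unname(score_to_word[m[, 4]]),
    stringsAsFactors = FALSE
  )
  marker_table(individuals, info, geno)
}

#' Write a marker score table
#'
#' Writes a [marker_table()] in the dialect read by [read_marker_table()].
#' Marker order and individual order are preserved exactly, so a
#' write/read round trip is the identity.
#'
#' @param table a [marker_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "marker_table"))
  sc <- matrix(as.character(table$geno), nrow = nrow(table$geno))
  sc[is.na(sc)] <- "-"
  rows <- paste(table$info$marker_id, table$info$system,
                word_to_score[table$info$parent1],
                word_to_score[table$info$parent2],
                apply(sc, 1, paste, collapse = "\t"),
                sep = "\t")
  out <- c(paste(c("#individuals:", table$individuals), collapse = "\t"), rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Parse a marker name into cross-type prefix, system code and fragment size
#'
#' Marker names concatenate a system-specific code (an AFLP primer-pair code
#' such as `E35M47`, an EST-SSR locus code such as `ESTB94`, or an
#' enzyme+primer code such as `DIsIvLI` for retrotransposon fingerprints)
#' with the fragment size in base pairs, optionally preceded by the cross
#' type (`D1-`, `D2-` or `C-`).  Because code and size are concatenated
#' without a separator, the size is taken as the maximal trailing integer
#' unless a declared locus/code list resolves the split (needed when the
#' code itself ends in digits, e.g. locus `ESTB94` allele `279` ->
#' `ESTB94279`).
#'
#' @param name marker name.
#' @param loci optional character vector of declared system/locus codes used
#'   to split code from size; the longest declared code that prefixes the
#'   name (with an all-digit remainder) wins.
#' @return A list with elements `cross_prefix` (`"D1"`, `"D2"`, `"C"` or
#'   `NA`), `system_code` and `fragment_size_bp`.
#' @export
parse_marker_name <- function(name, loci = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_("marker name must be a non-empty string")
  prefix <- NA_character_
  body <- name
  m <- regmatches(name, regexec("^(D1|D2|C)-(.+)$", name))[[1]]
  if (length(m)) {
    prefix <- m[[2]]
    body <- m[[3]]
  }
  if (!is.null(loci)) {
    loci <- loci[order(-nchar(loci))]
    for (code in loci) {
      if (startsWith(body, code)) {
        rest <- substring(body, nchar(code) + 1L)
        if (grepl("^[0-9]+$", rest)) {
          return(list(cross_prefix = prefix, system_code = code,
                      fragment_size_bp = as.integer(rest)))
        }
      }
    }
  }
  # Keygene AFLP primer-pair codes have the fixed E##M## shape and end in
  # digits themselves; split structurally before the generic fallback
  if (grepl("^E[0-9]{2}M[0-9]{2}$", body))
    stop_("'", name, "' is a bare primer-pair code with no fragment size")
  m <- regmatches(body, regexec("^(E[0-9]{2}M[0-9]{2})([0-9]+)$", body))[[1]]
  if (length(m) == 0)
    m <- regmatches(body, regexec("^(.*?)([0-9]+)$", body))[[1]]
  if (length(m) == 0 || !nzchar(m[[2]]))
    stop_("cannot parse a fragment size from '", name, "'")
  size <- as.integer(m[[3]])
  if (is.na(size) || size <= 0)
    stop_("fragment size in '", name, "' is not a positive integer")
  list(cross_prefix = prefix, system_code = m[[2]], fragment_size_bp = size)
}

#' Export an ordered map as text
#'
#' Writes either a flat TSV (`HG`, `CG`, `marker`, `position_cM`, `system`,
#' `cross_type`) or MapChart-style blocks (`group <CG>` followed by
#' `marker<TAB>position` lines) with cumulative Kosambi positions rounded to
#' two decimals.
#'
#' @param map a [linkage_map()].
#' @param path output path.
#' @param format `"tsv"` or `"mapchart"`.
#' @return `path`, invisibly.
#' @export
export_map_text <- function(map, path, format = c("tsv", "mapchart")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "linkage_map"))
  asn <- map$assignments
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    if (nrow(asn) == 0) {
      writeLines(character(0), con)
      return(invisible(path))
    }
    out <- c(paste(c("HG", "CG", "marker", "position_cM", "system",
                     "cross_type"), collapse = "\t"),
             paste(asn$hg, asn$cg, asn$marker,
                   sprintf("%.2f", asn$position_cM), asn$system,
                   asn$cross_type, sep = "\t"))
    writeLines(out, con)
  } else {
    blocks <- character(0)
    for (cg in map$cgs) {
      blocks <- c(blocks, paste("group", cg$name),
                  paste(cg$markers, sprintf("%.2f", cg$positions), sep = "\t"),
                  "")
    }
    writeLines(blocks, con)
  }
  invisible(path)
}
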