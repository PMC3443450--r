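#' Classify a marker's cross type from parental band scores
#'
#' A dominant single-dose locus is `D1` when only parent 1 carries the band
#' (simplex x nulliplex, segregating 1:1 in the F1), `D2` when only parent
#' 2 carries it, and `C` when both parents do (simplex x simplex,
#' segregating 3:1).  A band absent from both parents cannot segregate and
#' is `invalid`, as is any missing parental score.
#'
#' @param parent1_band,parent2_band `"present"`, `"absent"` or `"missing"`.
#' @return List with `cross_type` (`"D1"`, `"D2"`, `"C"` or `"invalid"`),
#'   `expected_ratio` (`"1:1"`, `"3:1"` or `NA`) and `reason` (non-`NA`
#'   only for invalid loci).
#' @export
classify_cross_type <- function(parent1_band, parent2_band) {
  ok <- c("present", "absent", "missing")
  if (!parent1_band %in% ok || !parent2_band %in% ok)
    stop_("parental band scores must be present/absent/missing")
  if (parent1_band == "missing" || parent2_band == "missing")
    return(list(cross_type = "invalid", expected_ratio = NA_character_,
                reason = "missing parental score"))
  if (parent1_band == "present" && parent2_band == "absent")
    list(cross_type = "D1", expected_ratio = "1:1", reason = NA_character_)
  else if (parent1_band == "absent" && parent2_band == "present")
    list(cross_type = "D2", expected_ratio = "1:1", reason = NA_character_)
  else if (parent1_band == "present" && parent2_band == "present")
    list(cross_type = "C", expected_ratio = "3:1", reason = NA_character_)
  else
    list(cross_type = "invalid", expected_ratio = NA_character_,
         reason = "band absent from both parents")
}

#' Pearson chi-square test of a single-dose segregation ratio
#'
#' Tests observed band-present/band-absent counts against the expected
#' 1:1 (D1/D2) or 3:1 (C) proportions with a plain 1-df Pearson chi-square
#' (no continuity correction).
#'
#' @param n_present,n_absent counts over non-missing progeny.
#' @param ratio `"1:1"` or `"3:1"`.
#' @return List with `chi2` and `p_value`.
#' @export
chisq_segregation <- function(n_present, n_absent, ratio = c("1:1", "3:1")) {
  ratio <- match.arg(ratio)
  stopifnot(is_count(n_present), is_count(n_absent))
  n <- n_present + n_absent
  if (n < 1) stop_("no scored progeny")
  p <- if (ratio == "1:1") c(0.5, 0.5) else c(0.75, 0.25)
  e <- n * p
  chi2 <- sum((c(n_present, n_absent) - e)^2 / e)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni-adjusted per-test significance level
#'
#' @param alpha_global family-wise significance level (default 0.05).
#' @param n_tests number of segregation tests performed.
#' @return List of class `bonferroni_threshold` with `alpha_global`,
#'   `n_tests` and `alpha_per_test = alpha_global / n_tests`.
#' @export
bonferroni_alpha <- function(alpha_global = 0.05, n_tests) {
  stopifnot(is.numeric(alpha_global), alpha_global > 0, alpha_global <= 1,
            is_count(n_tests), n_tests >= 1)
  structure(list(alpha_global = alpha_global, n_tests = as.integer(n_tests),
                 alpha_per_test = alpha_global / n_tests),
            class = "bonferroni_threshold")
}

#' @export
print.bonferroni_threshold <- function(x, ...) {
  cat(sprintf("Bonferroni: alpha %g over %d tests -> %.3g per test\n",
              x$alpha_global, x$n_tests, x$alpha_per_test))
  invisible(x)
}

#' Classify, test and filter single-dose markers
#'
#' Classifies every marker into D1/D2/C from the parental scores, tests its
#' segregation ratio with [chisq_segregation()] over the non-missing
#' progeny, and keeps markers whose p-value passes the Bonferroni-adjusted
#' threshold `alpha_global / n_tests`, where `n_tests` counts markers with
#' a valid cross type and at least one scored progeny.
#'
#' @param table a [marker_table()].
#' @param alpha_global family-wise significance level.
#' @return List of class `sdm_filter` with `results` (one row per marker:
#'   cross type, counts, chi-square, p-value, `kept`), `threshold` (a
#'   [bonferroni_alpha()]) and `summary` (marker counts per system:
#'   scorable, segregating, SDM and per cross type).
#' @export
filter_sdm <- function(table, alpha_global = 0.05) {
  stopifnot(inherits(table, "marker_table"))
  info <- table$info
  m <- nrow(info)
  cls <- mapply(classify_cross_type, info$parent1, info$parent2,
                SIMPLIFY = FALSE)
  cross <- vapply(cls, `[[`, character(1), "cross_type")
  ratio <- vapply(cls, `[[`, character(1), "expected_ratio")
  n_present <- rowSums(table$geno == 1L, na.rm = TRUE)
  n_absent <- rowSums(table$geno == 0L, na.rm = TRUE)
  testable <- cross != "invalid" & (n_present + n_absent) >= 1
  chi2 <- p_value <- rep(NA_real_, m)
  for (i in which(testable)) {
    ts <- chisq_segregation(n_present[i], n_absent[i], ratio[i])
    chi2[i] <- ts$chi2
    p_value[i] <- ts$p_value
  }
  n_tests <- sum(testable)
  thr <- if (n_tests >= 1) bonferroni_alpha(alpha_global, n_tests) else NULL
  kept <- testable & !is.na(p_value) &
    p_value >= (if (is.null(thr)) Inf else thr$alpha_per_test)
  results <- data.frame(
    marker_id = info$marker_id,
    system = info$system,
    cross_type = cross,
    expected_ratio = ratio,
    n_present = as.integer(n_present),
    n_absent = as.integer(n_absent),
    chi2 = chi2,
    p_value = p_value,
    kept = kept,
    stringsAsFactors = FALSE
  )
  systems <- c("AFLP", "EST_SSR", "RT")
  summary <- do.call(rbind, lapply(c(systems, "Total"), function(sys) {
    sel <- if (sys == "Total") rep(TRUE, m) else info$system == sys
    data.frame(system = sys,
               scorable = sum(sel),
               segregating = sum(sel & cross != "invalid"),
               sdm = sum(sel & kept),
               D1 = sum(sel & kept & cross == "D1"),
               D2 = sum(sel & kept & cross == "D2"),
               C = sum(sel & kept & cross == "C"))
  }))
  structure(list(results = results, threshold = thr, summary = summary),
            class = "sdm_filter")
}

#' @export
print.sdm_filter <- function(x, ...) {
  cat("Single-dose marker filter\n")
  if (!is.null(x$threshold)) print(x$threshold)
  print(x$summary, row.names = FALSE)
  invisible(x)
}
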