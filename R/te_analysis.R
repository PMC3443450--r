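#' Count target-system markers in fixed-width map bins
#'
#' Divides the map into `bin_cm` bins and counts markers of the target
#' system in each.  Bins are laid per co-segregation group from position 0
#' in half-open intervals `[k*bin, (k+1)*bin)`; a trailing partial bin
#' counts as one full bin, and the final bin is closed on the right so the
#' terminal marker (which defines the group length) is counted.  With
#' `scope = "whole_map"` the groups are concatenated and binned as one
#' axis instead.
#'
#' @param map a [linkage_map()].
#' @param target_system marker system to count (default `"RT"`).
#' @param bin_cm bin width in cM.
#' @param scope `"per_cg"` (default) or `"whole_map"`.
#' @return Object of class `marker_bins`: `counts` (all bins), `n_bins`,
#'   `detail` (per-CG data frame), plus the parameters.
#' @export
bin_markers <- function(map, target_system = "RT", bin_cm = 10,
                        scope = c("per_cg", "whole_map")) {
  scope <- match.arg(scope)
  stopifnot(inherits(map, "linkage_map"), bin_cm > 0)
  if (length(map$cgs) == 0) stop_("empty map")
  counts <- integer(0)
  detail <- list()
  if (scope == "per_cg") {
    for (cg in map$cgs) {
      len <- cg$length_cM
      nb <- max(1L, as.integer(ceiling(len / bin_cm)))
      idx <- match(cg$markers, map$assignments$marker)
      sys <- map$assignments$system[idx]
      pos <- cg$positions[sys == target_system]
      b <- pmin(floor(pos / bin_cm) + 1L, nb)
      cnt <- tabulate(b, nbins = nb)
      counts <- c(counts, cnt)
      detail[[cg$name]] <- data.frame(cg = cg$name, bin = seq_len(nb),
                                      count = cnt)
    }
  } else {
    lens <- vapply(map$cgs, `[[`, numeric(1), "length_cM")
    offset <- cumsum(c(0, head(lens, -1)))
    pos <- numeric(0)
    for (k in seq_along(map$cgs)) {
      cg <- map$cgs[[k]]
      idx <- match(cg$markers, map$assignments$marker)
      sys <- map$assignments$system[idx]
      pos <- c(pos, offset[k] + cg$positions[sys == target_system])
    }
    total <- sum(lens)
    nb <- max(1L, as.integer(ceiling(total / bin_cm)))
    counts <- tabulate(pmin(floor(pos / bin_cm) + 1L, nb), nbins = nb)
    detail <- list(data.frame(cg = "(whole map)", bin = seq_len(nb),
                              count = counts))
  }
  structure(list(counts = counts, n_bins = length(counts),
                 detail = do.call(rbind, unname(detail)),
                 target_system = target_system, bin_cm = bin_cm,
                 scope = scope),
            class = "marker_bins")
}

#' @export
print.marker_bins <- function(x, ...) {
  cat(sprintf("marker_bins: %d bins of %g cM (%s), %d %s markers\n",
              x$n_bins, x$bin_cm, x$scope, sum(x$counts), x$target_system))
  print(table(count = x$counts))
  invisible(x)
}

#' Poisson goodness-of-fit test for marker clustering
#'
#' If markers are placed at random, per-bin counts follow a Poisson
#' distribution with rate `lambda` estimated as the mean count per bin.
#' The chi-square statistic compares observed class counts (x = 0, 1, ...,
#' max observed) with `n_bins * lambda^x * exp(-lambda) / x!`; the degrees
#' of freedom are `c - 1 - 1` (number of classes minus one, minus one
#' estimated parameter).  By default no classes are pooled and the tail
#' mass beyond the largest observed count is excluded; `pool = TRUE`
#' merges the tail into a final `>= K` class with expected count at least
#' 1.
#'
#' @param counts integer vector of per-bin counts, or a [bin_markers()]
#'   result.
#' @param pool pool sparse tail classes (default `FALSE`).
#' @return Object of class `poisson_gof`: `lambda`, `n_bins`, `classes`
#'   (observed/expected per class), `chi2`, `df`, `p_value`.
#' @export
poisson_gof <- function(counts, pool = FALSE) {
  if (inherits(counts, "marker_bins")) counts <- counts$counts
  stopifnot(is.numeric(counts), all(counts >= 0),
            all(counts == floor(counts)))
  n <- length(counts)
  if (n < 1) stop_("no bins")
  lambda <- mean(counts)
  xmax <- max(counts)
  x <- 0:xmax
  obs <- tabulate(counts + 1L, nbins = xmax + 1L)
  expd <- n * dpois(x, lambda)
  if (pool) {
    # final class is ">= K" with expected mass >= 1 (Poisson tail included)
    tail_e <- n * (1 - ppois(x - 1, lambda))
    K <- xmax
    while (K > 1 && tail_e[K + 1L] < 1) K <- K - 1L
    x <- 0:K
    obs <- c(obs[seq_len(K)], sum(obs[-seq_len(K)]))
    expd <- c(expd[seq_len(K)], tail_e[K + 1L])
  }
  c_classes <- length(x)
  df <- c_classes - 2L
  if (df < 1)
    stop_("only ", c_classes, " count classes (need >= 3 for df >= 1); ",
          if (pool) "the pooling merged too many classes"
          else "check the pool option and the bin width")
  chi2 <- sum((obs - expd)^2 / expd)
  structure(list(lambda = lambda, n_bins = n,
                 classes = data.frame(x = x, observed = obs,
                                      expected = expd),
                 chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 pooled = pool),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf(
    "Poisson goodness of fit: lambda = %.4f over %d bins\nchi2 = %.3f, df = %d, p = %.3g\n",
    x$lambda, x$n_bins, x$chi2, x$df, x$p_value))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Call clusters of adjacent target-system markers
#'
#' Within each co-segregation group, takes the target-system markers in
#' map order (markers of other systems in between are ignored) and calls
#' maximal runs of two or more markers whose every consecutive gap is
#' strictly below `max_gap_cm`.
#'
#' @inheritParams bin_markers
#' @param max_gap_cm maximum (strict) adjacent gap in cM (default 5).
#' @return Data frame with one row per cluster: `cluster`, `cg`, `hg`,
#'   `markers` (comma-separated, map order), `n_markers`, `span_cM`,
#'   `start_cM`, `end_cM`.
#' @export
call_clusters <- function(map, target_system = "RT", max_gap_cm = 5) {
  stopifnot(inherits(map, "linkage_map"), max_gap_cm > 0)
  out <- list()
  for (cg in map$cgs) {
    idx <- match(cg$markers, map$assignments$marker)
    sel <- map$assignments$system[idx] == target_system
    if (sum(sel) < 2) next
    ids <- cg$markers[sel]
    pos <- cg$positions[sel]
    gap_ok <- diff(pos) < max_gap_cm
    run_id <- cumsum(c(0, !gap_ok))
    hg <- map$assignments$hg[idx][sel][1]
    for (run in split(seq_along(ids), run_id)) {
      if (length(run) < 2) next
      out[[length(out) + 1L]] <- data.frame(
        cg = cg$name, hg = hg,
        markers = paste(ids[run], collapse = ","),
        n_markers = length(run),
        span_cM = pos[run[length(run)]] - pos[run[1]],
        start_cM = pos[run[1]], end_cM = pos[run[length(run)]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(cluster = integer(0), cg = character(0),
                      hg = character(0), markers = character(0),
                      n_markers = integer(0), span_cM = numeric(0),
                      start_cM = numeric(0), end_cM = numeric(0)))
  res <- do.call(rbind, out)
  cbind(cluster = seq_len(nrow(res)), res)
}

#' Retrotransposon copy number from fingerprint band counts
#'
#' Each enzyme-primer combination fingerprints (nearly) every genomic copy
#' of the target element once, so the total number of amplified fragments
#' divided by the number of combinations estimates the copy number.
#'
#' @param total_fragments total band count over all combinations.
#' @param n_combinations number of enzyme-primer combinations.
#' @return Object of class `copy_number_estimate`: `total_fragments`,
#'   `n_combinations`, `estimate_raw`, `estimate_rounded` (half-up).
#' @export
copy_number <- function(total_fragments, n_combinations) {
  stopifnot(is_count(total_fragments), total_fragments >= 1,
            is_count(n_combinations), n_combinations >= 1)
  raw <- total_fragments / n_combinations
  structure(list(total_fragments = as.integer(total_fragments),
                 n_combinations = as.integer(n_combinations),
                 estimate_raw = raw,
                 estimate_rounded = as.integer(floor(raw + 0.5))),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("copy number: %d fragments / %d combinations = %.2f (~%d copies)\n",
              x$total_fragments, x$n_combinations, x$estimate_raw,
              x$estimate_rounded))
  invisible(x)
}
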