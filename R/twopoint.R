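PAIR_CLASSES <- c("D1xD1", "D2xD2", "CxC", "D1xC", "D2xC", "D1xD2")

phases_for_class <- function(pair_class) {
  switch(pair_class,
         D1xD1 = ,
         D2xD2 = ,
         D1xC = ,
         D2xC = c("coupling", "repulsion"),
         CxC = c("coupling-coupling", "coupling-repulsion",
                 "repulsion-coupling", "repulsion-repulsion"),
         D1xD2 = NA_character_,
         stop_("unknown pair class '", pair_class, "'"))
}

phase_components <- function(pair_class, phase) {
  if (is.na(phase)) return(c(NA_character_, NA_character_))
  switch(pair_class,
         D1xD1 = c(phase, NA_character_),
         D2xD2 = c(NA_character_, phase),
         D1xC = c(phase, NA_character_),
         D2xC = c(NA_character_, phase),
         CxC = strsplit(phase, "-", fixed = TRUE)[[1]],
         c(NA_character_, NA_character_))
}

# joint band-pattern probabilities, vectorized over r; both parental
# meioses share one recombination fraction (integrated-map convention)
pair_probs <- function(pair_class, phase, r) {
  s <- 1 - r
  switch(paste(pair_class, phase, sep = "|"),
    "D1xD1|coupling" = ,
    "D2xD2|coupling" = list(p11 = s / 2, p10 = r / 2, p01 = r / 2, p00 = s / 2),
    "D1xD1|repulsion" = ,
    "D2xD2|repulsion" = list(p11 = r / 2, p10 = s / 2, p01 = s / 2, p00 = r / 2),
    "CxC|coupling-coupling" = list(p11 = (2 + s^2) / 4, p10 = (1 - s^2) / 4,
                                   p01 = (1 - s^2) / 4, p00 = s^2 / 4),
    "CxC|coupling-repulsion" = ,
    "CxC|repulsion-coupling" = list(p11 = 0.5 + s * r / 4,
                                    p10 = 0.25 - s * r / 4,
                                    p01 = 0.25 - s * r / 4, p00 = s * r / 4),
    "CxC|repulsion-repulsion" = list(p11 = 0.5 + r^2 / 4,
                                     p10 = 0.25 - r^2 / 4,
                                     p01 = 0.25 - r^2 / 4, p00 = r^2 / 4),
    "D1xC|coupling" = ,
    "D2xC|coupling" = list(p11 = 0.5 - r / 4, p10 = r / 4,
                           p01 = 0.5 - s / 4, p00 = s / 4),
    "D1xC|repulsion" = ,
    "D2xC|repulsion" = list(p11 = 0.5 - s / 4, p10 = s / 4,
                            p01 = 0.5 - r / 4, p00 = r / 4),
    "D1xD2|NA" = ,
    "D1xD2|n/a" = {
      one <- rep(0.25, length(r))
      list(p11 = one, p10 = one, p01 = one, p00 = one)
    },
    stop_("no such pair class / phase: ", pair_class, " / ", phase)
  )
}

#' Joint band-pattern probabilities for a marker pair
#'
#' Probability of each of the four joint band patterns `(1,1)`, `(1,0)`,
#' `(0,1)`, `(0,0)` for a pair of single-dose markers, given the pair's
#' cross-type class, relative linkage phase and recombination fraction `r`.
#' Both parental meioses are independent with the same `r`; each parent
#' transmits one of its two homologs, recombinant between the loci with
#' probability `r`, and the single-dose model maps transmissions to bands
#' (D1 via parent 1, D2 via parent 2, C via either parent).
#'
#' @param pair_class one of `"D1xD1"`, `"D2xD2"`, `"CxC"`, `"D1xC"`,
#'   `"D2xC"`, `"D1xD2"`.
#' @param phase relative phase: `"coupling"`/`"repulsion"` for classes with
#'   one informative parent, `"coupling-coupling"` etc. (parent 1 then
#'   parent 2) for `"CxC"`; ignored for the uninformative `"D1xD2"`.
#' @param r recombination fraction in `[0, 0.5]`.
#' @return Named numeric of length 4 (`p11`, `p10`, `p01`, `p00`) summing
#'   to 1.
#' @export
joint_pattern_probs <- function(pair_class, phase, r) {
  pair_class <- match.arg(pair_class, PAIR_CLASSES)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 0.5)
    stop_("r must be a single value in [0, 0.5]")
  if (pair_class == "D1xD2") phase <- NA_character_
  if (!is.na(phase)) phase <- match.arg(phase, phases_for_class(pair_class))
  p <- pair_probs(pair_class, if (is.na(phase)) "NA" else phase, r)
  c(p11 = p$p11, p10 = p$p10, p01 = p$p01, p00 = p$p00)
}

pair_loglik <- function(pair_class, phase, r, n11, n10, n01, n00) {
  p <- pair_probs(pair_class, phase, r)
  xlogp(n11, p$p11) + xlogp(n10, p$p10) + xlogp(n01, p$p01) +
    xlogp(n00, p$p00)
}

# vectorized golden-section maximization of f on [0, 0.5]; endpoints and
# an optional closed-form candidate are compared explicitly
golden_rf <- function(f, len, extra = NULL, iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- rep(0, len)
  b <- rep(0.5, len)
  cc <- b - gr * (b - a)
  d <- a + gr * (b - a)
  fc <- f(cc)
  fd <- f(d)
  for (i in seq_len(iter)) {
    left <- fc >= fd
    b <- ifelse(left, d, b)
    a <- ifelse(left, a, cc)
    cc <- b - gr * (b - a)
    d <- a + gr * (b - a)
    fc <- f(cc)
    fd <- f(d)
  }
  x <- (a + b) / 2
  fx <- f(x)
  cand <- cbind(x = x, fx = fx)
  for (e in c(list(rep(0, len), rep(0.5, len)), extra)) {
    fe <- f(e)
    better <- fe > cand[, "fx"]
    cand[better, "x"] <- e[better]
    cand[better, "fx"] <- fe[better]
  }
  list(rf = cand[, "x"], loglik = cand[, "fx"])
}

# maximize the pair likelihood over r for one class+phase, vectorized over
# pairs; closed forms for the D-type classes, golden section otherwise
max_rf_vec <- function(pair_class, phase, n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  f <- function(r) pair_loglik(pair_class, phase, r, n11, n10, n01, n00)
  if (pair_class %in% c("D1xD1", "D2xD2")) {
    rec <- if (phase == "coupling") n10 + n01 else n11 + n00
    rf <- clamp(rec / n, 0, 0.5)
    list(rf = rf, loglik = f(rf))
  } else {
    golden_rf(f, length(n11))
  }
}

#' Two-point maximum-likelihood estimate for one marker pair
#'
#' Maximizes the multinomial likelihood of the four joint band-pattern
#' counts over the recombination fraction `r` in `[0, 0.5]` for every
#' admissible linkage phase, picks the phase with the highest maximized
#' likelihood (ties broken toward coupling, the configuration that
#' dominates single-dose polyploid data), and reports the LOD score
#' against free recombination (`r = 0.5`).
#'
#' @param counts numeric vector `(n11, n10, n01, n00)` of joint pattern
#'   counts over pairwise-complete individuals.
#' @param pair_class see [joint_pattern_probs()].  `"D1xD2"` pairs carry no
#'   two-point information and return a noninformative estimate.
#' @return List of class `pair_estimate`: `pair_class`, `rf`, `phase`,
#'   `phase_p1`, `phase_p2`, `loglik`, `LOD`, `n`.
#' @export
estimate_pair <- function(counts, pair_class) {
  pair_class <- match.arg(pair_class, PAIR_CLASSES)
  stopifnot(is.numeric(counts), length(counts) == 4, all(counts >= 0))
  n11 <- counts[[1]]; n10 <- counts[[2]]
  n01 <- counts[[3]]; n00 <- counts[[4]]
  n <- sum(counts)
  if (pair_class == "D1xD2") {
    return(structure(list(pair_class = pair_class, rf = NA_real_,
                          phase = NA_character_, phase_p1 = NA_character_,
                          phase_p2 = NA_character_, loglik = NA_real_,
                          LOD = NA_real_, n = n, informative = FALSE),
                     class = "pair_estimate"))
  }
  if (n < 1) stop_("no jointly scored individuals")
  best <- NULL
  for (phase in phases_for_class(pair_class)) {
    fit <- max_rf_vec(pair_class, phase, n11, n10, n01, n00)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) {
      best <- list(phase = phase, rf = unname(fit$rf),
                   loglik = unname(fit$loglik))
    }
  }
  ll0 <- pair_loglik(pair_class, phases_for_class(pair_class)[1], 0.5,
                     n11, n10, n01, n00)
  pc <- phase_components(pair_class, best$phase)
  structure(list(pair_class = pair_class, rf = best$rf, phase = best$phase,
                 phase_p1 = pc[1], phase_p2 = pc[2], loglik = best$loglik,
                 LOD = max(0, (best$loglik - ll0) / log(10)), n = n,
                 informative = TRUE),
            class = "pair_estimate")
}

#' @export
print.pair_estimate <- function(x, ...) {
  if (!x$informative) {
    cat("pair_estimate:", x$pair_class, "(noninformative)\n")
  } else {
    cat(sprintf("pair_estimate: %s  rf = %.4f  phase = %s  LOD = %.2f (n = %d)\n",
                x$pair_class, x$rf, x$phase, x$LOD, as.integer(x$n)))
  }
  invisible(x)
}

#' Two-point estimates for all informative marker pairs
#'
#' Computes, for every unordered pair of kept single-dose markers, the
#' maximum-likelihood recombination fraction, best linkage phase and LOD
#' score, using pairwise-complete observations.  D1 x D2 pairs (no shared
#' informative parent) are reported as noninformative rows.
#'
#' @param filter an [filter_sdm()] result (or a data frame with columns
#'   `marker_id`, `cross_type`, `kept`).
#' @param table the [marker_table()] the filter was computed from.
#' @return A data frame of class `pair_estimates` with columns `marker_a`,
#'   `marker_b`, `pair_class`, `phase`, `phase_p1`, `phase_p2`, `rf`,
#'   `LOD`, `loglik`, `n`.
#' @export
all_pairs <- function(filter, table) {
  res <- if (inherits(filter, "sdm_filter")) filter$results else filter
  stopifnot(inherits(table, "marker_table"))
  keep <- res$marker_id[res$kept]
  if (length(keep) < 2) stop_("need at least 2 kept markers")
  cross <- res$cross_type[match(keep, res$marker_id)]
  g <- table$geno[match(keep, table$info$marker_id), , drop = FALSE]
  A1 <- (g == 1L); A1[is.na(A1)] <- FALSE; storage.mode(A1) <- "double"
  A0 <- (g == 0L); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  N11 <- tcrossprod(A1)
  N10 <- tcrossprod(A1, A0)
  N00 <- tcrossprod(A0)
  ut <- which(upper.tri(N11), arr.ind = TRUE)
  I <- ut[, 1]; J <- ut[, 2]
  n11 <- N11[ut]; n10 <- N10[ut]
  n01 <- t(N10)[ut]; n00 <- N00[ut]

  key <- paste(cross[I], cross[J], sep = "x")
  map <- c(D1xD1 = "D1xD1", D2xD2 = "D2xD2", CxC = "CxC",
           D1xC = "D1xC", CxD1 = "D1xC", D2xC = "D2xC", CxD2 = "D2xC",
           D1xD2 = "D1xD2", D2xD1 = "D1xD2")
  cls <- unname(map[key])
  swapped <- key %in% c("CxD1", "CxD2")
  # canonicalize (a, b) roles: a is the D-type marker for mixed classes
  tmp <- n10[swapped]; n10[swapped] <- n01[swapped]; n01[swapped] <- tmp

  n <- n11 + n10 + n01 + n00
  rf <- LOD <- loglik <- rep(NA_real_, length(I))
  phase <- rep(NA_character_, length(I))
  for (pc in setdiff(unique(cls), "D1xD2")) {
    sel <- which(cls == pc & n >= 1)
    if (length(sel) == 0) next
    bl <- rep(-Inf, length(sel))
    brf <- rep(NA_real_, length(sel))
    bph <- rep(NA_character_, length(sel))
    for (ph in phases_for_class(pc)) {
      fit <- max_rf_vec(pc, ph, n11[sel], n10[sel], n01[sel], n00[sel])
      better <- fit$loglik > bl + 1e-12
      bl[better] <- fit$loglik[better]
      brf[better] <- fit$rf[better]
      bph[better] <- ph
    }
    ll0 <- pair_loglik(pc, phases_for_class(pc)[1], 0.5,
                       n11[sel], n10[sel], n01[sel], n00[sel])
    rf[sel] <- brf
    loglik[sel] <- bl
    LOD[sel] <- pmax(0, (bl - ll0) / log(10))
    phase[sel] <- bph
  }
  comp <- t(vapply(seq_along(cls), function(k)
    phase_components(cls[k], phase[k]), character(2)))
  out <- data.frame(
    marker_a = keep[I], marker_b = keep[J],
    pair_class = cls, phase = phase,
    phase_p1 = comp[, 1], phase_p2 = comp[, 2],
    rf = rf, LOD = LOD, loglik = loglik, n = as.integer(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_estimates", class(out))
  out
}
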