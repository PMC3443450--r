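clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# x * log(p) with the 0 * log(0) = 0 convention of multinomial likelihoods
xlogp <- function(x, p) {
  out <- x * log(p)
  out[x == 0] <- 0
  out
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

stop_ <- function(...) stop(..., call. = FALSE)

# canonical unordered-pair key for phase lookups
pair_key <- function(a, b) {
  swap <- a > b
  ifelse(swap, paste(b, a, sep = "\r"), paste(a, b, sep = "\r"))
}
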