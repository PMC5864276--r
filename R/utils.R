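# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count events in a half-open window [lo, hi)
#' @noRd
count_in_window <- function(times, lo, hi) {
  sum(times >= lo & times < hi)
}

#' Derive a reproducible sub-seed from a master seed and a component tag
#'
#' Mixes the master seed and a hash of the tag through three
#' multiplicative-congruential rounds so that related tags (e.g.
#' "unit_1", "unit_2", ...) yield well-scattered seeds: seeds in
#' arithmetic progression can produce correlated Mersenne-Twister
#' streams. All arithmetic stays below 2^53 (exact in doubles) and the
#' result lies in [1, 2^31 - 2], a valid R seed.
#' @noRd
derive_seed <- function(master, tag) {
  m <- 2147483647
  h <- 17
  for (c in utf8ToInt(tag)) h <- (h * 131 + c) %% m
  x <- (abs(as.numeric(master)) + 1) %% m
  x <- (x * 48271 + h) %% m
  x <- (x * 69621 + 113) %% m
  x <- (x * 48271 + h) %% m
  as.integer(x %% 2147483645 + 1)
}

#' Evaluate an expression under a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rank-normalize a numeric vector to approximate standard-normal scores
#'
#' z = qnorm((rank - 0.5) / n), average ranks for ties. Scale-free: depends
#' on the ordering only.
#' @noRd
rank_normalize <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

stop_validation <- function(...) {
  stop(structure(class = c("vpcue_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
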