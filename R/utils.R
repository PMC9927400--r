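#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' run seed so that stages stay reproducible independently of each other.
#' The derived seed always fits a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param stage character stage tag.
#' @param index optional integer sub-index (e.g. lesion number).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  h <- (h * 131071 + as.numeric(index) * 524287 + 17) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Hash a configuration object
#'
#' @param x any R object (typically a config list).
#' @return character hash; changes iff any parameter changes.
#' @export
config_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' The 13 unique 3D direction offsets
#'
#' Half of the 26 neighbourhood offsets, one per axis pair, used to aggregate
#' co-occurrence and run-length counts.
#'
#' @return integer matrix with columns (dx, dy, dz).
#' @export
directions_13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  # keep lexicographically positive half (dz, then dy, then dx)
  keep <- d[, 3] > 0 |
    (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  storage.mode(d) <- "integer"
  unname(d[keep, , drop = FALSE])
}
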