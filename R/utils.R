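# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user-supplied seed. Stages
#' (corpus generation, signature draws, bootstraps, MCMC) each draw their own
#' seed from the master seed with this function so that re-running a single
#' stage with the same master seed reproduces it exactly, independently of
#' the other stages.
#'
#' @param seed master integer seed.
#' @param stage character tag naming the consuming stage.
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "signatures")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small multiplicative hash of the stage tag, folded into the seed
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed` (NULL = use current
# stream), restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Exact bootstrap of the mean of a 0/1 vector: the resample mean is
# Binomial(n, phat)/n, so we draw from that law directly instead of
# materialising B x n resamples.
boot_binary_mean <- function(x, B, seed = NULL) {
  stopifnot(length(x) >= 1L, all(x %in% c(0, 1)))
  with_seed(seed, rbinom(B, length(x), mean(x)) / length(x))
}

percentile_ci <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split "a;b;c" into a unique token vector; NA / "" -> character(0)
split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  unique(trimws(strsplit(x, ";", fixed = TRUE)[[1L]]))
}

join_tokens <- function(x) paste(x, collapse = ";")

# case-folded, whitespace-stripped key used to match claims to signatures
normalize_key <- function(x) tolower(gsub("\\s+", "", x))

dgi_key <- function(drug, gene) paste(normalize_key(drug), normalize_key(gene), sep = "\r")
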