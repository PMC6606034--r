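# Combining per-condition moderated z-scores into one effect per drug-gene
# interaction, with a bootstrap CI that defines "generalized" interactions,
# and the coefficient of variation across experimental conditions.

#' Combine moderated z-scores into a single effect
#'
#' Classical Stouffer combination `sum(z) / sqrt(k)` of the per-condition
#' moderated z-scores of one drug-gene interaction. Its sign is the
#' experimental effect direction. `method = "mean"` divides by `k` instead;
#' this changes only the scale, never the sign, so replication-direction
#' results are invariant to the choice.
#'
#' @param zs numeric vector of finite z-scores, length `k >= 1`.
#' @param method `"stouffer"` (default) or `"mean"`.
#' @return the combined z (scalar).
#' @export
#' @examples
#' combine_z(c(1, 1, 1, 1)) # 2
combine_z <- function(zs, method = c("stouffer", "mean")) {
  method <- match.arg(method)
  if (length(zs) == 0L) stop("combine_z: empty z-score vector", call. = FALSE)
  if (!all(is.finite(zs))) stop("combine_z: non-finite z-score(s)", call. = FALSE)
  s <- sum(zs)
  if (method == "stouffer") s / sqrt(length(zs)) else s / length(zs)
}

#' Percentile bootstrap CI for the combined z-score
#'
#' Resamples the z-score vector with replacement (same size `k`) `B` times,
#' recomputes the combined z for each resample, and returns the equal-tailed
#' percentile interval. Resampling pools all conditions (cell lines, doses,
#' durations).
#'
#' @inheritParams combine_z
#' @param B number of bootstrap iterations (default 10000).
#' @param level interval coverage (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_combined_ci <- function(zs, B = 10000, level = 0.95, seed = NULL,
                                  method = c("stouffer", "mean")) {
  method <- match.arg(method)
  if (length(zs) == 0L) stop("bootstrap_combined_ci: empty z-score vector", call. = FALSE)
  if (!all(is.finite(zs))) stop("bootstrap_combined_ci: non-finite z-score(s)", call. = FALSE)
  stopifnot(B >= 1)
  k <- length(zs)
  denom <- if (method == "stouffer") sqrt(k) else k
  draws <- with_seed(seed, {
    m <- matrix(sample(zs, B * k, replace = TRUE), nrow = B, ncol = k)
    rowSums(m) / denom
  })
  percentile_ci(draws, level)
}

#' Does an interaction generalize across experimental conditions?
#'
#' An interaction is *generalized* when the bootstrap 95% CI of its combined
#' z-score excludes 0, i.e. the effect direction is consistent across cell
#' lines, doses and durations.
#'
#' @param ci95 numeric `c(lo, hi)`.
#' @return logical.
#' @export
is_generalized <- function(ci95) {
  stopifnot(length(ci95) == 2L, ci95[1] <= ci95[2])
  ci95[1] > 0 || ci95[2] < 0
}

#' Coefficient of variation of a DGI's z-scores
#'
#' `CV = sd(z) / |mean(z)|` with the sample (k-1) standard deviation: a
#' normalized measure of how variable an interaction is across experimental
#' conditions. A single z-score gives CV 0; a mean within `eps` of zero makes
#' the ratio unstable — both cases are flagged in the `"unstable"` attribute.
#'
#' @inheritParams combine_z
#' @param eps near-zero-mean guard (default `1e-8`).
#' @return non-negative scalar with logical attribute `"unstable"`.
#' @export
coefficient_of_variation <- function(zs, eps = 1e-8) {
  if (length(zs) == 0L) stop("coefficient_of_variation: empty z-score vector", call. = FALSE)
  if (length(zs) == 1L) return(structure(0, unstable = TRUE))
  m <- abs(mean(zs))
  if (m < eps) {
    return(structure(sd(zs) / eps, unstable = TRUE))
  }
  structure(sd(zs) / m, unstable = FALSE)
}

#' Combined-signature table for a whole corpus
#'
#' Applies [combine_z()], [bootstrap_combined_ci()], [is_generalized()] and
#' [coefficient_of_variation()] to every `(drug, gene)` key present in the
#' corpus signature table.
#'
#' @param corpus a `claim_corpus`.
#' @param B bootstrap iterations per interaction.
#' @param level CI coverage.
#' @param seed integer seed; each interaction draws a derived sub-seed.
#' @param method combination rule, see [combine_z()].
#' @return data frame with one row per interaction:
#'   `drug, gene, Z, lo, hi, k, generalized, cv, cv_unstable`.
#' @export
combine_signatures <- function(corpus, B = 10000, level = 0.95, seed = NULL,
                               method = c("stouffer", "mean")) {
  method <- match.arg(method)
  s <- corpus$signatures
  key <- dgi_key(s$drug, s$gene)
  idx <- split(seq_len(nrow(s)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(drug = s$drug[first], gene = s$gene[first],
                    stringsAsFactors = FALSE)
  res <- lapply(seq_along(idx), function(i) {
    zs <- s$z[idx[[i]]]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, names(idx)[i])
    ci <- bootstrap_combined_ci(zs, B = B, level = level, seed = sub_seed,
                                method = method)
    cv <- coefficient_of_variation(zs)
    c(Z = combine_z(zs, method), lo = ci[1], hi = ci[2], k = length(zs),
      generalized = as.numeric(is_generalized(ci)), cv = as.numeric(cv),
      cv_unstable = as.numeric(attr(cv, "unstable")))
  })
  m <- do.call(rbind, res)
  out <- cbind(out, as.data.frame(m))
  out$k <- as.integer(out$k)
  out$generalized <- as.logical(out$generalized)
  out$cv_unstable <- as.logical(out$cv_unstable)
  rownames(out) <- NULL
  out
}
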