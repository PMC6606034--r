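# Replication indicator, observed replication rate with bootstrap CI,
# permutation-null baseline, and the relative replication increase (RRI).

#' Replication indicator for claims
#'
#' A claim is replicated (`R = 1`) when the sign of the combined experimental
#' z-score matches the claimed direction: `increase` with `Z > 0` or
#' `decrease` with `Z < 0`. `Z = 0` (possible only in degenerate fixtures) is
#' scored as non-replication and flagged in the `"tie"` attribute.
#'
#' @param direction character vector in `{"increase", "decrease"}`.
#' @param Z numeric vector of combined z-scores, recycled against `direction`.
#' @return integer 0/1 vector with logical attribute `"tie"`.
#' @export
#' @examples
#' replication_indicator(c("increase", "decrease"), c(2.3, 2.3)) # 1 0
replication_indicator <- function(direction, Z) {
  stopifnot(all(direction %in% c("increase", "decrease")))
  if (length(direction) != length(Z)) {
    if (length(Z) == 1L) Z <- rep(Z, length(direction))
    else stop("direction and Z lengths differ", call. = FALSE)
  }
  tie <- Z == 0
  r <- as.integer((direction == "increase" & Z > 0) |
                    (direction == "decrease" & Z < 0))
  structure(r, tie = tie)
}

#' Observed replication rate with bootstrap CI
#'
#' The proportion of replicated claims, with a percentile CI over `B`
#' bootstrap resamples of the replication vector. The resample mean of a 0/1
#' vector is exactly `Binomial(n, phat)/n`, which is drawn directly.
#'
#' @param R binary replication vector.
#' @param B bootstrap iterations (default 100000).
#' @param level CI coverage.
#' @param seed optional integer seed.
#' @return list with `rate`, `ci` (lo, hi), `n`, and `draws` (the bootstrap
#'   replication-rate draws, used when pairing with a permutation null).
#' @export
observed_rr <- function(R, B = 100000, level = 0.95, seed = NULL) {
  if (length(R) == 0L) stop("observed_rr: empty replication vector", call. = FALSE)
  stopifnot(all(R %in% c(0, 1)), B >= 1)
  draws <- boot_binary_mean(R, B, seed)
  list(rate = mean(R), ci = percentile_ci(draws, level), n = length(R),
       draws = draws)
}

#' Permutation-null baseline replication rate
#'
#' Randomly re-matches claimed directions to combined z-scores: for each of
#' `P` permutations of the `Z` vector the mean replication indicator is
#' recorded. The mean of this permutation distribution is the baseline rate
#' `RR_rand`; its percentile interval quantifies its spread. The baseline
#' corrects for direction/sign imbalance: with fraction `p` of directions
#' "increase" and fraction `q` of positive z-scores the expected baseline is
#' `p*q + (1-p)*(1-q)`.
#'
#' @param direction character vector in `{"increase", "decrease"}`.
#' @param Z numeric vector of combined z-scores, same length.
#' @param P number of permutations (default 100000).
#' @param level CI coverage.
#' @param seed optional integer seed.
#' @return list with `rate`, `ci`, `n`, `draws` (per-permutation rates).
#' @export
random_rr <- function(direction, Z, P = 100000, level = 0.95, seed = NULL) {
  stopifnot(all(direction %in% c("increase", "decrease")), P >= 1)
  if (length(direction) != length(Z)) {
    stop("random_rr: direction and Z lengths differ", call. = FALSE)
  }
  inc <- direction == "increase"
  zs <- sign(Z)  # 0 never matches either direction
  draws <- with_seed(seed, {
    vapply(seq_len(P), function(i) {
      zp <- zs[sample.int(length(zs))]
      mean((inc & zp > 0) | (!inc & zp < 0))
    }, numeric(1))
  })
  list(rate = mean(draws), ci = percentile_ci(draws, level), n = length(Z),
       draws = draws)
}

#' Relative replication increase (RRI)
#'
#' Percentage increase of the observed replication rate over the
#' permutation-null baseline: `100 * (RR_obs - RR_rand) / RR_rand`.
#'
#' @param rr_obs observed rate (scalar or draws).
#' @param rr_rand baseline rate (scalar or draws), must be positive.
#' @return percentage (vectorized over draws).
#' @export
#' @examples
#' rri(0.75, 0.5) # 50
rri <- function(rr_obs, rr_rand) {
  if (any(rr_rand <= 0)) stop("rri: RR_rand must be > 0", call. = FALSE)
  100 * (rr_obs - rr_rand) / rr_rand
}

#' Replication-rate summary for one claim subset
#'
#' Computes `RR_obs` (bootstrap CI), `RR_rand` (permutation CI) and the RRI
#' with a CI formed by pairing bootstrap draws of the observed rate with
#' permutation draws of the baseline (ratio of paired draws, percentile
#' interval).
#'
#' @inheritParams random_rr
#' @param B bootstrap iterations for `RR_obs`.
#' @param label subset label carried into the result.
#' @return one-row data frame: `subset, n, rr_obs, rr_obs_lo, rr_obs_hi,
#'   rr_rand, rr_rand_lo, rr_rand_hi, rri, rri_lo, rri_hi`.
#' @export
replication_rates <- function(direction, Z, B = 10000, P = 10000,
                              level = 0.95, seed = NULL, label = "all") {
  R <- replication_indicator(direction, Z)
  obs <- observed_rr(R, B = B, level = level,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, "obs"))
  rnd <- random_rr(direction, Z, P = P, level = level,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "rand"))
  if (rnd$rate > 0) {
    m <- min(length(obs$draws), length(rnd$draws))
    rri_draws <- rri(obs$draws[seq_len(m)], pmax(rnd$draws[seq_len(m)], 1e-12))
    rri_ci <- percentile_ci(rri_draws, level)
    rri_pt <- rri(obs$rate, rnd$rate)
  } else {
    # degenerate subset (baseline never matches): RRI undefined
    rri_ci <- c(NA_real_, NA_real_)
    rri_pt <- NA_real_
  }
  data.frame(subset = label, n = length(Z),
             rr_obs = obs$rate, rr_obs_lo = obs$ci[1], rr_obs_hi = obs$ci[2],
             rr_rand = rnd$rate, rr_rand_lo = rnd$ci[1], rr_rand_hi = rnd$ci[2],
             rri = rri_pt, rri_lo = rri_ci[1], rri_hi = rri_ci[2],
             stringsAsFactors = FALSE)
}

#' Replication summary across corpus subsets
#'
#' Reproduces the standard subset layout: the whole corpus, generalized and
#' non-generalized interactions, and the five literature-support classes
#' (restricted to generalized interactions for the class rows is *not* done
#' here; rows are the plain class subsets).
#'
#' @param evaluation a per-claim data frame with columns `direction`, `Z`,
#'   `generalized`, `support_class` (as produced by the pipeline).
#' @param B,P,level,seed as in [replication_rates()].
#' @return data frame, one row per subset; subsets with no claims are
#'   omitted.
#' @export
replication_summary <- function(evaluation, B = 10000, P = 10000,
                                level = 0.95, seed = NULL) {
  subsets <- c(list(all = rep(TRUE, nrow(evaluation)),
                    generalized = evaluation$generalized,
                    non_generalized = !evaluation$generalized),
               setNames(lapply(support_classes,
                               function(cl) evaluation$support_class == cl),
                        support_classes))
  rows <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    if (!any(sel)) return(NULL)
    replication_rates(evaluation$direction[sel], evaluation$Z[sel],
                      B = B, P = P, level = level,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, nm),
                      label = nm)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
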