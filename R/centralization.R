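# Centralization of the research community around a claim: the Gini
# coefficient (and Lorenz curve) of the papers-per-author distribution in
# the claim's bipartite author-paper network.

#' Papers-per-author counts for one claim
#'
#' For each author appearing on at least one of the claim's papers, the
#' number of those papers they co-author — the degree sequence of the author
#' side of the bipartite author-paper network.
#'
#' @param corpus a `claim_corpus`.
#' @param claim_id claim with at least two papers.
#' @return named integer vector (names are author ids).
#' @export
author_paper_counts <- function(corpus, claim_id) {
  f <- corpus$findings[corpus$findings$claim_id == claim_id, , drop = FALSE]
  ids <- unique(f$paper_id)
  if (length(ids) < 2L) {
    stop("claim ", claim_id, " has fewer than 2 papers: ",
         "centralization is undefined", call. = FALSE)
  }
  auth <- unlist(corpus$papers$authors[match(ids, corpus$papers$paper_id)])
  tab <- table(auth)
  setNames(as.integer(tab), names(tab))
}

#' Gini coefficient of a count vector
#'
#' Relative mean absolute difference
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`: 0 when all authors contribute
#' equally, rising towards 1 as authorship concentrates on few investigators.
#' `corrected = TRUE` applies the small-sample factor `n / (n - 1)`.
#'
#' @param counts non-empty vector of positive numbers.
#' @param corrected apply the small-sample correction (default `FALSE`).
#' @return scalar in `[0, 1)` (uncorrected).
#' @export
#' @examples
#' gini(c(3, 1, 1, 1)) # 0.25
gini <- function(counts, corrected = FALSE) {
  if (length(counts) == 0L) stop("gini: empty count vector", call. = FALSE)
  stopifnot(all(counts > 0))
  n <- length(counts)
  g <- sum(abs(outer(counts, counts, "-"))) / (2 * n^2 * mean(counts))
  if (corrected && n > 1L) g <- g * n / (n - 1)
  g
}

#' Lorenz curve of a count vector
#'
#' Sorts the counts ascending and accumulates shares: point `i` is the
#' cumulative share of authors against the cumulative share of authorships.
#' The curve starts at (0, 0), ends at (1, 1), and its area links back to the
#' Gini coefficient (`gini ~ 1 - 2 * area` up to the `1/n` discretization of
#' the trapezoidal area).
#'
#' @inheritParams gini
#' @return data frame with columns `p` (share of authors) and `L`
#'   (share of authorships), starting at (0, 0).
#' @export
lorenz <- function(counts) {
  if (length(counts) == 0L) stop("lorenz: empty count vector", call. = FALSE)
  stopifnot(all(counts > 0))
  x <- sort(counts)
  data.frame(p = c(0, seq_along(x) / length(x)),
             L = c(0, cumsum(x) / sum(x)))
}

#' Plot a Lorenz curve
#'
#' @param counts passed to [lorenz()].
#' @param ... further arguments to [graphics::plot()].
#' @return the Lorenz points, invisibly.
#' @export
plot_lorenz <- function(counts, ...) {
  lc <- lorenz(counts)
  plot(lc$p, lc$L, type = "l", xlab = "cumulative share of authors",
       ylab = "cumulative share of authorships", xlim = c(0, 1), ylim = c(0, 1),
       ...)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(lc)
}

#' Centralization table for all multi-paper claims
#'
#' @param corpus a `claim_corpus`.
#' @param corrected passed to [gini()].
#' @return data frame `claim_id, gini, n_authors, n_papers`.
#' @export
centralization_table <- function(corpus, corrected = FALSE) {
  n_papers <- tapply(corpus$findings$paper_id, corpus$findings$claim_id,
                     function(p) length(unique(p)))
  ids <- names(n_papers)[n_papers >= 2]
  rows <- lapply(ids, function(cid) {
    cnt <- author_paper_counts(corpus, cid)
    data.frame(claim_id = cid, gini = gini(cnt, corrected = corrected),
               n_authors = length(cnt), n_papers = as.integer(n_papers[[cid]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame(claim_id = character(0),
                                              gini = numeric(0),
                                              n_authors = integer(0),
                                              n_papers = integer(0))
  rownames(out) <- NULL
  out
}
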