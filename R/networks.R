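# Per-claim multilayer networks over papers: an unweighted agreement layer
# and Jaccard-weighted overlap layers for authors, methods and references;
# independence scores and the author-overlap agreement analysis.

#' Jaccard coefficient of two sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty
#' (a paper with no recorded attribute shares nothing, i.e. maximal
#' independence).
#'
#' @param a,b character (or atomic) vectors treated as sets.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b"), c("b", "c")) # 1/3
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Multilayer dependency network for one claim
#'
#' Nodes are the papers reporting findings about the claim. The `agreement`
#' layer holds an unweighted edge between every pair of papers reporting the
#' same effect direction; the `authors`, `methods` and `references` layers
#' hold Jaccard-weighted edges (zero-weight pairs carry no edge). Claims with
#' fewer than two papers cannot exhibit dependencies and raise an error.
#'
#' @param corpus a `claim_corpus`.
#' @param claim_id the claim to build the network for.
#' @return a `claim_network`: list with `claim_id`, `papers` (node ids),
#'   `stance` (named by paper), and `layers`, a named list of edge data
#'   frames `paper_i, paper_j, weight`.
#' @export
build_claim_network <- function(corpus, claim_id) {
  f <- corpus$findings[corpus$findings$claim_id == claim_id, , drop = FALSE]
  ids <- unique(f$paper_id)
  if (length(ids) < 2L) {
    stop("claim ", claim_id, " has fewer than 2 papers: ",
         "network dependencies are undefined for single-paper claims",
         call. = FALSE)
  }
  stance <- setNames(f$stance[match(ids, f$paper_id)], ids)
  meta <- corpus$papers[match(ids, corpus$papers$paper_id), , drop = FALSE]
  pairs <- utils::combn(seq_along(ids), 2)
  layer_edges <- function(weights) {
    keep <- weights > 0
    data.frame(paper_i = ids[pairs[1, keep]], paper_j = ids[pairs[2, keep]],
               weight = weights[keep], stringsAsFactors = FALSE)
  }
  jac_layer <- function(col) {
    apply(pairs, 2, function(p) jaccard(meta[[col]][[p[1]]], meta[[col]][[p[2]]]))
  }
  agree_w <- apply(pairs, 2, function(p) as.numeric(stance[p[1]] == stance[p[2]]))
  structure(list(claim_id = claim_id, papers = ids, stance = stance,
                 layers = list(agreement = layer_edges(agree_w),
                               authors = layer_edges(jac_layer("authors")),
                               methods = layer_edges(jac_layer("methods")),
                               references = layer_edges(jac_layer("references")))),
            class = "claim_network")
}

#' @export
print.claim_network <- function(x, ...) {
  cat("claim_network for", x$claim_id, "-", length(x$papers), "papers;",
      "edges per layer:",
      paste(sprintf("%s=%d", names(x$layers),
                    vapply(x$layers, nrow, integer(1))), collapse = ", "), "\n")
  invisible(x)
}

#' Independence score of one network layer
#'
#' `IND = (Emax - W) / Emax` with `Emax = n(n-1)/2` the maximum number of
#' pairwise edges and `W` the sum of the layer's Jaccard edge weights: the
#' probability that two randomly chosen findings about the claim come from
#' disconnected sets of authors (social independence), methods
#' (methodological independence) or references (knowledge independence).
#'
#' @param network a `claim_network`.
#' @param layer one of `"authors"`, `"methods"`, `"references"`.
#' @return scalar in `[0, 1]`.
#' @export
independence_score <- function(network, layer = c("authors", "methods", "references")) {
  layer <- match.arg(layer)
  n <- length(network$papers)
  if (n < 2L) stop("independence undefined for fewer than 2 papers", call. = FALSE)
  emax <- n * (n - 1) / 2
  (emax - sum(network$layers[[layer]]$weight)) / emax
}

#' Social, methodological and knowledge independence of a claim
#'
#' @param network a `claim_network`.
#' @return named numeric `c(S_ind, M_ind, K_ind)`.
#' @export
independence_scores <- function(network) {
  c(S_ind = independence_score(network, "authors"),
    M_ind = independence_score(network, "methods"),
    K_ind = independence_score(network, "references"))
}

#' Independence scores for all multi-paper claims in a corpus
#'
#' @param corpus a `claim_corpus`.
#' @return data frame `claim_id, n_papers, S_ind, M_ind, K_ind` with one row
#'   per claim reported by at least two papers.
#' @export
independence_table <- function(corpus) {
  n_papers <- tapply(corpus$findings$paper_id, corpus$findings$claim_id,
                     function(p) length(unique(p)))
  ids <- names(n_papers)[n_papers >= 2]
  rows <- lapply(ids, function(cid) {
    sc <- independence_scores(build_claim_network(corpus, cid))
    data.frame(claim_id = cid, n_papers = as.integer(n_papers[[cid]]),
               S_ind = sc[["S_ind"]], M_ind = sc[["M_ind"]], K_ind = sc[["K_ind"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame(claim_id = character(0),
                                              n_papers = integer(0), S_ind = numeric(0),
                                              M_ind = numeric(0), K_ind = numeric(0))
  rownames(out) <- NULL
  out
}

#' Agreement between author-overlapping vs independent paper pairs
#'
#' Enumerates every within-claim pair of papers (pooled across claims, so a
#' paper pair reporting on several claims contributes one pair per claim),
#' splits pairs by whether the papers share at least one author, and compares
#' the proportion of pairs agreeing on the effect direction between the two
#' groups. The difference gets a percentile bootstrap CI from resampling
#' pairs within each group.
#'
#' @param corpus a `claim_corpus`.
#' @param B bootstrap iterations (default 100000).
#' @param level CI coverage.
#' @param seed optional integer seed.
#' @return list with `p_overlap`, `n_overlap`, `agree_overlap`, `p_indep`,
#'   `n_indep`, `agree_indep`, `diff`, `ci`; `diff`/`ci` are `NA` when either
#'   group is empty.
#' @export
pairwise_agreement <- function(corpus, B = 100000, level = 0.95, seed = NULL) {
  f <- corpus$findings
  meta <- corpus$papers
  by_claim <- split(seq_len(nrow(f)), f$claim_id)
  overlap <- logical(0)
  agree <- logical(0)
  for (idx in by_claim) {
    ids <- unique(f$paper_id[idx])
    if (length(ids) < 2L) next
    stance <- f$stance[idx][match(ids, f$paper_id[idx])]
    auth <- meta$authors[match(ids, meta$paper_id)]
    pr <- utils::combn(seq_along(ids), 2)
    overlap <- c(overlap, apply(pr, 2, function(p)
      length(intersect(auth[[p[1]]], auth[[p[2]]])) > 0))
    agree <- c(agree, apply(pr, 2, function(p) stance[p[1]] == stance[p[2]]))
  }
  res <- list(p_overlap = if (any(overlap)) mean(agree[overlap]) else NA_real_,
              n_overlap = sum(overlap), agree_overlap = sum(agree & overlap),
              p_indep = if (any(!overlap)) mean(agree[!overlap]) else NA_real_,
              n_indep = sum(!overlap), agree_indep = sum(agree & !overlap))
  if (res$n_overlap == 0L || res$n_indep == 0L) {
    res$diff <- NA_real_
    res$ci <- c(NA_real_, NA_real_)
    res$empty_group <- TRUE
    return(res)
  }
  d_ov <- boot_binary_mean(as.numeric(agree[overlap]), B,
                           if (is.null(seed)) NULL else derive_seed(seed, "ov"))
  d_in <- boot_binary_mean(as.numeric(agree[!overlap]), B,
                           if (is.null(seed)) NULL else derive_seed(seed, "in"))
  res$diff <- res$p_overlap - res$p_indep
  res$ci <- percentile_ci(d_ov - d_in, level)
  res$empty_group <- FALSE
  res
}
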