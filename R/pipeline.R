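# End-to-end orchestration: match -> combine -> support -> replicate ->
# network -> centralize -> regress -> report. Every stage is a pure function
# of (inputs, config, seed); stage boundaries log claim counts.

#' Per-claim evaluation table
#'
#' Joins the combined-signature statistics, literature-support posterior
#' summaries, replication indicator, independence scores, centralization and
#' journal prominence into one row per matched claim. Claims reported by a
#' single paper carry `NA` network columns.
#'
#' @param corpus a matched `claim_corpus`.
#' @param combined output of [combine_signatures()].
#' @param support output of [support_table()].
#' @return data frame, one row per claim.
#' @export
claim_evaluation <- function(corpus, combined, support) {
  cl <- corpus$claims
  key <- dgi_key(cl$drug, cl$gene)
  ci <- match(key, dgi_key(combined$drug, combined$gene))
  if (anyNA(ci)) {
    stop("claim_evaluation: claim(s) without combined signature: ",
         paste(cl$claim_id[is.na(ci)], collapse = ", "), call. = FALSE)
  }
  si <- match(cl$claim_id, support$claim_id)
  ev <- data.frame(claim_id = cl$claim_id, drug = cl$drug, gene = cl$gene,
                   direction = cl$direction,
                   Z = combined$Z[ci], lo = combined$lo[ci], hi = combined$hi[ci],
                   k = combined$k[ci], generalized = combined$generalized[ci],
                   CV = combined$cv[ci], cv_unstable = combined$cv_unstable[ci],
                   gamma = support$gamma[si], n = support$n[si],
                   L_supt = support$L_supt[si],
                   support_class = support$support_class[si],
                   stringsAsFactors = FALSE)
  ev$R <- as.integer(replication_indicator(ev$direction, ev$Z))
  ind <- independence_table(corpus)
  cen <- centralization_table(corpus)
  ii <- match(ev$claim_id, ind$claim_id)
  ev$S_ind <- ind$S_ind[ii]
  ev$M_ind <- ind$M_ind[ii]
  ev$K_ind <- ind$K_ind[ii]
  ev$n_papers <- ind$n_papers[ii]
  ev$n_papers[is.na(ev$n_papers)] <- 1L
  ev$C <- cen$gini[match(ev$claim_id, cen$claim_id)]
  # journal prominence: mean journal score over the claim's papers
  f <- corpus$findings
  js <- corpus$papers$journal_score[match(f$paper_id, corpus$papers$paper_id)]
  jmean <- tapply(js, f$claim_id, mean)
  ev$J <- as.numeric(jmean[ev$claim_id])
  ev
}

#' Regression analysis subsample
#'
#' The claims eligible for the network-dependency models: support class
#' Moderate or above (hence multi-paper, converging on a direction) *and*
#' generalized in the experimental data.
#'
#' @param evaluation from [claim_evaluation()].
#' @return the filtered rows.
#' @export
analysis_subsample <- function(evaluation) {
  keep <- evaluation$support_class %in% c("VeryHigh", "High", "Moderate") &
    evaluation$generalized & evaluation$n_papers >= 2
  evaluation[keep, , drop = FALSE]
}

pipeline_stage <- function(name, verbose, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) message(sprintf("[claimnet] stage %-12s done", name))
  res
}

#' Run the full evaluation pipeline
#'
#' Orchestrates all stages on a corpus (either supplied or simulated from a
#' [generator_config()]): matching claims to signatures, combining z-scores,
#' literature-support posteriors, replication-rate summaries by subset,
#' independence and centralization tables, the author-overlap agreement
#' analysis, and the three logistic model families on the analysis
#' subsample. Identical `(inputs, config, seed)` give identical outputs.
#'
#' @param corpus a `claim_corpus`, or `NULL` to simulate one.
#' @param config a [generator_config()] used when `corpus` is `NULL`.
#' @param seed master integer seed.
#' @param B bootstrap iterations (combined-z CIs and observed rates).
#' @param P permutation iterations for the null baseline.
#' @param support_method `"exact"` or `"mcmc"` posterior computation.
#' @param outdir optional directory; when given, every stage table is written
#'   as a TSV there.
#' @param verbose log stage completions and funnel counts.
#' @return list with `corpus`, `combined`, `support`, `evaluation`,
#'   `replication`, `independence`, `centralization`, `agreement`,
#'   `subsample`, and `models` (univariate panel, multivariate fit, two
#'   interaction fits; `NULL` when the subsample cannot support a fit).
#' @export
run_pipeline <- function(corpus = NULL, config = generator_config(), seed = 1L,
                         B = 10000, P = 10000,
                         support_method = c("exact", "mcmc"),
                         outdir = NULL, verbose = TRUE) {
  support_method <- match.arg(support_method)
  if (is.null(corpus)) {
    corpus <- pipeline_stage("simulate", verbose, simulate_corpus(config, seed))
  }
  matched <- pipeline_stage("match", verbose, {
    m <- match_corpus(corpus)
    if (nrow(m$claims) == 0L) {
      stop("no claims share a (drug, gene) key with the signature table")
    }
    m
  })
  if (verbose) {
    s <- attr(matched, "summary")
    message(sprintf("[claimnet] matched %d claims (%d supporting, %d opposing findings)",
                    s$n_claims, s$n_supporting, s$n_opposing))
  }
  combined <- pipeline_stage("combine", verbose,
    combine_signatures(matched, B = B, seed = derive_seed(seed, "combine")))
  support <- pipeline_stage("support", verbose,
    support_table(matched, method = support_method,
                  seed = derive_seed(seed, "support")))
  evaluation <- pipeline_stage("evaluate", verbose,
    claim_evaluation(matched, combined, support))
  replication <- pipeline_stage("replicate", verbose,
    replication_summary(evaluation, B = B, P = P,
                        seed = derive_seed(seed, "replicate")))
  independence <- pipeline_stage("network", verbose, independence_table(matched))
  centralization <- pipeline_stage("centralize", verbose,
    centralization_table(matched))
  agreement <- pipeline_stage("agreement", verbose,
    pairwise_agreement(matched, B = B, seed = derive_seed(seed, "agreement")))
  subsample <- analysis_subsample(evaluation)
  if (verbose) {
    message(sprintf("[claimnet] analysis subsample: %d of %d claims (multi-paper, Moderate+ support, generalized)",
                    nrow(subsample), nrow(evaluation)))
  }
  models <- pipeline_stage("regress", verbose, fit_models(subsample))
  out <- list(corpus = matched, combined = combined, support = support,
              evaluation = evaluation, replication = replication,
              independence = independence, centralization = centralization,
              agreement = agreement, subsample = subsample, models = models)
  if (!is.null(outdir)) write_pipeline(out, outdir)
  invisible(out)
}

fit_models <- function(subsample) {
  if (nrow(subsample) < 20L || length(unique(subsample$R)) < 2L) {
    return(NULL)
  }
  mi <- model_input(subsample)
  univ <- univariate_panel(mi)
  multi <- fit_logistic(mi, "multivariate")
  int_s <- fit_logistic(mi, "interaction", interaction_with = "S_ind")
  int_c <- fit_logistic(mi, "interaction", interaction_with = "C")
  list(univariate = univ, multivariate = multi,
       interaction_S = int_s, interaction_C = int_c)
}

write_pipeline <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(out$combined, "combined_signatures")
  wt(out$support, "support")
  wt(out$evaluation, "evaluation")
  wt(out$replication, "replication_rates")
  wt(out$independence, "independence")
  wt(out$centralization, "centralization")
  if (!is.null(out$models)) {
    wt(out$models$univariate, "odds_ratios_univariate")
    wt(out$models$multivariate$table, "odds_ratios_multivariate")
  }
  ag <- out$agreement
  wt(data.frame(group = c("author_overlap", "independent"),
                pairs = c(ag$n_overlap, ag$n_indep),
                agreeing = c(ag$agree_overlap, ag$agree_indep),
                proportion = c(ag$p_overlap, ag$p_indep)),
     "pairwise_agreement")
  invisible(outdir)
}
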