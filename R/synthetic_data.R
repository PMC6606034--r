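# Synthetic claim corpora with known ground truth. The generator emulates
# the statistical structure of a literature-curated drug-gene claim corpus
# joined to a high-throughput experiment: a long-tailed findings-per-claim
# distribution (~89% single-finding), high literature agreement driven by
# reporting noise plus publication bias ("filing away" findings that
# contradict the published majority, more strongly within author-overlapping
# teams), repeat-collaboration authorship that produces centralized
# communities, method/reference sets coupled to author overlap, and
# condition-structured z-scores with controllable generalizability and CV.

#' Generator configuration
#'
#' Defaults encode the corpus conditions the package targets: 89% of claims
#' carry a single finding and 8% two (geometric tail beyond), literature
#' agreement around 93%, a 4 x 4 x 3 condition grid (48 z-scores per
#' interaction), and moderate community centralization.
#'
#' @param n_claims number of claims.
#' @param single_prob,double_prob probability of exactly 1 / exactly 2
#'   findings per claim; the remainder is `3 + Geometric(tail_geom)`.
#' @param tail_geom geometric tail parameter for claims with 3+ findings.
#' @param frac_null fraction of claims with no true effect.
#' @param effect_shape,effect_rate Gamma law of the true effect magnitude
#'   `|mu|` for non-null claims (units of per-condition z).
#' @param report_sd sd of the noise on the per-study effect estimate whose
#'   sign is the reported direction; the first report fixes the claim's
#'   canonical direction.
#' @param pub_bias probability `b` that a finding contradicting the current
#'   published majority is filed away (never published) when its team is
#'   socially independent of the claim's community.
#' @param pub_bias_overlap same, when the team shares authors with the
#'   community (conformity is stronger inside collaborations).
#' @param author_pool global author pool size.
#' @param team_rate team size is `1 + Poisson(team_rate)`.
#' @param rho mean repeat-collaboration rate: expected fraction of author
#'   slots on a follow-up paper filled from the claim's existing community
#'   (per-claim rates drawn from a Beta law with this mean).
#' @param kappa method/reference coupling: probability that a team sharing
#'   authors with an earlier paper inherits (with one-token mutation) that
#'   paper's method and reference sets.
#' @param methods_pool,methods_per_paper,refs_pool,refs_per_paper token pool
#'   sizes and per-paper set sizes.
#' @param cell_lines,doses,durations condition grid dimensions.
#' @param sigma_c sd of the per-condition context shift (controls CV and the
#'   generalizability rate).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_claims = 1000,
                             single_prob = 0.89, double_prob = 0.08,
                             tail_geom = 0.5,
                             frac_null = 0.4,
                             effect_shape = 2, effect_rate = 1,
                             report_sd = 1,
                             pub_bias = 0.7, pub_bias_overlap = 0.98,
                             author_pool = max(200L, 2L * n_claims),
                             team_rate = 3,
                             rho = 0.3, kappa = 0.5,
                             methods_pool = 150, methods_per_paper = 5,
                             refs_pool = 3000, refs_per_paper = 12,
                             cell_lines = 4, doses = 4, durations = 3,
                             sigma_c = 1) {
  cfg <- as.list(environment())
  probs <- c(single_prob, double_prob, tail_geom, frac_null, pub_bias,
             pub_bias_overlap, rho, kappa)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (single_prob + double_prob > 1) {
    stop("generator_config: single_prob + double_prob must be <= 1", call. = FALSE)
  }
  if (n_claims < 1 || author_pool < 1) {
    stop("generator_config: need at least one claim and one author", call. = FALSE)
  }
  if (cell_lines < 1 || doses < 1 || durations < 1) {
    stop("generator_config: condition grid must be non-empty", call. = FALSE)
  }
  if (tail_geom <= 0) stop("generator_config: tail_geom must be in (0, 1]", call. = FALSE)
  structure(cfg, class = "generator_config")
}

draw_findings_per_claim <- function(n, cfg) {
  u <- runif(n)
  k <- ifelse(u < cfg$single_prob, 1L,
              ifelse(u < cfg$single_prob + cfg$double_prob, 2L,
                     3L + rgeom(n, cfg$tail_geom)))
  as.integer(k)
}

sample_set <- function(pool, size) {
  sample(pool, min(size, length(pool)), replace = FALSE)
}

#' Generate a synthetic claim corpus with ground truth
#'
#' Claims receive a latent true effect (null with probability `frac_null`,
#' otherwise a Gamma-distributed magnitude with a random direction). Findings
#' accrue sequentially: each candidate study estimates the effect with noise
#' and reports the estimate's sign; the first retained report fixes the
#' claim's canonical direction; later candidates contradicting the current
#' published majority are filed away with probability `pub_bias`
#' (`pub_bias_overlap` when the team overlaps the claim's community). Teams
#' form by repeat collaboration at per-claim rate drawn around `rho`;
#' method/reference sets are inherited across author-overlapping papers with
#' probability `kappa`, coupling the three overlap layers.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (all stages derive sub-seeds from it).
#' @return a `claim_corpus` (empty `signatures` slot; see
#'   [generate_signatures()]) with attribute `"ground_truth"`: a data frame
#'   `claim_id, drug, gene, direction, true_direction, mu_true, null,
#'   wrong_direction, n_findings, n_papers, rho_claim`.
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(derive_seed(seed, "corpus"), generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_claims
  k_target <- draw_findings_per_claim(n, cfg)
  is_null <- runif(n) < cfg$frac_null
  mu <- ifelse(is_null, 0, rgamma(n, cfg$effect_shape, cfg$effect_rate))
  true_dir <- ifelse(is_null, NA_character_,
                     ifelse(runif(n) < 0.5, "increase", "decrease"))
  # per-claim repeat-collaboration rates: low-concentration Beta with mean
  # rho, so corpora mix genuinely independent communities (rho_i ~ 0) with
  # tightly repeating ones (rho_i ~ 1)
  rho_claim <- if (cfg$rho == 0) rep(0, n)
    else if (cfg$rho == 1) rep(1, n)
    else rbeta(n, 2 * cfg$rho, 2 * (1 - cfg$rho))
  authors_all <- sprintf("A%05d", seq_len(cfg$author_pool))
  methods_all <- sprintf("M%04d", seq_len(cfg$methods_pool))
  refs_all <- sprintf("R%05d", seq_len(cfg$refs_pool))

  findings <- vector("list", n)
  papers <- vector("list", n)
  gt <- vector("list", n)
  paper_counter <- 0L
  for (i in seq_len(n)) {
    cid <- sprintf("C%05d", i)
    drug <- sprintf("drug%05d", i)
    gene <- sprintf("gene%05d", i)
    s_mu <- if (is_null[i]) 0 else if (true_dir[i] == "increase") mu[i] else -mu[i]
    community <- character(0)          # authors of retained papers
    retained_dirs <- character(0)
    canonical <- NA_character_
    claim_papers <- list()
    attempts <- 0L
    max_attempts <- 60L * k_target[i]
    while (length(retained_dirs) < k_target[i] && attempts < max_attempts) {
      attempts <- attempts + 1L
      # team assembly: repeat collaborators from the community, rest global
      ts <- 1L + rpois(1L, cfg$team_rate)
      n_rep <- if (length(community)) rbinom(1L, ts, rho_claim[i]) else 0L
      team <- unique(c(sample_set(community, n_rep),
                       sample_set(authors_all, ts - min(n_rep, length(community)))))
      overlap <- length(intersect(team, community)) > 0
      # the study's effect estimate; its sign is the reported direction
      est <- s_mu + rnorm(1L, 0, cfg$report_sd)
      dir <- if (est > 0) "increase" else "decrease"
      if (length(retained_dirs)) {
        n_inc <- sum(retained_dirs == "increase")
        majority <- if (n_inc * 2L == length(retained_dirs)) canonical
          else if (n_inc * 2L > length(retained_dirs)) "increase" else "decrease"
        if (dir != majority) {
          b <- if (overlap) cfg$pub_bias_overlap else cfg$pub_bias
          if (runif(1L) < b) next    # filed away, never published
        }
      }
      # published: create the paper
      paper_counter <- paper_counter + 1L
      pid <- sprintf("P%06d", paper_counter)
      donors <- claim_papers[vapply(claim_papers, function(p)
        length(intersect(p$authors, team)) > 0, logical(1))]
      inherit <- length(donors) > 0 && runif(1L) < cfg$kappa
      if (inherit) {
        donor <- donors[[sample.int(length(donors), 1L)]]
        mutate1 <- function(set, pool) {
          set[sample.int(length(set), 1L)] <- sample(pool, 1L)
          unique(set)
        }
        meths <- mutate1(donor$methods, methods_all)
        refs <- mutate1(donor$references, refs_all)
      } else {
        meths <- sample_set(methods_all, cfg$methods_per_paper)
        refs <- sample_set(refs_all, cfg$refs_per_paper)
      }
      if (is.na(canonical)) canonical <- dir
      retained_dirs <- c(retained_dirs, dir)
      community <- unique(c(community, team))
      claim_papers[[length(claim_papers) + 1L]] <-
        list(paper_id = pid, authors = team, methods = meths, references = refs,
             journal_score = rlnorm(1L, 0, 1), dir = dir)
    }
    kp <- length(claim_papers)
    findings[[i]] <- data.frame(
      claim_id = cid, drug = drug, gene = gene, direction = canonical,
      paper_id = vapply(claim_papers, `[[`, "", "paper_id"),
      stance = ifelse(retained_dirs == canonical, "support", "oppose"),
      stringsAsFactors = FALSE)
    papers[[i]] <- claim_papers
    gt[[i]] <- data.frame(
      claim_id = cid, drug = drug, gene = gene, direction = canonical,
      true_direction = true_dir[i], mu_true = mu[i], null = is_null[i],
      wrong_direction = !is_null[i] && canonical != true_dir[i],
      n_findings = kp, n_papers = kp, rho_claim = rho_claim[i],
      stringsAsFactors = FALSE)
  }
  findings <- do.call(rbind, findings)
  gt <- do.call(rbind, gt)
  flat <- unlist(papers, recursive = FALSE)
  papers_df <- data.frame(paper_id = vapply(flat, `[[`, "", "paper_id"),
                          stringsAsFactors = FALSE)
  papers_df$authors <- lapply(flat, `[[`, "authors")
  papers_df$methods <- lapply(flat, `[[`, "methods")
  papers_df$references <- lapply(flat, `[[`, "references")
  papers_df$journal_score <- vapply(flat, `[[`, 0, "journal_score")
  empty_sig <- data.frame(drug = character(0), gene = character(0),
                          cell_line = character(0), dose = character(0),
                          duration = character(0), z = numeric(0),
                          stringsAsFactors = FALSE)
  corpus <- new_corpus(findings, papers_df, empty_sig)
  attr(corpus, "ground_truth") <- gt
  corpus
}

#' Generate condition-structured signatures for a synthetic corpus
#'
#' For every claim, draws one moderated z-score per condition in the
#' `cell_lines x doses x durations` grid:
#' `z = s * mu_true + sigma_c * delta(condition) + e`, with `s` the signed
#' true direction (0 for null claims), `delta` a per-claim, per-condition
#' standard-normal context shift scaled by `sigma_c`, and `e` unit
#' measurement noise. Large `sigma_c` inflates the coefficient of variation
#' and suppresses generalization.
#'
#' @param corpus a corpus from [generate_corpus()] (must carry ground truth).
#' @param config the same [generator_config()].
#' @param seed integer seed.
#' @return the corpus with its `signatures` table filled in.
#' @export
generate_signatures <- function(corpus, config = generator_config(), seed = 1L) {
  gt <- attr(corpus, "ground_truth")
  if (is.null(gt)) stop("generate_signatures: corpus has no ground truth", call. = FALSE)
  grid <- expand.grid(cell_line = sprintf("CL%02d", seq_len(config$cell_lines)),
                      dose = sprintf("dose%02d", seq_len(config$doses)),
                      duration = sprintf("dur%02d", seq_len(config$durations)),
                      stringsAsFactors = FALSE)
  k <- nrow(grid)
  n <- nrow(gt)
  sig <- with_seed(derive_seed(seed, "signatures"), {
    s <- ifelse(gt$null, 0, ifelse(gt$true_direction == "increase", 1, -1))
    z <- rep(s * gt$mu_true, each = k) +
      config$sigma_c * rnorm(n * k) + rnorm(n * k)
    data.frame(drug = rep(gt$drug, each = k), gene = rep(gt$gene, each = k),
               cell_line = rep(grid$cell_line, n), dose = rep(grid$dose, n),
               duration = rep(grid$duration, n), z = z,
               stringsAsFactors = FALSE)
  })
  corpus$signatures <- sig
  corpus
}

#' One-call synthetic corpus with signatures
#'
#' @inheritParams generate_corpus
#' @return a complete `claim_corpus` with ground truth attribute.
#' @export
simulate_corpus <- function(config = generator_config(), seed = 1L) {
  generate_signatures(generate_corpus(config, seed), config, seed)
}
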