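test_that("jaccard handles the boundary and fractional cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 0)  # empty sets share nothing
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b", "c")), 1 / 3)  # set semantics
})

test_that("claim networks carry the four layers with hand-computed edges", {
  # two papers, same authors, same stance
  f <- data.frame(claim_id = "c1", drug = "d", gene = "g", direction = "increase",
                  paper_id = c("p1", "p2"), stance = "support",
                  stringsAsFactors = FALSE)
  p <- data.frame(paper_id = c("p1", "p2"), authors = "a1;a2",
                  methods = c("m1", "m2"), references = c("r1", "r2"),
                  journal_score = 1, stringsAsFactors = FALSE)
  s <- data.frame(drug = "d", gene = "g", cell_line = "CL1", dose = "d1",
                  duration = "t1", z = 1, stringsAsFactors = FALSE)
  net <- build_claim_network(read_fixture(f, p, s), "c1")
  expect_equal(nrow(net$layers$agreement), 1)
  expect_equal(net$layers$authors$weight, 1)
  expect_equal(nrow(net$layers$methods), 0)  # zero-weight pairs carry no edge

  # three pairwise-disjoint papers: overlap layers empty
  f3 <- data.frame(claim_id = "c1", drug = "d", gene = "g", direction = "increase",
                   paper_id = c("p1", "p2", "p3"),
                   stance = c("support", "support", "oppose"),
                   stringsAsFactors = FALSE)
  p3 <- data.frame(paper_id = c("p1", "p2", "p3"),
                   authors = c("a1", "a2", "a3"), methods = c("m1", "m2", "m3"),
                   references = c("r1", "r2", "r3"), journal_score = 1,
                   stringsAsFactors = FALSE)
  net3 <- build_claim_network(read_fixture(f3, p3, s), "c1")
  expect_equal(nrow(net3$layers$authors), 0)
  expect_equal(nrow(net3$layers$agreement), 1)  # only p1-p2 agree
  expect_equal(independence_scores(net3),
               c(S_ind = 1, M_ind = 1, K_ind = 1))

  # four papers with specified sets: enumerate pairs by hand
  f4 <- data.frame(claim_id = "c1", drug = "d", gene = "g", direction = "increase",
                   paper_id = paste0("p", 1:4), stance = "support",
                   stringsAsFactors = FALSE)
  p4 <- data.frame(paper_id = paste0("p", 1:4),
                   authors = c("a1;a2", "a2;a3", "a4", "a1;a2"),
                   methods = "m1", references = c("r1", "r1", "r1", "r2"),
                   journal_score = 1, stringsAsFactors = FALSE)
  net4 <- build_claim_network(read_fixture(f4, p4, s), "c1")
  au <- net4$layers$authors
  expect_equal(nrow(au), 3)  # p1-p2 (1/3), p1-p4 (1), p2-p4 (1/3)
  expect_equal(sum(au$weight), 1 / 3 + 1 + 1 / 3)
  expect_equal(nrow(net4$layers$methods), 6)  # all pairs share m1
  expect_equal(independence_score(net4, "methods"), 0)
  expect_equal(independence_score(net4, "references"), (6 - 3) / 6)

  expect_error(build_claim_network(tiny_corpus(), "c2"), "fewer than 2")
})

test_that("independence hits its boundaries and the worked fraction", {
  mk <- function(authors) {
    f <- data.frame(claim_id = "c1", drug = "d", gene = "g",
                    direction = "increase",
                    paper_id = paste0("p", seq_along(authors)),
                    stance = "support", stringsAsFactors = FALSE)
    p <- data.frame(paper_id = paste0("p", seq_along(authors)),
                    authors = authors, methods = "m1", references = "r1",
                    journal_score = 1, stringsAsFactors = FALSE)
    s <- data.frame(drug = "d", gene = "g", cell_line = "CL1", dose = "d1",
                    duration = "t1", z = 1, stringsAsFactors = FALSE)
    build_claim_network(read_fixture(f, p, s), "c1")
  }
  expect_equal(independence_score(mk(c("a1;a2", "a1;a2", "a1;a2")), "authors"), 0)
  expect_equal(independence_score(mk(c("a1", "a2", "a3")), "authors"), 1)
  # pairwise JC {0.5, 0, 0}: (3 - 0.5) / 3
  expect_equal(independence_score(mk(c("a1;a2", "a1", "a3")), "authors"),
               (3 - 0.5) / 3)
})

test_that("independence is invariant to paper relabeling and anti-monotone in overlap", {
  base <- c("a1;a2", "a3;a4", "a5;a6")
  more_overlap <- c("a1;a2", "a1;a4", "a5;a6")  # one pair gains overlap
  mk <- function(authors, ids) {
    f <- data.frame(claim_id = "c1", drug = "d", gene = "g",
                    direction = "increase", paper_id = ids,
                    stance = "support", stringsAsFactors = FALSE)
    p <- data.frame(paper_id = ids, authors = authors, methods = "m1",
                    references = "r1", journal_score = 1, stringsAsFactors = FALSE)
    s <- data.frame(drug = "d", gene = "g", cell_line = "CL1", dose = "d1",
                    duration = "t1", z = 1, stringsAsFactors = FALSE)
    independence_score(build_claim_network(read_fixture(f, p, s), "c1"), "authors")
  }
  expect_equal(mk(base, c("p1", "p2", "p3")), mk(base, c("x9", "q2", "zz")))
  expect_lt(mk(more_overlap, c("p1", "p2", "p3")), mk(base, c("p1", "p2", "p3")))
})

test_that("pairwise agreement splits pairs by author overlap", {
  corpus <- pair_count_corpus(n_ov = 40, a_ov = 38, n_in = 60, a_in = 42)
  ag <- pairwise_agreement(corpus, B = 2000, seed = 5)
  expect_equal(ag$n_overlap, 40)
  expect_equal(ag$p_overlap, 38 / 40)
  expect_equal(ag$p_indep, 42 / 60)
  expect_equal(ag$diff, 38 / 40 - 42 / 60)
  expect_true(ag$ci[1] < ag$diff && ag$diff < ag$ci[2])
  # empty group is flagged
  ag2 <- pairwise_agreement(pair_count_corpus(10, 9, 0, 0), B = 100, seed = 1)
  expect_true(ag2$empty_group)
  expect_true(is.na(ag2$diff))
})

test_that("raising author overlap in the generator lowers mean independence", {
  cfg_lo <- generator_config(n_claims = 250, rho = 0, single_prob = 0.3,
                             double_prob = 0.3)
  cfg_hi <- generator_config(n_claims = 250, rho = 0.8, single_prob = 0.3,
                             double_prob = 0.3)
  ind_lo <- independence_table(generate_corpus(cfg_lo, seed = 9))
  ind_hi <- independence_table(generate_corpus(cfg_hi, seed = 9))
  expect_gt(mean(ind_lo$S_ind), mean(ind_hi$S_ind))
  expect_gt(mean(ind_lo$M_ind), mean(ind_hi$M_ind))  # coupling via kappa
  expect_gt(mean(ind_lo$K_ind), mean(ind_hi$K_ind))
})
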