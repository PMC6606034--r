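test_that("config validation rejects infeasible settings", {
  expect_error(generator_config(pub_bias = 1.2), "probabilities")
  expect_error(generator_config(single_prob = 0.8, double_prob = 0.3), "<= 1")
  expect_error(generator_config(n_claims = 0), "at least one")
  expect_error(generator_config(cell_lines = 0), "grid")
  expect_s3_class(generator_config(), "generator_config")
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- generator_config(n_claims = 80)
  a <- simulate_corpus(cfg, seed = 101)
  b <- simulate_corpus(cfg, seed = 101)
  expect_identical(a$findings, b$findings)
  expect_identical(a$signatures, b$signatures)
  expect_identical(attr(a, "ground_truth"), attr(b, "ground_truth"))
  c2 <- simulate_corpus(cfg, seed = 102)
  expect_false(identical(a$findings, c2$findings))
})

test_that("default config reproduces the long-tailed findings distribution", {
  corp <- generate_corpus(generator_config(n_claims = 4000), seed = 19)
  gt <- attr(corp, "ground_truth")
  expect_equal(mean(gt$n_findings == 1), 0.89, tolerance = 0.03)
  expect_gt(max(gt$n_findings), 3)  # long tail present
})

test_that("unbiased null-only generation shows no overlap-linked agreement", {
  cfg <- generator_config(n_claims = 1200, frac_null = 1, pub_bias = 0,
                          pub_bias_overlap = 0, rho = 0,
                          single_prob = 0.2, double_prob = 0.3)
  corp <- generate_corpus(cfg, seed = 23)
  ag <- pairwise_agreement(corp, B = 3000, seed = 23)
  # null effects + unbiased publication: pairs agree at chance
  pooled <- (ag$agree_overlap + ag$agree_indep) / (ag$n_overlap + ag$n_indep)
  expect_equal(pooled, 0.5, tolerance = 0.05)
  if (!ag$empty_group) {
    expect_true(ag$ci[1] <= 0 && 0 <= ag$ci[2])
  }
})

test_that("signature context noise drives CV up and generalization down", {
  base <- generator_config(n_claims = 150, frac_null = 0)
  noisy <- generator_config(n_claims = 150, frac_null = 0, sigma_c = 6)
  c0 <- simulate_corpus(base, seed = 29)
  c1 <- simulate_corpus(noisy, seed = 29)
  s0 <- combine_signatures(c0, B = 300, seed = 1)
  s1 <- combine_signatures(c1, B = 300, seed = 1)
  expect_gt(mean(s1$cv), mean(s0$cv))
  expect_lt(mean(s1$generalized), mean(s0$generalized))
  expect_lt(stats::median(s0$cv), stats::median(s1$cv))
})

test_that("null-only signatures generalize at the nominal 5% rate", {
  cfg <- generator_config(n_claims = 400, frac_null = 1)
  corp <- simulate_corpus(cfg, seed = 37)
  cs <- combine_signatures(corp, B = 400, seed = 37)
  expect_lt(abs(mean(cs$generalized) - 0.05), 0.03)
})

test_that("strong effects with no context noise always generalize", {
  cfg <- generator_config(n_claims = 60, frac_null = 0, sigma_c = 0,
                          effect_shape = 1e6, effect_rate = 1e6 / 5)
  corp <- simulate_corpus(cfg, seed = 41)
  cs <- combine_signatures(corp, B = 300, seed = 41)
  expect_true(all(cs$generalized))
})

test_that("ground truth is internally consistent with the corpus", {
  corp <- simulate_corpus(generator_config(n_claims = 200), seed = 43)
  gt <- attr(corp, "ground_truth")
  expect_setequal(gt$claim_id, corp$claims$claim_id)
  expect_equal(gt$n_findings,
               as.vector(table(corp$findings$claim_id)[gt$claim_id]))
  expect_true(all(gt$mu_true[gt$null] == 0))
  expect_true(all(is.na(gt$true_direction[gt$null])))
  expect_true(all(gt$direction %in% c("increase", "decrease")))
  # signatures cover the full condition grid for every claim
  expect_equal(nrow(corp$signatures), 200 * 4 * 4 * 3)
})
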