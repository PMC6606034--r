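test_that("replication indicator matches sign of combined z to claimed direction", {
  expect_equal(as.integer(replication_indicator("increase", 2.3)), 1L)
  expect_equal(as.integer(replication_indicator("decrease", 2.3)), 0L)
  expect_equal(as.integer(replication_indicator("decrease", -0.1)), 1L)
  r <- replication_indicator(c("increase", "decrease"), c(0, -1))
  expect_equal(as.integer(r), c(0L, 1L))
  expect_equal(attr(r, "tie"), c(TRUE, FALSE))
  expect_error(replication_indicator("up", 1), "increase")
})

test_that("observed replication rate and bootstrap CI behave", {
  o <- observed_rr(c(1, 1, 1), B = 500, seed = 1)
  expect_equal(o$rate, 1)
  expect_equal(o$ci, c(1, 1))
  expect_equal(observed_rr(c(1, 0, 1, 0), B = 500, seed = 1)$rate, 0.5)
  expect_error(observed_rr(integer(0)), "empty")
  set.seed(8)
  R <- rbinom(5000, 1, 0.556)
  o2 <- observed_rr(R, B = 5000, seed = 2)
  expect_equal(o2$rate, 0.556, tolerance = 0.03)
  expect_true(o2$ci[1] < o2$rate, o2$rate < o2$ci[2])
})

test_that("permutation baseline is exact in degenerate cases", {
  r <- random_rr(rep("increase", 6), c(1, 2, 3, 4, 5, 6), P = 200, seed = 1)
  expect_equal(r$rate, 1)          # invariant under permutation
  expect_equal(r$ci, c(1, 1))
  r2 <- random_rr(c("increase", "decrease"), c(2, -3), P = 4000, seed = 1)
  expect_true(all(r2$draws %in% c(0, 1)))
  expect_equal(r2$rate, 0.5, tolerance = 0.05)  # both assignments equally likely
  expect_error(random_rr("increase", c(1, 2)), "lengths differ")
})

test_that("rri is the percentage increase over the baseline", {
  expect_equal(rri(0.75, 0.5), 50)
  expect_equal(rri(0.42, 0.42), 0)
  expect_error(rri(0.5, 0), "RR_rand")
  # the corpus-level rates reported for the real data imply ~10.5% at
  # printed precision
  expect_equal(rri(0.556, 0.503), 10.54, tolerance = 0.005)
})

test_that("replication_rates assembles a coherent subset row", {
  set.seed(21)
  n <- 400
  dir <- ifelse(runif(n) < 0.5, "increase", "decrease")
  Z <- ifelse(dir == "increase", 1, -1) * abs(rnorm(n)) *
    ifelse(runif(n) < 0.8, 1, -1)  # 80% replicating
  row <- replication_rates(dir, Z, B = 2000, P = 2000, seed = 3)
  expect_equal(row$rr_obs, mean(as.integer(replication_indicator(dir, Z))))
  expect_true(row$rr_obs_lo <= row$rr_obs && row$rr_obs <= row$rr_obs_hi)
  expect_equal(row$rr_rand, 0.5, tolerance = 0.02)
  expect_true(row$rri_lo <= row$rri && row$rri <= row$rri_hi)
  expect_gt(row$rri, 0)
})

test_that("generalized claims replicate more when effects drive generalization", {
  corp <- simulate_corpus(generator_config(n_claims = 600, frac_null = 0.5),
                          seed = 17)
  cs <- combine_signatures(corp, B = 400, seed = 17)
  cl <- corp$claims
  idx <- match(paste(cl$drug, cl$gene), paste(cs$drug, cs$gene))
  R <- as.integer(replication_indicator(cl$direction, cs$Z[idx]))
  gen <- cs$generalized[idx]
  expect_gt(mean(R[gen]), mean(R[!gen]))
})

test_that("replication_summary covers the standard subsets", {
  ev <- data.frame(direction = rep(c("increase", "decrease"), 50),
                   Z = rep(c(1, -1, 1, 2, -2), 20),
                   generalized = rep(c(TRUE, FALSE), each = 50),
                   support_class = rep(c("Low", "Moderate"), 50),
                   stringsAsFactors = FALSE)
  rs <- replication_summary(ev, B = 300, P = 300, seed = 1)
  expect_true(all(c("all", "generalized", "non_generalized", "Moderate", "Low")
                  %in% rs$subset))
  expect_false("VeryHigh" %in% rs$subset)  # empty subsets omitted
  expect_equal(rs$n[rs$subset == "all"], 100)
})
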