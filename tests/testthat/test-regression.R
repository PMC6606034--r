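test_that("min-max rescaling maps extremes to 0 and 1", {
  expect_equal(rescale_minmax(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(rescale_minmax(c(-2, 0, 2)), c(0, 0.5, 1))
  expect_error(rescale_minmax(c(5, 5)), "degenerate")
})

test_that("logistic fits recover known generating coefficients", {
  set.seed(31)
  n <- 5000
  x <- runif(n)
  p <- plogis(-1 + 2 * x)
  d <- data.frame(R = rbinom(n, 1, p), x = x)
  fit <- fit_logistic(d, "univariate", predictor = "x")
  b1 <- fit$table$estimate[fit$table$term == "x"]
  expect_equal(b1, 2, tolerance = 0.15)
  expect_equal(fit$table$or[2], exp(b1))
  expect_false(fit$separation)
})

test_that("wald odds-ratio intervals are calibrated under the null", {
  set.seed(32)
  covered <- vapply(1:20, function(i) {
    d <- data.frame(R = rbinom(2000, 1, 0.5), x = runif(2000))
    tab <- fit_logistic(d, "univariate", predictor = "x")$table
    tab$or_lo[2] <= 1 && 1 <= tab$or_hi[2]
  }, logical(1))
  expect_gte(sum(covered), 17)
})

test_that("degenerate and singular designs are rejected by name", {
  d <- data.frame(R = rbinom(100, 1, 0.5), x = rnorm(100))
  d$zero <- 0
  expect_error(model_input(within(d, {
    claim_id <- 1; L_supt <- zero; S_ind <- x; M_ind <- x; K_ind <- x
    C <- x; J <- x; CV <- x
  })), "degenerate")
  d2 <- data.frame(R = rbinom(200, 1, 0.5), a = rnorm(200))
  d2$b <- d2$a  # perfectly collinear
  expect_error(
    fit_logistic(d2, "interaction"),  # no L_supt column
    "object|interaction|L_supt")
  d3 <- d2
  names(d3) <- c("R", "L_supt", "CV")
  d3$S_ind <- d3$L_supt
  fml_fit <- tryCatch(fit_logistic(d3, "multivariate"), error = function(e) e)
  expect_true(inherits(fml_fit, "error"))  # missing predictors is an error
})

test_that("perfect separation is flagged", {
  d <- data.frame(R = rep(c(0, 1), each = 50), x = rep(c(0, 1), each = 50))
  expect_warning(fit <- fit_logistic(d, "univariate", predictor = "x"),
                 "separation")
  expect_true(fit$separation)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  p <- sort(runif(15))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force min-over-tails definition", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
      tail_idx <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
      adj[i] <- min(1, min(p[tail_idx] * n / rank(p, ties.method = "first")[tail_idx]))
    }
    adj
  }
  set.seed(33)
  for (i in 1:10) {
    p <- runif(sample(3:25, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("interaction models expose the paper form and the main-effect variant", {
  set.seed(34)
  n <- 3000
  d <- data.frame(L_supt = runif(n), S_ind = runif(n), C = runif(n), CV = runif(n))
  eta <- -2 + 4 * d$L_supt * d$S_ind + 0.5 * d$CV
  d$R <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(d, "interaction", interaction_with = "S_ind")
  expect_setequal(fit$table$term, c("(Intercept)", "CV", "L_supt:S_ind"))
  b <- fit$table$estimate[fit$table$term == "L_supt:S_ind"]
  expect_equal(b, 4, tolerance = 0.5)
  fit_me <- fit_logistic(d, "interaction", interaction_with = "S_ind",
                         main_effects = TRUE)
  expect_true(all(c("L_supt", "S_ind") %in% fit_me$table$term))
})

test_that("predicted surfaces are monotone and recover generator probabilities", {
  set.seed(35)
  n <- 4000
  d <- data.frame(L_supt = runif(n), S_ind = runif(n), CV = runif(n))
  truth <- function(l, s, cv) plogis(-2 + 4 * l * s + 0.5 * cv)
  d$R <- rbinom(n, 1, truth(d$L_supt, d$S_ind, d$CV))
  fit <- fit_logistic(d, "interaction", interaction_with = "S_ind")
  surf <- predict_surface(fit, n_grid = 11, cv = 0.5)
  expect_equal(attr(surf, "with"), "S_ind")
  # monotone in L_supt at fixed partner value (positive product coefficient)
  for (xv in unique(surf$x)[c(2, 6, 11)]) {
    expect_true(all(diff(surf$prob[surf$x == xv]) >= 0))
  }
  # plug-in oracle at grid nodes
  expect_equal(surf$prob, truth(surf$L_supt, surf$x, 0.5), tolerance = 0.06)
  expect_error(predict_surface(fit_logistic(d, "univariate", predictor = "CV")),
               "interaction")
})
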