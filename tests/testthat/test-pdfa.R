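test_that("the discriminant core matches analytic and reference oracles", {
  set.seed(1)
  n <- 200
  mu1 <- c(0, 0); mu2 <- c(3, 1)
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  ch <- chol(sigma)
  x1 <- matrix(rnorm(n * 2), n, 2) %*% ch
  x2 <- sweep(matrix(rnorm(n * 2), n, 2) %*% ch, 2, mu2, "+")
  train <- rbind(x1, x2)
  colnames(train) <- c("v1", "v2")
  y <- rep(c("a", "b"), each = n)
  test <- as.matrix(expand.grid(v1 = seq(-3, 6, 0.25),
                                v2 = seq(-3, 4, 0.25)))

  pred <- lda_fit_classify(train, y, test)

  # analytic Fisher rule from the sample moments
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s_pooled <- (cov(x1) * (n - 1) + cov(x2) * (n - 1)) / (2 * n - 2)
  w <- solve(s_pooled, m2 - m1)
  thresh <- sum(w * (m1 + m2)) / 2
  oracle <- ifelse(test %*% w > thresh, "b", "a")
  expect_equal(pred, as.vector(oracle))

  # and MASS::lda (equal priors) agrees
  skip_if_not_installed("MASS")
  mfit <- MASS::lda(train, grouping = y, prior = c(0.5, 0.5))
  mpred <- as.character(predict(mfit, test)$class)
  expect_equal(pred, mpred)
})

test_that("classification accuracy is near 1 for separated classes and near chance otherwise", {
  set.seed(2)
  sep_train <- rbind(matrix(rnorm(400), 200, 2),
                     matrix(rnorm(400, mean = 6), 200, 2))
  y <- rep(c("a", "b"), each = 200)
  sep_test <- rbind(matrix(rnorm(400), 200, 2),
                    matrix(rnorm(400, mean = 6), 200, 2))
  acc <- mean(lda_fit_classify(sep_train, y, sep_test) == y)
  expect_gte(acc, 0.99)

  same_train <- matrix(rnorm(800), 400, 2)
  same_test <- matrix(rnorm(800), 400, 2)
  acc0 <- mean(lda_fit_classify(same_train, y, same_test) == y)
  expect_lt(abs(acc0 - 0.5), 0.1)
})

test_that("singular pooled covariance falls back to a ridge", {
  set.seed(3)
  x <- matrix(rnorm(60), 30, 2)
  x <- cbind(x, x[, 1] + x[, 2])        # exactly collinear third variable
  y <- rep(c("a", "b"), 15)
  expect_message(fit <- vocalaccom:::lda_train(x, y), "ridge")
  expect_true(all(is.finite(fit$w)))
})

test_that("crossed pDFA reports the study's result shape deterministically", {
  d <- make_crossed_data(seed = 10, shift = 1.5)
  des <- pdfa_design(variables = paste0("V", 1:4), n_permutations = 150,
                     n_selection_rounds = 5, seed = 77)
  res <- crossed_pdfa(d, des)
  expect_s3_class(res, "pdfa")
  expect_equal(res$n_calls, 320)
  expect_equal(res$n_individuals, 8)
  expect_true(res$pct_actual_correct >= 0 && res$pct_actual_correct <= 100)
  expect_true(res$pct_expected_correct >= 0 &&
                res$pct_expected_correct <= 100)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # identical design and seed reproduce the result exactly
  res2 <- crossed_pdfa(d, des)
  expect_identical(res[c("pct_expected_correct", "pct_actual_correct",
                         "p_value")],
                   res2[c("pct_expected_correct", "pct_actual_correct",
                          "p_value")])
  # a clear condition effect is detected
  expect_lt(res$p_value, 0.05)
})

test_that("pDFA is invariant to variable order and affine rescaling", {
  d <- make_crossed_data(seed = 11, shift = 1)
  des <- function(vars) {
    pdfa_design(variables = vars, n_permutations = 120,
                n_selection_rounds = 5, seed = 5)
  }
  base <- crossed_pdfa(d, des(paste0("V", 1:4)))
  reordered <- crossed_pdfa(d, des(paste0("V", c(3, 1, 4, 2))))
  expect_equal(base$p_value, reordered$p_value)
  expect_equal(base$pct_actual_correct, reordered$pct_actual_correct)

  d2 <- d
  d2$V2 <- d2$V2 * 1000 - 17
  rescaled <- crossed_pdfa(d2, des(paste0("V", 1:4)))
  expect_equal(base$p_value, rescaled$p_value)
  expect_equal(base$pct_actual_correct, rescaled$pct_actual_correct,
               tolerance = 1e-10)
})

test_that("pDFA rejects non-crossed designs and bad quotas", {
  d <- make_crossed_data(seed = 12)
  d <- d[!(d$caller == "ind01" & d$condition == "B"), ]
  expect_error(
    crossed_pdfa(d, pdfa_design(variables = paste0("V", 1:4),
                                n_permutations = 100)),
    "not crossed")
  d2 <- make_crossed_data(seed = 13, n_call = 5)
  expect_error(
    crossed_pdfa(d2, pdfa_design(variables = paste0("V", 1:4),
                                 n_permutations = 100, cell_quota = 10)),
    "quota")
  expect_error(pdfa_design(variables = "V1", n_permutations = 10), ">= 100")
})

test_that("under the null, actual and expected accuracy coincide", {
  d <- make_crossed_data(seed = 14, shift = 0)
  res <- crossed_pdfa(d, pdfa_design(variables = paste0("V", 1:4),
                                     n_permutations = 200,
                                     n_selection_rounds = 10, seed = 3))
  expect_lt(abs(res$pct_actual_correct - res$pct_expected_correct), 5)
  expect_gt(res$p_value, 0.05)
})
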