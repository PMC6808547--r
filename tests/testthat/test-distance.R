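test_that("trimmed mean matches hand computations and a brute-force oracle", {
  expect_equal(trimmed_mean(c(1:9, 100), trim = 0.10), 5.5)   # drops 1 and 100
  expect_equal(trimmed_mean(c(5, 1, 9), trim = 0.10), 5)      # floor = 0
  expect_error(trimmed_mean(numeric(0)), "trimming")
  # oracle equivalence: sort, slice, mean
  set.seed(41)
  for (i in 1:200) {
    v <- rnorm(sample(1:60, 1))
    tr <- runif(1, 0, 0.4)
    k <- floor(tr * length(v))
    if (length(v) - 2 * k < 1) next
    s <- sort(v)
    oracle <- mean(s[(k + 1):(length(v) - k)])
    expect_equal(trimmed_mean(v, tr), oracle, tolerance = 1e-12)
  }
})

test_that("population centroid is a mean of per-individual trimmed means", {
  # all calls identical -> centroid at that point
  sc <- matrix(rep(c(1, -2, 3), each = 20), 20, 3)
  ids <- rep(c("a", "b"), 10)
  cen <- population_centroid(sc, ids)
  expect_equal(unname(cen$coordinates), c(1, -2, 3))

  # symmetric individuals -> midpoint
  sc2 <- rbind(matrix(rep(c(2, 2), each = 15), 15, 2),
               matrix(rep(c(-2, -2), each = 15), 15, 2))
  cen2 <- population_centroid(sc2, rep(c("a", "b"), each = 15))
  expect_equal(unname(cen2$coordinates), c(0, 0))

  expect_error(population_centroid(sc, rep("a", 20)), ">= 2")

  # two-stage brute-force oracle on random data
  set.seed(42)
  for (i in 1:50) {
    n_ind <- sample(2:6, 1)
    ids <- rep(sprintf("i%d", seq_len(n_ind)), each = 15)
    sc <- matrix(rnorm(15 * n_ind * 4), ncol = 4)
    cen <- population_centroid(sc, ids)
    oracle <- colMeans(t(vapply(unique(ids), function(i) {
      apply(sc[ids == i, , drop = FALSE], 2, function(v) {
        s <- sort(v); k <- floor(0.1 * length(v))
        mean(s[(k + 1):(length(v) - k)])
      })
    }, numeric(4))))
    expect_equal(unname(cen$coordinates), unname(oracle), tolerance = 1e-12)
  }
})

test_that("a single outlier call cannot move the centroid", {
  set.seed(43)
  sc <- matrix(rnorm(40), 20, 2)
  ids <- rep(c("a", "b"), each = 10)
  cen <- population_centroid(sc, ids)
  sc_out <- sc
  sc_out[3, ] <- c(1e6, -1e6)   # one wild call of individual "a" (>= 10 calls)
  cen_out <- population_centroid(sc_out, ids)
  expect_lt(max(abs(cen_out$coordinates - cen$coordinates)), 0.5)
})

test_that("weighted distance follows the stated formula", {
  expect_equal(weighted_distance(c(3, 4), c(0, 0), c(1, 1)), 5)
  expect_equal(weighted_distance(c(2, 4), c(0, 0), c(0.5, 0.25)), sqrt(2))
  expect_equal(weighted_distance(c(1, 1), c(1, 1), c(0.4, 0.2)), 0)
  expect_error(weighted_distance(c(1, 2, 3), c(0, 0), c(1, 1)),
               "dimensionality")
  # translation invariance
  set.seed(44)
  for (i in 1:20) {
    s <- rnorm(4); cen <- rnorm(4); p <- runif(4); shift <- rnorm(4)
    expect_equal(weighted_distance(s, cen, p),
                 weighted_distance(s + shift, cen + shift, p),
                 tolerance = 1e-12)
  }
  # equal proportions reduce to a scaled Euclidean distance
  s <- c(1, 2, 3); cen <- c(0, 1, -1)
  expect_equal(weighted_distance(s, cen, rep(0.25, 3)),
               0.25 * sqrt(sum((s - cen)^2)))
  # the sqrt variant puts the weights inside the squares
  expect_equal(weighted_distance(c(2, 4), c(0, 0), c(0.5, 0.25),
                                 method = "sqrt"),
               sqrt(0.5 * 4 + 0.25 * 16))
  # brute-force oracle on random instances
  for (i in 1:50) {
    k <- sample(2:6, 1)
    s <- rnorm(k); cen <- rnorm(k); p <- runif(k)
    expect_equal(weighted_distance(s, cen, p),
                 sqrt(sum((p * (s - cen))^2)), tolerance = 1e-12)
  }
})

test_that("distance records keep one row per call with consistent logs", {
  set.seed(45)
  n <- 30
  scores <- matrix(rnorm(2 * n), n, 2)
  meta <- data.frame(caller = rep(c("m1", "m2"), n / 2), sex = "F",
                     call_type = "phee", week = rep(1:5, 6),
                     condition = "NewSoc")
  base_scores <- matrix(rnorm(80), 40, 2)
  cen <- population_centroid(base_scores, rep(c("z1", "z2"), 20))
  model <- structure(list(proportions = c(0.4, 0.2, 0.1), n_retained = 2L),
                     class = "retained_pca")
  rec <- build_distance_records(scores, meta, cen, model)
  expect_equal(nrow(rec), n)
  expect_true(all(rec$distance > 0))
  expect_equal(rec$ln_distance, log(rec$distance))
  # a call exactly on the centroid is clamped with a warning
  scores0 <- rbind(cen$coordinates)
  meta0 <- meta[1, ]
  expect_warning(rec0 <- build_distance_records(scores0, meta0, cen, model),
                 "clamped")
  expect_equal(rec0$ln_distance, log(1e-12))
})
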