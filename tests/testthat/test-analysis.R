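make_separable <- function(n_per_class = 10L, n_classes = 3L, sd = 0.05,
                           seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    centers <- diag(n_classes)[k, ]
    matrix(rep(centers, n_per_class), ncol = n_classes, byrow = TRUE) +
      rnorm(n_per_class * n_classes, sd = sd)
  }))
  decode_dataset(x, rep(seq_len(n_classes), each = n_per_class))
}

test_that("nearest-centroid decoder separates one-hot classes perfectly", {
  d <- make_separable()
  dec <- train_linear_decoder(d, seed = 1L)
  expect_equal(dec$cv_accuracy, 1)
  expect_equal(dec$train_accuracy, 1)
  expect_equal(dec$chance, 1 / 3)
})

test_that("label shuffling destroys decodability", {
  d <- make_separable(n_per_class = 20L)
  set.seed(2)
  d$labels <- sample(d$labels)
  dec <- train_linear_decoder(d, seed = 2L)
  ci <- boot_ci(dec$cv_pred == as.character(d$labels))
  expect_true(ci[1] <= dec$chance + 0.15)
})

test_that("training accuracy is at least cross-validated accuracy", {
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6)
  x[1:20, 1] <- x[1:20, 1] + 0.8
  d <- decode_dataset(x, rep(1:2, each = 20))
  dec <- train_linear_decoder(d, seed = 3L)
  expect_gte(dec$train_accuracy, dec$cv_accuracy)
})

test_that("decoder input validation", {
  expect_error(decode_dataset(matrix(0, 4, 2), rep(1, 4)), "2 label")
  expect_error(decode_dataset(matrix(0, 4, 2), 1:3), "one label per")
})

test_that("cross-decoding equals within-decoding when train == test", {
  d <- make_separable(n_per_class = 12L)
  cd <- cross_decode(d, d, n_shuffle = 200L, seed = 4L)
  expect_equal(cd$accuracy, 1)
  expect_equal(cd$within_cv_accuracy, 1)
})

test_that("cross-decoding orthogonal random patterns sits at chance", {
  set.seed(5)
  mk <- function() decode_dataset(matrix(rnorm(60 * 8), 60, 8),
                                  rep(1:3, each = 20))
  cd <- cross_decode(mk(), mk(), n_shuffle = 300L, seed = 5L)
  expect_gte(cd$accuracy, cd$null_lo - 0.05)
  expect_lte(cd$accuracy, cd$null_hi + 0.05)
})

test_that("cross-decoding rejects mismatched label spaces or units", {
  d1 <- make_separable()
  d2 <- decode_dataset(matrix(rnorm(20), 10, 2), rep(1:2, each = 5))
  expect_error(cross_decode(d1, d2), "label spaces|unit")
})

test_that("pattern similarity: identical, inverted, and null cases", {
  v <- c(0.1, 0.9, 0.3, 0.6)
  expect_equal(pattern_similarity(v, v), 1)
  expect_equal(pattern_similarity(v, mean(v) - (v - mean(v))), -1)
  expect_true(is.na(pattern_similarity(rep(1, 4), v)))
  expect_error(pattern_similarity(1:3, 1:4))
})

test_that("similarity of independent random vectors averages to zero", {
  # brute-force Monte-Carlo over length-4 pairs
  set.seed(6)
  sims <- vapply(seq_len(4000L), function(i) {
    pattern_similarity(rnorm(4), rnorm(4))
  }, 0)
  expect_lt(abs(mean(sims)), 0.02)
  expect_true(all(sims >= -1 & sims <= 1))
})

test_that("similarity is symmetric and affine-invariant", {
  set.seed(7)
  for (k in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(pattern_similarity(a, b), pattern_similarity(b, a))
    expect_equal(pattern_similarity(2.5 * a + 1, 2.5 * b + 1),
                 pattern_similarity(a, b), tolerance = 1e-12)
  }
})

test_that("decode_timecourse reports one row per window with chance", {
  set.seed(8)
  n_f <- n_features(canon)
  labels <- rep(1:2, each = 10L)
  traces <- lapply(labels, function(l) {
    tr <- matrix(abs(rnorm(60 * (n_f + 4), sd = 0.05)), 60, n_f + 4)
    tr[31:60, l] <- tr[31:60, l] + 0.8
    tr
  })
  rep_tc <- decode_timecourse(traces, labels,
                              windows = list(early = c(1, 30),
                                             late = c(31, 60)),
                              units = "feature", params = canon, seed = 8L)
  expect_identical(nrow(rep_tc), 2L)
  expect_equal(rep_tc$chance, c(0.5, 0.5))
  expect_gt(rep_tc$accuracy[rep_tc$window == "late"], 0.9)
  expect_s3_class(autoplot(rep_tc), "ggplot")
})

test_that("tidy and glance summarize decoder fits", {
  d <- make_separable()
  dec <- train_linear_decoder(d, seed = 9L)
  td <- tidy(dec)
  expect_identical(nrow(td), 1L)
  expect_true(all(c("accuracy", "ci_lo", "ci_hi", "chance") %in% names(td)))
  gl <- glance(dec)
  expect_identical(gl$n_classes, 3L)
  cd <- cross_decode(d, d, n_shuffle = 100L, seed = 9L)
  expect_true(all(c("accuracy", "null_lo", "null_hi") %in%
                    names(tidy(cd))))
})

test_that("regularized logistic decoder is available as a flag", {
  skip_if_not_installed("nnet")
  d <- make_separable(n_per_class = 8L)
  dec <- train_linear_decoder(d, seed = 10L, method = "logistic")
  expect_gte(dec$cv_accuracy, 0.9)
})
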