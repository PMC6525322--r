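test_that("initialization is deterministic and row-normalized", {
  s1 <- init_network(canon, seed = 0L)
  s2 <- init_network(canon, seed = 0L)
  expect_identical(s1, s2)
  expect_false(identical(s1$W_fc, init_network(canon, seed = 1L)$W_fc))

  expect_equal(unname(sqrt(rowSums(s1$W_fc^2))),
               rep(canon$w_norm, canon$n_conj))
  expect_equal(unname(sqrt(rowSums(s1$W_cf^2))),
               rep(canon$w_norm, n_features(canon)))
  expect_true(all(s1$f == 0) && all(s1$c == 0) && s1$t == 0L)

  # no jitter: every incoming row identical
  s0 <- init_network(wm_params(w_init_scale = 0), seed = 3L)
  expect_equal(s0$W_fc, matrix(s0$W_fc[1, 1], nrow(s0$W_fc),
                               ncol(s0$W_fc)), ignore_attr = TRUE)
})

test_that("silent network with zero weights and no noise is a fixed point", {
  p <- wm_params(noise_sigma = 0, w_init_scale = 0)
  s <- init_network(p, 1L)
  s$W_fc[] <- 0
  s$W_cf[] <- 0
  res <- run_epoch(s, numeric(n_features(p)), 50L, p)
  expect_true(all(res$trace == 0))
})

test_that("step errors on dimension mismatch and counts time", {
  s <- init_network(canon, 1L)
  expect_error(step_network(s, numeric(3), canon), "length")
  s2 <- step_network(s, numeric(n_features(canon)), canon)
  expect_identical(s2$t, 1L)
})

test_that("single-item attractor persists through a long noiseless delay", {
  enc <- encode_one(canon0, seed = 7L)
  del <- run_epoch(enc$state, numeric(n_features(canon0)), 500L, canon0)
  fmean <- colMeans(del$trace[, seq_len(n_features(canon0))])
  expect_true(all(fmean[enc$units] > 0.5))
  expect_true(all(fmean[-enc$units] < 0.2))
})

test_that("lateral inhibition resolves equal drive into a single winner", {
  # two conjunctive units given equal feedforward drive, tiny weight
  # jitter: competition must break the tie within 100 steps
  p <- wm_params(noise_sigma = 0)
  s <- init_network(p, 42L)
  item <- make_items(1L, p)
  res <- run_epoch(s, encode_input(item, p), 100L, p)
  c_end <- res$trace[100, n_features(p) + seq_len(p$n_conj)]
  expect_identical(sum(c_end > 0.5), 1L)
  ranked <- sort(c_end, decreasing = TRUE)
  expect_gt(ranked[1] - ranked[2], 0.3)
})

test_that("encoding competition never admits more than one winner", {
  # across many single-item encodings: at most one conjunctive unit's
  # second-half mean rate exceeds 0.5, and a clear majority of epochs
  # resolve a unique winner (the remainder resolve later in the trial)
  n_winners <- vapply(1:20, function(seed) {
    enc <- encode_one(canon0, seed = seed)
    half <- canon0$timing$stim %/% 2L
    cmean <- colMeans(enc$trace[half:canon0$timing$stim,
                                n_features(canon0) +
                                  seq_len(canon0$n_conj)])
    sum(cmean > 0.5)
  }, 0)
  expect_true(all(n_winners <= 1))
  expect_gte(mean(n_winners == 1), 0.7)
})

test_that("plasticity with silent units leaves weights unchanged", {
  s <- init_network(canon, 5L)
  s2 <- plasticity_update(s, canon)
  expect_equal(s2$W_fc, s$W_fc)
  expect_equal(s2$W_cf, s$W_cf)
})

test_that("Hebbian co-activity concentrates the synapse and erodes the rest", {
  p <- wm_params(noise_sigma = 0)
  s <- init_network(p, 8L)
  s$f[3] <- 1
  s$c[2] <- 1
  before <- s$W_fc[2, ]
  for (k in 1:100) s <- plasticity_update(s, p)
  expect_identical(which.max(s$W_fc[2, ]), 3L)
  expect_identical(which.max(s$W_cf[3, ]), 2L)
  # row normalization forces every other synapse in the row to shrink
  expect_true(all(s$W_fc[2, -3] < before[-3]))
  expect_equal(sqrt(sum(s$W_fc[2, ]^2)), p$w_norm, tolerance = 1e-10)
})

test_that("fused epoch equals step_network + plasticity_update composition", {
  p <- wm_params()  # with noise: exercises the shared RNG stream
  s <- init_network(p, 21L)
  i_ext <- encode_input(make_items(1L, p), p)
  set.seed(99)
  fused <- run_epoch(s, i_ext, 5L, p, record = FALSE)$state
  set.seed(99)
  s2 <- s
  for (k in 1:5) {
    s2 <- plasticity_update(step_network(s2, i_ext, p), p)
  }
  expect_equal(fused$f, s2$f, tolerance = 1e-12)
  expect_equal(fused$W_fc, s2$W_fc, tolerance = 1e-12)
  expect_equal(fused$W_cf, s2$W_cf, tolerance = 1e-12)
})

test_that("rates and weight norms stay bounded under prolonged random input", {
  p <- wm_params()
  s <- init_network(p, 13L)
  set.seed(13)
  worst_rate <- 0
  for (chunk in 1:200) {
    i_ext <- runif(n_features(p), -1, 2)
    res <- run_epoch(s, i_ext, 500L, p)
    s <- res$state
    worst_rate <- max(worst_rate, max(res$trace))
    expect_true(min(res$trace) >= 0)
    expect_true(all(sqrt(rowSums(s$W_fc^2)) <= p$w_norm + 1e-8))
    expect_true(all(sqrt(rowSums(s$W_cf^2)) <= p$w_norm + 1e-8))
  }
  expect_lte(worst_rate, 1)
})

test_that("a second item silences the first but spares its synaptic trace", {
  # the trace survives whenever a distinct conjunction encodes item 2;
  # seeds fixed on trials where the winners differ
  hits <- 0L
  for (seed in c(1L, 2L, 5L, 8L)) {
    set.seed(seed)
    s <- init_network(canon, seed)
    items <- make_items(2L, canon)
    n_f <- n_features(canon)
    s <- run_epoch(s, rep(-1, n_f), canon$timing$reset, canon,
                   record = FALSE)$state
    e1 <- run_epoch(s, encode_input(items[1, ], canon),
                    canon$timing$stim, canon)
    w1 <- which.max(colMeans(e1$trace[26:50, n_f + 1:4]))
    s <- run_epoch(e1$state, numeric(n_f), canon$timing$gap, canon,
                   record = FALSE)$state
    e2 <- run_epoch(s, encode_input(items[2, ], canon),
                    canon$timing$stim, canon)
    w2 <- which.max(colMeans(e2$trace[26:50, n_f + 1:4]))
    if (w1 == w2) next
    hits <- hits + 1L
    u1 <- which(encode_input(items[1, ], canon) > 0)
    expect_true(all(e2$state$f[u1] < 0.2))
    expect_true(all(rank(-e2$state$W_fc[w1, ])[u1] <= 3))
  }
  expect_gte(hits, 3L)
})

test_that("variant contracts: facilitation is presynaptic and shared", {
  p <- wm_params(variant = "facilitation_only")
  s <- init_network(p, 3L)
  s$f[5] <- 1
  s2 <- plasticity_update(s, p)
  expect_gt(s2$u_f[5], 0)
  expect_equal(s2$u_f[-5], numeric(n_features(p) - 1L))
  # weights untouched: facilitation has no Hebbian term
  expect_identical(s2$W_fc, s$W_fc)
})

test_that("no_c_to_f_plasticity freezes the feedback weights", {
  p <- wm_params(variant = "no_c_to_f_plasticity", noise_sigma = 0)
  s <- init_network(p, 3L)
  res <- run_epoch(s, encode_input(make_items(1L, p), p), 50L, p)
  expect_identical(res$state$W_cf, s$W_cf)
  expect_false(identical(res$state$W_fc, s$W_fc))
})

test_that("no_conjunctive_layer recurs through W_ff with a silent diagonal", {
  p <- wm_params(variant = "no_conjunctive_layer", noise_sigma = 0)
  s <- init_network(p, 3L)
  res <- run_epoch(s, encode_input(make_items(1L, p), p), 50L, p)
  expect_true(all(res$trace[, n_features(p) + seq_len(p$n_conj)] == 0))
  expect_false(identical(res$state$W_ff, s$W_ff))
  expect_true(all(diag(res$state$W_ff) == 0))
})

test_that("epoch traces are labeled, sized, and tidyable", {
  s <- init_network(canon, 2L)
  res <- run_epoch(s, numeric(n_features(canon)), 1L, canon)
  expect_identical(nrow(res$trace), 1L)
  res <- run_epoch(s, numeric(n_features(canon)), 25L, canon)
  td <- tidy_trace(res$trace)
  expect_identical(nrow(td), 25L * (n_features(canon) + canon$n_conj))
  expect_setequal(unique(td$unit_type), c("feature", "conjunctive"))
  expect_true(all(td$rate >= 0 & td$rate <= 1))
})
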