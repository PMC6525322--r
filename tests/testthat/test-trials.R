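test_that("trial scripts have the scripted epoch structure and duration", {
  set.seed(1)
  items <- make_items(2L, canon)
  sc <- build_trial(items, canon)
  expect_identical(sc$epochs$kind,
                   c("reset", "stimulus", "blank", "stimulus", "blank",
                     "delay", "probe", "readout", "blank"))
  tm <- canon$timing
  expect_identical(script_duration(sc),
                   tm$reset + 2L * (tm$stim + tm$gap) + tm$delay +
                     tm$probe + tm$readout + tm$blank)
  # trace length equals scripted duration
  out <- run_trial(init_network(canon, 1L), sc, canon)
  expect_identical(nrow(out$result$trace), script_duration(sc))
})

test_that("pulse epochs are uniform input embedded in the delay", {
  set.seed(2)
  items <- make_items(2L, canon)
  sc <- build_trial(items, canon, pulse = list(strength = 1, duration = 10))
  pr <- which(sc$epochs$kind == "pulse")
  expect_length(pr, 1L)
  expect_equal(sc$epochs$input[[pr]], rep(1, n_features(canon)))
  expect_identical(sc$epochs$duration[pr], 10L)
  # the pulse replaces delay time: total duration unchanged
  expect_identical(script_duration(sc),
                   script_duration(build_trial(items, canon)))
  expect_error(
    build_trial(items, canon, pulse = list(strength = 1, duration = 10,
                                           at = 500)),
    "outside the delay")
})

test_that("retro-cue input is the cued item's single feature", {
  set.seed(3)
  items <- make_items(2L, canon)
  sc <- build_trial(items, canon, retrocue = list(item = 1L, dim = 1L))
  cu <- which(sc$epochs$kind == "cue")
  expect_length(cu, 1L)
  target <- encode_input(items[1, ], canon)
  target[-feature_unit(1L, items$color[1], canon)] <- 0
  expect_equal(sc$epochs$input[[cu]], target)
})

test_that("probe interference adds a report-dimension feature to the probe", {
  set.seed(4)
  items <- make_items(1L, canon)
  sc <- build_trial(items, canon, probe_item = 1L, probe_interference = 2L)
  pr <- which(sc$epochs$kind == "probe")
  expect_identical(sum(sc$epochs$input[[pr]] > 0), 2L)
  expect_gt(sc$epochs$input[[pr]][feature_unit(2L, 2L, canon)], 0)
})

test_that("probe-free scripts never produce a report", {
  set.seed(5)
  items <- make_items(1L, canon)
  sc <- build_trial(items, canon, probe_item = 1L)
  sc$epochs <- sc$epochs[sc$epochs$kind != "probe", ]
  out <- run_trial(init_network(canon, 5L), sc, canon)
  expect_true(is.na(out$result$reported))
  expect_false(out$result$correct)
})

test_that("single-item recall by pattern completion works noiselessly", {
  r <- quick_trial(canon0, 1L, 1L, seed = 5L)
  expect_true(r$correct)
  expect_gte(r$rt_steps, 1L)
})

test_that("identical state, script and seed give identical results", {
  set.seed(6)
  items <- make_items(2L, canon)
  sc <- build_trial(items, canon, probe_item = 1L)
  s <- init_network(canon, 6L)
  set.seed(123); r1 <- run_trial(s, sc, canon)
  set.seed(123); r2 <- run_trial(s, sc, canon)
  expect_identical(r1$result$reported, r2$result$reported)
  expect_identical(r1$result$trace, r2$result$trace)
  expect_identical(r1$state$W_fc, r2$state$W_fc)
})

test_that("weights carry across trials; rates are quenched by the reset", {
  s <- init_network(canon, 7L)
  set.seed(7)
  items <- make_items(1L, canon)
  sc <- build_trial(items, canon, probe_item = 1L)
  out <- run_trial(s, sc, canon)
  expect_gt(out$state$t, 0L)
  expect_false(identical(out$state$W_fc, s$W_fc))
  # second trial in the same block starts with a reset epoch
  out2 <- run_trial(out$state, sc, canon)
  tr <- unclass(out2$result$trace)
  expect_lt(max(tr[canon$timing$reset, ]), 0.35)
})

test_that("shuffled weights reduce reports to the guessing level", {
  shuf <- lapply(seq_len(80L), function(i) {
    quick_trial(canon, 2L, 1L, seed = 2000L + 37L * i,
                shuffle_before_probe = TRUE)
  })
  reported <- !vapply(shuf, function(r) is.na(r$reported), TRUE)
  expect_gt(mean(reported), 0.1)  # random completion does produce reports
  acc_rep <- vapply(shuf[reported], `[[`, TRUE, "correct")
  ci <- boot_ci(acc_rep)
  expect_true(ci[1] - 0.12 <= 0.25 && 0.25 <= ci[2] + 0.12)
  # overall accuracy cannot exceed the guessing level by much
  expect_lte(mean(vapply(shuf, `[[`, TRUE, "correct")), 0.4)
})

test_that("rule trials: script shape and pattern completion", {
  rules <- tibble::tibble(color = c(1L, 3L), response = c(2L, 4L))
  sc <- build_rule_trial(rules, 1L, canon)
  expect_identical(sum(sc$epochs$kind == "stimulus"), 2L)
  expect_identical(sum(sc$epochs$kind == "probe"), 1L)
  # rule stimuli co-activate a color and a motor-plan feature
  st <- which(sc$epochs$kind == "stimulus")[1]
  expect_identical(which(sc$epochs$input[[st]] > 0),
                   c(feature_unit(1L, 1L, canon),
                     feature_unit(3L, 2L, canon)))
  expect_identical(sc$target_response, 2L)
  expect_false(sc$generalization)
  # a color outside the rule set is allowed and flagged
  sc2 <- build_rule_trial(rules, 2L, canon)
  expect_true(sc2$generalization)
  # four rules produce four encoding epochs
  rules4 <- tibble::tibble(color = 1:4, response = c(2L, 1L, 4L, 3L))
  expect_identical(sum(build_rule_trial(rules4, 1L, canon)$epochs$kind ==
                         "stimulus"), 4L)
})

test_that("an encoded rule maps its stimulus to its response", {
  # stochastic pattern completion: majority of seeds must recall the
  # rule's motor plan
  rules <- tibble::tibble(color = 2L, response = 3L)
  hits <- vapply(1:10, function(i) {
    s <- init_network(canon, 400L + i)
    sc <- build_rule_trial(rules, 2L, canon)
    r <- run_trial(s, sc, canon, record = FALSE)$result
    isTRUE(r$correct)
  }, TRUE)
  expect_gte(mean(hits), 0.7)
})

test_that("trial scripts survive a JSON round trip", {
  set.seed(8)
  items <- make_items(2L, canon)
  sc <- build_trial(items, canon, probe_item = 2L,
                    retrocue = list(item = 1L, dim = 3L))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_script_json(sc, tmp)
  sc2 <- read_script_json(tmp)
  expect_identical(sc2$epochs$kind, sc$epochs$kind)
  expect_identical(sc2$epochs$duration, sc$epochs$duration)
  expect_equal(sc2$epochs$input, sc$epochs$input)
  expect_equal(sc2$probe_feature, sc$probe_feature)
  # replay gives identical behavior
  s <- init_network(canon, 8L)
  set.seed(11); r1 <- run_trial(s, sc, canon, record = FALSE)
  set.seed(11); r2 <- run_trial(s, sc2, canon, record = FALSE)
  expect_identical(r1$result$reported, r2$result$reported)
})
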