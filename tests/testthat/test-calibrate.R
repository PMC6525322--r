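test_that("a search space containing the canonical point passes", {
  res <- calibrate(canon, search = list(eta = canon$eta), seed = 2L,
                   n_trials = 32L)
  expect_true(res$passed)
  expect_equal(res$params$eta, canon$eta)
  expect_true(all(c("target", "value", "pass", "mandatory") %in%
                    names(res$report)))
})

test_that("calibration without plasticity fails loudly", {
  expect_error(
    calibrate(canon, search = list(eta = 0), seed = 3L, n_trials = 16L),
    "calibration failed")
})

test_that("the report lists pass/fail per target per cell", {
  res <- calibrate(canon, search = list(eta = c(canon$eta, 0)), seed = 4L,
                   n_trials = 32L)
  expect_identical(length(unique(res$report$cell)), 2L)
  per_cell <- table(res$report$cell)
  expect_true(all(per_cell == per_cell[1]))
  expect_type(res$report$pass, "logical")
})
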