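test_that("experiment tables are exactly reproducible from (config, seed)", {
  t1 <- exp_set_size(canon, n_trials = 10L, set_sizes = c(1L, 2L),
                     seed = 5L)
  t2 <- exp_set_size(canon, n_trials = 10L, set_sizes = c(1L, 2L),
                     seed = 5L)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "config_hash"), attr(t2, "config_hash"))
  t3 <- exp_set_size(canon, n_trials = 10L, set_sizes = c(1L, 2L),
                     seed = 6L)
  expect_false(identical(t1$value, t3$value))
})

test_that("experiment tables are long-format with traceable rows", {
  tab <- exp_set_size(canon, n_trials = 8L, set_sizes = 2L, seed = 1L)
  expect_s3_class(tab, "wm_experiment")
  expect_true(all(c("experiment", "set_size", "block", "trial", "seed",
                    "measurement", "value") %in% names(tab)))
  expect_setequal(unique(tab$measurement),
                  c("correct", "rt_steps", "reported"))
  expect_true(all(!is.na(tab$seed)))
  sm <- summarize_experiment(tab, by = "set_size")
  expect_identical(nrow(sm), 1L)
  expect_identical(sm$n, 8L)
})

test_that("parameter sweep crosses the grid and tags rows", {
  sw <- parameter_sweep(canon, grid = list(eta = c(0, canon$eta)),
                        experiment = "set_size", seed = 2L,
                        n_trials = 8L, set_sizes = 2L)
  expect_setequal(unique(sw$sweep_eta), c(0, canon$eta))
  expect_identical(length(unique(sw$sweep_cell)), 2L)
  # empty grid: a single canonical run
  sw0 <- parameter_sweep(canon, grid = list(), experiment = "set_size",
                         seed = 2L, n_trials = 6L, set_sizes = 1L)
  expect_identical(unique(sw0$sweep_cell), 1L)
  expect_error(parameter_sweep(canon, experiment = "not_an_experiment"),
               "unknown experiment")
})

test_that("without plasticity there is no synaptic storage of earlier items", {
  p0 <- wm_params_override(canon, eta = 0)
  acc <- quick_accuracy(p0, 2L, 1L, n = 40L, seed0 = 300L)
  ci <- boot_ci(vapply(seq_len(40L), function(i) {
    quick_trial(p0, 2L, 1L, seed = 300L + 37L * i)$correct
  }, TRUE))
  expect_true(ci[1] <= 0.25 + 0.1)
})

test_that("previous-trial rows flag block-initial trials for exclusion", {
  tab <- exp_previous_trial_benefit(canon, n_trials = 20L, seed = 3L,
                                    block_size = 10L)
  first <- dplyr::filter(tab, .data$measurement == "correct",
                         .data$first_of_block)
  expect_identical(nrow(first), 2L)  # one per block
  expect_true(all(!dplyr::filter(tab, .data$trial > 1)$first_of_block))
})

test_that("trial-history tables carry lagged pair structure", {
  tab <- exp_trial_history(canon, n_trial_series = 40L, seed = 4L,
                           max_lag = 3L)
  sim <- dplyr::filter(tab, .data$measurement == "similarity")
  expect_setequal(unique(sim$lag), 1:3)
  expect_true(all(sim$pair_type %in% c("same", "different", "partial")))
  expect_true(all(sim$value >= -1 & sim$value <= 1, na.rm = TRUE))
  # lag-1 pairs can have no intervening violations
  expect_true(all(sim$n_violations[sim$lag == 1] == 0))
  gl <- history_gap_lag(tab, n_boot = 200L)
  expect_true(is.numeric(gl$lag_undetectable))
  expect_identical(nrow(gl$by_lag), 3L)
})

test_that("whole-report rows probe every position once per trial", {
  tab <- exp_serial_position(canon, n_trials = 8L, seed = 5L,
                             whole_report_trials = 4L)
  wr <- dplyr::filter(tab, .data$measurement == "wr_correct")
  expect_identical(nrow(wr), 4L * 4L)
  expect_identical(sort(unique(wr$position)), 1:4)
})

test_that("ablation experiment emits the capability matrix for all variants", {
  tab <- exp_ablations(canon, n_trials = 10L, seed = 6L)
  expect_setequal(unique(tab$variant),
                  c("full", "facilitation_only", "no_c_to_f_plasticity",
                    "no_conjunctive_layer"))
  expect_true(all(c("persistence", "cue_shift", "correct") %in%
                    tab$measurement))
  checks <- experiment_checks(tab)
  expect_identical(nrow(checks), 9L)
})

test_that("autoplot renders an experiment summary", {
  tab <- exp_set_size(canon, n_trials = 8L, set_sizes = c(1L, 2L),
                      seed = 7L)
  expect_s3_class(autoplot(tab), "ggplot")
})

test_that("experiment tables round-trip through CSV with config echo", {
  tab <- exp_set_size(canon, n_trials = 6L, set_sizes = 1L, seed = 8L)
  dir <- withr::local_tempdir()
  csv <- write_experiment(tab, dir, canon)
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(dir, "set_size_config.json")))
  back <- read_experiment(csv)
  expect_identical(attr(back, "experiment"), "set_size")
  expect_identical(attr(back, "seed"), attr(tab, "seed"))
  expect_equal(back$value, tab$value)
})
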