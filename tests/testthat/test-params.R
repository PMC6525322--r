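test_that("parameter validation rejects impossible configurations", {
  expect_error(wm_params(n_conj = 0), "counts")
  expect_error(wm_params(tau = 0), "tau")
  expect_error(wm_params(eta = -0.1), "eta")
  expect_error(wm_params(noise_sigma = -1), "noise_sigma")
  expect_error(wm_params(w_norm = 0), "w_norm")
  expect_error(wm_params(timing = list(bogus = 5)), "timing")
  expect_error(wm_params(report_dim = 7), "report_dim")
})

test_that("canonical config ships as YAML and round-trips", {
  p <- canonical_params()
  expect_s3_class(p, "wm_params")
  expect_identical(p$n_dims, 3L)
  expect_identical(p$n_feat_per_dim, 4L)
  expect_identical(p$n_conj, 4L)
  expect_identical(p$variant, "full")

  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, tmp)
  p2 <- read_params(tmp)
  expect_equal(unclass(p2), unclass(p))
  expect_identical(config_hash(p2), config_hash(p))
})

test_that("missing config file errors with the path in the message", {
  expect_error(read_params("/no/such/config.yaml"), "/no/such/config.yaml")
})

test_that("config hash is stable and sensitive to parameter changes", {
  p <- wm_params()
  expect_identical(config_hash(p), config_hash(wm_params()))
  expect_false(config_hash(p) ==
                 config_hash(wm_params_override(p, eta = p$eta * 2)))
})

test_that("wm_params_override revalidates", {
  p <- wm_params()
  expect_error(wm_params_override(p, tau = -1), "tau")
  expect_identical(wm_params_override(p, variant = "facilitation_only")$
                     variant_code, 1L)
})
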