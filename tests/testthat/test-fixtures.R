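test_that("shipped golden fixtures regenerate bit for bit", {
  stored <- system.file("extdata", "fixtures", package = "plastwm")
  skip_if(stored == "", "no shipped fixture bundle")
  manifest <- jsonlite::read_json(file.path(stored, "manifest.json"),
                                  simplifyVector = TRUE)
  dir <- withr::local_tempdir()
  generate_fixtures(seed = manifest$seed[1], dir = dir,
                    every = manifest$every[1])
  files <- list.files(stored)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(stored, f)),
                     label = paste("fixture", f))
  }
})

test_that("fixture bundle covers every model variant", {
  stored <- system.file("extdata", "fixtures", package = "plastwm")
  skip_if(stored == "", "no shipped fixture bundle")
  manifest <- jsonlite::read_json(file.path(stored, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_setequal(unique(manifest$variant),
                  c("full", "facilitation_only", "no_c_to_f_plasticity",
                    "no_conjunctive_layer"))
})

test_that("fixture traces have the scripted number of sampled steps", {
  dir <- withr::local_tempdir()
  manifest <- generate_fixtures(seed = 11L, dir = dir, every = 50L)
  for (i in seq_len(nrow(manifest))) {
    tr <- utils::read.csv(file.path(
      dir, paste0(manifest$scenario[i], "_trace.csv")))
    n_units <- length(unique(paste(tr$unit_type, tr$unit_index)))
    expect_equal(nrow(tr) / n_units, ceiling(manifest$steps[i] / 50))
  }
})
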