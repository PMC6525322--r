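test_that("items are unique per dimension and bounded by feature count", {
  set.seed(1)
  it <- make_items(4L, canon)
  for (d in dimension_names(canon)) {
    expect_setequal(it[[d]], 1:4)
  }
  expect_error(make_items(5L, canon), "unique")
})

test_that("shared-feature mode shares exactly one dimension", {
  set.seed(2)
  for (k in 1:20) {
    it <- make_items(2L, canon, shared_feature = TRUE)
    same <- vapply(dimension_names(canon),
                   function(d) it[[d]][1] == it[[d]][2], TRUE)
    expect_identical(sum(same), 1L)
  }
  expect_error(make_items(1L, canon, shared_feature = TRUE), "2 items")
})

test_that("encode_input uses the dimension-major unit layout", {
  it <- tibble::tibble(item = 1L, color = 1L, orientation = 1L,
                       location = 1L)
  x <- encode_input(it, canon)
  expect_identical(which(x > 0), c(1L, 5L, 9L))
  expect_identical(sum(x > 0), canon$n_dims)
  expect_equal(max(x), canon$stim_drive)

  set.seed(3)
  it2 <- make_items(1L, canon)
  x2 <- encode_input(it2, canon)
  expect_identical(sum(x2 > 0), 3L)
  expect_identical(which(x2 > 0)[2],
                   feature_unit(2L, it2$orientation, canon))
})

test_that("single_feature_input drives exactly one unit", {
  x <- single_feature_input(3L, 2L, canon)
  expect_identical(which(x > 0), feature_unit(3L, 2L, canon))
  expect_equal(sum(x), canon$stim_drive)
  expect_error(single_feature_input(3L, 9L, canon))
})

test_that("dimension names generalize beyond three dimensions", {
  expect_identical(dimension_names(canon),
                   c("color", "orientation", "location"))
  expect_identical(dimension_names(wm_params(n_dims = 2, report_dim = 2,
                                             probe_dim = 1)),
                   c("dim1", "dim2"))
})
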