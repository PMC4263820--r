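test_that("tidy and glance summarise a creep run", {
  run <- default_run("intact")
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("case", "time", "hold_time", "metric", "value"))
  expect_true("displacement_mm" %in% td$metric)
  expect_equal(unique(td$case), "intact")

  gl <- glance(run)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$displacement_end_mm, gl$displacement_ramp_mm)
  expect_equal(gl$creep_increase_pct,
               creep_increase_pct(gl$displacement_ramp_mm,
                                  gl$displacement_end_mm))
})

test_that("plot methods return ggplot objects", {
  run <- default_run("intact")
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_load_partition(run), "ggplot")
  expect_s3_class(plot_fluid_support(run), "ggplot")
})

test_that("drainage partition reports sealed patch interiors", {
  run <- default_run("intact")
  dp <- drainage_partition(run, 1)
  expect_true(all(dp$seal_level >= 0 & dp$seal_level <= 1))
  expect_true(any(dp$status == "sealed"))
  expect_true(any(dp$status == "draining"))
})
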