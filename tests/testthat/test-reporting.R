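test_that("percent activity normalizes each column to its reachable maximum", {
  ty <- random_toy(3, seed = 11)
  m <- feeding_model(ty$spec, ty$params)
  rs <- enumerate_states(m)
  pct <- percent_activity(rs)
  units <- colnames(rs$resp)
  live <- setdiff(units, attr(pct, "zero_max"))
  expect_true(all(pct[, units] >= 0 & pct[, units] <= 100))
  # the max state scores 100; element-wise recomputation oracle
  for (u in live) {
    expect_equal(max(pct[, u]), 100)
    expect_equal(pct[, u], 100 * rs$resp[, u] / max(rs$resp[, u]))
  }
  # all-zero columns are flagged and reported as zero
  rs0 <- enumerate_states(zero_model())
  p0 <- percent_activity(rs0)
  expect_setequal(attr(p0, "zero_max"), colnames(rs0$resp))
})

test_that("food-intake classes partition [0, 100] at the published breaks", {
  expect_identical(classify_fi(43.0), "low")
  expect_identical(classify_fi(81.0), "high")
  expect_identical(classify_fi(60.0), "medium")
  expect_identical(classify_fi(43.0001), "medium")
  expect_identical(classify_fi(80.9999), "medium")
  expect_error(classify_fi(101), "\\[0, 100\\]")
  # exact partition: every value gets exactly one class
  x <- seq(0, 100, by = 0.25)
  cls <- classify_fi(x)
  expect_true(all(cls %in% c("low", "medium", "high")))
  expect_identical(sum(cls == "low") + sum(cls == "medium") +
                     sum(cls == "high"), length(x))
})

test_that("configuration summaries match direct formulas", {
  tab <- data.frame(A = c(0, 100), B = c(50, 50))
  s <- summarize_configurations(tab)
  expect_equal(s$mean[s$unit == "A"], 50)
  expect_equal(s$median[s$unit == "B"], 50)

  one <- data.frame(A = 42, B = 7)
  s1 <- summarize_configurations(one)
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$mean, c(42, 7))

  set.seed(12)
  rnd <- as.data.frame(matrix(runif(60, 0, 100), 15, 4))
  s2 <- summarize_configurations(rnd)
  expect_equal(s2$mean, unname(colMeans(rnd)))
  expect_equal(s2$median, unname(apply(rnd, 2, median)))
  expect_equal(s2$q3 - s2$q1,
               unname(apply(rnd, 2, quantile, 0.75) -
                        apply(rnd, 2, quantile, 0.25)))
  expect_equal(s2$max - s2$min, unname(apply(rnd, 2, max) - apply(rnd, 2, min)))
})

test_that("report export writes the matrices and bundle", {
  rs <- enumerate_states(archive_model())
  dir <- tempfile("report")
  bundle <- export_report(rs, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "agrp_pomc_anomalous_high.csv")))
  expect_true(file.exists(file.path(dir, "lh_gaba_fi_low.csv")))
  expect_identical(length(bundle$table3), 13L)
  expect_identical(length(bundle$table4), 8L)
  expect_gte(bundle$counts$agrp_pomc$anomalous_high, 0L)
})
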