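test_that("truth-table fixture holds the full corpus", {
  expect_length(truth, 32)
  expect_identical(attr(truth, "n_scored"), 39L)
  expect_identical(vapply(truth, `[[`, 0L, "id"), 1:32)
  # spot checks against the published outcomes
  expect_identical(truth[[16]]$expected$FI, "no_change")
  expect_identical(truth[[5]]$expected$FI, "increase")
  expect_identical(truth[[26]]$expected$OXT, "increase")  # excitation
  expect_identical(truth[[27]]$expected$POMC, "decrease") # inhibition
  expect_identical(truth[[28]]$expected$FI, "na")
})

test_that("manipulation programs are applied purely and correctly", {
  m <- archive_model()
  before <- m$params

  # experiment 1: POMC knockout lesions the unit
  inst <- apply_manipulations(m, truth[[1]])
  expect_identical(inst$state$live[["POMC"]], 0)
  expect_identical(m$params, before)   # purity

  # experiment 18: projection forced to stim level AND PVH GABAR zeroed
  inst18 <- apply_manipulations(m, truth[[18]])
  expect_equal(inst18$state$overrides[["AgRP->OXT"]], m$stim_level)
  expect_identical(unname(inst18$model$params["OXT.GABAR"]), 0)
  expect_identical(inst18$model$params["POMC.GABAR"], m$params["POMC.GABAR"])

  # experiment 4: receptor knockout hits every unit expressing Y1R
  inst4 <- apply_manipulations(m, truth[[4]])
  expect_true(all(inst4$model$params[c("POMC.Y1R", "OXT.Y1R", "NAc.Y1R")] == 0))

  # empty manipulation list is the identity
  inst0 <- apply_manipulations(m, list())
  expect_identical(inst0$model$params, m$params)
  expect_equal(inst0$state, make_initial_state(canon))

  expect_error(apply_manipulations(m, parse_manipulations("lesion(BOGUS)")),
               "unknown unit")
  expect_error(
    apply_manipulations(m, parse_manipulations("zero_receptor(POMC,OXR)")),
    "no such receptor")
})

test_that("the 30 percent criterion classifies with strict boundaries", {
  expect_identical(classify_change(130.1, 100), "increase")
  expect_identical(classify_change(130.0, 100), "no_change")
  expect_identical(classify_change(69.9, 100), "decrease")
  expect_identical(classify_change(70.0, 100), "no_change")
  expect_identical(classify_change(0, 0), "no_change")
  expect_identical(classify_change(0.01, 0), "increase")
  # scale equivariance: classify(kv, kb) = classify(v, b) for k > 0
  set.seed(5)
  v <- runif(50, 0, 10); b <- runif(50, 0, 10); k <- runif(50, 0.1, 9)
  expect_identical(classify_change(k * v, k * b), classify_change(v, b))
})

test_that("the silent network misses exactly the change-expecting cells", {
  # every observation classifies no_change, so the error equals the number
  # of truth-table cells expecting a change (brute-tallied from the fixture)
  n_change <- sum(vapply(truth, function(e) {
    sum(unlist(e$expected) %in% c("increase", "decrease"))
  }, 0L))
  expect_identical(n_change, 31L)
  expect_identical(truth_table_error(zero_model(), truth), 31L)
})

test_that("truth-table error is order-invariant and bounded", {
  m <- feeding_model(canon, random_params(canon))
  e1 <- truth_table_error(m, truth)
  set.seed(9)
  e2 <- truth_table_error(m, truth[sample(32)])
  expect_identical(e1, e2)
  expect_gte(e1, 0L)
  expect_lte(e1, 39L)
})

test_that("predict() agrees with truth_table_error()", {
  m <- archive_model()
  pr <- predict(m, truth)
  expect_identical(nrow(pr), 39L)
  expect_identical(sum(!pr$match), unname(truth_table_error(m, truth)))
})

test_that("significance check recovers the closed-form t statistic", {
  # synthetic groups with known means: compare against the direct formula
  a <- c(10, 11, 12, 13)
  b <- c(20, 22, 24, 26)
  p_direct <- {
    t_stat <- (mean(a) - mean(b)) /
      sqrt(var(a) / length(a) + var(b) / length(b))
    df <- (var(a) / length(a) + var(b) / length(b))^2 /
      ((var(a) / length(a))^2 / (length(a) - 1) +
       (var(b) / length(b))^2 / (length(b) - 1))
    2 * pt(-abs(t_stat), df)
  }
  expect_equal(unname(t.test(a, b)$p.value), p_direct)

  # identical groups show no separation
  expect_gt(t.test(c(1, 2, 3), c(1, 2, 3))$p.value, 0.99)
})
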