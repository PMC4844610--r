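test_that("a population seeded with an archived optimum returns error 0 at once", {
  cfg <- ga_config(pop_size = 30L, generations = 5L)
  res <- run_ga(canon, truth, cfg, seed = 3,
                init = rbind(archive_params[[1]]))
  expect_identical(res$error, 0L)
  expect_identical(res$generations, 1L)
  expect_gte(nrow(res$zero_solutions), 1)
})

test_that("the GA is deterministic given a seed and respects bounds", {
  # band_start = 0.3 disables the anneal so the key is on a fixed scale
  cfg <- ga_config(pop_size = 24L, generations = 15L, band_start = 0.3)
  r1 <- run_ga(canon, truth, cfg, seed = 11)
  r2 <- run_ga(canon, truth, cfg, seed = 11)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$trace, r2$trace)
  b <- feedcircuit:::.ga_bounds(canon, cfg)
  expect_true(all(r1$params >= b$lo - 1e-12))
  expect_true(all(r1$params <= b$hi + 1e-12))
  # greedy replacement: at fixed band the best selection key never worsens
  expect_true(all(diff(r1$trace) <= 1e-12))
})

test_that("representatives are ordered by distance from the zero vector", {
  pn <- param_names(canon)
  v <- function(d) {
    x <- make_params(canon)
    x[1] <- d
    x
  }
  arch <- rbind(v(1), v(2), v(9))
  colnames(arch) <- pn
  reps <- select_representatives(arch)
  expect_equal(unname(reps$Near[1]), 1)
  expect_equal(unname(reps$Middle[1]), 2)
  expect_equal(unname(reps$Far[1]), 9)
  expect_equal(unname(reps$Average[1]), 4)

  # degenerate archive: all four representatives coincide
  same <- rbind(v(2), v(2), v(2))
  colnames(same) <- pn
  reps2 <- select_representatives(same)
  expect_equal(reps2$Near, reps2$Far)
  expect_equal(reps2$Middle, reps2$Average)
})

test_that("parameter correlations match the closed-form Pearson test", {
  set.seed(21)
  arch <- matrix(runif(10 * 51), 10, 51)
  colnames(arch) <- param_names(canon)
  # plant a perfect anticorrelation
  arch[, 2] <- 1 - arch[, 1]
  cm <- parameter_correlations(arch, p_cutoff = 0.01)
  expect_equal(unname(cm[1, 2]), -1)
  expect_true(all(diag(cm) == 1))
  expect_equal(cm, t(cm))
  # entry-wise oracle: direct r and t-distribution p
  r13 <- cor(arch[, 1], arch[, 3])
  p13 <- 2 * pt(-abs(r13 * sqrt(8 / (1 - r13^2))), df = 8)
  expect_equal(attr(cm, "p")[1, 3], p13)
  expect_identical(unname(cm[1, 3]), if (p13 < 0.01) r13 else 0)

  # zero-variance parameters are masked and flagged
  arch[, 5] <- 1
  cm2 <- parameter_correlations(arch)
  expect_true(param_names(canon)[5] %in% attr(cm2, "flagged"))
  expect_true(all(cm2[5, -5] == 0))

  expect_error(parameter_correlations(arch[1:2, ]), "at least 3")
})

test_that("the shipped archive holds only verified zero-error vectors", {
  expect_gte(nrow(archive_df), 3)
  expect_true(all(archive_df$error == 0L))
  expect_equal(archive_df$distance,
               param_distance(archive_df[, param_names(canon)]),
               tolerance = 1e-8)
  # re-verify a couple against the error function itself
  take <- unique(c(1L, nrow(archive_df)))
  for (i in take) {
    expect_identical(truth_table_error(archive_model(i), truth), 0L)
  }
})
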