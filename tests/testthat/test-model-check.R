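test_that("unsatisfiable antecedents are vacuously true and flagged", {
  m <- toy_chain2()
  rs <- enumerate_states(m)
  r <- check_invariant(rs, prop_nc(),
                       list(prop_pos("U1"), prop_zero("U1")),  # contradiction
                       prop_pos("U2"))
  expect_true(r$holds)
  expect_true(r$vacuous)
  expect_true(is.na(r$witness))
})

test_that("invariants are dual to searches, with a matching witness", {
  for (s in 1:15) {
    ty <- random_toy(sample(2:4, 1), seed = 200 + s)
    m <- feeding_model(ty$spec, ty$params)
    rs <- enumerate_states(m)
    r <- check_invariant(rs, prop_nc(), prop_pos("U1"), prop_pos("U2"))
    hits <- search_states(rs, function(x) x[, "U1"] > rs$tol &
                            !(x[, "U2"] > rs$tol), include_init = TRUE)
    expect_identical(r$holds, hits$count == 0L)
    if (!r$holds) expect_true(r$witness %in% hits$idx)
  }
})

test_that("strengthening the antecedent never falsifies a true invariant", {
  for (s in 1:15) {
    ty <- random_toy(sample(2:4, 1), seed = 300 + s)
    m <- feeding_model(ty$spec, ty$params)
    rs <- enumerate_states(m)
    weak <- check_invariant(rs, prop_nc(), prop_pos("U1"), prop_pos("U2"))
    strong <- check_invariant(rs, prop_nc(),
                              list(prop_pos("U1"), prop_pos("U2")),
                              prop_pos("U2"))
    if (weak$holds) expect_true(strong$holds)
  }
})

test_that("witnesses are reproducible (lexicographically smallest key)", {
  ty <- random_toy(3, seed = 77)
  m <- feeding_model(ty$spec, ty$params)
  rs <- enumerate_states(m)
  r1 <- check_invariant(rs, prop_nc(), prop_nc(), prop_pos("U3"))
  r2 <- check_invariant(rs, prop_nc(), prop_nc(), prop_pos("U3"))
  expect_identical(r1$witness, r2$witness)
  if (!r1$holds) {
    viol <- which(!(rs$resp[, "U3"] > rs$tol))
    expect_identical(rs$keys[r1$witness], min(rs$keys[viol]))
  }
})

test_that("suite structure matches the two published analyses", {
  # structural checks only; truth values are asserted under zero-error
  # parameterizations in the acceptance suite
  rs <- enumerate_states(archive_model())
  t3 <- run_table3_suite(rs)
  expect_identical(nrow(t3), 13L)
  expect_identical(t3$consequent[2], "FI = low")
  expect_true(all(t3$consequent[-2] == "FI = high"))
  t4 <- run_table4_suite(rs)
  expect_identical(nrow(t4), 8L)
  expect_identical(sum(t4$consequent == "FI = low"), 4L)
})
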