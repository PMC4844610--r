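test_that("canonical network has the documented structure", {
  expect_s3_class(canon, "network_spec")
  neural <- setdiff(canon$units$id, canon$fi)
  expect_length(neural, 12)
  expect_identical(sum(canon$units$rule), 8L)
  expect_setequal(canon$units$id[canon$units$rule],
                  c("AgRP", "POMC", "NGABA", "OXT", "MCH", "OX", "LHGal", "NT"))
  expect_setequal(setdiff(canon$output_stage_order, "FI"),
                  c("NTSCA", "NTSGLP1", "VTA", "NAc"))
  expect_length(canon$substances, 5)
  expect_length(param_names(canon), 51)
  expect_true(is_canonical_network(canon))
})

test_that("validation rejects malformed specs", {
  bad <- canon
  bad$receptors$sources[[1]] <- "substance:nonexistent"
  expect_error(validate_network_spec(bad), "undeclared ligand source")

  # a unit-level cycle must be caught
  t <- make_toy_chain(2)
  cyc <- t$spec
  cyc$receptors$sources[[1]] <- "unit:U2:T"
  expect_error(validate_network_spec(cyc), "not acyclic")

  chk <- canon
  chk$n_params <- 50L
  expect_error(validate_network_spec(chk), "checksum")
})

test_that("parameter vectors are checked against the spec", {
  p <- make_params(canon, 1)
  expect_named(p)
  expect_length(p, 51)
  expect_error(make_params(canon, c(a = 1)), "parameter names")
  p["POMC.LepRB"] <- -1
  expect_error(feeding_model(canon, p), "nonnegative")
})

test_that("network spec JSON round-trips and matches the shipped fixture", {
  tmp <- tempfile(fileext = ".json")
  write_network_spec(canon, tmp)
  back <- read_network_spec(tmp)
  expect_identical(param_names(back), param_names(canon))
  expect_identical(back$units, canon$units)
  expect_identical(back$receptors$sources, canon$receptors$sources)
  expect_identical(back$output_stage_order, canon$output_stage_order)

  shipped <- read_network_spec(system.file("extdata", "network_canonical.json",
                                           package = "feedcircuit"))
  expect_identical(shipped$receptors, canon$receptors)
  expect_identical(shipped$units, canon$units)
})

test_that("parameter i/o round-trips in both layouts", {
  p <- random_params(canon)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_params(p, csv)
  write_params(p, js)
  expect_equal(read_params(canon, csv), p)
  expect_equal(read_params(canon, js), p)

  # supplementary-table-shaped layout (unit, receptor, value)
  parts <- strsplit(names(p), ".", fixed = TRUE)
  df <- data.frame(unit = vapply(parts, `[[`, "", 1),
                   receptor = vapply(parts, `[[`, "", 2),
                   value = unname(p))
  sup <- tempfile(fileext = ".csv")
  write.csv(df, sup, row.names = FALSE)
  expect_equal(read_params(canon, sup), p)
})
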