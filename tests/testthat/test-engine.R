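test_that("POMC net input reproduces the printed update equation", {
  p <- make_params(canon)
  p["POMC.LepRB"] <- 1
  p["POMC.Y1R"] <- 0.5
  p["POMC.GABAR"] <- 0.5
  p["POMC.FHT2CR"] <- 1
  m <- feeding_model(canon, p)
  st <- make_initial_state(canon, substances = c(leptin = 2))
  st$resp[["AgRP"]] <- 1   # NPY = GABA = AgRP response; NGABA silent
  # leptin*1 - 0.5*NPY - 0.5*(GABA sums) + 1*(5HT) + 0
  expect_equal(compute_net_input("POMC", st, m), 2 - 0.5 - 0.5 + 1)

  # risperidone halves into the 5HT2C strength, clamped at zero
  st$drugs[["risperidone"]] <- 1
  expect_equal(compute_net_input("POMC", st, m), 1.5)
  st$drugs[["risperidone"]] <- 10
  expect_equal(compute_net_input("POMC", st, m), 1.0)
})

test_that("net input equals an independent term-by-term summation", {
  set.seed(71)
  for (rep in 1:5) {
    p <- random_params(canon)
    m <- feeding_model(canon, p)
    st <- make_initial_state(canon)
    st$resp[canon$units$id] <- runif(13, 0, 3)
    st$drugs[] <- runif(5, 0, 0.5)
    st$substances[] <- runif(5, 0, 2)
    for (unit in c("POMC", "OXT", "VTA", "NAc", "FI")) {
      rc <- canon$receptors[canon$receptors$unit == unit, ]
      expected <- p[[paste0(unit, ".Bias")]]
      for (i in seq_len(nrow(rc))) {
        lig <- 0
        for (s in rc$sources[[i]]) {
          mult <- if (startsWith(s, "-")) -1 else 1
          s <- sub("^-", "", s)
          parts <- strsplit(s, ":")[[1]]
          lev <- switch(parts[1],
            substance = st$substances[[parts[2]]],
            drug = st$drugs[[parts[2]]],
            unit = st$resp[[parts[2]]])
          lig <- lig + mult * lev
        }
        w <- p[[paste(unit, rc$receptor[i], sep = ".")]]
        if (rc$hook[i] == "risperidone_halving") {
          w <- max(0, w - st$drugs[["risperidone"]] / 2)
        }
        expected <- expected + rc$sign[i] * w * lig
      }
      expect_equal(compute_net_input(unit, st, m), unname(expected),
                   tolerance = 1e-12)
    }
  }
})

test_that("NTSCA CCK gate follows the sensitization rule", {
  p <- make_params(canon)
  p["NTSCA.LepRB"] <- 0.5   # modulator sum = 0.5 with only leptin active
  p["NTSCA.CCKR"] <- 1
  m <- feeding_model(canon, p)
  st <- make_initial_state(canon,
                           substances = c(ghrelin = 0, FHT = 0, glucose = 0))
  # modulator sum 0.5 > 0, CCK = 1 > 0, CCKR = 1 > 0: CCK term included
  expect_equal(gated_net_input_ntsca(st, m), 0.5 + 1)

  # negative modulator sum excludes the CCK term entirely
  p2 <- p
  p2["NTSCA.GHSR"] <- 0.7
  m2 <- feeding_model(canon, p2)
  st2 <- make_initial_state(canon, substances = c(FHT = 0, glucose = 0))
  expect_equal(gated_net_input_ntsca(st2, m2), 0.5 - 0.7)

  # zero CCK closes the gate even with a positive modulator sum
  st3 <- make_initial_state(canon,
                            substances = c(CCK = 0, ghrelin = 0, FHT = 0,
                                           glucose = 0))
  expect_equal(gated_net_input_ntsca(st3, m), 0.5)

  # zeroed CCK receptor closes the gate too
  p4 <- p
  p4["NTSCA.CCKR"] <- 0
  expect_equal(gated_net_input_ntsca(st, feeding_model(canon, p4)), 0.5)
})

test_that("unit responses are bounded at zero and gated by the live flag", {
  expect_equal(unit_response(-3.2, 1, 0), 0)
  expect_equal(unit_response(2.5, 0, 10), 0)
  expect_equal(unit_response(2.5, 1, 0), 2.5)
  expect_equal(unit_response(-2, 1, 5), 3)
  expect_error(unit_response(1, live = 2), "live")
})

test_that("output-stage elaboration is idempotent", {
  set.seed(72)
  for (rep in 1:5) {
    m <- feeding_model(canon, random_params(canon))
    st <- make_initial_state(canon)
    st$resp[canon$units$id[canon$units$rule]] <- runif(8, 0, 3)
    once <- propagate_output_stage(st, m)
    twice <- propagate_output_stage(once, m)
    expect_equal(twice$resp, once$resp, tolerance = 1e-12)
    expect_equal(twice$net, once$net, tolerance = 1e-12)
  }
})

test_that("the zero network is silent and the fixed point is reached", {
  m <- zero_model()
  term <- run_to_fixed_point(m)
  expect_true(all(term$resp == 0))
  expect_true(all(term$net == 0))

  # nonnegativity of every response in arbitrary parameterizations
  set.seed(73)
  for (rep in 1:10) {
    m2 <- feeding_model(canon, random_params(canon))
    term2 <- run_to_fixed_point(m2)
    expect_true(all(term2$resp >= 0))
  }
})

test_that("a purely excitatory strength never decreases its owner's response", {
  set.seed(74)
  for (rep in 1:10) {
    p <- random_params(canon)
    p2 <- p
    p2["POMC.LepRB"] <- p["POMC.LepRB"] + runif(1, 0.1, 1)
    r1 <- run_to_fixed_point(feeding_model(canon, p))$resp[["POMC"]]
    r2 <- run_to_fixed_point(feeding_model(canon, p2))$resp[["POMC"]]
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("negative initial levels are rejected", {
  expect_error(make_initial_state(canon, substances = c(leptin = -1)),
               "nonnegative")
  expect_error(make_initial_state(canon, drugs = c(bogus = 1)), "unknown drug")
})
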