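test_that("a two-unit chain enumerates exactly the hand-derived states", {
  m <- toy_chain2()
  rs <- enumerate_states(m)
  # hand enumeration: init (0,0); U1 fires (1,0); U2 after U1 (1,1).
  # U2 cannot fire first: its fresh net (0) equals its stored net.
  expect_identical(nrow(rs$resp), 3L)
  expect_identical(sum(rs$terminal), 1L)
  expect_equal(rs$resp[rs$terminal, ], c(U1 = 1, U2 = 1))
  expect_identical(rs$layer, c(0L, 1L, 2L))

  # inhibitory middle link floors the downstream response
  t3 <- make_toy_chain(3, c(1, -1, 1))
  m3 <- feeding_model(t3$spec, t3$params)
  rs3 <- enumerate_states(m3)
  term <- rs3$resp[rs3$terminal, ]
  expect_equal(unname(term[["U3"]]), 0)
})

test_that("applicability and stepping follow the conditional-rule semantics", {
  m <- toy_chain2()
  st <- propagate_output_stage(make_initial_state(m$spec), m)
  expect_identical(applicable_rules(st, m), "U1")
  expect_error(step(st, "U2", m), "not applicable")
  s1 <- step(st, "U1", m)
  expect_equal(s1$resp[["U1"]], 1)
  # stepping twice on the same unit with unchanged inputs is not applicable
  expect_false("U1" %in% applicable_rules(s1, m))
  s2 <- step(s1, "U2", m)
  expect_length(applicable_rules(s2, m), 0)

  # zero-parameter model: the elaborated init is immediately terminal
  rs0 <- enumerate_states(zero_model())
  expect_identical(nrow(rs0$resp), 1L)
  expect_true(rs0$terminal[1])
})

test_that("enumeration equals the brute-force oracle on toy networks", {
  fixed <- list(make_toy_chain(2), make_toy_chain(3, c(1, -0.5, 2)),
                make_toy_chain(4, c(1, 1, 1, 1)))
  for (t in fixed) {
    m <- feeding_model(t$spec, t$params)
    rs <- enumerate_states(m)
    bf <- brute_force_enumerate(m)
    expect_setequal(rs$keys, bf$keys)
    expect_setequal(rs$keys[rs$terminal], bf$terminal_keys)
    expect_identical(unname(bf$min_depth[rs$keys]), rs$layer)
  }
  # seeded random acyclic toys (property-style)
  for (s in 1:40) {
    ty <- random_toy(sample(2:4, 1), seed = s)
    m <- feeding_model(ty$spec, ty$params)
    rs <- enumerate_states(m)
    bf <- brute_force_enumerate(m)
    expect_setequal(rs$keys, bf$keys)
    expect_setequal(rs$keys[rs$terminal], bf$terminal_keys)
    expect_identical(unname(bf$min_depth[rs$keys]), rs$layer)
  }
})

test_that("acyclic toys are confluent and match the imperative fixed point", {
  for (s in 41:60) {
    ty <- random_toy(sample(2:4, 1), seed = s)
    m <- feeding_model(ty$spec, ty$params)
    rs <- enumerate_states(m)
    tb <- terminal_and_baseline(rs)
    expect_length(tb$terminal_idx, 1)
    expect_true(tb$agrees_with_fixed_point)
    expect_lte(max_terminal_layer(rs), nrow(rs$resp))
  }
})

test_that("search honors predicates, dedup and the init-exclusion rule", {
  m <- toy_chain2()
  rs <- enumerate_states(m)
  # contradiction matches nothing
  expect_identical(search_states(rs, "U1>1, U1<0")$count, 0L)
  # matches the brute-force filter (init excluded by the >=1-rewrite mode)
  got <- search_states(rs, "U2>0")
  by_hand <- which(rs$resp[, "U2"] > 0 & seq_len(nrow(rs$resp)) != 1L)
  expect_identical(got$idx, by_hand)
  # the init would match U1==0 but is excluded unless asked for
  expect_identical(search_states(rs, "U1==0")$count, 0L)
  expect_identical(search_states(rs, "U1==0", include_init = TRUE)$count, 1L)
  expect_error(search_states(rs, "BOGUS>0"), "unknown unit")
})

test_that("reachable sets expose layers, pending rules and transitions", {
  ty <- random_toy(3, seed = 99)
  m <- feeding_model(ty$spec, ty$params)
  rs <- enumerate_states(m)
  expect_identical(rs$layer[1], 0L)
  # every non-terminal state has a successor, terminals none
  from <- rs$transitions[, "from"]
  expect_setequal(which(!rs$terminal), unique(from))
  expect_false(any(which(rs$terminal) %in% from))
  # pending flags agree with applicable_rules recomputation
  st <- rs$init
  st$net <- setNames(rs$net[1, ], colnames(rs$net))
  st$resp <- setNames(rs$resp[1, ], colnames(rs$resp))
  expect_setequal(colnames(rs$pending)[rs$pending[1, ]],
                  applicable_rules(st, m))
})
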