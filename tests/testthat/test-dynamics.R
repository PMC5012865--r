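# The N = 2 chain system and N = 1 balanced system are defined in
# helper-systems.R with their hand-derived behavior.

test_that("budded vesicles and per-compartment flows match the rule matrices", {
  rs <- chain_ruleset_n2()
  st <- c(1L, 2L)
  expect_equal(budded_vesicles(st, rs), c(1L, 2L))
  fl <- vesicle_flows(2L, st, rs)
  expect_equal(fl$outgoing, 2L) # [10] buds its own X vesicle
  expect_equal(fl$incoming, 1L) # the Y vesicle fuses in
  expect_error(vesicle_flows(3L, st, rs), "not present")
  expect_equal(budded_vesicles(integer(0), rs), integer(0))
  rs0 <- ruleset(matrix(0L, 3, 3), rs$F, N = 2)
  expect_equal(budded_vesicles(st, rs0), integer(0))
})

test_that("collapse_or is the bitwise OR of vesicle vectors", {
  expect_equal(collapse_or(c(2L, 1L), 2), c(1L, 1L))
  expect_equal(collapse_or(integer(0), 2), c(0L, 0L))
  expect_equal(collapse_or(c(6L, 3L), 3), c(1L, 1L, 1L))
})

test_that("the composition update obeys the full gain/loss truth table", {
  # per label: c' = in | (!out & c)
  for (cc in 0:1) for (ii in 0:1) for (oo in 0:1) {
    expected <- ii | (!oo & cc)
    expect_equal(update_compartment(cc, ii, oo), as.integer(expected))
  }
  expect_equal(update_compartment(c(1, 0), c(0, 1), c(1, 0)), c(0L, 1L))
  expect_equal(update_compartment(c(1, 1), c(0, 0), c(0, 0)), c(1L, 1L))
  expect_equal(update_compartment(c(0, 1), c(0, 0), c(0, 1)), c(0L, 0L))
})

test_that("orphan detection scans fusion columns over present compartments", {
  rs <- chain_ruleset_n2()
  expect_equal(find_orphans(c(1L, 2L), rs), 2L) # X vesicle has no target
  rs_all <- ruleset(rs$G, matrix(1L, 3, 3), N = 2)
  expect_equal(find_orphans(c(1L, 2L), rs_all), integer(0))
  expect_equal(find_orphans(integer(0), rs), integer(0))
})

test_that("one synchronous update reproduces the hand-evaluated chain step", {
  rs <- chain_ruleset_n2()
  sc <- step_cell(c(1L, 2L), rs)
  expect_equal(sc$state, c(1L, 2L))
  expect_equal(sc$created, 2L)
  expect_equal(sc$matured, cbind(from = 2L, to = 1L))
  expect_equal(sc$dissipated, 1L)

  # empty state is inert
  sc0 <- step_cell(integer(0), rs)
  expect_equal(sc0$state, integer(0))
  expect_equal(nrow(sc0$matured), 0L)

  # transport balance: in = out leaves the compartment unchanged
  rs1 <- balanced_ruleset_n1()
  sc1 <- step_cell(1L, rs1)
  expect_equal(sc1$state, 1L)
  expect_equal(sc1$created, integer(0))
  expect_equal(nrow(sc1$matured), 0L)
  expect_equal(sc1$dissipated, integer(0))
})

test_that("orbit detection finds fixed points, cycles, and non-convergence", {
  rs <- chain_ruleset_n2()
  orb <- run_to_orbit(rs, c(1L, 2L))
  expect_true(is_homeostatic(orb))
  expect_equal(orb$period, 1L)
  expect_equal(orb$states[[1L]], c(1L, 2L))
  expect_equal(orb$homotypic_types, 2L)

  # a lone [10] compartment renucleates itself: fixed point {[10]}
  orb2 <- run_to_orbit(rs, 2L)
  expect_equal(orb2$period, 1L)
  expect_equal(orb2$states[[1L]], 2L)
  expect_equal(orb2$homotypic_types, 2L)

  orb1 <- run_to_orbit(balanced_ruleset_n1(), 1L)
  expect_true(is_homeostatic(orb1))
  expect_equal(orb1$homotypic_types, integer(0))

  # engineered 2-cycle {[11]} -> {[01],[10]} -> {[11]}: [11] buds an X
  # vesicle (orphan there, so it renucleates [10]) and matures to [01];
  # then [01] absorbs the X vesicle budded by [10] (which itself
  # dissipates), reforming [11].
  G <- matrix(0L, 3, 3); F <- matrix(0L, 3, 3)
  G[2, 2] <- 1L # [10] buds [10]
  G[3, 2] <- 1L # [11] buds [10]
  F[1, 2] <- 1L # compartment [01] accepts the X vesicle
  rs2 <- ruleset(G, F, N = 2)
  orbc <- run_to_orbit(rs2, 3L)
  expect_true(orbc$reached)
  expect_equal(orbc$period, 2L)
  expect_equal(orbc$states[[1L]], 3L)
  expect_equal(orbc$states[[2L]], c(1L, 2L))
  expect_false(is_homeostatic(orbc))

  # cap exhaustion is a reported outcome: impossible to repeat within 0 steps
  orbx <- run_to_orbit(rs, c(1L, 2L), max_steps = 0L)
  expect_false(orbx$reached)
  expect_true(is.na(orbx$period))
})

test_that("period-1 states are fixed points of the update", {
  set.seed(101)
  for (rep in 1:20) {
    rs <- sample_rules(N = 4, A = sample(1:3, 1), g = runif(1), f = runif(1))
    orb <- run_to_orbit(rs, sample_initial_state(4))
    if (is_homeostatic(orb)) {
      st <- orb$states[[1L]]
      expect_identical(step_cell(st, rs)$state, st)
      # orphan consistency: homotypic types have no fusion target present
      for (j in orb$homotypic_types) {
        expect_true(all(rs$F[st, j] == 0L))
      }
    }
  }
})

test_that("every budded vesicle is a bitwise subset of its source compartment", {
  set.seed(77)
  for (rep in 1:10) {
    rs <- sample_rules(N = 5, A = 3, g = runif(1), f = runif(1))
    st <- sample_initial_state(5)
    for (i in st) {
      for (j in vesicle_flows(i, st, rs)$outgoing) {
        expect_identical(bitwAnd(j, i), j)
      }
    }
  }
})

test_that("orbit detection agrees with the naive transition-graph oracle", {
  # exhaustive over all states for N = 2; random rules
  set.seed(11)
  for (rep in 1:5) {
    rs <- sample_rules(N = 2, A = 2, g = runif(1), f = runif(1))
    all_states <- lapply(0:7, function(m) which(bitwAnd(bitwShiftR(m, 0:2), 1L) == 1L))
    for (st in all_states) {
      a <- run_to_orbit(rs, st, max_steps = 64L)
      b <- naive_orbit(rs, st, max_steps = 64L)
      expect_equal(a$reached, b$reached)
      expect_equal(a$period, b$period)
      expect_equal(a$steps_to_orbit, b$steps_to_orbit)
    }
  }
  # random subset of the 2^7 states for N = 3
  set.seed(12)
  rs <- sample_rules(N = 3, A = 2, g = 0.5, f = 0.3)
  for (rep in 1:30) {
    st <- sample_initial_state(3)
    a <- run_to_orbit(rs, st, max_steps = 128L)
    b <- naive_orbit(rs, st, max_steps = 128L)
    expect_equal(a$period, b$period)
    if (a$reached) expect_equal(a$states, b$states)
  }
})

test_that("dynamics are bit-identical under replay", {
  res1 <- replay_run(5, 2, 0.3, 0.6, run_seed = 4242L)
  res2 <- replay_run(5, 2, 0.3, 0.6, run_seed = 4242L)
  expect_identical(res1$rules$G, res2$rules$G)
  expect_identical(res1$rules$F, res2$rules$F)
  expect_identical(res1$initial, res2$initial)
  expect_identical(res1$orbit$states, res2$orbit$states)
})
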