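test_that("the worked two-label chain maps to the expected typed graph", {
  rs <- chain_ruleset_n2()
  orb <- run_to_orbit(rs, c(1L, 2L))
  net <- build_network(rs, orb)
  expect_equal(net$nodes, c(1L, 2L))
  # Y vesicle [01] carries from [01] to [10]
  expect_equal(net$vesicle_edges$from, 1L)
  expect_equal(net$vesicle_edges$to, 2L)
  expect_equal(net$vesicle_edges$vesicles[[1L]], 1L)
  # orphan X vesicle budded by [10] recreates [10]: creation self-edge
  expect_equal(net$creation_edges, data.frame(from = 2L, to = 2L))
  expect_equal(net$maturation_edges, data.frame(from = 2L, to = 1L))
  expect_equal(net$node_next, c(0L, 1L)) # [01] dissipates, [10] -> [01]

  # transport-balanced single node: vesicle self-edge only
  net1 <- build_network(balanced_ruleset_n1(), run_to_orbit(balanced_ruleset_n1(), 1L))
  expect_equal(net1$vesicle_edges$from, 1L)
  expect_equal(net1$vesicle_edges$to, 1L)
  expect_equal(nrow(net1$creation_edges), 0L)
  expect_equal(nrow(net1$maturation_edges), 0L)

  # non-homeostatic input is a contract error
  G <- matrix(0L, 3, 3); F <- matrix(0L, 3, 3)
  G[2, 2] <- 1L; G[3, 2] <- 1L; F[1, 2] <- 1L
  cyc <- run_to_orbit(ruleset(G, F, N = 2), 3L)
  expect_error(build_network(ruleset(G, F, N = 2), cyc), "homeostatic")
})

test_that("networks with no budding have no edges", {
  rs <- ruleset(matrix(0L, 3, 3), matrix(1L, 3, 3), N = 2)
  orb <- run_to_orbit(rs, c(1L, 2L))
  net <- build_network(rs, orb)
  expect_equal(nrow(network_edges(net)), 0L)
  expect_true(is_trivial(net))
  expect_length(connected_subsets(net), 2L)
})

test_that("connected subsets partition the node set", {
  rs <- chain_ruleset_n2()
  net <- build_network(rs, run_to_orbit(rs, c(1L, 2L)))
  expect_length(connected_subsets(net), 1L)
  expect_false(is_trivial(net))

  # two disconnected blocks built by hand
  net2 <- make_net(nodes = c(1L, 2L, 5L, 6L),
                   maturation = data.frame(from = c(1L, 5L), to = c(2L, 6L)))
  subs <- connected_subsets(net2)
  expect_length(subs, 2L)
  expect_equal(sort(unname(lengths(subs))), c(2L, 2L))
})

test_that("maturation chains classify terminals, cycles, and dissipation", {
  rs <- chain_ruleset_n2()
  net <- build_network(rs, run_to_orbit(rs, c(1L, 2L)))
  ch <- find_chains(net)
  expect_equal(nrow(ch$chains), 1L)
  expect_equal(ch$chains$start, 2L)
  expect_equal(ch$chains$length, 1L)
  expect_equal(ch$chains$terminal, 1L)
  expect_equal(ch$chains$terminal_kind, "fixed")
  expect_true(ch$chains$dissipates)

  # no creation edges -> no chains
  net0 <- make_net(nodes = c(1L, 2L), maturation = data.frame(from = 1L, to = 2L))
  expect_equal(nrow(find_chains(net0)$chains), 0L)

  # hand-built 3-cycle fed by a creation edge
  net3 <- make_net(nodes = 1:4,
                   creation = data.frame(from = 2L, to = 1L),
                   maturation = data.frame(from = c(1L, 2L, 3L, 4L),
                                           to = c(2L, 3L, 4L, 2L)))
  ch3 <- find_chains(net3)
  expect_equal(ch3$chains$terminal_kind, "cycle")
  expect_equal(ch3$chains$length, 1L) # truncated before the repeat of 2
  expect_length(ch3$cycles, 1L)
  expect_setequal(ch3$cycles[[1L]], c(2L, 3L, 4L))

  # pure maturation cycle with no creation edge is still reported
  net4 <- make_net(nodes = 1:3,
                   maturation = data.frame(from = c(1L, 2L, 3L),
                                           to = c(2L, 3L, 1L)))
  ch4 <- find_chains(net4)
  expect_equal(nrow(ch4$chains), 0L)
  expect_length(ch4$cycles, 1L)
})

test_that("chain decomposition covers each creation target once and chains may converge", {
  # two chains converging on a shared fixed terminal
  net <- make_net(nodes = 1:5,
                  creation = data.frame(from = c(5L, 5L), to = c(1L, 2L)),
                  maturation = data.frame(from = c(1L, 2L, 3L), to = c(3L, 3L, 4L)))
  ch <- find_chains(net)$chains
  expect_equal(sort(ch$start), c(1L, 2L))
  expect_equal(ch$terminal, c(4L, 4L))
  expect_equal(ch$length, c(2L, 2L))
})

test_that("retrograde fractions reproduce the worked 10-compartment example", {
  # 10 compartments, 8 maturing pairs, 8 retrograde vesicle pairs overall
  # of which 6 oppose maturation: f_all = 8/90, f_subset = 6/8
  nodes <- 1:10
  mat <- data.frame(from = 1:8, to = c(2:8, 9L))
  ves_pairs <- rbind(
    data.frame(from = c(2L, 3L, 4L, 5L, 6L, 7L), to = c(1L, 2L, 3L, 4L, 5L, 6L)), # oppose maturation
    data.frame(from = c(10L, 9L), to = c(3L, 10L)) # elsewhere
  )
  net <- make_net(nodes = nodes, maturation = mat, vesicle = ves_pairs)
  rs <- retrograde_stats(net)
  expect_equal(rs$n_pairs, 90L)
  expect_equal(rs$f_all, 8 / 90)
  expect_equal(rs$f_A_matures_to_B, 6 / 8)

  # no vesicle edges -> all fractions zero (conditioning sets non-empty)
  net0 <- make_net(nodes = 1:3, maturation = data.frame(from = 1L, to = 2L))
  rs0 <- retrograde_stats(net0)
  expect_equal(rs0$f_all, 0)
  expect_equal(rs0$f_A_matures_to_B, 0)

  # complete vesicle digraph -> all fractions one
  full <- expand.grid(from = 1:3, to = 1:3)
  full <- full[full$from != full$to, ]
  netf <- make_net(nodes = 1:3, vesicle = full,
                   maturation = data.frame(from = 1L, to = 2L))
  rsf <- retrograde_stats(netf)
  expect_equal(rsf$f_all, 1)
  expect_equal(rsf$f_vesicle_pairs, 1)
  expect_equal(rsf$f_B_matures_to_A, 1)
  expect_equal(rsf$f_A_matures_to_B, 1)

  # vesicle self-edges are excluded from pair statistics
  netself <- make_net(nodes = 1:2, vesicle = data.frame(from = 1L, to = 1L))
  expect_equal(retrograde_stats(netself)$f_all, 0)
})

test_that("label sinks are detected from per-label flow graphs", {
  # two-node graph, one edge carrying the label, nothing out of the target
  net <- make_net(nodes = c(2L, 4L), N = 3L,
                  vesicle = data.frame(from = 4L, to = 2L))
  net$vesicle_edges$vesicles <- list(4L) # carries label 1 (msb of N = 3)
  expect_equal(label_sinks(net), 1L)
  # a label never carried by any vesicle has no sink
  net$vesicle_edges$vesicles <- list(1L) # label 3 flows 4 -> 2
  expect_equal(label_sinks(net), 3L)

  # closed two-node loop: label circulates, no sink
  net2 <- make_net(nodes = c(2L, 4L), N = 3L,
                   vesicle = data.frame(from = c(4L, 2L), to = c(2L, 4L)))
  net2$vesicle_edges$vesicles <- list(4L, 4L)
  expect_equal(label_sinks(net2), integer(0))

  # the worked chain: X cycles via the creation edge, Y is delivered to
  # [10] and leaves only by compartment maturation, not by vesicle flow
  rs <- chain_ruleset_n2()
  netc <- build_network(rs, run_to_orbit(rs, c(1L, 2L)))
  expect_equal(label_sinks(netc), 2L)
})

test_that("per-network summaries report the worked chain correctly", {
  rs <- chain_ruleset_n2()
  net <- build_network(rs, run_to_orbit(rs, c(1L, 2L)))
  s <- summarize_networks(list(net))
  expect_equal(s$n_compartments, 2L)
  expect_equal(s$n_vesicle_types, 2L)
  expect_equal(s$n_stable, 0L) # one matures, one dissipates
  expect_equal(s$maturation_fraction, 0.5)
  expect_equal(s$n_chains, 1L)
  expect_equal(s$chain_lengths[[1L]], 1L)
  expect_false(s$trivial)

  netb <- build_network(balanced_ruleset_n1(),
                        run_to_orbit(balanced_ruleset_n1(), 1L))
  sb <- summarize_networks(list(netb))
  expect_equal(sb$maturation_fraction, 0)
  expect_equal(sb$n_stable, 1L)
})
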