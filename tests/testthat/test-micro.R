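test_that("reaction propensities match direct substitution", {
  p <- micro_params()
  # two free X vesicles and no compartments: only the homotypic channel
  st <- list(nX = 2, nY = 0, x = numeric(0), y = numeric(0))
  r <- reaction_rates(st, p)
  expect_equal(r$homotypic, p$A * 2 * 1)
  expect_length(r$bud_x, 0)
  # a compartment with x = 0 has no X-dependent channels
  st2 <- list(nX = 5, nY = 3, x = 0, y = 4)
  r2 <- reaction_rates(st2, p)
  expect_equal(r2$bud_x, 0)
  expect_equal(r2$fuse_x, 0)
  expect_equal(r2$fuse_y, 0)
  expect_equal(r2$bud_y, p$D * 4)
  # vesicle-sized compartment (2,0): X-fusion factor reduces to A
  st3 <- list(nX = 1, nY = 0, x = 2, y = 0)
  r3 <- reaction_rates(st3, p)
  expect_equal(r3$fuse_x, p$A * 1)
})

test_that("stochastic simulation conserves both totals exactly", {
  p <- micro_params(xtot = 40, ytot = 200)
  run <- gillespie_run(p, t_end = 2, seed = 5, check_every = 1L)
  # conservation is asserted at every event inside the run; re-check the
  # final state independently
  expect_equal(run$final$nX + sum(run$final$x), p$xtot)
  expect_equal(run$final$nY + sum(run$final$y), p$ytot)
  expect_gt(run$n_events, 100)
})

test_that("the vesicle pools equilibrate and are reproducible by seed", {
  p <- micro_params(xtot = 40, ytot = 200)
  a <- gillespie_run(p, t_end = 3, seed = 17)
  b <- gillespie_run(p, t_end = 3, seed = 17)
  expect_identical(a$nXbar, b$nXbar)
  expect_identical(a$snapshots, b$snapshots)
  # pool averages over the two halves of the equilibrium window agree
  sn <- a$snapshots[a$snapshots$time > 0.6, ]
  h1 <- sn[seq_len(nrow(sn) %/% 2), ]
  h2 <- sn[(nrow(sn) %/% 2 + 1):nrow(sn), ]
  expect_lt(abs(mean(h1$nY) - mean(h2$nY)), 5 * stats::sd(sn$nY) / sqrt(nrow(h1)) + 1)
})

test_that("the mean-field vector field and fixed point satisfy the defining equations", {
  p <- micro_params()
  expect_equal(ode_field(0, 3, p, 0.5, 10), c(0, -3 * p$D))
  expect_error(ode_field(0, 0, p, 0.5, 10), "undefined")
  fp <- micro_fixed_point(p, 0.457, 10.6)
  f <- ode_field(fp[["x"]], fp[["y"]], p, 0.457, 10.6)
  expect_equal(f, c(0, 0), tolerance = 1e-10)
  # analytic Jacobian matches finite differences
  J <- micro_jacobian(2, 5, p, 0.457, 10.6)
  eps <- 1e-7
  num <- matrix(0, 2, 2)
  f0 <- ode_field(2, 5, p, 0.457, 10.6)
  num[, 1] <- (ode_field(2 + eps, 5, p, 0.457, 10.6) - f0) / eps
  num[, 2] <- (ode_field(2, 5 + eps, p, 0.457, 10.6) - f0) / eps
  expect_equal(J, num, tolerance = 1e-4)
})

test_that("the oscillation condition matches Jacobian eigenvalues across parameters", {
  # B/(B+D) * C nY/(C nY + D) > 1/2 at the reference parameters: (10/11)(53/54)
  ref <- stability_condition(micro_params(), 10.6)
  expect_equal(ref$lhs, (10 / 11) * (53 / 54))
  expect_true(ref$unstable)
  # limits: B -> 0 stable, D -> 0 unstable
  expect_false(stability_condition(micro_params(B = 1e-6), 10.6)$unstable)
  expect_true(stability_condition(micro_params(D = 1e-4), 10.6)$lhs > 0.99)
  # sign of the leading eigenvalue at the interior fixed point agrees with
  # the analytic condition over a B scan crossing the threshold
  for (B in c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 50)) {
    p <- micro_params(B = B)
    cond <- stability_condition(p, 10.6)
    fp <- micro_fixed_point(p, 0.457, 10.6)
    ev <- eigen(micro_jacobian(fp[["x"]], fp[["y"]], p, 0.457, 10.6))$values
    expect_equal(max(Re(ev)) > 0, cond$unstable)
  }
})

test_that("the maturation cycle exists iff the oscillation condition holds", {
  p <- micro_params()
  lc <- limit_cycle(p, 0.457, 10.6)
  expect_true(lc$oscillatory)
  expect_true(is.finite(lc$period))
  expect_gt(lc$period, 0)
  expect_gt(lc$y_max, lc$x_max) # matures into a Y-rich compartment
  # nearby nucleation states collapse onto the same transit
  lc2 <- limit_cycle(p, 0.457, 10.6, x0 = 3, y0 = 0.5)
  expect_lt(abs(lc2$y_max - lc$y_max) / lc$y_max, 0.05)
  expect_lt(abs(lc2$period - lc$period) / lc$period, 0.05)
  # parameters violating the condition converge to the fixed point
  lcs <- limit_cycle(micro_params(B = 0.5), 0.457, 10.6)
  expect_false(lcs$oscillatory)
  expect_true(is.na(lcs$period))
  tail_state <- utils::tail(lcs$trajectory, 1)
  expect_equal(tail_state$x, lcs$fixed_point[["x"]], tolerance = 1e-3)
})

test_that("stochastic compartment cycles approximate the mean-field transit", {
  run <- gillespie_run(micro_params(), t_end = 6, seed = 8)
  lc <- limit_cycle(micro_params(), run$nXbar, run$nYbar)
  # compartments born after the pools have equilibrated
  done <- run$completed[run$completed$birth > 2, ]
  # per-compartment peak Y content matches the deterministic transit peak
  # within stochastic tolerance
  expect_gt(nrow(done), 50)
  expect_lt(abs(stats::median(done$ymax) - lc$y_max) / lc$y_max, 0.5)
})
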