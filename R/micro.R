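#' Parameters of the microscopic two-label maturation model
#'
#' A well-mixed cytoplasm carries two molecule types `X` and `Y` on
#' vesicles (one unit each) and compartments (anything larger than a
#' vesicle, i.e. `x + y >= 2` units). `X` vesicles fuse homotypically to
#' nucleate compartments and, much less efficiently, to compartments; `Y`
#' vesicles fuse only to compartments; compartments never fuse to one
#' another.
#'
#' @param xtot,ytot total amounts of `X` and `Y`, in vesicle units.
#' @param A homotypic/cooperative fusion rate constant (units per minute).
#' @param B,C,D budding and fusion rate constants (per minute); `1/D` is
#'   the approximate time a compartment takes to fully vesiculate.
#' @return list of class `micro_params`. Defaults are the reference
#'   parameter set `{xtot, ytot} = {250, 5000}`,
#'   `{A, B, C, D} = {1000, 10, 5, 1}`.
#' @export
micro_params <- function(xtot = 250, ytot = 5000, A = 1000, B = 10, C = 5, D = 1) {
  p <- list(xtot = xtot, ytot = ytot, A = A, B = B, C = C, D = D)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "micro_params")
}

#' Reaction propensities of a microscopic state
#'
#' The reaction channels are: homotypic nucleation of two `X` vesicles
#' into a `(2, 0)` compartment at rate `A nX (nX - 1)`; per compartment
#' `(x, y)`: budding of an `X` vesicle at rate `B x`, budding of a `Y`
#' vesicle at rate `D y`, fusion of an `X` vesicle at rate
#' `A x^2 / (x + y)^2 nX` (reducing to the homotypic constant `A` in the
#' vesicle limit), and fusion of a `Y` vesicle at rate `C x nY`.
#'
#' @param state list with `nX`, `nY` (free vesicle pools) and integer
#'   vectors `x`, `y` (per-compartment contents, `x + y >= 2`).
#' @param params a [micro_params()].
#' @return list with `homotypic` (scalar rate) and per-compartment rate
#'   vectors `bud_x`, `bud_y`, `fuse_x`, `fuse_y`.
#' @export
reaction_rates <- function(state, params) {
  x <- state$x; y <- state$y
  s2 <- (x + y)^2
  list(
    homotypic = params$A * state$nX * (state$nX - 1),
    bud_x = params$B * x,
    bud_y = params$D * y,
    fuse_x = if (length(x)) params$A * x^2 / s2 * state$nX else numeric(0),
    fuse_y = params$C * x * state$nY
  )
}

#' Exact stochastic simulation of the microscopic model
#'
#' Gillespie simulation of the reaction system described in
#' [reaction_rates()]. All mass starts as free vesicles
#' (`nX = xtot`, `nY = ytot`). Total `X` and `Y` are conserved exactly at
#' every event (asserted during the run). After a burn-in fraction of the
#' simulated time, the free vesicle pools are time-averaged; the system
#' reaches an equilibrium in which these pools and the census of
#' compartment compositions are approximately constant, while individual
#' compartments cycle through nucleation, maturation and vesiculation.
#'
#' @param params a [micro_params()].
#' @param t_end simulated time in minutes.
#' @param seed optional integer passed to `set.seed()`.
#' @param burn_in fraction of `t_end` discarded before time-averaging
#'   (default 0.2).
#' @param n_snapshots number of evenly spaced census snapshots to record.
#' @param check_every assert exact conservation every this many events
#'   (1 = every event).
#' @return list with `nXbar`, `nYbar` (time-averaged pools over the
#'   equilibrium window), `snapshots` (data.frame `time`, `nX`, `nY`,
#'   `n_compartments`, `x_comp`, `y_comp`), `completed` (data.frame of
#'   finished compartment lifetimes: `birth`, `death`, `xmax`, `ymax`),
#'   `final` (final state), `n_events`, and the call parameters.
#' @examples
#' \donttest{
#' run <- gillespie_run(micro_params(), t_end = 5, seed = 1)
#' c(run$nXbar, run$nYbar)
#' }
#' @export
gillespie_run <- function(params, t_end, seed = NULL, burn_in = 0.2,
                          n_snapshots = 500L, check_every = 1L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(t_end > 0)
  xtot <- params$xtot; ytot <- params$ytot
  A <- params$A; B <- params$B; C <- params$C; D <- params$D

  nX <- xtot; nY <- ytot
  x <- numeric(0); y <- numeric(0)
  birth <- numeric(0); xmax <- numeric(0); ymax <- numeric(0)

  t <- 0
  t_burn <- burn_in * t_end
  accX <- 0; accY <- 0; acc_t <- 0
  snap_times <- seq(0, t_end, length.out = n_snapshots)
  snap_i <- 1L
  sn_t <- numeric(n_snapshots); sn_nX <- numeric(n_snapshots)
  sn_nY <- numeric(n_snapshots); sn_nc <- integer(n_snapshots)
  sn_x <- numeric(n_snapshots); sn_y <- numeric(n_snapshots)
  done_birth <- numeric(0); done_death <- numeric(0)
  done_xmax <- numeric(0); done_ymax <- numeric(0)
  n_events <- 0L

  record_up_to <- function(now) {
    while (snap_i <= n_snapshots && snap_times[snap_i] <= now) {
      sn_t[snap_i] <<- snap_times[snap_i]
      sn_nX[snap_i] <<- nX; sn_nY[snap_i] <<- nY
      sn_nc[snap_i] <<- length(x)
      sn_x[snap_i] <<- sum(x); sn_y[snap_i] <<- sum(y)
      snap_i <<- snap_i + 1L
    }
  }

  repeat {
    s <- x + y
    r_hom <- A * nX * (nX - 1)
    r_budx <- B * x
    r_budy <- D * y
    r_fusx <- if (length(x)) A * x^2 / s^2 * nX else numeric(0)
    r_fusy <- C * x * nY
    rates <- c(r_hom, r_budx, r_budy, r_fusx, r_fusy)
    total <- sum(rates)
    if (total <= 0) {
      record_up_to(t_end)
      if (t < t_end && t >= t_burn) {
        accX <- accX + nX * (t_end - max(t, t_burn))
        accY <- accY + nY * (t_end - max(t, t_burn))
        acc_t <- acc_t + (t_end - max(t, t_burn))
      }
      break
    }
    dt <- stats::rexp(1, total)
    t_next <- t + dt
    # time-weighted pool averages over the post-burn-in window
    lo <- max(t, t_burn); hi <- min(t_next, t_end)
    if (hi > lo) {
      accX <- accX + nX * (hi - lo)
      accY <- accY + nY * (hi - lo)
      acc_t <- acc_t + (hi - lo)
    }
    record_up_to(min(t_next, t_end))
    if (t_next >= t_end) break
    t <- t_next
    n_events <- n_events + 1L

    k <- sample.int(length(rates), 1L, prob = rates)
    nc <- length(x)
    if (k == 1L) {
      # homotypic nucleation: two X vesicles -> compartment (2, 0)
      nX <- nX - 2
      x <- c(x, 2); y <- c(y, 0)
      birth <- c(birth, t); xmax <- c(xmax, 2); ymax <- c(ymax, 0)
    } else if (k <= 1L + nc) {
      i <- k - 1L                      # bud an X vesicle
      nX <- nX + 1
      x[i] <- x[i] - 1
      if (x[i] + y[i] < 2) {
        if (x[i] == 1) nX <- nX + 1 else if (y[i] == 1) nY <- nY + 1
        done_birth <- c(done_birth, birth[i]); done_death <- c(done_death, t)
        done_xmax <- c(done_xmax, xmax[i]); done_ymax <- c(done_ymax, ymax[i])
        x <- x[-i]; y <- y[-i]; birth <- birth[-i]
        xmax <- xmax[-i]; ymax <- ymax[-i]
      }
    } else if (k <= 1L + 2L * nc) {
      i <- k - 1L - nc                 # bud a Y vesicle
      nY <- nY + 1
      y[i] <- y[i] - 1
      if (x[i] + y[i] < 2) {
        if (x[i] == 1) nX <- nX + 1 else if (y[i] == 1) nY <- nY + 1
        done_birth <- c(done_birth, birth[i]); done_death <- c(done_death, t)
        done_xmax <- c(done_xmax, xmax[i]); done_ymax <- c(done_ymax, ymax[i])
        x <- x[-i]; y <- y[-i]; birth <- birth[-i]
        xmax <- xmax[-i]; ymax <- ymax[-i]
      }
    } else if (k <= 1L + 3L * nc) {
      i <- k - 1L - 2L * nc            # fuse an X vesicle
      nX <- nX - 1
      x[i] <- x[i] + 1
      if (x[i] > xmax[i]) xmax[i] <- x[i]
    } else {
      i <- k - 1L - 3L * nc            # fuse a Y vesicle
      nY <- nY - 1
      y[i] <- y[i] + 1
      if (y[i] > ymax[i]) ymax[i] <- y[i]
    }
    if (n_events %% check_every == 0L) {
      if (nX + sum(x) != xtot || nY + sum(y) != ytot) {
        stop("conservation of xtot/ytot violated at event ", n_events)
      }
    }
  }
  record_up_to(t_end)

  list(
    nXbar = accX / acc_t, nYbar = accY / acc_t,
    snapshots = data.frame(time = sn_t, nX = sn_nX, nY = sn_nY,
                           n_compartments = sn_nc,
                           x_comp = sn_x, y_comp = sn_y),
    completed = data.frame(birth = done_birth, death = done_death,
                           xmax = done_xmax, ymax = done_ymax),
    final = list(nX = nX, nY = nY, x = x, y = y),
    n_events = n_events, params = params, t_end = t_end,
    burn_in = burn_in, seed = seed
  )
}

#' Mean-field vector field of a single compartment
#'
#' In the mean-field limit a compartment's contents `(x, y)` obey
#' `dx/dt = A nXbar x^2 / (x + y)^2 - B x` and
#' `dy/dt = C nYbar x - D y`, where `nXbar`, `nYbar` are the time-averaged
#' free vesicle pools of the stochastic system.
#'
#' @param x,y compartment contents (vesicle units), `x + y > 0`.
#' @param params a [micro_params()].
#' @param nXbar,nYbar time-averaged free vesicle pools.
#' @return numeric vector `c(dx, dy)`.
#' @export
ode_field <- function(x, y, params, nXbar, nYbar) {
  if (x + y <= 0) stop("ode_field is undefined at x = y = 0")
  c(
    params$A * nXbar * x^2 / (x + y)^2 - params$B * x,
    params$C * nYbar * x - params$D * y
  )
}

#' Interior fixed point of the mean-field equations
#'
#' Solving `dx/dt = dy/dt = 0` with `x > 0` gives
#' `y* = (C nYbar / D) x*` and
#' `x* = A nXbar / (B (1 + C nYbar / D)^2)`.
#'
#' @inheritParams ode_field
#' @return numeric vector `c(x = x*, y = y*)`.
#' @export
micro_fixed_point <- function(params, nXbar, nYbar) {
  k <- params$C * nYbar / params$D
  xs <- params$A * nXbar / (params$B * (1 + k)^2)
  c(x = xs, y = k * xs)
}

#' Oscillation condition of the mean-field model
#'
#' The interior fixed point loses stability (no stable fixed point; a
#' limit cycle appears) when
#' `(B / (B + D)) * (C nYbar / (C nYbar + D)) > 1/2`: roughly, `X`
#' vesicles must bud rapidly and `Y` vesicles must fuse rapidly.
#'
#' @param params a [micro_params()].
#' @param nYbar time-averaged free `Y` vesicle pool.
#' @return list with `unstable` (logical: no stable fixed point) and
#'   `lhs`, the value of the parametric expression.
#' @export
stability_condition <- function(params, nYbar) {
  lhs <- (params$B / (params$B + params$D)) *
    (params$C * nYbar / (params$C * nYbar + params$D))
  list(unstable = lhs > 0.5, lhs = lhs)
}

#' Jacobian of the mean-field system at a point
#' @inheritParams ode_field
#' @return 2x2 numeric matrix (analytic).
#' @export
micro_jacobian <- function(x, y, params, nXbar, nYbar) {
  s <- x + y
  dfdx <- params$A * nXbar * (2 * x / s^2 - 2 * x^2 / s^3) - params$B
  dfdy <- -2 * params$A * nXbar * x^2 / s^3
  matrix(c(dfdx, params$C * nYbar, dfdy, -params$D), 2, 2)
}

#' Deterministic maturation cycle of the mean-field model
#'
#' Integrates the mean-field equations from a nucleation state (default a
#' fresh `(2, 0)` compartment, the product of homotypic fusion of two `X`
#' vesicles) with a stiff-capable adaptive integrator. When the
#' oscillation condition holds, the interior fixed point is unstable and
#' the trajectory performs one transit — growth by `X`/`Y` fusion,
#' maturation as `X` buds away, and final decay of `y` (vesiculation) —
#' before falling below the one-vesicle dissolution scale `x + y < 2`,
#' where the compartment leaves the census and the cycle is closed by
#' renucleation. The returned closed orbit is this transit; its period is
#' the transit time and its extrema trace the creation, maturation and
#' vesiculation phases (and correspond to the Boolean compartment
#' compositions of the two-label maturation chain). The transit is
#' strongly attracting: nearby nucleation states collapse onto the same
#' orbit. When the oscillation condition fails the trajectory converges
#' to the stable fixed point instead and no cycle is reported.
#'
#' @param params a [micro_params()].
#' @param nXbar,nYbar time-averaged free pools (e.g. from
#'   [gillespie_run()]).
#' @param x0,y0 initial compartment contents (`x0 + y0 >= 2`).
#' @param t_max integration horizon (minutes).
#' @param dissolve dissolution scale: the transit ends when `x + y` drops
#'   below this (default 2, the smallest compartment).
#' @param rtol relative integration tolerance.
#' @return list with `cycle` (data.frame `time`, `x`, `y` over one
#'   transit, or `NULL`), `period` (transit time; `NA` when no cycle),
#'   `x_max`, `y_max` (extrema of the transit), `fixed_point`, and
#'   `oscillatory` (the stability condition).
#' @export
limit_cycle <- function(params, nXbar, nYbar, x0 = 2, y0 = 0,
                        t_max = 200, dissolve = 2, rtol = 1e-8) {
  fp <- micro_fixed_point(params, nXbar, nYbar)
  cond <- stability_condition(params, nYbar)
  deriv <- function(t, st, p) {
    list(ode_field(max(st[1L], 0), max(st[2L], 0), params, nXbar, nYbar))
  }
  times <- seq(0, t_max, by = 0.005)
  if (!cond$unstable) {
    sol <- deSolve::lsoda(c(x = x0, y = y0), times, deriv, parms = NULL,
                          rtol = rtol, atol = 1e-12)
    return(list(cycle = NULL, period = NA_real_,
                x_max = NA_real_, y_max = NA_real_,
                fixed_point = fp, oscillatory = FALSE,
                trajectory = data.frame(time = sol[, "time"],
                                        x = sol[, "x"], y = sol[, "y"])))
  }
  # stop when the compartment shrinks back through the dissolution scale
  root <- function(t, st, p) st[1L] + st[2L] - 0.99 * dissolve
  sol <- deSolve::lsoda(c(x = x0, y = y0), times, deriv, parms = NULL,
                        rtol = rtol, atol = 1e-12, rootfunc = root)
  ts <- sol[, "time"]; xs <- sol[, "x"]; ys <- sol[, "y"]
  ended <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot"))
  if (!ended) {
    return(list(cycle = NULL, period = NA_real_,
                x_max = NA_real_, y_max = NA_real_,
                fixed_point = fp, oscillatory = TRUE,
                trajectory = data.frame(time = ts, x = xs, y = ys)))
  }
  list(
    cycle = data.frame(time = ts, x = xs, y = ys),
    period = ts[length(ts)],
    x_max = max(xs), y_max = max(ys),
    fixed_point = fp, oscillatory = TRUE
  )
}
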