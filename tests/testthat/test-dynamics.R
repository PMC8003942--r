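# time integration of the coupled system

test_that("reaction RHS matches the kinetic equations nodewise", {
  g <- make_grid(2, 5)
  one <- matrix(1, 5, 5)
  # zero state with unit production: derivatives are (alpha, alpha)
  st0 <- state_pair(0 * one, 0 * one, g)
  d0 <- reaction_rhs(constant_model(), st0, t = 0)
  expect_equal(d0$dm, one)
  expect_equal(d0$dn, one)
  # symmetric steady state of 1 - u - u^2 = 0
  ustar <- (sqrt(5) - 1) / 2
  dss <- reaction_rhs(constant_model(), state_pair(ustar * one, ustar * one, g), 0)
  expect_equal(dss$dm, 0 * one, tolerance = 1e-14)
  expect_equal(dss$dn, 0 * one, tolerance = 1e-14)
  # theta = 0 decouples the species
  m <- matrix(runif(25), 5)
  dec <- model_spec(2, 3, 5, 7, 0, mobility = "none")
  da <- reaction_rhs(dec, state_pair(m, 0 * one, g), 1)
  db <- reaction_rhs(dec, state_pair(m, one, g), 1)
  expect_equal(da$dm, db$dm)
  # spatial rates are evaluated at each node's coordinates
  sp <- model_spec(rate_spec("tanh_half"), 0, 0, 0, 0, mobility = "none")
  dsp <- reaction_rhs(sp, st0, 0)
  co <- rdgep:::.grid_coords(g)
  expect_equal(dsp$dm, 0.5 * (tanh((co$x * co$y - 0.5) / 0.2) + 1))
})

test_that("well-mixed integration holds constants and finds fixed points", {
  zero <- model_spec(0, 0, 0, 0, 0, mobility = "none")
  tr <- simulate_ode(zero, 2.5, 0.75, integrator_config(t_end = 4))
  expect_true(all(tr$m == 2.5))
  expect_true(all(tr$n == 0.75))
  # constant rates alpha = beta = theta = 1 converge to (sqrt(5)-1)/2
  tr2 <- simulate_ode(constant_model(), 3, 0.1, integrator_config(t_end = 20))
  ustar <- (sqrt(5) - 1) / 2
  expect_lt(abs(tail(tr2$m, 1) - ustar), 1e-6)
  expect_lt(abs(tail(tr2$n, 1) - ustar), 1e-6)
  # strong self-degradation: analytic e^{-1000 t} decay
  fast <- model_spec(0, 1e3, 0, 0, 0, mobility = "none")
  tr3 <- simulate_ode(fast, 1, 0, integrator_config(scheme = "rk4", dt = 1e-5,
                                                    t_end = 0.05))
  expect_lt(tail(tr3$m, 1), 1e-6)
  expect_equal(tail(tr3$m, 1), exp(-1000 * 0.05), tolerance = 1e-3)
})

test_that("well-mixed integration agrees with deSolve on a registry model", {
  skip_if_not_installed("deSolve")
  mod <- get_model(1)
  f <- function(t, y, parms) {
    list(c(rate_eval(mod$alpha_m, t) - rate_eval(mod$beta_m, t) * y[1] -
             rate_eval(mod$theta, t) * y[1] * y[2],
           rate_eval(mod$alpha_ns, t) - rate_eval(mod$beta_ns, t) * y[2] -
             rate_eval(mod$theta, t) * y[1] * y[2]))
  }
  ref <- deSolve::ode(c(m = 2, n = 1), times = 0:4, func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- simulate_ode(mod, 2, 1, integrator_config(scheme = "rk4", dt = 1e-3))
  idx <- match(0:4, round(tr$times, 9))
  expect_equal(tr$m[idx], unname(ref[, "m"]), tolerance = 1e-7)
  expect_equal(tr$n[idx], unname(ref[, "n"]), tolerance = 1e-7)
})

test_that("spatial-rate models require an evaluation point and blow-ups abort", {
  expect_error(simulate_ode(get_model(13, mobility = "none"), 1, 1,
                            integrator_config(t_end = 1)),
               "evaluation point")
  explode <- model_spec(rate_spec("custom", fn = function(t, x, y) exp(20 * t)),
                        0, 0, 0, 0, mobility = "none")
  expect_error(simulate_ode(explode, 1, 1, integrator_config(t_end = 2)),
               "exceeded")
})

test_that("stability limit follows h^2 / (2 d D) and CFL is enforced", {
  g <- make_grid(2, 51)  # h = 0.02
  expect_equal(stability_limit(g, diffusion_model(1e-3)), 0.1)
  expect_identical(stability_limit(g, constant_model(mobility = "none")), Inf)
  # doubling the resolution quarters the limit
  g2 <- make_grid(2, 101)
  expect_equal(stability_limit(g2, diffusion_model(1e-3)), 0.025)
  # only the mobile species' coefficient matters
  m <- model_spec(0, 0, 0, 0, 0, d_m = 1, d_ns = 1e-3, mobility = "ns_only")
  expect_equal(stability_limit(g, m), 0.1)
  # euler refuses a step beyond the limit before stepping
  st <- seeded_state(g, windowed = FALSE)
  expect_error(
    simulate_pde(diffusion_model(1e-3), st, bc_spec("neumann"),
                 integrator_config(scheme = "euler", dt = 0.2, t_end = 1)),
    "CFL")
})

test_that("pure diffusion decays the Dirichlet eigenmode at the analytic rate", {
  g <- make_grid(2, 101)
  ax <- grid_axis(g)
  f <- outer(sin(pi * ax), sin(pi * ax))
  traj <- simulate_pde(diffusion_model(1e-3), state_pair(f, f, g),
                       bc_spec("dirichlet"), integrator_config(t_end = 4))
  ctr <- (g$n + 1) / 2
  ratio <- traj$states[[5]]$m[ctr, ctr] / f[ctr, ctr]
  expect_equal(ratio, exp(-2 * pi^2 * 1e-3 * 4), tolerance = 1e-2)
})

test_that("pure diffusion under Neumann conserves total abundance", {
  g <- make_grid(2, 51)
  st <- seeded_state(g, seed = 3, windowed = FALSE)
  traj <- simulate_pde(diffusion_model(1e-3), st, bc_spec("neumann"),
                       integrator_config(t_end = 4))
  expect_equal(traj$abundance_m / traj$abundance_m[1], rep(1, 5),
               tolerance = 1e-6)
  expect_equal(traj$abundance_n / traj$abundance_n[1], rep(1, 5),
               tolerance = 1e-6)
})

test_that("pure diffusion with euler under CFL has non-increasing max-norm", {
  g <- make_grid(2, 31)
  st <- seeded_state(g, seed = 5, windowed = FALSE)
  traj <- simulate_pde(diffusion_model(5e-3), st, bc_spec("dirichlet"),
                       integrator_config(scheme = "euler",
                                         output_times = 0:4))
  maxima <- vapply(traj$states, function(s) max(abs(s$m)), numeric(1))
  expect_true(all(diff(maxima) <= 1e-12))
})

test_that("Dirichlet snapshots vanish on the boundary for every model", {
  g <- make_grid(2, 21)
  st <- seeded_state(g, seed = 1, windowed = TRUE)
  mask <- rdgep:::.boundary_mask(g)
  for (id in c(1, 6, 11)) {
    traj <- simulate_pde(get_model(id), st, bc_spec("dirichlet"),
                         integrator_config(t_end = 2, output_times = 0:2))
    for (s in traj$states) {
      expect_identical(unique(s$m[mask]), 0)
      expect_identical(unique(s$n[mask]), 0)
    }
  }
})

test_that("mobility modes add diffusion only to the mobile species", {
  g <- make_grid(2, 15)
  st <- seeded_state(g, seed = 2, windowed = TRUE)
  cfg <- integrator_config(t_end = 1, output_times = c(0, 1))
  run <- function(mob, d_m = 1e-3, d_ns = 1e-3) {
    simulate_pde(get_model(1, d_m = d_m, d_ns = d_ns, mobility = mob),
                 st, bc_spec("dirichlet"), cfg)
  }
  # with d_ns = 0, "both" and "mi_only" coincide; symmetrically for d_m = 0
  expect_equal(traj_max_diff(run("both", d_ns = 0), run("mi_only", d_ns = 0)),
               0)
  expect_equal(traj_max_diff(run("both", d_m = 0), run("ns_only", d_m = 0)),
               0)
  # mobility changes the solution when both coefficients are positive
  expect_gt(traj_max_diff(run("both"), run("none")), 0)
})

test_that("without mobility the field integrates each node as a well-mixed cell", {
  g <- make_grid(2, 7)
  st <- seeded_state(g, seed = 4, windowed = FALSE)
  cfg <- integrator_config(scheme = "rk4", dt = 1e-2, t_end = 4)
  mod <- get_model(3, mobility = "none")  # includes a spatial tanh rate
  traj <- simulate_pde(mod, st, bc_spec("neumann"), cfg)
  co <- rdgep:::.grid_coords(g)
  for (nd in c(1L, 17L, 25L)) {
    tr <- simulate_ode(mod, st$m[nd], st$n[nd], cfg,
                       x = co$x[nd], y = co$y[nd])
    idx <- match(0:4, round(tr$times, 9))
    got <- vapply(traj$states, function(s) s$m[nd], numeric(1))
    expect_equal(got, tr$m[idx], tolerance = 1e-9)
  }
})

test_that("uniform states with uniform rates stay uniform and track the ODE", {
  g <- make_grid(2, 11)
  u0 <- matrix(1.2, g$n, g$n)
  v0 <- matrix(0.4, g$n, g$n)
  mod <- get_model(1)  # purely temporal rates, both species mobile
  cfg <- integrator_config(t_end = 4)
  traj <- simulate_pde(mod, state_pair(u0, v0, g), bc_spec("neumann"), cfg)
  ode <- simulate_ode(mod, 1.2, 0.4, cfg)
  idx <- match(0:4, round(ode$times, 9))
  for (i in seq_along(traj$times)) {
    expect_lt(diff(range(traj$states[[i]]$m)), 1e-10)
    expect_equal(traj$states[[i]]$m[1, 1], ode$m[idx[i]], tolerance = 1e-6)
  }
})

test_that("halving the step changes snapshots below tolerance", {
  g <- make_grid(2, 31)
  st <- seeded_state(g, seed = 1, windowed = TRUE)
  run <- function(dt, sch) {
    simulate_pde(get_model(1), st, bc_spec("dirichlet"),
                 integrator_config(scheme = sch, dt = dt, t_end = 4))
  }
  expect_lt(traj_max_diff(run(1e-2, "rk4"), run(5e-3, "rk4")), 1e-3)
  # euler converges at first order: successive halvings shrink the
  # difference by about a factor 2
  d1 <- traj_max_diff(run(2e-3, "euler"), run(1e-3, "euler"))
  d2 <- traj_max_diff(run(1e-3, "euler"), run(5e-4, "euler"))
  expect_equal(d1 / d2, 2, tolerance = 0.25)
})

test_that("registry models keep concentrations essentially non-negative", {
  g <- make_grid(2, 21)
  st <- seeded_state(g, seed = 1, windowed = TRUE)
  for (id in seq_len(15)) {
    traj <- simulate_pde(get_model(id), st, bc_spec("dirichlet"),
                         integrator_config(t_end = 4))
    expect_gt(traj$min_value, -1e-6)
  }
})

test_that("trajectory bookkeeping: snapshot times, first state, abundances", {
  g <- make_grid(2, 15)
  st <- seeded_state(g, seed = 9, windowed = TRUE)
  traj <- simulate_pde(get_model(2), st, bc_spec("dirichlet"),
                       integrator_config(t_end = 4))
  expect_identical(traj$times, c(0, 1, 2, 3, 4))
  expect_identical(traj$step_times, c(0, 1, 2, 3, 4))
  # first snapshot is the (boundary-pinned) initial condition
  expect_equal(traj$states[[1]]$m, st$m, tolerance = 1e-14)
  expect_equal(traj$abundance_m[1], total_abundance(st$m, g))
  expect_true(all(diff(traj$times) > 0))
})
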