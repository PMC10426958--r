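pars <- jr_parameters()

test_that("sigmoid hits its midpoint, bounds and monotonicity", {
  expect_equal(jr_sigmoid(pars$v0, pars), pars$vmax)
  expect_equal(jr_sigmoid(1e6, pars), 2 * pars$vmax)
  expect_equal(jr_sigmoid(-1e6, pars), 0)
  v <- seq(-50, 50, by = 0.5)
  s <- jr_sigmoid(v, pars)
  expect_true(all(s > 0 & s < 2 * pars$vmax))
  expect_true(all(diff(s) > 0))
})

test_that("derivatives wire positions to velocities and obey the closed form", {
  set.seed(1)
  for (k in 1:5) {
    st <- rnorm(6, 0, 5)
    d <- jr_derivatives(st, input_value = runif(1, 0, 0.3), pars)
    expect_equal(d[1:3], st[4:6])
  }
  # zero state, zero input: dy3/dt = A a S[0] with S[0] = 2 vmax/(1+exp(r v0))
  d0 <- jr_derivatives(rep(0, 6), 0, pars)
  S0 <- 2 * pars$vmax / (1 + exp(pars$r * pars$v0))
  expect_equal(d0[4], pars$A * pars$a * S0)
  expect_equal(d0[5], pars$A * pars$a * (0 + pars$C2 * S0))
  expect_equal(d0[6], pars$B * pars$b * pars$C4 * S0)
})

test_that("fixed points are roots of the full system", {
  for (p in c(0, 0.05, 0.09, 0.15)) {
    roots <- fixed_point(pars, p = p, tolerance = 1e-10)
    for (rt in roots) {
      expect_lt(max(abs(jr_derivatives(rt$state, p, pars))), 1e-10)
      # algebraic consistency of the excitatory branch
      y0 <- rt$state[1]
      expect_equal(rt$state[2],
                   pars$A / pars$a *
                     (p + pars$C2 * jr_sigmoid(pars$C1 * y0, pars)),
                   tolerance = 1e-8)
    }
    # below the oscillation onset a stable equilibrium exists; above it the
    # equilibrium loses stability (the limit cycle takes over)
    n_stable <- sum(vapply(roots, `[[`, logical(1), "stable"))
    if (p <= 0.09) expect_gte(n_stable, 1) else expect_equal(n_stable, 0)
  }
})

test_that("network input reduces to drive at g = 0 and adds sigmoid coupling", {
  sc <- toy_connectome()
  drive <- drive_config(sc)
  out <- rep(3, 3)
  expect_equal(network_input(1, out, drive, coupling_config(g = 0), sc, 0.01),
               drive$p[1] + 0.01)
  # two nodes, unit weight, donor sitting at v0: coupling term is g * vmax
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  sc2 <- structural_connectome(w, w * 10, c("a", "b"), rep("cortical", 2))
  drive2 <- drive_config(sc2)
  val <- network_input(1, c(0, pars$v0), drive2, coupling_config(g = 2), sc2,
                       noise_sample = 0.005)
  # only node 2 feeds node 1 (w[2,1] = 1)
  expect_equal(val, drive2$p[1] + 0.005 +
                 2 * (jr_sigmoid(0, pars) * 0 + pars$vmax * 1))
})

test_that("identical seeds give bit-identical simulations", {
  sc <- random_connectome(n = 5, n_driver = 1, seed = 4)
  cfg <- sim_config(duration = 3000, transient = 500, seed = 99)
  drive <- drive_config(sc, driver_role = "thalamic", driver_eta = 0.022)
  a <- simulate_network(sc, pars, drive, coupling_config(g = 2), cfg)
  b <- simulate_network(sc, pars, drive, coupling_config(g = 2), cfg)
  expect_identical(a$signals, b$signals)
  cfg2 <- cfg; cfg2$seed <- 100L
  c2 <- simulate_network(sc, pars, drive, coupling_config(g = 2), cfg2)
  expect_false(identical(a$signals, c2$signals))
})

test_that("a noise-free damped node converges to the fixed-point root", {
  sc <- single_node()
  for (p in c(0, 0.05, 0.09)) {
    sim <- simulate_network(sc, pars,
                            drive_config(sc, cortical_p = p, cortical_eta = 0),
                            coupling_config(g = 0),
                            sim_config(duration = 10000, transient = 2000,
                                       seed = 1))
    roots <- fixed_point(pars, p = p)
    stable <- roots[vapply(roots, `[[`, logical(1), "stable")]
    dist <- min(vapply(stable, function(rt)
      max(abs(sim$final_state[, 1] - rt$state)), numeric(1)))
    expect_lt(dist, 1e-6)
  }
})

test_that("the damped regime stays near its fixed point, the oscillatory does not", {
  sc <- single_node()
  damped <- simulate_network(sc, pars,
                             drive_config(sc, cortical_p = 0.09,
                                          cortical_eta = 2.2e-8),
                             config = sim_config(duration = 10000,
                                                 transient = 2000, seed = 2))
  x <- post_transient(damped)
  expect_lt(max(x) - min(x), 1e-3)
  osc <- simulate_network(sc, pars,
                          drive_config(sc, cortical_p = 0.15,
                                       cortical_eta = 2.2e-8),
                          config = sim_config(duration = 10000,
                                              transient = 2000, seed = 2))
  xo <- post_transient(osc)
  expect_gt(max(xo) - min(xo), 1)
  peak <- spectral_summary(xo, osc$fs)$peak_freq
  expect_gte(peak, 8)
  expect_lte(peak, 12)
})

test_that("halving dt moves the limit-cycle spectral peak by < 2%", {
  sc <- single_node()
  peaks <- vapply(c(0.1, 0.05), function(dt) {
    sim <- simulate_network(sc, pars,
                            drive_config(sc, cortical_p = 0.2,
                                         cortical_eta = 0),
                            config = sim_config(duration = 8000,
                                                transient = 2000, dt = dt,
                                                seed = 3))
    spectral_summary(post_transient(sim), sim$fs)$peak_freq
  }, numeric(1))
  expect_lt(abs(peaks[2] - peaks[1]) / peaks[1], 0.02)
})

test_that("identical uncoupled noise-free nodes evolve identically", {
  sc <- uncoupled_nodes(4)
  sim <- simulate_network(sc, pars,
                          drive_config(sc, cortical_p = 0.13,
                                       cortical_eta = 0),
                          config = sim_config(duration = 4000,
                                              transient = 1000, seed = 5))
  for (i in 2:4) expect_equal(sim$signals[i, ], sim$signals[1, ])
})

test_that("conduction delays change coupled dynamics", {
  w <- matrix(c(0, 5, 5, 0), 2, 2)
  sc_fast <- structural_connectome(w, w * 2, c("a", "b"), rep("cortical", 2))
  sc_slow <- structural_connectome(w, w * 30, c("a", "b"), rep("cortical", 2))
  cfg <- sim_config(duration = 4000, transient = 1000, seed = 8)
  drive <- function(sc) drive_config(sc, cortical_p = 0.12, cortical_eta = 0)
  a <- simulate_network(sc_fast, pars, drive(sc_fast),
                        coupling_config(g = 10), cfg)
  b <- simulate_network(sc_slow, pars, drive(sc_slow),
                        coupling_config(g = 10), cfg)
  expect_false(isTRUE(all.equal(a$signals, b$signals)))
})

test_that("bifurcation scan reports extrema per group across the grid", {
  sc <- random_connectome(n = 6, n_driver = 2, seed = 6)
  tab <- bifurcation_scan(sc, pars,
                          drive_config(sc, driver_role = "thalamic",
                                       driver_eta = 0.022),
                          coupling_config(), "g", grid = c(0, 2),
                          sim_config = sim_config(duration = 3000,
                                                  transient = 1000, seed = 7))
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$group), c("cortical", "driver", "all"))
  expect_true(all(tab$vmax >= tab$vmin))

  # damped single node: max ~ min ~ fixed-point output
  sn <- single_node()
  tb <- bifurcation_scan(sn, pars,
                         drive_config(sn, cortical_p = 0.09, cortical_eta = 0),
                         coupling_config(), "g", grid = 0,
                         sim_config = sim_config(duration = 10000,
                                                 transient = 5000, seed = 1))
  roots <- fixed_point(pars, p = 0.09)
  v_fp <- roots[[which(vapply(roots, `[[`, logical(1), "stable"))[1]]]$v
  row <- tb[tb$group == "cortical", ]
  expect_equal(row$vmax, v_fp, tolerance = 1e-3)
  expect_equal(row$vmin, v_fp, tolerance = 1e-3)
})
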