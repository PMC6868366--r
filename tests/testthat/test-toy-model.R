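test_that("potential energy matches its definition and symmetries", {
  p <- toy_params()
  expect_equal(potential_energy(c(1, 0), toy_params(G = 1e-300)), 0,
               tolerance = 1e-12)
  expect_equal(potential_energy(c(-1, 0), toy_params(G = 1e-300)), 0,
               tolerance = 1e-12)
  expect_equal(potential_energy(c(0, 0), p), p$a + p$G)
  set.seed(1)
  pts <- matrix(runif(40, -2, 2), ncol = 2)
  expect_equal(potential_energy(pts, p),
               oracle_V(pts[, 1], pts[, 2]), tolerance = 1e-12)
  # even in x and in y
  expect_equal(potential_energy(pts, p),
               potential_energy(cbind(-pts[, 1], pts[, 2]), p))
  expect_equal(potential_energy(pts, p),
               potential_energy(cbind(pts[, 1], -pts[, 2]), p))
})

test_that("the outside saddle lies strictly below the inside barrier", {
  p <- toy_params()
  s <- outside_saddle(p)
  # independent golden-section search on the oracle potential
  o <- optimize(function(y) oracle_V(0, y), c(1e-6, 5))
  expect_equal(s$height, o$objective, tolerance = 1e-8)
  expect_lt(s$height, p$a + p$G)
})

test_that("force equals the negative potential gradient", {
  p <- toy_params(tilt = 0.3)
  set.seed(2)
  for (i in 1:10) {
    pt <- runif(2, -1.8, 1.8)
    f <- force_field(pt, p)
    fd <- -oracle_grad(pt[1], pt[2], tilt = 0.3)
    expect_equal(as.numeric(f), fd, tolerance = 1e-6)
  }
  expect_equal(as.numeric(force_field(c(0, 0), toy_params())), c(0, 0))
  expect_equal(as.numeric(force_field(c(1, 0), toy_params(G = 1e-300))),
               c(0, 0), tolerance = 1e-12)
})

test_that("the integrator is symplectic in the zero-friction limit", {
  p0 <- toy_params(gamma = 1e-12, kBT = 1e-300)
  tr <- propagate_until(phase_point(c(-1.1, 0.2), c(0.3, -0.1)),
                        list(), max_steps = 1e4, params = p0)
  E <- potential_energy(tr$frames[, c("x", "y")], p0) +
    0.5 * rowSums(tr$frames[, c("vx", "vy")]^2)
  expect_lt(max(E) - min(E), 1e-4 * p0$a)
})

test_that("a resting particle with zero force and temperature stays put", {
  p0 <- toy_params(kBT = 1e-300)
  pp <- phase_point(c(0, 0))  # force vanishes at the origin by symmetry
  out <- langevin_step(pp, p0)
  expect_equal(out$position, c(0, 0))
  expect_equal(out$time, p0$dt)
})

test_that("langevin steps are reproducible under a seed", {
  p <- toy_params()
  pp <- phase_point(c(-1, 0), c(0.1, 0.2))
  set.seed(7); a <- langevin_step(pp, p)
  set.seed(7); b <- langevin_step(pp, p)
  expect_identical(a, b)
  expect_true(all(is.finite(c(a$position, a$velocity))))
})

test_that("propagate_until honors stop states and step budgets", {
  p <- toy_params()
  st <- default_toy_states()
  tr <- propagate_until(phase_point(c(-1, 0)), st, max_steps = 1e4,
                        params = p)
  expect_equal(nrow(tr$frames), 1L)
  expect_equal(tr$stop_reason, "A")
  set.seed(3)
  tr2 <- propagate_until(phase_point(c(0, 0)), list(), max_steps = 1000,
                         params = p)
  expect_equal(tr2$stop_reason, "max")
  expect_equal(nrow(tr2$frames), 1000 / p$save_interval + 1)
  expect_equal(tr2$steps, 1000)
})

test_that("trajectories from the saddle commit symmetrically", {
  p <- toy_params()
  st <- default_toy_states()
  set.seed(4)
  hits <- replicate(200, {
    tr <- propagate_until(phase_point(c(0, 0)), st, max_steps = 1e5,
                          params = p)
    tr$stop_reason
  })
  frac_b <- mean(hits == "B")
  # binomial 99% CI around 1/2 for 200 replicas
  expect_gt(frac_b, 0.5 - 2.58 * sqrt(0.25 / 200))
  expect_lt(frac_b, 0.5 + 2.58 * sqrt(0.25 / 200))
})

test_that("the toy order map is symmetric and monotone in |y|", {
  map <- toy_order_map()
  ys <- seq(-2, 2, by = 0.1)
  fr <- cbind(time = 0, x = 0, y = ys, vx = 0, vy = 0)
  ops <- toy_order_values(fr, map)
  rev_ops <- toy_order_values(cbind(time = 0, x = 0, y = -ys, vx = 0,
                                    vy = 0), map)
  expect_equal(ops$hydration_like, rev_ops$hydration_like)
  expect_true(all(ops$hydration_like >= 0))
  ord <- order(abs(ys))
  expect_true(all(diff(ops$hydration_like[ord]) >= 0))
  expect_true(all(ops$opening_like <= 0))
})

test_that("brute-force rates are symmetric at the symmetric defaults", {
  bf <- shared_brute()
  se <- sqrt(bf$se_AB^2 + bf$se_BA^2)
  expect_lt(abs(bf$k_AB - bf$k_BA), 3 * se)
  expect_gt(bf$n_AB + bf$n_BA, 20)
})

test_that("raising the well scale lowers both rates", {
  bf <- shared_brute()
  set.seed(9011)
  bf_hi <- brute_force_rates(params = toy_params(a = 3), n_steps = 6e6)
  expect_lt(bf_hi$k_AB, bf$k_AB)
  expect_lt(bf_hi$k_BA, bf$k_BA)
})

test_that("rates satisfy detailed balance against quadrature populations", {
  p <- toy_params(tilt = 0.6)
  set.seed(9012)
  bf <- brute_force_rates(params = p, n_steps = 8e6)
  ratio <- bf$k_AB / bf$k_BA
  target <- oracle_basin_ratio(tilt = 0.6)  # pi_B / pi_A
  rel_se <- sqrt(1 / bf$n_AB + 1 / bf$n_BA)
  expect_lt(abs(log(ratio) - log(target)), 3 * rel_se)
  # the package quadrature agrees with the independent oracle
  eq <- equilibrium_populations(p)
  expect_equal(eq$p_B / eq$p_A, target, tolerance = 1e-3)
})

test_that("insufficient transition sampling is reported, not silently used", {
  p <- toy_params(a = 6, G = 8)
  set.seed(5)
  expect_error(brute_force_rates(params = p, n_steps = 2e5),
               "fewer than 5 transitions")
})

test_that("parameter validation rejects non-physical settings", {
  expect_error(toy_params(a = -1), "positive")
  expect_error(toy_params(dt = 0.5, gamma = 4), "dt \\* gamma")
  expect_error(toy_params(save_interval = 0), "save_interval")
  expect_error(phase_point(c(1, NA)), "finite")
})
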