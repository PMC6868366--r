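test_that("interface sets validate ordering and reporting position", {
  expect_error(interface_set(c(0.5, 0.4)), "strictly increasing")
  expect_error(interface_set(c(0, 0.5, 1), lambda_rep = 2), "lambda_rep")
  ifc <- default_toy_interfaces()
  expect_equal(ifc$lambdas[1], -0.8)
  expect_equal(ifc$lambda_rep, 0.8)
  expect_length(ifc$lambdas, 9L)
})

test_that("rate arithmetic reproduces the reported factor products", {
  k_fwd <- rate_from_components(5.5e8, 1.5e-5, 0.09)
  expect_equal(k_fwd, 742.5)           # prints as 742 at integer precision
  expect_lt(abs(k_fwd - 742), 0.5 + 1e-9)
  k_bwd <- rate_from_components(1.45e9, 1.2e-3, 0.94)
  expect_equal(signif(k_bwd, 2), 1.6e6)
  expect_equal(rate_from_components(0, 0.5, 0.5), 0)
  expect_equal(rate_from_components(5.5e8, 0, 0.09), 0)
  expect_error(rate_from_components(5.5e8, 1.5, 0.09), "0, 1")
  expect_error(rate_from_components(-1, 0.5, 0.5), "non-negative")
})

test_that("free energies from rate ratios match the reported values", {
  expect_lt(abs(free_energy_from_rates(742, 1.6e5) - 5.4), 0.05)
  # the experimental pair is reported as 5.5; ln(3670/14.2) = 5.555,
  # the last reported digit
  expect_lt(abs(free_energy_from_rates(14.2, 3670) - 5.5), 0.1)
  expect_equal(free_energy_from_rates(10, 10), 0)
  expect_equal(free_energy_from_rates(2, 6), -free_energy_from_rates(6, 2))
  expect_error(free_energy_from_rates(0, 1), "positive")
})

test_that("constructed flux series count one crossing per re-entry", {
  st <- default_toy_states()$A
  mk <- function(xs) cbind(time = (seq_along(xs) - 1) * 0.1, x = xs, y = 0,
                           vx = 0, vy = 0)
  # in A, cross, recross without re-entry (counted once), re-enter, cross
  xs <- c(-1.0, -0.9, -0.7, -0.79, -0.75, -0.9, -1.0, -0.6, -1.0)
  fl <- flux_from_state_run(mk(xs), st, -0.8)
  expect_equal(fl$n_crossings, 2L)
  expect_equal(fl$flux, 2 / (0.1 * 8))
  # exactly k crossings with re-entries between them
  xs2 <- c(-1, -0.5, -1, -0.5, -1, -0.5, -1)
  fl2 <- flux_from_state_run(mk(xs2), st, -0.8)
  expect_equal(fl2$n_crossings, 3L)
  expect_equal(fl2$flux, 3 / 0.6)
  expect_error(flux_from_state_run(mk(c(0, 0.5)), st, -0.8),
               "never visits")
})

test_that("single-ensemble WHAM equals the reverse-cumulative histogram", {
  breaks <- seq(-0.8, 0.2, by = 0.1)
  ens <- structure(list(i = 1L, lambda_i = -0.8,
                        max_lambda = c(-0.75, -0.75, -0.55, -0.35, 0.15),
                        ends_in_product = rep(FALSE, 5),
                        weights = c(4, 2, 2, 1, 1), n_paths = 5),
                   class = "tis_ensemble")
  h <- crossing_histogram(ens, breaks)
  prof <- wham_combine(list(h), interface_set(c(-0.8, 0.2)))
  expect_equal(prof$p_tot[1], 1)
  direct <- rev(cumsum(rev(c(h$counts, 0)))) / sum(h$counts)
  expect_equal(prof$p_tot, direct)
  expect_true(all(diff(prof$p_tot) <= 1e-12))
})

test_that("two-ensemble WHAM obeys the conditional product rule", {
  breaks <- seq(0, 1, by = 0.25)
  # ensemble 1 (lambda >= 0): half its paths cross lambda = 0.5 -> f1 = 0.5
  h1 <- structure(list(i = 1L, lambda_i = 0, breaks = breaks,
                       counts = c(40, 40, 60, 20), n_paths = 160),
                  class = "crossing_histogram")
  # ensemble 2 (lambda >= 0.5): a quarter cross lambda = 0.75 -> f2 = 0.25
  h2 <- structure(list(i = 2L, lambda_i = 0.5, breaks = breaks,
                       counts = c(0, 0, 90, 30), n_paths = 120),
                  class = "crossing_histogram")
  prof <- wham_combine(list(h1, h2), interface_set(c(0, 0.5, 1)))
  at <- function(l) prof$p_tot[match(l, prof$lambda)]
  expect_equal(at(0), 1)
  expect_equal(at(0.5), 0.5, tolerance = 1e-8)
  expect_equal(at(0.75), 0.5 * 0.25, tolerance = 1e-8)
  # invariance to rescaling one histogram's total count
  h2b <- h2
  h2b$counts <- h2$counts * 7
  h2b$n_paths <- h2$n_paths * 7
  prof2 <- wham_combine(list(h1, h2b), interface_set(c(0, 0.5, 1)))
  expect_equal(prof2$p_tot, prof$p_tot, tolerance = 1e-8)
})

test_that("non-overlapping ensembles are reported as a gap", {
  breaks <- seq(0, 1, by = 0.25)
  h1 <- structure(list(i = 1L, lambda_i = 0, breaks = breaks,
                       counts = c(100, 0, 0, 0), n_paths = 100),
                  class = "crossing_histogram")
  h2 <- structure(list(i = 2L, lambda_i = 0.5, breaks = breaks,
                       counts = c(0, 0, 50, 50), n_paths = 100),
                  class = "crossing_histogram")
  expect_error(wham_combine(list(h1, h2), interface_set(c(0, 0.5, 1))),
               "no overlap")
})

test_that("interface ensembles only contain paths beyond their interface", {
  eng <- toy_engine()
  st <- default_toy_states()
  ifc <- default_toy_interfaces()
  set.seed(201)
  init <- generate_initial_path(eng, st, init = phase_point(c(-1.4, 0)),
                                from = 1L)
  ens <- sample_interface_ensemble(3, ifc, eng, st, init, n_trials = 80)
  expect_true(all(ens$max_lambda >= ens$lambda_i))
  expect_equal(sum(ens$weights), 80)
})

test_that("an interface just outside the state is crossed almost surely", {
  eng <- toy_engine()
  st <- default_toy_states()
  ifc <- interface_set(c(-0.8, -0.795, 0.8))
  set.seed(202)
  init <- generate_initial_path(eng, st, init = phase_point(c(-1.4, 0)),
                                from = 1L)
  ens <- sample_interface_ensemble(1, ifc, eng, st, init, n_trials = 150)
  frac_at <- function(l) sum(ens$weights[ens$max_lambda >= l]) /
    sum(ens$weights)
  # one histogram-resolution step beyond the boundary: near-certain
  expect_gt(frac_at(-0.795), 0.9)
  # and the conditional crossing fraction decays with distance
  expect_gt(frac_at(-0.795), frac_at(-0.7))
  expect_gt(frac_at(-0.7), frac_at(-0.6))
})

test_that("crossing probabilities fall when the central barrier rises", {
  st <- default_toy_states()
  set.seed(203)
  lo <- run_tis(toy_engine(toy_params(G = 2)), st, n_trials = 120,
                flux_steps = 2e5, seed = 204)
  hi <- run_tis(toy_engine(toy_params(G = 5)), st, n_trials = 120,
                flux_steps = 2e5, seed = 204)
  expect_lt(profile_at(hi$profile, 0.4), profile_at(lo$profile, 0.4))
  expect_lt(hi$components$k, lo$components$k)
})

test_that("the co-location diagnostic detects a lingering intermediate", {
  # constructed profile: steep fall over [0, 0.5], plateau over [0.5, 1];
  # constructed paths linger (spread transversally) in the plateau region
  lam <- seq(0, 1, by = 0.05)
  p_tot <- ifelse(lam <= 0.5, exp(-10 * lam), exp(-5) * exp(-0.2 * (lam - 0.5)))
  prof <- structure(data.frame(lambda = lam, p_tot = p_tot),
                    class = c("crossing_profile", "data.frame"))
  eng <- toy_engine()
  mk <- function(seed) {
    set.seed(seed)
    xs <- c(seq(0.025, 0.475, by = 0.05),           # swift passage
            runif(40, 0.5, 1))                      # lingering, spread out
    sampled_path(cbind(time = seq_along(xs) * 0.05, x = xs,
                       y = runif(length(xs), -1, 1), vx = 0, vy = 0), eng)
  }
  paths <- lapply(1:20, mk)
  bx <- seq(0, 1, by = 0.1)
  dens <- path_density(paths, "lambda_like", "opening_like",
                       bx, seq(-70, 5, by = 5))
  col <- profile_density_colocation(prof, dens, bx)
  expect_gt(col$correlation, 0)
  # and the flat half really carries more mass than the steep half
  expect_gt(sum(col$mass[6:10]), sum(col$mass[1:5]))
})
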