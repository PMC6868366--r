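test_that("path density counts each path at most once per bin", {
  eng <- toy_engine()
  mk <- function(xs, ys, id = 1L)
    sampled_path(cbind(time = (seq_along(xs) - 1) * 0.05, x = xs, y = ys,
                       vx = 0, vy = 0), eng, id = id)
  bx <- seq(-1, 1, by = 0.5)
  by <- seq(-120, 0, by = 30)
  # one path visiting m distinct bins sums to m
  p1 <- mk(c(-0.9, -0.4, 0.1, 0.6), c(0, 0, 0, 0))
  d1 <- path_density(list(p1), "lambda_like", "opening_like", bx, by)
  expect_equal(sum(d1), 4)
  # re-entering the same bin five times still counts once
  p2 <- mk(rep(c(-0.9, -0.95), 5), rep(0, 10))
  d2 <- path_density(list(p2), "lambda_like", "opening_like", bx, by)
  expect_equal(sum(d2), 1)
  expect_equal(max(d2), 1)
  # n copies of one path raise every visited cell to n
  d3 <- path_density(rep(list(p1), 7), "lambda_like", "opening_like",
                     bx, by)
  expect_equal(max(d3), 7)
  expect_equal(sum(d3 > 0), 4)
  # empty ensemble gives an empty matrix with valid axes
  d0 <- path_density(list(), "lambda_like", "opening_like", bx, by)
  expect_equal(sum(d0), 0)
  expect_equal(dim(d0), c(length(bx) - 1L, length(by) - 1L))
})

test_that("angular bins wrap at the periodic boundary", {
  eng <- toy_engine()
  p <- fake_ops_path(opening = c(-179, 185), hydration = c(1, 1))
  brk <- seq(-180, 180, by = 10)
  d <- path_density(list(p), "lambda_like", "opening_like",
                    breaks_x = c(0, 10), breaks_y = brk, periodic_y = TRUE)
  # 185 wraps to -175: both frames fall into the (-180, -170] bin
  expect_equal(sum(d), 1)
  expect_equal(which(d[1, ] > 0), 1L)
})

test_that("channel features are exact frame extrema", {
  p <- fake_ops_path(opening = c(-10, -10, -10), hydration = c(3, 3, 3))
  expect_equal(channel_features(p)$theta_min, -10)
  p2 <- fake_ops_path(opening = c(-5, -60, -20), hydration = c(8, 25, 12))
  f2 <- channel_features(p2)
  expect_equal(f2$theta_min, -60)
  expect_equal(f2$n_water_max, 25)
  # invariance under frame order
  p3 <- fake_ops_path(opening = c(-20, -5, -60), hydration = c(12, 8, 25))
  expect_equal(channel_features(p3), f2)
})

test_that("the dividing line classifies with the DNA-study coefficients", {
  line <- channel_line(0.185, 32, 2)
  expect_equal(classify_channel(list(theta_min = -60, n_water_max = 40),
                                line), "outside")    # boundary 20.9
  expect_equal(classify_channel(list(theta_min = -22, n_water_max = 10),
                                line), "inside")     # boundary 27.93
  expect_equal(classify_channel(list(theta_min = -40, n_water_max = 25),
                                line), "neither")    # band [22.6, 26.6]
  expect_error(channel_line(margin = -1), "non-negative")
})

test_that("undecided labels inherit the previous accepted label", {
  expect_equal(propagate_labels(c("inside", "neither", "neither",
                                  "outside"), "inside"),
               c("inside", "inside", "inside", "outside"))
  expect_equal(propagate_labels(c("neither", "inside"), "outside"),
               c("outside", "inside"))
  x <- c("inside", "outside", "inside")
  expect_equal(propagate_labels(x, "inside"), x)
})

test_that("outside fractions track run labels", {
  expect_equal(outside_fraction_curve(rep(list(rep("outside", 5)), 3)),
               rep(1, 5))
  expect_equal(outside_fraction_curve(rep(list(rep("inside", 5)), 3)),
               rep(0, 5))
  runs <- c(rep(list(c(rep("inside", 3), rep("outside", 497))), 7),
            rep(list(rep("inside", 500)), 3))
  curve <- outside_fraction_curve(runs)
  expect_equal(curve[500], 0.7)
  expect_warning(outside_fraction_curve(list(rep("inside", 3),
                                             rep("inside", 5))),
                 "truncated")
})

test_that("relaxation-time fits recover generating time constants", {
  for (tau in c(350, 50)) {
    t <- 1:1000
    curve <- 1 - exp(-t / tau)
    fit <- fit_relaxation_tau(curve)
    expect_equal(fit$tau, tau, tolerance = 1e-3)
    expect_lt(fit$residual, 1e-6)
  }
  expect_error(fit_relaxation_tau(rep(1, 100)), "constant")
  expect_error(fit_relaxation_tau(c(0.5, 1.2)), "0, 1")
})

test_that("the Bayesian posterior reproduces the reported value", {
  c0 <- switch_counts(7, 10, 0, 10)
  p <- bayes_channel_preference(c0)
  expect_equal(p, 0.99948, tolerance = 1e-5)
  # exact complement identity
  swapped <- switch_counts(0, 10, 7, 10)
  expect_equal(p + bayes_channel_preference(swapped), 1, tolerance = 1e-12)
  # symmetric evidence is uninformative
  expect_equal(bayes_channel_preference(switch_counts(0, 10, 0, 10)), 0.5,
               tolerance = 1e-12)
  expect_error(bayes_channel_preference(switch_counts(0, 0, 0, 5)),
               "zero observations")
})

test_that("the Beta comparison matches Monte Carlo for arbitrary counts", {
  set.seed(13)
  for (i in 1:4) {
    s1 <- sample(0:12, 1); n1 <- s1 + sample(1:10, 1)
    s2 <- sample(0:12, 1); n2 <- s2 + sample(1:10, 1)
    p <- bayes_channel_preference(switch_counts(s1, n1, s2, n2))
    nmc <- 1e6
    x <- rbeta(nmc, s1 + 1, n1 - s1 + 1)
    y <- rbeta(nmc, s2 + 1, n2 - s2 + 1)
    phat <- mean(x > y)
    se <- sqrt(max(phat * (1 - phat), 1e-12) / nmc)
    expect_lt(abs(p - phat), 3 * se + 1e-7)
  }
})

test_that("posterior odds behave as p/(1-p)", {
  expect_equal(posterior_odds(0.5), 1)
  expect_gt(posterior_odds(0.999484), 1900)
  expect_lt(posterior_odds(0.999484), 2100)
  set.seed(14)
  for (p in runif(5, 0.01, 0.99))
    expect_equal(posterior_odds(p) * posterior_odds(1 - p), 1)
  expect_error(posterior_odds(1), "strictly between")
  expect_error(posterior_odds(0), "strictly between")
})

test_that("switching probability estimates recover the generator", {
  set.seed(15)
  runs <- simulate_label_runs(10, 500, p_switch = 1 / 350)
  est <- estimate_switch_probability(runs)
  expect_lt(abs(est$p_count - 1 / 350) / (1 / 350), 0.3)
  # all runs switching immediately give a count estimate near one
  fast <- lapply(1:5, function(i) c("inside", rep("outside", 9)))
  expect_equal(estimate_switch_probability(fast)$p_count, 1)
  # no switches: bounded, no point estimate
  none <- rep(list(rep("inside", 200)), 5)
  est0 <- estimate_switch_probability(none)
  expect_true(is.na(est0$p_count))
  expect_equal(est0$upper_bound, 3 / est0$n_inside_trials)
})

test_that("one-directional switching gives monotone outside fractions", {
  set.seed(16)
  runs <- simulate_label_runs(20, 300, p_switch = 0.01, p_back = 0)
  curve <- outside_fraction_curve(runs)
  expect_true(all(curve >= 0 & curve <= 1))
  expect_true(all(diff(curve) >= 0))
})

test_that("classifier outside fraction matches brute-force reactive paths", {
  eng <- toy_engine()
  line <- toy_channel_line()
  segs <- shared_segments()
  seg_lab <- vapply(segs, function(s)
    classify_channel(channel_features(sampled_path(s, eng)), line),
    character(1))
  frac_ref <- mean(seg_lab == "outside")
  labs <- ensemble_channel_labels(shared_tps(), line)
  frac_tps <- mean(labs == "outside")
  expect_lt(abs(frac_tps - frac_ref), 0.1)
})
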