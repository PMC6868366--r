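# Independent oracles and shared fixtures for the test suite.
# The potential is re-implemented here in plain R so that tests of the
# compiled surface compare against an independent formula.

oracle_V <- function(x, y, a = 2, b = 1, G = 3, sigma = 0.5, tilt = 0) {
  a * (x^2 - 1)^2 + b * y^4 +
    G * exp(-(x^2 + y^2) / (2 * sigma^2)) - tilt * x
}

# central finite-difference gradient of the oracle potential
oracle_grad <- function(x, y, h = 1e-6, ...) {
  c((oracle_V(x + h, y, ...) - oracle_V(x - h, y, ...)) / (2 * h),
    (oracle_V(x, y + h, ...) - oracle_V(x, y - h, ...)) / (2 * h))
}

# Boltzmann bin probabilities of the x marginal by 2-D quadrature
oracle_x_bin_probs <- function(breaks, kBT = 1, ...) {
  ygrid <- seq(-3, 3, length.out = 601)
  marg <- function(xs) vapply(xs, function(xx)
    sum(exp(-oracle_V(xx, ygrid, ...) / kBT)), numeric(1))
  p <- vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- max(breaks[i], -4)
    hi <- min(breaks[i + 1], 4)
    xs <- seq(lo, hi, length.out = 161)
    sum(marg(xs)) * (xs[2] - xs[1])
  }, numeric(1))
  p / sum(p)
}

# equilibrium basin populations of the oracle potential (half-planes)
oracle_basin_ratio <- function(kBT = 1, ...) {
  g <- expand.grid(x = seq(-3, 3, length.out = 401),
                   y = seq(-3, 3, length.out = 401))
  w <- exp(-oracle_V(g$x, g$y, ...) / kBT)
  sum(w[g$x > 0]) / sum(w[g$x < 0])
}

# hand-built straight-line connecting path between the default toy states
# (first frame in A, last in B, interior outside both); n_interior >= 1
synthetic_connecting_path <- function(n_interior, engine = toy_engine(),
                                      id = 0L, y = 0) {
  xs <- c(-0.85, seq(-0.75, 0.75, length.out = n_interior), 0.85)
  frames <- cbind(time = (seq_along(xs) - 1) * 0.05, x = xs, y = y,
                  vx = 1, vy = 0)
  sampled_path(frames, engine, id = id)
}

# fake path carrying explicit order-parameter sequences (for analysis ops)
fake_ops_path <- function(opening, hydration) {
  structure(list(frames = NULL,
                 ops = data.frame(lambda_like = seq_along(opening),
                                  opening_like = opening,
                                  hydration_like = hydration),
                 id = 0L, parent_id = NA_integer_,
                 shoot_index = NA_integer_, direction = NA_character_),
            class = "sampled_path")
}

# cache for expensive shared objects (built once per test session)
.shared <- new.env(parent = emptyenv())

shared_brute <- function() {
  if (is.null(.shared$brute)) {
    set.seed(9001)
    .shared$brute <- brute_force_rates(n_steps = 1e7)
  }
  .shared$brute
}

shared_segments <- function() {
  if (is.null(.shared$segments)) {
    .shared$segments <- harvest_reactive_segments(n_steps = 1e7,
                                                  seed = 9002)
  }
  .shared$segments
}

shared_tis <- function(direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  key <- paste0("tis_", direction)
  if (is.null(.shared[[key]])) {
    eng <- toy_engine()
    st <- default_toy_states()
    .shared[[key]] <- if (direction == "forward")
      run_tis(eng, st, n_trials = 2500, flux_steps = 1e6, seed = 9005)
    else
      run_tis(eng, rev(st), n_trials = 2500, flux_steps = 1e6,
              lambda_sign = -1, seed = 9006)
  }
  .shared[[key]]
}

shared_tps <- function() {
  if (is.null(.shared$tps)) {
    eng <- toy_engine()
    st <- default_toy_states()
    set.seed(9003)
    init <- generate_initial_path(eng, st)
    .shared$tps <- run_tps(init, 1500, eng, st, seed = 9004)
  }
  .shared$tps
}
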