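#' Parameters of the two-channel Langevin model
#'
#' The model is a single particle of mass `mass` moving on the
#' two-dimensional surface
#' \deqn{V(x,y) = a (x^2-1)^2 + b y^4 + G e^{-(x^2+y^2)/(2\sigma^2)} - t x}
#' under underdamped Langevin dynamics at temperature `kBT`. The quartic
#' double well along `x` provides two metastable basins near (-1, 0) and
#' (+1, 0), the analogues of the Watson-Crick and Hoogsteen states. The
#' central Gaussian of height `G` blocks the direct route over the origin
#' (the "inside" channel, barrier about `a + G`), so most reactive flux
#' detours through finite `|y|` (the "outside" channel, barrier about
#' 3.2 kBT at the defaults, saddle near `|y| = 0.85`).
#'
#' @param a Quartic well scale (kBT units). Default 2.
#' @param b Transverse stiffness (kBT units). Default 1.
#' @param G Central barrier height (kBT units). Default 3.
#' @param sigma Central barrier width (length units). Default 0.5.
#' @param kBT Thermal energy. Default 1.
#' @param gamma Friction coefficient (1/time). Default 2.5.
#' @param dt Integration timestep (time). Default 0.01.
#' @param mass Particle mass. Default 1.
#' @param save_interval Integration steps per saved frame. Default 5.
#' @param tilt Linear bias `-tilt * x` breaking the x -> -x symmetry;
#'   default 0 (symmetric surface). Used to validate detailed balance on an
#'   asymmetric surface.
#' @return An object of class `toy_params`.
#' @export
toy_params <- function(a = 2, b = 1, G = 3, sigma = 0.5, kBT = 1,
                       gamma = 2.5, dt = 0.01, mass = 1, save_interval = 5,
                       tilt = 0) {
  p <- list(a = a, b = b, G = G, sigma = sigma, kBT = kBT, gamma = gamma,
            dt = dt, mass = mass, save_interval = as.integer(save_interval),
            tilt = tilt)
  for (nm in c("a", "b", "G", "sigma", "kBT", "gamma", "dt", "mass")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("toy_params: '", nm, "' must be a single positive number")
  }
  if (p$dt * p$gamma >= 1)
    stop("toy_params: dt * gamma must be < 1 for a sensible discretization")
  if (p$save_interval < 1L)
    stop("toy_params: save_interval must be >= 1")
  class(p) <- "toy_params"
  p
}

#' @export
print.toy_params <- function(x, ...) {
  cat("Two-channel Langevin model parameters\n")
  cat(sprintf("  V(x,y) = %g (x^2-1)^2 + %g y^4 + %g exp(-(x^2+y^2)/(2 %g^2))",
              x$a, x$b, x$G, x$sigma))
  if (x$tilt != 0) cat(sprintf(" - %g x", x$tilt))
  cat("\n")
  cat(sprintf("  kBT = %g, gamma = %g, dt = %g, mass = %g, save_interval = %d\n",
              x$kBT, x$gamma, x$dt, x$mass, x$save_interval))
  invisible(x)
}

#' Phase-space point of the toy model
#'
#' @param position Numeric (x, y) in reduced length units.
#' @param velocity Numeric (vx, vy); default zero.
#' @param time Reduced time stamp; default 0.
#' @return An object of class `phase_point`.
#' @export
phase_point <- function(position, velocity = c(0, 0), time = 0) {
  stopifnot(length(position) == 2L, length(velocity) == 2L,
            length(time) == 1L)
  if (!all(is.finite(c(position, velocity, time))))
    stop("phase_point: components must be finite")
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 time = as.numeric(time)),
            class = "phase_point")
}

#' Potential energy of the toy surface
#'
#' @param p Numeric (x, y), or a two-column matrix of positions.
#' @param params A [toy_params()] object.
#' @return Potential energy (kBT units), one value per position.
#' @export
potential_energy <- function(p, params = toy_params()) {
  p <- as_xy_matrix(p)
  cpp_potential(p[, 1], p[, 2], params$a, params$b, params$G, params$sigma,
                params$tilt)
}

#' Force on the toy surface (minus the potential gradient)
#'
#' @inheritParams potential_energy
#' @return A two-column matrix of (fx, fy), one row per position.
#' @export
force_field <- function(p, params = toy_params()) {
  p <- as_xy_matrix(p)
  f <- cpp_force(p[, 1], p[, 2], params$a, params$b, params$G, params$sigma,
                 params$tilt)
  colnames(f) <- c("fx", "fy")
  f
}

as_xy_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    return(p)
  }
  stopifnot(length(p) == 2L)
  matrix(as.numeric(p), nrow = 1L)
}

#' One Langevin integration step
#'
#' Advances a phase point by a single BAOAB step (velocity-Verlet kicks and
#' drifts around an exact Ornstein-Uhlenbeck velocity refresh). The update is
#' deterministic given the R random-number state, so `set.seed()` before the
#' call reproduces it exactly. At `gamma -> 0`, `kBT -> 0` the step reduces
#' to symplectic velocity Verlet.
#'
#' @param p A [phase_point()].
#' @param params A [toy_params()] object.
#' @return The updated `phase_point`, with `time` advanced by `dt`.
#' @export
langevin_step <- function(p, params = toy_params()) {
  stopifnot(inherits(p, "phase_point"))
  res <- cpp_propagate(c(p$position, p$velocity), p$time,
                       params$a, params$b, params$G, params$sigma,
                       params$tilt, params$kBT, params$gamma, params$dt,
                       params$mass, max_steps = 1L, save_interval = 1L,
                       stops = matrix(numeric(0), 0, 4))
  fr <- res$frames
  n <- nrow(fr)
  phase_point(fr[n, 2:3], fr[n, 4:5], fr[n, 1])
}

#' Propagate the toy model until a stop state is reached
#'
#' Integrates Langevin dynamics from `p`, recording a frame every
#' `params$save_interval` steps, until the first recorded frame lies inside
#' one of the `stop` states or `max_steps` integration steps have been
#' taken. Stop-state membership is checked on the saved-frame grid, so all
#' package measurements (brute force, TPS, TIS) see the same Markov chain of
#' frames. The starting configuration counts as the first frame and is
#' checked before any step is taken.
#'
#' @param p A [phase_point()] starting condition.
#' @param stop A list of [state_definition()] objects (possibly empty).
#' @param max_steps Maximum number of integration steps (>= 1).
#' @param params A [toy_params()] object.
#' @return A `toy_traj` object: list with `frames` (matrix with columns
#'   time, x, y, vx, vy), `stop_reason` (`"max"` or the name of the state
#'   that terminated the run), and `steps` taken.
#' @export
propagate_until <- function(p, stop = list(), max_steps, params = toy_params()) {
  stopifnot(inherits(p, "phase_point"), max_steps >= 1)
  boxes <- states_to_boxes(stop)
  res <- cpp_propagate(c(p$position, p$velocity), p$time,
                       params$a, params$b, params$G, params$sigma,
                       params$tilt, params$kBT, params$gamma, params$dt,
                       params$mass, max_steps = as.integer(max_steps),
                       save_interval = params$save_interval, stops = boxes)
  frames <- res$frames
  colnames(frames) <- c("time", "x", "y", "vx", "vy")
  reason <- if (res$stop == 0L) "max" else
    unname(vapply(stop, `[[`, "", "name"))[res$stop]
  structure(list(frames = frames, stop_reason = reason, steps = res$steps),
            class = "toy_traj")
}

#' Map toy coordinates to DNA-like order parameters
#'
#' Defines the correspondence between the toy model's coordinates and the
#' order parameters of the base-flipping problem: `lambda_like` is `x`
#' (progress coordinate), `opening_like = -theta_scale * |y|` is a signed
#' opening-angle proxy in degrees (0 inside the duplex, strongly negative in
#' the solvent-exposed channel), and `hydration_like = round(w0 + w1 |y|)`
#' is a non-negative integer hydration-shell count (about `w0` in the
#' inside channel, `w0 + w1` in the outside channel, echoing hydration
#' numbers of roughly 8 vs 20-25 for buried vs exposed bases).
#'
#' @param w0,w1 Hydration-count calibration constants (defaults 8 and 15).
#' @param theta_scale Degrees of opening per unit `|y|` (default 60).
#' @return An object of class `toy_order_map`.
#' @export
toy_order_map <- function(w0 = 8, w1 = 15, theta_scale = 60) {
  stopifnot(w0 >= 0, w1 >= 0, theta_scale > 0)
  structure(list(w0 = w0, w1 = w1, theta_scale = theta_scale),
            class = "toy_order_map")
}

#' Evaluate the toy order map on trajectory frames
#'
#' @param frames A frame matrix with columns including `x` and `y` (as
#'   produced by [propagate_until()]), or a `toy_traj`.
#' @param map A [toy_order_map()].
#' @return A data frame with columns `lambda_like`, `opening_like`,
#'   `hydration_like` (integer).
#' @export
toy_order_values <- function(frames, map = toy_order_map()) {
  if (inherits(frames, "toy_traj")) frames <- frames$frames
  x <- frames[, "x"]
  ay <- abs(frames[, "y"])
  data.frame(lambda_like = x,
             opening_like = -map$theta_scale * ay,
             hydration_like = as.integer(round(map$w0 + map$w1 * ay)))
}

#' Default metastable-state definitions of the toy model
#'
#' Core sets mirroring tight order-parameter windows around the two
#' base-pairing geometries: A = \{x < -0.8, |y| < 0.35\} and
#' B = \{x > 0.8, |y| < 0.35\}.
#'
#' @return A named list of two [state_definition()] objects, `A` and `B`.
#' @export
default_toy_states <- function() {
  list(A = state_definition("A", min = c(x = -Inf, y = -0.35),
                            max = c(x = -0.8, y = 0.35)),
       B = state_definition("B", min = c(x = 0.8, y = -0.35),
                            max = c(x = Inf, y = 0.35)))
}

#' Brute-force rate constants by long direct simulation
#'
#' Runs a long equilibrium Langevin trajectory and counts core-set
#' (state-to-state) transitions: every frame is labeled by the last core set
#' visited, a transition A to B is an A-labeled to B-labeled change, and the
#' rate is the transition count divided by the total time carrying the
#' source label. This is the oracle against which TIS rates are validated;
#' the corresponding direct computation is far out of reach for the all-atom
#' DNA problem.
#'
#' @param params A [toy_params()] object.
#' @param states Named list of two [state_definition()]s (default
#'   [default_toy_states()]).
#' @param n_steps Total integration steps (default 2e7).
#' @param init Starting [phase_point()]; default rests in the first state's
#'   basin at (-1, 0).
#' @param seed Optional integer seed recorded in the output; if `NULL` the
#'   current RNG state is used.
#' @param chunk_steps Steps per internal propagation chunk (memory bound).
#' @return A list with `k_AB`, `k_BA`, their standard errors `se_AB`,
#'   `se_BA` (Poisson counting), transition counts `n_AB`, `n_BA`, label
#'   times `time_A`, `time_B`, `n_steps` and `seed`.
#' @export
brute_force_rates <- function(params = toy_params(),
                              states = default_toy_states(),
                              n_steps = 2e7,
                              init = phase_point(c(-1, 0)),
                              seed = NULL,
                              chunk_steps = 2e6) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(states) == 2L)
  cnt <- label_transition_counts(params, states, n_steps, init, chunk_steps)
  if (cnt$n_AB + cnt$n_BA < 5)
    stop("brute_force_rates: fewer than 5 transitions observed; ",
         "increase n_steps or lower the barriers")
  k_AB <- cnt$n_AB / cnt$time_A
  k_BA <- cnt$n_BA / cnt$time_B
  list(k_AB = k_AB, k_BA = k_BA,
       se_AB = k_AB / sqrt(max(cnt$n_AB, 1)),
       se_BA = k_BA / sqrt(max(cnt$n_BA, 1)),
       n_AB = cnt$n_AB, n_BA = cnt$n_BA,
       time_A = cnt$time_A, time_B = cnt$time_B,
       n_steps = n_steps, seed = seed)
}

label_transition_counts <- function(params, states, n_steps, init,
                                    chunk_steps) {
  done <- 0
  state <- init
  lab_carry <- NA_integer_
  n_AB <- 0L; n_BA <- 0L; t_A <- 0; t_B <- 0
  dtf <- params$dt * params$save_interval
  while (done < n_steps) {
    todo <- min(chunk_steps, n_steps - done)
    tr <- propagate_until(state, stop = list(), max_steps = todo,
                          params = params)
    fr <- tr$frames
    lab <- frame_state_labels(fr, states, carry = lab_carry)
    # drop the first frame of continuation chunks (it repeats the carry frame)
    use <- if (done > 0) -1L else TRUE
    l <- lab[use]
    ch <- which(diff(l) != 0 & !is.na(diff(l)))
    if (length(ch)) {
      n_AB <- n_AB + sum(l[ch] == 1L & l[ch + 1L] == 2L)
      n_BA <- n_BA + sum(l[ch] == 2L & l[ch + 1L] == 1L)
    }
    t_A <- t_A + sum(l == 1L, na.rm = TRUE) * dtf
    t_B <- t_B + sum(l == 2L, na.rm = TRUE) * dtf
    n <- nrow(fr)
    state <- phase_point(fr[n, 2:3], fr[n, 4:5], fr[n, 1])
    lab_carry <- lab[length(lab)]
    done <- done + tr$steps
  }
  list(n_AB = n_AB, n_BA = n_BA, time_A = t_A, time_B = t_B)
}

#' Label frames by the last core set visited
#'
#' @param frames Frame matrix with `x`, `y` columns.
#' @param states Named list of [state_definition()]s.
#' @param carry Label (index into `states`) carried in from an earlier
#'   segment, or `NA`.
#' @return Integer vector: index of the last state visited at each frame
#'   (`NA` before any state has been entered).
#' @export
frame_state_labels <- function(frames, states, carry = NA_integer_) {
  if (inherits(frames, "toy_traj")) frames <- frames$frames
  id <- rep(NA_integer_, nrow(frames))
  for (i in seq_along(states)) {
    id[in_state_frames(frames, states[[i]])] <- i
  }
  if (!is.na(carry) && is.na(id[1])) id[1] <- as.integer(carry)
  as.integer(zoo::na.locf(id, na.rm = FALSE))
}

#' Harvest reactive segments from a long direct run
#'
#' Runs long equilibrium dynamics and extracts the transition (reactive)
#' segments: the frames from the last visit of one core set to the first
#' entry of the other. These segments are distributed as the true
#' transition-path ensemble and serve as the reference against which the
#' TPS ensemble is validated.
#'
#' @inheritParams brute_force_rates
#' @return List of frame matrices, one per transition (either direction),
#'   each starting with its last in-state frame and ending with its first
#'   frame in the other state.
#' @export
harvest_reactive_segments <- function(params = toy_params(),
                                      states = default_toy_states(),
                                      n_steps = 1e7,
                                      init = phase_point(c(-1, 0)),
                                      seed = NULL,
                                      chunk_steps = 2e6) {
  if (!is.null(seed)) set.seed(seed)
  segs <- list()
  done <- 0
  state <- init
  pend <- NULL       # frames since the last in-core frame (open excursion)
  pend_lab <- NA_integer_
  while (done < n_steps) {
    todo <- min(chunk_steps, n_steps - done)
    tr <- propagate_until(state, stop = list(), max_steps = todo,
                          params = params)
    fr <- tr$frames
    if (done > 0) fr <- fr[-1, , drop = FALSE]
    in1 <- in_state_frames(fr, states[[1]])
    in2 <- in_state_frames(fr, states[[2]])
    ci <- which(in1 | in2)
    li <- ifelse(in1[ci], 1L, 2L)
    if (length(ci)) {
      if (!is.na(pend_lab) && li[1] != pend_lab)
        segs[[length(segs) + 1L]] <-
          rbind(pend, fr[1:ci[1], , drop = FALSE])
      for (p in which(diff(li) != 0L))
        segs[[length(segs) + 1L]] <-
          fr[ci[p]:ci[p + 1L], , drop = FALSE]
      pend <- fr[ci[length(ci)]:nrow(fr), , drop = FALSE]
      pend_lab <- li[length(li)]
    } else if (!is.na(pend_lab)) {
      pend <- rbind(pend, fr)
    }
    n <- nrow(tr$frames)
    state <- phase_point(tr$frames[n, 2:3], tr$frames[n, 4:5],
                         tr$frames[n, 1])
    done <- done + tr$steps
  }
  segs
}

#' Equilibrium basin populations by quadrature
#'
#' Integrates the Boltzmann factor `exp(-V/kBT)` on a fine grid over the
#' half-planes x < 0 and x > 0, giving the equilibrium populations of the
#' two basins independently of any dynamics. Used to validate detailed
#' balance of the sampled rates and to define the reference free-energy
#' difference `dG = -log(p_B / p_A)` in kBT.
#'
#' @param params A [toy_params()] object.
#' @param xlim,ylim Integration box (defaults generously cover the wells).
#' @param n Grid points per axis (default 601).
#' @return List with `p_A`, `p_B` (normalized populations) and `dG`.
#' @export
equilibrium_populations <- function(params = toy_params(),
                                    xlim = c(-3, 3), ylim = c(-3, 3),
                                    n = 601) {
  x <- seq(xlim[1], xlim[2], length.out = n)
  y <- seq(ylim[1], ylim[2], length.out = n)
  g <- expand.grid(x = x, y = y)
  w <- exp(-cpp_potential(g$x, g$y, params$a, params$b, params$G,
                          params$sigma, params$tilt) / params$kBT)
  zA <- sum(w[g$x < 0]); zB <- sum(w[g$x > 0])
  p_A <- zA / (zA + zB); p_B <- zB / (zA + zB)
  list(p_A = p_A, p_B = p_B, dG = -log(p_B / p_A))
}

#' Height of the outside saddle of the toy surface
#'
#' Minimizes `V(0, y)` over `y > 0` numerically; at the defaults this is
#' about 3.23 kBT, strictly below the inside barrier `a + G`.
#'
#' @param params A [toy_params()] object.
#' @return List with `height` and the minimizing `y`.
#' @export
outside_saddle <- function(params = toy_params()) {
  f <- function(y) as.numeric(potential_energy(cbind(0, y), params))
  o <- optimize(f, c(1e-6, 5))
  list(height = o$objective, y = o$minimum)
}
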