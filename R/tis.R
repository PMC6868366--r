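#' Ordered interface set along the progress coordinate
#'
#' @param lambdas Strictly increasing interface positions; the first value
#'   is the initial-state boundary `lambda_0`.
#' @param lambda_rep Reporting interface at which the total crossing
#'   probability is read off (default: the outermost interface).
#' @return An object of class `interface_set`.
#' @export
interface_set <- function(lambdas, lambda_rep = max(lambdas)) {
  stopifnot(length(lambdas) >= 2L)
  if (any(diff(lambdas) <= 0))
    stop("interface_set: lambdas must be strictly increasing")
  if (lambda_rep < lambdas[1] || lambda_rep > lambdas[length(lambdas)])
    stop("interface_set: lambda_rep must lie within [lambda_0, lambda_n]")
  structure(list(lambdas = lambdas, lambda_rep = lambda_rep),
            class = "interface_set")
}

#' Default interface set of the toy model
#'
#' Eight equally spaced interfaces between the state boundaries at
#' x = -0.8 and x = +0.8, plus the initial boundary itself.
#'
#' @param from,to State boundaries on the progress coordinate.
#' @param n Number of interfaces beyond the initial boundary (default 8).
#' @return An [interface_set()].
#' @export
default_toy_interfaces <- function(from = -0.8, to = 0.8, n = 8) {
  interface_set(seq(from, to, length.out = n + 1L))
}

# progress-coordinate values of a frame matrix (sign = -1 samples the
# reverse transition on the mirrored coordinate)
lambda_values <- function(frames, lambda_sign = 1) {
  lambda_sign * frames[, "x"]
}

# TIS path validity for ensemble at lambda_i: starts in the initial state,
# ends in a state, visits no state in between, and reaches lambda_i
tis_valid_frames <- function(frames, states, initial_state_idx, lambda_i,
                             lambda_sign = 1) {
  cc <- frames_connect(frames, states)
  cc$from == initial_state_idx && cc$to != 0L && cc$interior_ok &&
    max(lambda_values(frames, lambda_sign)) >= lambda_i
}

#' Sample one TIS interface ensemble
#'
#' One-way-shooting Monte Carlo over paths that start in the initial
#' state, cross the interface `lambda_i`, and end in either state. The
#' maximum progress-coordinate value of the current path is recorded at
#' every trial (rejected trials re-count the previous path), giving the
#' crossing histogram of the ensemble; for the outermost ensemble the
#' recorded fraction of paths committing to the product state estimates
#' the commitment probability.
#'
#' @param i Ensemble index (1-based into `interfaces$lambdas`): the
#'   ensemble of paths crossing `lambda_i = interfaces$lambdas[i]`. The
#'   innermost ensemble (i = 1) is conditioned on crossing the state
#'   boundary `lambda_0` itself; rates use ensembles 1 to n - 1.
#' @param interfaces An [interface_set()].
#' @param engine A [toy_engine()].
#' @param states Named list of two [state_definition()]s; the first is the
#'   initial state.
#' @param initial A valid `sampled_path` crossing `lambda_i` (a full
#'   connecting path works for every ensemble).
#' @param n_trials Shooting trials recorded after burn-in.
#' @param burn_in Equilibration trials discarded before recording (default
#'   `n_trials %/% 4`); needed because every ensemble is seeded from one
#'   full connecting path, which is an atypically far-crossing member of
#'   the inner ensembles.
#' @param max_length_factor Trial-length cap as a multiple of the initial
#'   path length.
#' @param lambda_sign +1 to sample along `x`, -1 for the mirrored reverse
#'   transition.
#' @return A `tis_ensemble`: `max_lambda` and `ends_in_product` per stored
#'   path, `weights`, `acceptance_ratio`, `lambda_i`, `n_paths`.
#' @export
sample_interface_ensemble <- function(i, interfaces, engine, states,
                                      initial, n_trials,
                                      burn_in = n_trials %/% 4,
                                      max_length_factor = 50,
                                      lambda_sign = 1) {
  lambda_i <- interfaces$lambdas[i]
  valid <- function(frames, states_)
    tis_valid_frames(frames, states_, 1L, lambda_i, lambda_sign)
  if (!valid(initial$frames, states))
    stop("sample_interface_ensemble: initial path is not a valid member ",
         "of the ensemble at lambda = ", lambda_i)
  max_length <- max_length_factor * path_length(initial)
  cur <- initial
  path_max <- function(p) max(lambda_values(p$frames, lambda_sign))
  path_in_b <- function(p) frames_connect(p$frames, states)$to == 2L
  max_lambda <- numeric(0)
  ends_in_product <- logical(0)
  weights <- numeric(0)
  n_acc <- 0L
  for (t in seq_len(burn_in + n_trials)) {
    shot <- one_way_shot(cur, engine, states, max_length, trial_id = t)
    accepted <- FALSE
    if (shot$record$completed)
      accepted <- accept_trial(cur, shot$trial, states, valid_fun = valid)
    if (accepted) cur <- shot$trial
    if (t <= burn_in) next
    if (accepted) n_acc <- n_acc + 1L
    if (accepted || length(weights) == 0L) {
      max_lambda <- c(max_lambda, path_max(cur))
      ends_in_product <- c(ends_in_product, path_in_b(cur))
      weights <- c(weights, 1)
    } else {
      weights[length(weights)] <- weights[length(weights)] + 1
    }
  }
  if (length(weights) == 0L) {
    max_lambda <- path_max(cur)
    ends_in_product <- path_in_b(cur)
    weights <- 1
  }
  structure(list(i = i, lambda_i = lambda_i, max_lambda = max_lambda,
                 ends_in_product = ends_in_product, weights = weights,
                 acceptance_ratio = if (n_trials > 0) n_acc / n_trials
                 else NA_real_,
                 n_paths = length(max_lambda), n_trials = n_trials),
            class = "tis_ensemble")
}

#' Crossing histogram of an interface ensemble
#'
#' Weighted histogram of the maximum progress-coordinate value per path on
#' a shared grid.
#'
#' @param ensemble A `tis_ensemble`.
#' @param breaks Grid break points (strictly increasing, covering all
#'   observed maxima).
#' @return A `crossing_histogram`: `i`, `lambda_i`, `breaks`, `counts`
#'   (length `length(breaks) - 1`), `n_paths` (total weight).
#' @export
crossing_histogram <- function(ensemble, breaks) {
  if (any(ensemble$max_lambda < ensemble$lambda_i - 1e-12))
    stop("crossing_histogram: ensemble contains a path below its interface")
  bin <- findInterval(ensemble$max_lambda, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  if (any(bin == 0L | bin >= length(breaks)))
    stop("crossing_histogram: breaks do not cover the observed maxima")
  counts <- numeric(length(breaks) - 1L)
  for (k in seq_along(bin))
    counts[bin[k]] <- counts[bin[k]] + ensemble$weights[k]
  structure(list(i = ensemble$i, lambda_i = ensemble$lambda_i,
                 breaks = breaks, counts = counts,
                 n_paths = sum(ensemble$weights)),
            class = "crossing_histogram")
}

#' Combine crossing histograms into the total crossing probability (WHAM)
#'
#' Maximum-likelihood combination of the per-interface histograms of
#' maximum progress-coordinate values into one normalized reverse-cumulative
#' crossing probability `p_tot(lambda | lambda_0)`. Each ensemble `i` is
#' treated as sampling the (unknown) unbiased distribution of maxima
#' restricted to `lambda >= lambda_i`; the self-consistent weights
#' `w_b = M_b / sum_i N_i 1(lambda_b >= lambda_i) / Z_i`, with
#' `Z_i = sum_{b >= i} w_b`, are iterated from a uniform start to relative
#' tolerance 1e-10. The result starts at 1 at `lambda_0`, is
#' non-increasing, and is invariant to rescaling any single histogram's
#' total count.
#'
#' @param histograms List of `crossing_histogram`s on a shared `breaks`
#'   grid (one per interface, inner to outer).
#' @param interfaces The [interface_set()] they belong to.
#' @param tol Relative convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A `crossing_profile`: data frame with columns `lambda` (the
#'   break points) and `p_tot`.
#' @export
wham_combine <- function(histograms, interfaces, tol = 1e-10,
                         max_iter = 10000) {
  stopifnot(length(histograms) >= 1L)
  breaks <- histograms[[1]]$breaks
  for (h in histograms)
    if (!isTRUE(all.equal(h$breaks, breaks)))
      stop("wham_combine: histograms must share one grid")
  B <- length(breaks) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nI <- length(histograms)
  counts <- do.call(rbind, lapply(histograms, `[[`, "counts"))
  Ni <- rowSums(counts)
  # support of ensemble i: bins fully above its interface
  support <- do.call(rbind, lapply(histograms, function(h)
    breaks[-length(breaks)] >= h$lambda_i - 1e-12))
  # adjacent ensembles must overlap
  if (nI > 1L) {
    for (i in seq_len(nI - 1L)) {
      above <- counts[i, ] > 0 & support[i + 1L, ]
      if (!any(above))
        stop("wham_combine: no overlap between the ensembles at lambda = ",
             histograms[[i]]$lambda_i, " and lambda = ",
             histograms[[i + 1L]]$lambda_i)
    }
  }
  M <- colSums(counts)
  w <- rep(1 / B, B)
  for (iter in seq_len(max_iter)) {
    Z <- as.numeric(support %*% w)
    denom <- colSums(Ni / Z * support)
    w_new <- ifelse(denom > 0, M / denom, 0)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w) / pmax(w, 1e-300)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  p <- rev(cumsum(rev(c(w, 0))))  # P(max >= break_k)
  p <- p / p[1]
  structure(data.frame(lambda = breaks, p_tot = p),
            class = c("crossing_profile", "data.frame"))
}

#' Read the total crossing probability off a profile
#'
#' @param profile A `crossing_profile`.
#' @param lambda Query position (snapped to the nearest grid point).
#' @return `p_tot(lambda | lambda_0)`.
#' @export
profile_at <- function(profile, lambda) {
  i <- which.min(abs(profile$lambda - lambda))
  profile$p_tot[i]
}

#' Effective positive flux through the innermost interface
#'
#' Counts first crossings of `lambda_0` along a long trajectory
#' initialized in the state, counting at most one crossing per state
#' re-entry (immediate recrossings without re-entering the state do not
#' count), and divides by the total time spent in or attached to the state
#' (all time, unless `other_states` are given, in which case time carrying
#' another state's label is excluded).
#'
#' @param trajectory A `toy_traj` or frame matrix from a run started in
#'   `state`.
#' @param state The initial-state [state_definition()].
#' @param lambda0 Innermost-interface position on the progress coordinate.
#' @param lambda_sign +1 for the forward coordinate, -1 for the mirrored
#'   one.
#' @param other_states Optional list of competing states whose attached
#'   time is excluded.
#' @return List with `flux` (1/time), `n_crossings`, `time`.
#' @export
flux_from_state_run <- function(trajectory, state, lambda0,
                                lambda_sign = 1, other_states = list()) {
  frames <- if (inherits(trajectory, "toy_traj")) trajectory$frames else
    trajectory
  ins <- in_state_frames(frames, state)
  if (!any(ins))
    stop("flux_from_state_run: trajectory never visits the state")
  lam <- lambda_values(frames, lambda_sign)
  n <- nrow(frames)
  dtf <- if (n > 1L) frames[2, "time"] - frames[1, "time"] else 0
  entries <- which(ins & !c(FALSE, ins[-n]))
  ups <- which(lam > lambda0 & c(FALSE, lam[-n] <= lambda0))
  hit <- findInterval(ups, entries)
  n_cross <- length(unique(hit[hit > 0L]))
  if (length(other_states)) {
    lab <- frame_state_labels(frames, c(list(state), other_states))
    time <- sum(lab == 1L, na.rm = TRUE) * dtf
  } else {
    time <- (n - 1L) * dtf
  }
  time <- unname(time)
  if (time <= 0) stop("flux_from_state_run: no time attached to the state")
  list(flux = n_cross / time, n_crossings = n_cross, time = time)
}

#' Rate constant from its TIS factors
#'
#' `k = flux * p_tot(lambda_rep | lambda_0) * p_commit`: the flux out of
#' the initial state through the innermost interface, times the probability
#' of reaching the reporting interface before returning, times the
#' probability of committing to the product state once there. With the
#' values reported for the DNA system (flux 5.5e8 /s, crossing probability
#' 1.5e-5 at lambda = 1.0, commitment 0.09) this gives the
#' Watson-Crick-to-Hoogsteen rate of about 742 /s.
#'
#' @param flux Flux out of the initial state (1/time), >= 0.
#' @param p_tot_at_rep Total crossing probability at the reporting
#'   interface, between 0 and 1.
#' @param p_commit Commitment probability, between 0 and 1.
#' @return Rate constant (1/time).
#' @export
rate_from_components <- function(flux, p_tot_at_rep, p_commit) {
  if (!is.finite(flux) || flux < 0)
    stop("rate_from_components: flux must be non-negative")
  for (p in c(p_tot_at_rep, p_commit))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("rate_from_components: probabilities must lie in [0, 1]")
  flux * p_tot_at_rep * p_commit
}

#' Free-energy difference from a pair of rate constants
#'
#' `dG = log(k_backward / k_forward)` in kBT: positive when the forward
#' product state is higher in free energy (less populated) than the
#' reactant.
#'
#' @param k_forward,k_backward Rate constants (> 0, same units).
#' @return Free-energy difference in kBT.
#' @export
free_energy_from_rates <- function(k_forward, k_backward) {
  if (k_forward <= 0 || k_backward <= 0)
    stop("free_energy_from_rates: rates must be strictly positive")
  log(k_backward / k_forward)
}

#' Run a full TIS rate calculation on the toy model
#'
#' Seeds every interface ensemble from one harvested connecting path,
#' samples them by one-way shooting, WHAM-combines the crossing histograms
#' into the total crossing probability, measures the flux out of the
#' initial state from a long direct run in the state, takes the commitment
#' probability from the outermost ensemble, and multiplies the three
#' factors into the rate constant.
#'
#' @param engine A [toy_engine()].
#' @param states Named list of two [state_definition()]s; the transition
#'   sampled is from the first to the second.
#' @param interfaces An [interface_set()] on the (possibly mirrored)
#'   progress coordinate.
#' @param n_trials Shooting trials per interface ensemble (recorded after
#'   a burn-in of `n_trials %/% 4` further trials).
#' @param flux_steps Integration steps of the flux run.
#' @param grid_res Resolution of the shared crossing-histogram grid
#'   (default 0.005).
#' @param lambda_sign +1 for the A-to-B transition along `x`, -1 for the
#'   mirrored B-to-A transition.
#' @param max_length_factor Trial-length cap multiplier.
#' @param seed Optional seed applied via `set.seed` and recorded.
#' @return A `tis_result`: `profile` (crossing profile), `components`
#'   (flux, p_tot_at_rep, p_commit, k, k_se), `ensembles`, `interfaces`,
#'   `seed`.
#' @export
run_tis <- function(engine, states, interfaces = default_toy_interfaces(),
                    n_trials = 500, flux_steps = 2e6, grid_res = 0.005,
                    lambda_sign = 1, max_length_factor = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- engine$params
  init_center <- state_center(states[[1]])
  initial <- generate_initial_path(engine, states,
                                   init = phase_point(init_center),
                                   from = 1L)
  nI <- length(interfaces$lambdas) - 1L
  ensembles <- vector("list", nI)
  for (i in seq_len(nI))
    ensembles[[i]] <- sample_interface_ensemble(
      i, interfaces, engine, states, initial, n_trials,
      max_length_factor = max_length_factor, lambda_sign = lambda_sign)

  lam0 <- interfaces$lambdas[1]
  maxmax <- max(vapply(ensembles, function(e) max(e$max_lambda), numeric(1)))
  breaks <- seq(lam0, maxmax + grid_res, by = grid_res)
  hists <- lapply(ensembles, crossing_histogram, breaks = breaks)
  profile <- wham_combine(hists, interfaces)
  p_tot_rep <- profile_at(profile, interfaces$lambda_rep)

  # commitment probability: among outermost-ensemble paths that reached the
  # reporting interface, the weighted fraction ending in the product state
  outer <- ensembles[[nI]]
  rep_mask <- outer$max_lambda >= interfaces$lambda_rep
  p_commit <- if (any(rep_mask))
    sum(outer$weights[rep_mask & outer$ends_in_product]) /
      sum(outer$weights[rep_mask]) else 0

  flux_run <- propagate_until(phase_point(init_center), stop = list(),
                              max_steps = flux_steps, params = params)
  fl <- flux_from_state_run(flux_run, states[[1]], lam0,
                            lambda_sign = lambda_sign,
                            other_states = states[-1])

  k <- rate_from_components(fl$flux, p_tot_rep, p_commit)

  # error estimate: block standard errors of the per-trial conditional
  # crossing indicators (accounting for chain autocorrelation), Poisson
  # counting error on the flux, block error on the commitment fraction
  rel_var <- 1 / max(fl$n_crossings, 1)
  for (i in seq_len(nI)) {
    e <- ensembles[[i]]
    nxt <- if (i < nI) interfaces$lambdas[i + 1L] else interfaces$lambda_rep
    series <- rep(e$max_lambda >= nxt, e$weights)
    f <- mean(series)
    f <- min(max(f, 1e-12), 1)
    rel_var <- rel_var + (block_se(series) / f)^2
  }
  if (p_commit > 0 && p_commit < 1) {
    cseries <- rep(outer$ends_in_product, outer$weights)[
      rep(rep_mask, outer$weights)]
    rel_var <- rel_var + (block_se(cseries) / p_commit)^2
  }
  k_se <- k * sqrt(rel_var)

  structure(list(profile = profile,
                 components = list(flux = fl$flux, p_tot_at_rep = p_tot_rep,
                                   p_commit = p_commit, k = k, k_se = k_se),
                 ensembles = ensembles, interfaces = interfaces,
                 flux_details = fl, seed = seed),
            class = "tis_result")
}

#' @export
print.tis_result <- function(x, ...) {
  c_ <- x$components
  cat(sprintf(paste0("tis_result: flux = %.4g, p_tot(rep) = %.4g, ",
                     "p_commit = %.4g\n  k = %.4g +/- %.2g (1/time)\n"),
              c_$flux, c_$p_tot_at_rep, c_$p_commit, c_$k, c_$k_se))
  invisible(x)
}

#' Co-location of flat crossing-profile regions with path density
#'
#' Diagnostic relating the total crossing probability to a path ensemble:
#' where the log-profile slope is flat the system tends to linger, which
#' in systems with on-pathway intermediates shows up as high path density
#' at the same progress-coordinate values. Returns the Spearman rank
#' correlation between the inverse absolute log-slope of the profile and
#' the density mass per progress-coordinate bin; positive values indicate
#' co-location. On surfaces with a single saddle along the coordinate and
#' no intermediate (such as the built-in toy model at its defaults) there
#' is no lingering region and the correlation carries no signal.
#'
#' @param profile A `crossing_profile`.
#' @param density A matrix from [path_density()] whose rows are bins of
#'   the progress coordinate.
#' @param breaks_x The progress-coordinate breaks of `density` (defaults
#'   to its `breaks_x` attribute).
#' @return List with `correlation`, `inv_slope` and `mass` per bin.
#' @export
profile_density_colocation <- function(profile, density,
                                       breaks_x = attr(density,
                                                       "breaks_x")) {
  stopifnot(!is.null(breaks_x), nrow(density) == length(breaks_x) - 1L)
  mass <- rowSums(density)
  slope <- vapply(seq_len(length(breaks_x) - 1L), function(i) {
    p1 <- profile_at(profile, breaks_x[i])
    p2 <- profile_at(profile, breaks_x[i + 1])
    abs(log(p2) - log(p1)) / (breaks_x[i + 1] - breaks_x[i])
  }, numeric(1))
  inv_slope <- 1 / pmax(slope, 1e-6)
  list(correlation = suppressWarnings(
         cor(inv_slope, mass, method = "spearman")),
       inv_slope = inv_slope, mass = mass)
}

# block-averaged standard error of the mean of a (correlated) series
block_se <- function(x, n_blocks = 20L) {
  n <- length(x)
  if (n < 2L) return(if (n == 1L) abs(x) else 0)
  n_blocks <- max(2L, min(n_blocks, n %/% 2L))
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  sd(bm) / sqrt(length(bm))
}

state_center <- function(state) {
  lo <- state$min; hi <- state$max
  ctr <- (pmax(lo, -2) + pmin(hi, 2)) / 2
  as.numeric(ctr[c("x", "y")])
}
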