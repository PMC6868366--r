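#' Sampling engine wrapping the toy Langevin dynamics
#'
#' Bundles the dynamical parameters and the order-parameter map into the
#' engine object consumed by the TPS/TIS samplers. The samplers only touch
#' the engine through [engine_propagate()] and [engine_order_values()], so
#' an alternative dynamics (e.g. replayed frames) can be slotted in by
#' providing methods for another class.
#'
#' @param params A [toy_params()] object.
#' @param map A [toy_order_map()].
#' @return An object of class `toy_engine`.
#' @export
toy_engine <- function(params = toy_params(), map = toy_order_map()) {
  structure(list(params = params, map = map), class = "toy_engine")
}

#' Propagate a frame under an engine until a stop state is reached
#'
#' @param engine A sampling engine, e.g. [toy_engine()].
#' @param frame Numeric frame vector (time, x, y, vx, vy).
#' @param states List of [state_definition()] stop states.
#' @param max_steps Integration-step budget.
#' @return A `toy_traj`.
#' @export
engine_propagate <- function(engine, frame, states, max_steps) {
  UseMethod("engine_propagate")
}

#' @export
engine_propagate.toy_engine <- function(engine, frame, states, max_steps) {
  propagate_until(phase_point(frame[2:3], frame[4:5], frame[1]),
                  stop = states, max_steps = max_steps,
                  params = engine$params)
}

#' Order-parameter values of frames under an engine
#'
#' @inheritParams engine_propagate
#' @param frames Frame matrix.
#' @return Data frame of per-frame order-parameter values.
#' @export
engine_order_values <- function(engine, frames) {
  UseMethod("engine_order_values")
}

#' @export
engine_order_values.toy_engine <- function(engine, frames) {
  toy_order_values(frames, engine$map)
}

#' Construct a sampled path
#'
#' A path is an ordered sequence of saved frames with a per-frame
#' order-parameter cache and provenance metadata (which trial produced it,
#' from which parent, at which shooting frame, in which direction).
#'
#' @param frames Frame matrix (columns time, x, y, vx, vy).
#' @param engine Engine used to fill the order-parameter cache.
#' @param id,parent_id Path identifiers (trial numbers; the initial path is
#'   id 0).
#' @param shoot_index,direction Shooting provenance.
#' @return An object of class `sampled_path`.
#' @export
sampled_path <- function(frames, engine, id = 0L, parent_id = NA_integer_,
                         shoot_index = NA_integer_,
                         direction = NA_character_) {
  structure(list(frames = frames,
                 ops = engine_order_values(engine, frames),
                 id = as.integer(id), parent_id = as.integer(parent_id),
                 shoot_index = as.integer(shoot_index),
                 direction = direction),
            class = "sampled_path")
}

#' @export
print.sampled_path <- function(x, ...) {
  cat(sprintf("sampled_path id=%d: %d frames, t in [%.3g, %.3g]\n",
              x$id, nrow(x$frames), x$frames[1, "time"],
              x$frames[nrow(x$frames), "time"]))
  invisible(x)
}

#' Path length in frames
#' @param path A `sampled_path`.
#' @return Integer frame count.
#' @export
path_length <- function(path) nrow(path$frames)

# endpoint/interior state bookkeeping on a frame matrix
frames_connect <- function(frames, states) {
  s_first <- which_state(frames[1, c("x", "y")], states)
  n <- nrow(frames)
  s_last <- which_state(frames[n, c("x", "y")], states)
  interior_ok <- TRUE
  if (n > 2L) {
    mid <- frames[2:(n - 1L), , drop = FALSE]
    for (st in states)
      interior_ok <- interior_ok && !any(in_state_frames(mid, st))
  }
  list(from = s_first, to = s_last, interior_ok = interior_ok,
       connects = s_first != 0L && s_last != 0L && s_first != s_last &&
         interior_ok)
}

#' Validate the TPS path invariant
#'
#' Accepted paths must start in one state, end in the other, and visit no
#' state in between.
#'
#' @param path A `sampled_path`.
#' @param states Named list of the two sampled [state_definition()]s.
#' @return Logical scalar.
#' @export
path_is_valid <- function(path, states) {
  frames_connect(path$frames, states)$connects
}

#' Generate an initial transition path by high-temperature harvesting
#'
#' The rare transition is first provoked in a boosted-temperature run
#' (thermal energy multiplied by `boost`); a configuration near the top of
#' the harvested transition is then requenched to the target temperature by
#' drawing fresh Maxwell velocities and shooting forward and backward until
#' both segments reach a state. The attempt is repeated until the two
#' segments land in different states, which yields a valid connecting path
#' at the target temperature. Deterministic given the RNG state.
#'
#' @param engine A [toy_engine()].
#' @param states Named list of two [state_definition()]s.
#' @param boost Temperature multiplier for the harvesting run (default 5).
#' @param max_steps Step budget per propagation segment (default 1e5) and
#'   per harvesting chunk.
#' @param max_tries Requenching attempts before giving up (default 200).
#' @param init Starting [phase_point()] for the harvesting run.
#' @param from Index (into `states`) of the state the returned path must
#'   start in; the harvested path is time-reversed if needed (equilibrium
#'   dynamics is reversible). `NULL` keeps the harvested orientation.
#' @param seed Optional seed applied via `set.seed` and recorded.
#' @return A `sampled_path` with id 0 satisfying [path_is_valid()].
#' @export
generate_initial_path <- function(engine, states, boost = 5,
                                  max_steps = 1e5, max_tries = 200,
                                  init = phase_point(c(-1, 0)),
                                  from = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- engine$params
  hot <- params
  hot$kBT <- params$kBT * boost
  sdv <- sqrt(params$kBT / params$mass)

  harvest_crossing_frames <- function() {
    # run hot dynamics until a core-to-core transition; return the frames
    # of the transition segment (exclusive of the core frames)
    state <- init
    carry <- NA_integer_
    for (chunk in 1:50) {
      tr <- propagate_until(state, stop = list(), max_steps = max_steps,
                            params = hot)
      lab <- frame_state_labels(tr$frames, states, carry = carry)
      ch <- which(diff(lab) != 0 & !is.na(diff(lab)))
      if (length(ch)) {
        j <- ch[1]
        lo <- max(which(!is.na(lab[1:j]) & lab[1:j] == lab[j]))
        return(tr$frames[lo:(j + 1L), , drop = FALSE])
      }
      n <- nrow(tr$frames)
      state <- phase_point(tr$frames[n, 2:3], tr$frames[n, 4:5],
                           tr$frames[n, 1])
      carry <- lab[n]
    }
    stop("generate_initial_path: no transition found in the boosted run ",
         "within the step budget")
  }

  seg <- harvest_crossing_frames()
  # configurations near the channel midpoint, most central first
  ord <- order(abs(seg[, "x"]))
  for (try in seq_len(max_tries)) {
    row <- seg[ord[(try - 1L) %% nrow(seg) + 1L], ]
    v <- rnorm(2, 0, sdv)
    fwd <- propagate_until(phase_point(row[2:3], v, 0), stop = states,
                           max_steps = max_steps, params = params)
    bwd <- propagate_until(phase_point(row[2:3], -v, 0), stop = states,
                           max_steps = max_steps, params = params)
    if (fwd$stop_reason == "max" || bwd$stop_reason == "max") next
    if (fwd$stop_reason == bwd$stop_reason) next
    nb <- nrow(bwd$frames)
    back <- bwd$frames[nb:1, , drop = FALSE]
    back[, 4:5] <- -back[, 4:5]
    frames <- rbind(back, fwd$frames[-1, , drop = FALSE])
    frames <- rebuild_times(frames, params)
    path <- sampled_path(frames, engine, id = 0L)
    if (path_is_valid(path, states)) {
      if (!is.null(from) &&
          frames_connect(path$frames, states)$from != from) {
        fr <- path$frames[nrow(path$frames):1, , drop = FALSE]
        fr[, 4:5] <- -fr[, 4:5]
        path <- sampled_path(rebuild_times(fr, params), engine, id = 0L)
      }
      return(path)
    }
  }
  stop("generate_initial_path: could not requench a connecting path within ",
       max_tries, " attempts")
}

rebuild_times <- function(frames, params) {
  frames[, "time"] <- (seq_len(nrow(frames)) - 1L) *
    params$dt * params$save_interval
  frames
}

#' One-way shooting move
#'
#' Picks a shooting frame uniformly from the interior frames of the current
#' path (endpoints, which lie in the states, are excluded), chooses forward
#' or backward with probability 1/2, and integrates a fresh segment from
#' the shooting frame until a state is hit or the frame budget is
#' exhausted. Forward shots keep the old path up to the shooting frame and
#' append the new segment; backward shots integrate with negated velocities
#' and fresh noise, reverse the segment, and prepend it to the old path
#' from the shooting frame on.
#'
#' @param current The current `sampled_path`.
#' @param engine A [toy_engine()].
#' @param states Named list of [state_definition()]s used as stop states.
#' @param max_length Maximum trial-path length in frames.
#' @param trial_id Identifier stamped on the trial path.
#' @return List with `trial` (a `sampled_path`, or NULL when the budget was
#'   exhausted) and `record` (one-row data frame: trial, shoot_index,
#'   direction, trial_length, completed, reason).
#' @export
one_way_shot <- function(current, engine, states, max_length,
                         trial_id = NA_integer_) {
  n <- path_length(current)
  if (n < 3L)
    stop("one_way_shot: current path has no interior frames")
  j <- if (n == 3L) 2L else sample(2:(n - 1L), 1L)
  forward <- runif(1) < 0.5
  params <- engine$params
  si <- params$save_interval

  if (forward) {
    budget <- max(1L, (max_length - j)) * si
    seg <- engine_propagate(engine, current$frames[j, ], states, budget)
    if (seg$stop_reason == "max")
      return(shot_reject(trial_id, j, "forward", "max_length"))
    frames <- rbind(current$frames[1:j, , drop = FALSE],
                    seg$frames[-1, , drop = FALSE])
  } else {
    budget <- max(1L, (max_length - (n - j + 1L))) * si
    row <- current$frames[j, ]
    row[4:5] <- -row[4:5]
    seg <- engine_propagate(engine, row, states, budget)
    if (seg$stop_reason == "max")
      return(shot_reject(trial_id, j, "backward", "max_length"))
    nb <- nrow(seg$frames)
    back <- seg$frames[nb:1, , drop = FALSE]
    back[, 4:5] <- -back[, 4:5]
    frames <- rbind(back, current$frames[(j + 1L):n, , drop = FALSE])
  }
  frames <- rebuild_times(frames, params)
  trial <- sampled_path(frames, engine, id = trial_id,
                        parent_id = current$id, shoot_index = j,
                        direction = if (forward) "forward" else "backward")
  rec <- data.frame(trial = trial_id, shoot_index = j,
                    direction = if (forward) "forward" else "backward",
                    trial_length = nrow(frames), completed = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  list(trial = trial, record = rec)
}

shot_reject <- function(trial_id, j, direction, reason) {
  list(trial = NULL,
       record = data.frame(trial = trial_id, shoot_index = j,
                           direction = direction, trial_length = NA_integer_,
                           completed = FALSE, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Metropolis acceptance of a completed shooting trial
#'
#' A trial is rejected outright unless it connects the two states with no
#' interior state visits; a connecting trial is accepted with probability
#' `min(1, L_old / L_new)` where `L` is the frame count. Together with
#' uniform shooting-point selection over interior frames this is the
#' correct acceptance rule for flexible-length one-way shooting.
#'
#' @param old The current `sampled_path`.
#' @param trial The completed trial `sampled_path`.
#' @param states Named list of the two sampled states.
#' @param valid_fun Validity predicate `function(frames, states)` returning
#'   TRUE/FALSE; defaults to the TPS connecting criterion.
#' @return Logical: accept or reject (draws one uniform variate when the
#'   trial is valid).
#' @export
accept_trial <- function(old, trial, states, valid_fun = NULL) {
  ok <- if (is.null(valid_fun)) {
    frames_connect(trial$frames, states)$connects
  } else {
    valid_fun(trial$frames, states)
  }
  if (!ok) return(FALSE)
  runif(1) < min(1, path_length(old) / path_length(trial))
}

#' Run a transition path sampling chain
#'
#' Markov chain over path space with one-way shooting and Metropolis
#' acceptance. On rejection the previous path is retained and re-counted
#' (its ensemble weight is incremented), the standard path-ensemble
#' weighting. Both A-to-B and B-to-A connecting paths are kept, with
#' direction metadata.
#'
#' @param initial A valid initial `sampled_path` (see
#'   [generate_initial_path()]).
#' @param n_trials Number of shooting trials.
#' @param engine A [toy_engine()].
#' @param states Named list of two [state_definition()]s.
#' @param max_length_factor Trial-length cap as a multiple of the initial
#'   path length (default 50).
#' @param seed Optional seed applied via `set.seed` and recorded.
#' @return A `tps_ensemble`: list with `paths` (accepted paths, the initial
#'   path first), `weights` (trials each path represents, counting
#'   rejections), `records` (per-trial data frame), `acceptance_ratio`,
#'   `length_histogram` (table of accepted path lengths), `seed`.
#' @export
run_tps <- function(initial, n_trials, engine, states,
                    max_length_factor = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!path_is_valid(initial, states))
    stop("run_tps: initial path does not satisfy the path invariants")
  max_length <- max_length_factor * path_length(initial)
  paths <- list(initial)
  weights <- 1
  cur <- 1L
  records <- vector("list", n_trials)
  n_acc <- 0L
  for (t in seq_len(n_trials)) {
    shot <- one_way_shot(paths[[cur]], engine, states, max_length,
                         trial_id = t)
    rec <- shot$record
    accepted <- FALSE
    if (rec$completed) {
      accepted <- accept_trial(paths[[cur]], shot$trial, states)
      if (accepted && !path_is_valid(shot$trial, states))
        stop("run_tps: accepted path violates the path invariants")
      if (!accepted && rec$reason == "") rec$reason <- "metropolis"
    }
    rec$accepted <- accepted
    records[[t]] <- rec
    if (accepted) {
      n_acc <- n_acc + 1L
      paths[[length(paths) + 1L]] <- shot$trial
      weights <- c(weights, 1)
      cur <- length(paths)
    } else {
      weights[cur] <- weights[cur] + 1
    }
  }
  records <- if (n_trials > 0) do.call(rbind, records) else
    data.frame(trial = integer(), shoot_index = integer(),
               direction = character(), trial_length = integer(),
               completed = logical(), reason = character(),
               accepted = logical())
  lens <- vapply(paths, path_length, integer(1))
  structure(list(paths = paths, weights = weights, records = records,
                 acceptance_ratio = if (n_trials > 0) n_acc / n_trials else
                   NA_real_,
                 length_histogram = table(rep(lens, weights)),
                 n_trials = n_trials, seed = seed),
            class = "tps_ensemble")
}

#' @export
print.tps_ensemble <- function(x, ...) {
  cat(sprintf("tps_ensemble: %d trials, %d accepted paths (ratio %.3f)\n",
              x$n_trials, length(x$paths) - 1L,
              ifelse(is.na(x$acceptance_ratio), NA, x$acceptance_ratio)))
  invisible(x)
}

#' Number of decorrelated paths in an ensemble
#'
#' Counts accepted paths that share no frames with the previous
#' decorrelated path; the first accepted (initial) path is decorrelated by
#' definition. Frame identity is exact equality of the (x, y) coordinates,
#' which is the right notion here because shooting moves copy frames
#' verbatim between parent and child paths.
#'
#' @param ensemble A `tps_ensemble`.
#' @return Integer count (>= 1).
#' @export
decorrelated_count <- function(ensemble) {
  keyf <- function(p) paste(p$frames[, "x"], p$frames[, "y"])
  ref <- keyf(ensemble$paths[[1]])
  count <- 1L
  for (p in ensemble$paths[-1]) {
    k <- keyf(p)
    if (!any(k %in% ref)) {
      count <- count + 1L
      ref <- k
    }
  }
  count
}

#' Shooting genealogy of an ensemble
#'
#' @param ensemble A `tps_ensemble`.
#' @return Data frame with one row per accepted trial: `parent_id`,
#'   `child_id`, `shoot_index`, `direction`. The forest is rooted at the
#'   initial path (id 0) and every accepted path is reachable from it.
#' @export
path_tree_edges <- function(ensemble) {
  acc <- ensemble$paths[-1]
  if (length(acc) == 0L)
    return(data.frame(parent_id = integer(), child_id = integer(),
                      shoot_index = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(acc, function(p) {
    if (is.na(p$parent_id))
      stop("path_tree_edges: path ", p$id, " lacks provenance")
    data.frame(parent_id = p$parent_id, child_id = p$id,
               shoot_index = p$shoot_index, direction = p$direction,
               stringsAsFactors = FALSE)
  }))
}
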