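#' Define a metastable state by order-parameter windows
#'
#' A state is a conjunction of open interval constraints on named order
#' parameters (for the toy model, the coordinates `x` and `y`; for the DNA
#' problem, e.g. a `lambda` window plus hydrogen-bond distance cutoffs).
#'
#' @param name State name (e.g. `"WC"`, `"HG"`, `"A"`, `"B"`).
#' @param min,max Named numeric vectors of lower/upper bounds over the same
#'   set of variables; `-Inf`/`Inf` allowed.
#' @return An object of class `state_definition`.
#' @export
state_definition <- function(name, min, max) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(min)) || is.null(names(max)) ||
      !setequal(names(min), names(max)))
    stop("state_definition: min and max must be named over the same variables")
  max <- max[names(min)]
  if (any(min >= max))
    stop("state_definition: every min must be strictly below its max")
  structure(list(name = name, min = min, max = max),
            class = "state_definition")
}

#' @export
print.state_definition <- function(x, ...) {
  cat("State", x$name, "\n")
  for (v in names(x$min))
    cat(sprintf("  %g < %s < %g\n", x$min[[v]], v, x$max[[v]]))
  invisible(x)
}

#' Test whether an order-parameter vector lies inside a state
#'
#' Pure predicate evaluation: all of the state's interval constraints must
#' hold strictly. Referencing an order parameter absent from `values` is an
#' error naming the parameter.
#'
#' @param values Named numeric vector (or single-row data frame / list) of
#'   order-parameter values.
#' @param state A [state_definition()].
#' @return Logical scalar.
#' @export
in_state <- function(values, state) {
  values <- unlist(values)
  miss <- setdiff(names(state$min), names(values))
  if (length(miss))
    stop("in_state: order parameter(s) missing from input: ",
         paste(miss, collapse = ", "))
  v <- values[names(state$min)]
  all(v > state$min & v < state$max)
}

#' Assert that two states are disjoint for a given vector
#'
#' @param values Named numeric vector of order-parameter values.
#' @param states List of [state_definition()]s.
#' @return Index (1-based) of the state containing `values`, or 0L; error if
#'   more than one state contains it.
#' @export
which_state <- function(values, states) {
  hits <- which(vapply(states, function(s) in_state(values, s), logical(1)))
  if (length(hits) > 1L)
    stop("which_state: states ",
         paste(vapply(states[hits], `[[`, "", "name"), collapse = ", "),
         " are not disjoint at this point")
  if (length(hits) == 0L) 0L else hits
}

# vectorized membership over a frame matrix with named columns
in_state_frames <- function(frames, state) {
  vars <- names(state$min)
  miss <- setdiff(vars, colnames(frames))
  if (length(miss))
    stop("in_state: order parameter(s) missing from frames: ",
         paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(frames))
  for (v in vars)
    ok <- ok & frames[, v] > state$min[[v]] & frames[, v] < state$max[[v]]
  ok
}

# states defined on (x, y) -> stop boxes for the C++ propagator
states_to_boxes <- function(states) {
  if (length(states) == 0L) return(matrix(numeric(0), 0, 4))
  rows <- lapply(states, function(s) {
    if (!setequal(names(s$min), c("x", "y")))
      stop("toy propagation requires states defined on x and y; state '",
           s$name, "' uses: ", paste(names(s$min), collapse = ", "))
    c(s$min[["x"]], s$max[["x"]], s$min[["y"]], s$max[["y"]])
  })
  do.call(rbind, rows)
}
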