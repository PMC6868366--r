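#' Default pipeline configuration
#'
#' @return Nested list of all configuration defaults: toy-model parameters,
#'   order map, TPS settings (number of independent runs and trials per
#'   run), TIS settings (interfaces and trials per ensemble), and analysis
#'   settings (channel line, feature bins).
#' @export
default_config <- function() {
  tp <- unclass(toy_params())
  list(system = "toy",
       toy = tp,
       order_map = unclass(toy_order_map()),
       tps = list(n_runs = 2L, n_trials = 200L, max_length_factor = 50),
       tis = list(n_trials = 150L, flux_steps = 5e5, n_interfaces = 8L,
                  grid_res = 0.005, run = TRUE),
       analysis = list(line = unclass(toy_channel_line())))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, validates it against the schema, and fills
#' unset fields with the defaults of [default_config()]. Every stochastic
#' stage derives its seed from the single required top-level `seed`, so a
#' configuration file reproduces a run bit for bit.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list with class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Validate an in-memory configuration
#'
#' @param raw Configuration list (e.g. from [load_config()] or built in
#'   code). Must contain an integer `seed`.
#' @return Validated, default-filled configuration of class `run_config`.
#' @export
validate_config <- function(raw) {
  if (is.null(raw$seed))
    stop("config: required field 'seed' is missing")
  if (!is.numeric(raw$seed) || length(raw$seed) != 1L ||
      raw$seed != round(raw$seed))
    stop("config: field 'seed' must be a single integer")
  def <- default_config()
  cfg <- modify_defaults(def, raw[setdiff(names(raw), "seed")])
  cfg$seed <- as.integer(raw$seed)
  if (!identical(cfg$system, "toy"))
    stop("config: field 'system' must be 'toy' (frame replay engines are ",
         "constructed in code)")
  # materialize typed objects to surface invariant violations early
  do.call(toy_params, cfg$toy)
  do.call(toy_order_map, cfg$order_map)
  do.call(channel_line, cfg$analysis$line)
  for (f in c("n_runs", "n_trials")) {
    if (!is.numeric(cfg$tps[[f]]) || cfg$tps[[f]] < 0)
      stop("config: field 'tps.", f, "' must be a non-negative number")
  }
  if (cfg$tis$n_interfaces < 1)
    stop("config: field 'tis.n_interfaces' must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

modify_defaults <- function(def, upd) {
  for (nm in names(upd)) {
    if (is.list(def[[nm]]) && is.list(upd[[nm]]))
      def[[nm]] <- modify_defaults(def[[nm]], upd[[nm]])
    else def[[nm]] <- upd[[nm]]
  }
  def
}

#' Save a configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# documented seed-splitting scheme: stage k of run r uses
# seed + 1000 * k + r (all well below 2^31 for config seeds < 2^30)
stage_seed <- function(seed, stage, run = 0L) {
  as.integer((seed + 1000L * stage + run) %% .Machine$integer.max)
}

#' Run the full pipeline on one configuration
#'
#' Executes the stages in order: harvest an initial transition path,
#' run the configured number of independent TPS chains, classify their
#' channels and compute the switching analysis, then (unless disabled)
#' run TIS in both directions and combine fluxes, crossing probabilities
#' and commitment probabilities into forward and backward rate constants
#' and the free-energy difference. Per-stage seeds are split
#' deterministically from the configuration seed; a structured log records
#' stage timings and seeds.
#'
#' @param config A validated `run_config` (see [load_config()] /
#'   [validate_config()]).
#' @return A `results_bundle`: `config`, `tps` (per-run summaries and
#'   label sequences), `analysis` (outside-fraction curve, switch counts,
#'   posterior), `rates` (forward, backward, dG; or a `skipped` marker),
#'   `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  log <- list()
  note <- function(stage, seed, t0)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, seed = seed, seconds = round(proc.time()[3] - t0, 3))

  params <- do.call(toy_params, config$toy)
  map <- do.call(toy_order_map, config$order_map)
  engine <- toy_engine(params, map)
  states <- default_toy_states()
  line <- do.call(channel_line, config$analysis$line)

  # TPS runs
  tps_runs <- list()
  label_runs <- list()
  for (r in seq_len(config$tps$n_runs)) {
    t0 <- proc.time()[3]
    sd_r <- stage_seed(config$seed, 2L, r)
    set.seed(sd_r)
    init <- generate_initial_path(engine, states)
    ens <- run_tps(init, config$tps$n_trials, engine, states,
                   max_length_factor = config$tps$max_length_factor)
    label_runs[[r]] <- ensemble_channel_labels(ens, line)
    tps_runs[[r]] <- list(
      seed = sd_r,
      acceptance_ratio = ens$acceptance_ratio,
      n_accepted = length(ens$paths) - 1L,
      decorrelated = decorrelated_count(ens),
      initial_channel = classify_channel(channel_features(init), line))
    note(paste0("tps_run_", r), sd_r, t0)
  }

  # switching / channel analysis
  t0 <- proc.time()[3]
  analysis <- list()
  if (length(label_runs)) {
    analysis$outside_fraction <- outside_fraction_curve(label_runs)
    starts <- vapply(label_runs, `[`, "", 1)
    in_runs <- label_runs[starts == "inside"]
    out_runs <- label_runs[starts == "outside"]
    counts <- switch_counts(
      s1 = count_switching_runs(in_runs, "inside", "outside"),
      n1 = length(in_runs),
      s2 = count_switching_runs(out_runs, "outside", "inside"),
      n2 = length(out_runs))
    analysis$switch_counts <- counts
    analysis$posterior <- if (counts$n1 > 0 && counts$n2 > 0)
      bayes_channel_preference(counts) else NA_real_
    analysis$switch_probability <- if (length(in_runs))
      estimate_switch_probability(in_runs) else NULL
  }
  note("analysis", NA_integer_, t0)

  # TIS in both directions
  rates <- list(skipped = TRUE)
  tis <- list()
  if (isTRUE(config$tis$run) && config$tis$n_trials > 0) {
    ifc <- default_toy_interfaces(n = config$tis$n_interfaces)
    t0 <- proc.time()[3]
    sd_f <- stage_seed(config$seed, 3L)
    tis$forward <- run_tis(engine, states,
                           interfaces = ifc,
                           n_trials = config$tis$n_trials,
                           flux_steps = config$tis$flux_steps,
                           grid_res = config$tis$grid_res,
                           lambda_sign = 1, seed = sd_f)
    note("tis_forward", sd_f, t0)
    t0 <- proc.time()[3]
    sd_b <- stage_seed(config$seed, 4L)
    tis$backward <- run_tis(engine, rev(states),
                            interfaces = ifc,
                            n_trials = config$tis$n_trials,
                            flux_steps = config$tis$flux_steps,
                            grid_res = config$tis$grid_res,
                            lambda_sign = -1, seed = sd_b)
    note("tis_backward", sd_b, t0)
    k_f <- tis$forward$components$k
    k_b <- tis$backward$components$k
    rates <- list(skipped = FALSE, k_forward = k_f, k_backward = k_b,
                  dG = if (k_f > 0 && k_b > 0)
                    free_energy_from_rates(k_f, k_b) else NA_real_)
  }

  structure(list(config = config, tps = tps_runs, analysis = analysis,
                 tis = tis, rates = rates,
                 log = do.call(rbind, log),
                 total_seconds = round(proc.time()[3] - t_all, 3)),
            class = "results_bundle")
}

#' Summarize a results bundle
#'
#' Report mirroring the layout of a rate-constant table: forward and
#' backward rate, free-energy difference, plus the channel-preference
#' posterior and the endpoint of the outside-fraction curve. Missing
#' stages are marked rather than dropped.
#'
#' @param bundle A `results_bundle` from [run_pipeline()], or a list with
#'   a `rates` element.
#' @param format `"text"` (one aligned block, returned as a character
#'   vector of lines) or `"json"` (single JSON string).
#' @return Character; the report. Also printed when `format = "text"`.
#' @export
report_summary <- function(bundle, format = c("text", "json")) {
  format <- match.arg(format)
  r <- bundle$rates
  vals <- list(
    k_forward = if (!is.null(r) && !isTRUE(r$skipped)) r$k_forward else NA,
    k_backward = if (!is.null(r) && !isTRUE(r$skipped)) r$k_backward else NA,
    dG = if (!is.null(r) && !isTRUE(r$skipped)) r$dG else NA,
    posterior_outside_preferred =
      if (!is.null(bundle$analysis$posterior)) bundle$analysis$posterior
      else NA,
    outside_fraction_final =
      if (!is.null(bundle$analysis$outside_fraction))
        unname(tail(bundle$analysis$outside_fraction, 1)) else NA)
  if (format == "json")
    return(as.character(jsonlite::toJSON(vals, auto_unbox = TRUE,
                                         digits = NA, na = "null")))
  fmt <- function(v, digits = 4)
    if (is.na(v)) "  (not computed)" else format(signif(v, digits))
  lines <- c("rate and channel summary",
             sprintf("  k_forward  (1/time): %s", fmt(vals$k_forward)),
             sprintf("  k_backward (1/time): %s", fmt(vals$k_backward)),
             sprintf("  dG (kBT)           : %s",
                     if (is.na(vals$dG)) "  (not computed)" else
                       sprintf("%.1f", vals$dG)),
             sprintf("  P(outside preferred): %s",
                     fmt(vals$posterior_outside_preferred, 6)),
             sprintf("  outside fraction at final trial: %s",
                     fmt(vals$outside_fraction_final)))
  lines
}
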