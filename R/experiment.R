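# End-to-end experiment orchestration: generate two referral cohorts,
# simulate unit booking under the historical and weighted-queue policies,
# and evaluate time-to-unit with the six-stratum survival report.

#' Experiment configuration
#'
#' @param pre_spec,post_spec [cohort_spec()]s for the two cohorts; default
#'   [default_specs()].
#' @param unit a [unit_config()].
#' @param pre_policy,post_policy triage policies simulated for each cohort
#'   (defaults: the historical ABCD-descending practice for the pre cohort,
#'   the weighted queue for the post cohort).
#' @param model_path classifier model YAML (default: the bundled synthetic
#'   example model).
#' @param anchors_path risk-anchor YAML (default: the bundled
#'   literature-derived anchors).
#' @param horizon censoring horizon in days.
#' @param seed master seed; every stage draws from a named sub-stream of it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(pre_spec = default_specs()$pre,
                              post_spec = default_specs()$post,
                              unit = unit_config(),
                              pre_policy = "ABCD_DESC",
                              post_policy = "WEIGHTED_QUEUE",
                              model_path =
                                tiaqueue_example("example_classifier.yaml"),
                              anchors_path =
                                tiaqueue_example("abcd2_risk_anchors.yaml"),
                              horizon = 28L, seed = 1L) {
  stopifnot(inherits(pre_spec, "cohort_spec"),
            inherits(post_spec, "cohort_spec"),
            inherits(unit, "unit_config"), horizon > 0)
  pre_policy <- match.arg(pre_policy, POLICIES)
  post_policy <- match.arg(post_policy, POLICIES)
  for (p in c(model_path, anchors_path)) {
    if (!file.exists(p)) {
      stop(sprintf("experiment config: no such file: %s", p), call. = FALSE)
    }
  }
  structure(list(pre_spec = pre_spec, post_spec = post_spec, unit = unit,
                 pre_policy = pre_policy, post_policy = post_policy,
                 model_path = model_path, anchors_path = anchors_path,
                 horizon = as.integer(horizon), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys: `n_pre`, `n_post`, `daily_capacity`, `pre_policy`,
#' `post_policy`, `model_path`, `anchors_path`, `horizon`, `seed`, plus any
#' [cohort_spec()] argument under `pre_spec:` / `post_spec:`.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  specs <- default_specs(n_pre = cfg$n_pre %||% 2465L,
                         n_post = cfg$n_post %||% 1992L)
  override <- function(spec, ov) {
    if (is.null(ov)) return(spec)
    args <- utils::modifyList(unclass(spec)[setdiff(names(unclass(spec)),
                                                    "max_rejection_rounds")],
                              ov)
    do.call(cohort_spec, args)
  }
  experiment_config(
    pre_spec = override(specs$pre, cfg$pre_spec),
    post_spec = override(specs$post, cfg$post_spec),
    unit = unit_config(daily_capacity = cfg$daily_capacity %||% 5L),
    pre_policy = cfg$pre_policy %||% "ABCD_DESC",
    post_policy = cfg$post_policy %||% "WEIGHTED_QUEUE",
    model_path = cfg$model_path %||% tiaqueue_example("example_classifier.yaml"),
    anchors_path = cfg$anchors_path %||%
      tiaqueue_example("abcd2_risk_anchors.yaml"),
    horizon = cfg$horizon %||% 28L,
    seed = cfg$seed %||% 1L
  )
}

#' Run the full triage experiment
#'
#' Pipeline: generate the two synthetic cohorts -> apply the filter cascade ->
#' derive ABCD2 scores era-appropriately -> classify -> simulate unit booking
#' under each cohort's policy -> attach arrivals -> produce the six-stratum
#' survival comparison report. Deterministic given the config (all randomness
#' flows from named sub-streams of the master seed).
#'
#' @param config an [experiment_config()].
#' @return list of class `triage_experiment`: `report` (six-stratum table),
#'   `km` (Kaplan-Meier coordinates), `pre`, `post` (scored cohorts with
#'   arrivals), `arrivals_pre`, `arrivals_post`, and `log` (seed, versions,
#'   config hash — everything needed to re-run).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("experiment stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  model <- stage("load_model", read_classifier_model(config$model_path))
  curves <- stage("load_anchors",
                  fit_risk_curves(read_risk_anchors(config$anchors_path)))

  # The unit books every referral it can triage (final diagnosis and study
  # co-enrollment are unknown at triage time); the filter cascade selects the
  # analysis cohort afterwards. So the stream fed to the simulator is every
  # referral with usable timestamps, while the report is computed on the
  # filtered subset.
  prep <- function(spec, stream_name) {
    raw <- stage("generate",
                 generate_cohort(spec, substream_seed(config$seed, stream_name)))
    has_dates <- !is.na(raw$referrals$onset_datetime) &
      !is.na(raw$referrals$referral_datetime)
    stream <- referral_cohort(raw$referrals[has_dates, , drop = FALSE],
                              raw$label, validate = FALSE)
    stream <- stage("score", derive_abcd2(stream, fallback = TRUE))
    # classify on an imputed copy: the PRE_QUEUE scoring path leaves raw
    # fields unimputed, but the classifier's field features need values
    stream$referrals$p_tia <- stage("classify",
      predict_tia_probability(model, impute_missing(stream))$p_tia)
    analysis <- stage("filter", apply_cohort_filters(raw))
    list(stream = stream, analysis = analysis)
  }
  pre <- prep(config$pre_spec, "pre_cohort")
  post <- prep(config$post_spec, "post_cohort")

  arrivals_pre <- stage("simulate_pre",
    simulate_unit(pre$stream, config$unit, config$pre_policy,
                  seed = substream_seed(config$seed, "simulate_pre"),
                  curves = curves))
  arrivals_post <- stage("simulate_post",
    simulate_unit(post$stream, config$unit, config$post_policy,
                  seed = substream_seed(config$seed, "simulate_post"),
                  curves = curves))

  # analysis cohorts: era-appropriate scoring, arrivals joined from the
  # simulated stream
  finish <- function(p, arrivals) {
    scored <- stage("score", derive_abcd2(p$analysis))
    scored$referrals$p_tia <- stage("classify",
      predict_tia_probability(model, impute_missing(scored))$p_tia)
    attach_arrivals(scored, arrivals)
  }
  pre <- finish(pre, arrivals_pre)
  post <- finish(post, arrivals_post)

  report <- stage("evaluate",
                  stratified_report(pre, post, horizon = config$horizon))
  km <- stage("evaluate", km_coordinates(pre, post, horizon = config$horizon))

  log <- list(
    seed = config$seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("tiaqueue")),
    config_hash = config_hash(config),
    policies = c(pre = config$pre_policy, post = config$post_policy),
    daily_capacity = config$unit$daily_capacity,
    n_pre = nrow(pre$referrals), n_post = nrow(post$referrals)
  )
  structure(list(report = report, km = km, pre = pre, post = post,
                 arrivals_pre = arrivals_pre, arrivals_post = arrivals_post,
                 log = log),
            class = "triage_experiment")
}

# MD5 of the canonical JSON form of a config (file contents included, so a
# changed model or anchor file changes the hash).
config_hash <- function(config) {
  canon <- list(
    pre_spec = unclass(config$pre_spec), post_spec = unclass(config$post_spec),
    unit = unclass(config$unit),
    policies = c(config$pre_policy, config$post_policy),
    model = paste(readLines(config$model_path, warn = FALSE), collapse = "\n"),
    anchors = paste(readLines(config$anchors_path, warn = FALSE),
                    collapse = "\n"),
    horizon = config$horizon, seed = config$seed
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.triage_experiment <- function(x, ...) {
  cat(sprintf("<triage_experiment> seed %d, capacity %d/day (%s vs %s)\n",
              x$log$seed, x$log$daily_capacity, x$log$policies[["pre"]],
              x$log$policies[["post"]]))
  print(x$report, digits = 3)
  invisible(x)
}

#' Write an experiment bundle to a directory
#'
#' Emits `report.csv` (the six-stratum table), `km_curves.csv`, per-cohort
#' referral and arrival files, and a timestamped plain-text `run.log`.
#' All tabular outputs are deterministic given the config; only the log
#' carries a wall-clock timestamp.
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "triage_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(experiment$report, file.path(dir, "report.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(experiment$km, file.path(dir, "km_curves.csv"),
                   row.names = FALSE, na = "")
  write_referrals(experiment$pre, file.path(dir, "referrals_pre.csv"))
  write_referrals(experiment$post, file.path(dir, "referrals_post.csv"))
  for (tag in c("pre", "post")) {
    arr <- experiment[[paste0("arrivals_", tag)]]
    arr$appointment_datetime <- format_datetime(arr$appointment_datetime)
    arr$arrival_datetime <- format_datetime(arr$arrival_datetime)
    utils::write.csv(arr, file.path(dir, sprintf("arrivals_%s.csv", tag)),
                     row.names = FALSE, na = "")
  }
  log <- experiment$log
  writeLines(c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", log$seed),
    sprintf("r_version: %s", log$r_version),
    sprintf("package_version: %s", log$package_version),
    sprintf("config_hash: %s", log$config_hash),
    sprintf("pre_policy: %s", log$policies[["pre"]]),
    sprintf("post_policy: %s", log$policies[["post"]]),
    sprintf("daily_capacity: %d", log$daily_capacity),
    sprintf("n_pre: %d", log$n_pre),
    sprintf("n_post: %d", log$n_post)
  ), file.path(dir, "run.log"))
  invisible(dir)
}
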