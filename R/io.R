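# Plain-CSV serialization for every parameter table, a YAML scenario config,
# and a reproducibility manifest. All tables round-trip losslessly (readr
# writes shortest-roundtrip doubles).

#' Read and write parameter tables as CSV
#'
#' Each model object has a flat CSV form with explicit stratum columns:
#' joint population distributions (`age_group, gender, bmi_cat, glycemic,
#' probability`), life tables (`age, gender, q`), BMI drift parameters
#' (`age_group, gender, mean_change, p_change, sd, bmi_floor`), transition
#' sets (`age_group, gender, bmi_cat, from, to_no_diabetes, to_prediabetes,
#' to_diabetes, n_pairs`), diabetic mortality models (`param, value`),
#' entry-schedule counts (`year, count`) and visit panels (`subject_id,
#' visit_month, age, gender, bmi, glycemic_state`). Readers validate
#' headers strictly and rebuild the corresponding object.
#'
#' @param path CSV file path.
#' @param x Object to write.
#' @name prediasim-io
NULL

read_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(path, " is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname prediasim-io
#' @export
read_pop_distribution <- function(path) {
  pop_distribution(read_strict(path, c("age_group", "gender", "bmi_cat",
                                       "glycemic", "probability")))
}

#' @rdname prediasim-io
#' @export
write_pop_distribution <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname prediasim-io
#' @export
read_life_table <- function(path) {
  life_table(read_strict(path, c("age", "gender", "q")))
}

#' @rdname prediasim-io
#' @export
write_life_table <- function(x, path) {
  readr::write_csv(x$table, path)
  invisible(path)
}

#' @rdname prediasim-io
#' @export
read_tpm_set <- function(path) {
  tpm_set(read_strict(path, c("age_group", "gender", "bmi_cat", "from",
                              "to_no_diabetes", "to_prediabetes",
                              "to_diabetes")))
}

#' @rdname prediasim-io
#' @export
write_tpm_set <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname prediasim-io
#' @export
read_bmi_drift <- function(path) {
  df <- read_strict(path, c("age_group", "gender", "mean_change", "p_change"))
  bmi_drift(df, sd = if ("sd" %in% names(df)) df$sd[1] else 0.5,
            bmi_floor = if ("bmi_floor" %in% names(df)) df$bmi_floor[1] else 15)
}

#' @rdname prediasim-io
#' @export
write_bmi_drift <- function(x, path) {
  readr::write_csv(dplyr::mutate(x$params, sd = x$sd, bmi_floor = x$bmi_floor),
                   path)
  invisible(path)
}

#' @rdname prediasim-io
#' @export
read_diabetic_mortality <- function(path) {
  df <- read_strict(path, c("param", "value"))
  v <- stats::setNames(df$value, df$param)
  req <- c("h0", "beta_age", "beta_male", "beta_bmi", "constant",
           "age_center", "bmi_center")
  missing_p <- setdiff(req, names(v))
  if (length(missing_p) > 0) {
    stop(path, " is missing mortality parameters: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  diabetic_mortality(h0 = v[["h0"]], beta_age = v[["beta_age"]],
                     beta_male = v[["beta_male"]], beta_bmi = v[["beta_bmi"]],
                     constant = v[["constant"]],
                     age_center = v[["age_center"]],
                     bmi_center = v[["bmi_center"]])
}

#' @rdname prediasim-io
#' @export
write_diabetic_mortality <- function(x, path) {
  readr::write_csv(tibble::tibble(
    param = c("h0", "beta_age", "beta_male", "beta_bmi", "constant",
              "age_center", "bmi_center"),
    value = c(x$h0, x$beta_age, x$beta_male, x$beta_bmi, x$constant,
              x$age_center, x$bmi_center)), path)
  invisible(path)
}

#' @rdname prediasim-io
#' @param counts_path,dist_path Paths for the per-year counts table and the
#'   entrant distribution.
#' @export
read_entry_schedule <- function(counts_path, dist_path) {
  entry_schedule(read_strict(counts_path, c("year", "count")),
                 read_pop_distribution(dist_path))
}

#' @rdname prediasim-io
#' @export
write_entry_schedule <- function(x, counts_path, dist_path) {
  readr::write_csv(x$counts, counts_path)
  write_pop_distribution(x$dist, dist_path)
  invisible(c(counts_path, dist_path))
}

#' @rdname prediasim-io
#' @export
read_panel <- function(path) {
  validate_panel(read_strict(path, c("subject_id", "visit_month", "age",
                                     "gender", "bmi", "glycemic_state")))
}

#' @rdname prediasim-io
#' @export
write_panel <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Load a scenario from a YAML config
#'
#' The config names the horizon, agent count, agent-scale factor, master
#' seed, start year, the paths of every parameter table (relative paths are
#' resolved against the config file's directory), and optionally an
#' intervention block (`preset`, `age_band`, `per_person_cost`) and economic
#' settings (`benefit_per_case`, `discount_rate`).
#'
#' @param path YAML file.
#' @return A list with `scenario` (a [scenario()]), `horizon`, `n_agents`,
#'   `seed`, `intervention` (spec or NULL), `benefit_per_case`,
#'   `discount_rate` and the raw `config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- function(field) {
    if (is.null(cfg[[field]])) {
      stop("config is missing required field: ", field, call. = FALSE)
    }
    cfg[[field]]
  }
  horizon <- need("horizon")
  n_agents <- need("n_agents")
  if (horizon < 0) stop("config field `horizon` must be >= 0", call. = FALSE)
  if (n_agents < 1) stop("config field `n_agents` must be >= 1", call. = FALSE)
  paths <- need("paths")
  root <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^([/~]|[A-Za-z]:)", p)) p else
    file.path(root, p)
  for (f in c("init_dist", "entry_counts", "entry_dist", "tpms",
              "life_table", "mortality", "drift")) {
    if (is.null(paths[[f]])) {
      stop("config `paths` is missing entry: ", f, call. = FALSE)
    }
    if (!file.exists(resolve(paths[[f]]))) {
      stop("config path for `", f, "` does not exist: ", resolve(paths[[f]]),
           call. = FALSE)
    }
  }
  scn <- scenario(
    init_dist = read_pop_distribution(resolve(paths$init_dist)),
    entry = read_entry_schedule(resolve(paths$entry_counts),
                                resolve(paths$entry_dist)),
    tpms = read_tpm_set(resolve(paths$tpms)),
    lt = read_life_table(resolve(paths$life_table)),
    dm = read_diabetic_mortality(resolve(paths$mortality)),
    drift = read_bmi_drift(resolve(paths$drift)),
    agent_scale = cfg$agent_scale %||% 1,
    start_year = cfg$start_year %||% 2010
  )
  spec <- NULL
  if (!is.null(cfg$intervention)) {
    iv <- cfg$intervention
    spec <- intervention_preset(
      iv$preset %||% stop("config `intervention` needs a `preset`",
                          call. = FALSE),
      age_range = unlist(iv$age_band %||% c(25, 65)),
      per_person_cost = iv$per_person_cost
    )
  }
  list(scenario = scn, horizon = as.integer(horizon),
       n_agents = as.integer(n_agents), seed = as.integer(cfg$seed %||% 1),
       intervention = spec,
       benefit_per_case = cfg$benefit_per_case %||% 85200,
       discount_rate = cfg$discount_rate %||% 0, config = cfg)
}

#' Write the synthetic scenario's tables to a directory
#'
#' Materializes every input of a scenario as CSV in the dialects read back
#' by the `read_*` functions, plus a ready-to-run `config.yaml`.
#'
#' @param scn A `sim_scenario` (e.g. [make_default_scenario()]).
#' @param dir Output directory (created if needed).
#' @param horizon,n_agents,seed Run configuration recorded in the config.
#' @return The config path, invisibly.
#' @export
write_scenario <- function(scn, dir, horizon = 15,
                           n_agents = scn$n_agents %||% 10000,
                           seed = scn$seed %||% 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pop_distribution(scn$init_dist, file.path(dir, "init_dist.csv"))
  write_entry_schedule(scn$entry, file.path(dir, "entry_counts.csv"),
                       file.path(dir, "entry_dist.csv"))
  write_tpm_set(scn$tpms, file.path(dir, "tpms.csv"))
  write_life_table(scn$lt, file.path(dir, "life_table.csv"))
  write_diabetic_mortality(scn$dm, file.path(dir, "mortality.csv"))
  write_bmi_drift(scn$drift, file.path(dir, "drift.csv"))
  cfg <- list(
    start_year = scn$start_year, horizon = horizon, n_agents = n_agents,
    agent_scale = scn$agent_scale, seed = seed,
    paths = list(init_dist = "init_dist.csv",
                 entry_counts = "entry_counts.csv",
                 entry_dist = "entry_dist.csv", tpms = "tpms.csv",
                 life_table = "life_table.csv", mortality = "mortality.csv",
                 drift = "drift.csv")
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

run_manifest <- function(cfg_path, cfg, extra = list()) {
  root <- dirname(normalizePath(cfg_path))
  files <- unlist(cfg$config$paths)
  files <- ifelse(grepl("^([/~]|[A-Za-z]:)", files), files,
                  file.path(root, files))
  c(list(
    package = "prediasim",
    version = as.character(utils::packageVersion("prediasim")),
    seed = cfg$seed,
    horizon = cfg$horizon,
    n_agents = cfg$n_agents,
    agent_scale = cfg$scenario$agent_scale,
    config = normalizePath(cfg_path),
    input_md5 = as.list(tools::md5sum(files))
  ), extra)
}

#' Run a simulation from a config file
#'
#' Loads the scenario, builds the baseline population, simulates the
#' configured horizon (with the configured intervention, if any) and writes
#' `outcomes.csv` plus a `manifest.json` recording the seed, input file
#' hashes and package version -- enough to reproduce the run bit-identically.
#'
#' @param config_path YAML config (see [read_scenario_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The `sim_result`, invisibly.
#' @export
cli_simulate <- function(config_path, out_dir) {
  cfg <- read_scenario_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- build_initial_population(
    cfg$scenario$init_dist, cfg$n_agents,
    seed = substream_seed(cfg$seed, 0L, "baseline"))
  res <- simulate_horizon(pop, cfg$scenario, cfg$horizon, cfg$seed,
                          intervention = cfg$intervention)
  stopifnot(!anyNA(res$outcomes$new_cases), all(res$outcomes$new_cases >= 0),
            all(res$outcomes$deaths >= 0))
  readr::write_csv(res$outcomes, file.path(out_dir, "outcomes.csv"))
  jsonlite::write_json(run_manifest(config_path, cfg),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Run a paired cost-effectiveness comparison from a config file
#'
#' For each requested age band, runs a paired control/intervention
#' simulation and writes a comparison table (averted diabetes and deaths,
#' mean diabetes-free-survival gain, intervention cost, aversion savings and
#' total savings, with monetary columns also given in $1000) plus a
#' manifest.
#'
#' @param config_path YAML config; must contain an `intervention` block.
#' @param out_dir Output directory.
#' @param bands List of age bands (default 25-65, 35-65, 45-65, 55-65).
#' @return The comparison tibble, invisibly.
#' @export
cli_compare <- function(config_path, out_dir,
                        bands = list(c(25, 65), c(35, 65), c(45, 65),
                                     c(55, 65))) {
  cfg <- read_scenario_config(config_path)
  if (is.null(cfg$intervention)) {
    stop("config has no `intervention` block to compare", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- compare_age_bands(cfg$scenario, cfg$intervention, bands = bands,
                           horizon = cfg$horizon, n_agents = cfg$n_agents,
                           seed = cfg$seed,
                           benefit_per_case = cfg$benefit_per_case,
                           discount_rate = cfg$discount_rate)
  stopifnot(!anyNA(tab$total_savings),
            all(abs(tab$total_savings -
                      (tab$aversion_savings - tab$intervention_cost)) < 1e-6))
  tab$intervention_cost_k <- tab$intervention_cost / 1000
  tab$aversion_savings_k <- tab$aversion_savings / 1000
  tab$total_savings_k <- tab$total_savings / 1000
  readr::write_csv(tab, file.path(out_dir, "comparison.csv"))
  jsonlite::write_json(run_manifest(config_path, cfg),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
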