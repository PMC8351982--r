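# Configuration loading, pipeline commands, and tabular output writing.

CONFIG_KEYS <- c("cycle_years", "n_cycles", "start_age", "discount_rate",
                 "thresholds", "hti_price", "hti_efficacy",
                 "background_mortality", "seed", "n_iterations",
                 "n_replicates", "population", "parameter_table")

#' Load a run configuration
#'
#' Reads a YAML configuration and returns the model configuration, the
#' adjunct efficacy spec, the population spec and run sizes. An empty (or
#' `NULL`) file yields the full base case: half-year cycles, 60 cycles,
#' entry age 45, 1.5\% discounting, $10,000 adjunct price, uniform
#' \[0, 1\] RRR, thresholds $50k/$100k/$150k per QALY, and 15,925
#' procedures/year for 10 years.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return List of class `run_config`: `config` ([model_config()]), `hti`
#'   ([hti_efficacy()]), `pop` ([population_spec()]), `specs`
#'   ([load_parameter_table()]), `seed`, `n_iterations`, `n_replicates`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  grab <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  bg <- grab("background_mortality", list())
  if (is.logical(bg)) bg <- list(enabled = bg)
  lt <- if (!is.null(bg$table_path)) load_life_table(bg$table_path) else NULL
  cfg <- tryCatch(
    model_config(
      cycle_years = grab("cycle_years", 0.5),
      n_cycles = grab("n_cycles", 60L),
      start_age = grab("start_age", 45),
      discount_rate = grab("discount_rate", 0.015),
      hti_price = grab("hti_price", 10000),
      thresholds = unlist(grab("thresholds", c(50000, 100000, 150000))),
      background_mortality = if (!is.null(bg$enabled)) bg$enabled else TRUE,
      life_table = lt),
    error = function(e) stop("invalid configuration: ", conditionMessage(e),
                             call. = FALSE))
  he <- grab("hti_efficacy", list())
  hti <- hti_efficacy(
    family = if (!is.null(he$family)) he$family else "uniform01",
    mu = if (!is.null(he$mu)) he$mu else 0.5,
    sigma = if (!is.null(he$sigma)) he$sigma else 0.15,
    fixed_value = if (!is.null(he$fixed_value)) he$fixed_value else 0.5)
  po <- grab("population", list())
  pop <- population_spec(
    procedures_per_year = if (!is.null(po$procedures_per_year))
      po$procedures_per_year else 15925,
    horizon_years = if (!is.null(po$horizon_years)) po$horizon_years else 10)
  specs <- load_parameter_table(grab("parameter_table", NULL))
  structure(list(config = cfg, hti = hti, pop = pop, specs = specs,
                 seed = grab("seed", 1L),
                 n_iterations = as.integer(grab("n_iterations", 7000L)),
                 n_replicates = as.integer(grab("n_replicates", 100L))),
            class = "run_config")
}

#' Write analysis outputs deterministically
#'
#' Data frames are written as CSV (fixed column order, full precision,
#' no row names); everything else as JSON. Identical inputs produce
#' byte-identical files.
#'
#' @param results Named list; each element a data.frame (`<name>.csv`) or
#'   a list (`<name>.json`).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  files
}

summary_to_list <- function(s) {
  list(cost_hti = s$cost_hti, cost_std = s$cost_std,
       qaly_hti = s$qaly_hti, qaly_std = s$qaly_std, icer = s$icer,
       ceac = as.list(setNames(s$ceac$probability,
                               paste0("threshold_", s$ceac$threshold))),
       evpi_population = as.list(setNames(s$evpi$population,
                                          paste0("threshold_",
                                                 s$evpi$threshold))))
}

#' Run a named pipeline stage end to end
#'
#' Executes one analysis (`"base-case"`, `"elasticity"`, `"tornado"`,
#' `"scenarios"`, `"evppi"`, or `"validate"`) from a run configuration,
#' writes its CSV/JSON outputs plus a manifest to `out_dir`, and returns
#' the manifest.
#'
#' @param command Pipeline stage name.
#' @param run A [load_config()] result (or a YAML path).
#' @param out_dir Output directory.
#' @param seed,n_iterations,n_replicates Optional overrides of the
#'   configured values.
#' @return The manifest (list), invisibly.
#' @export
run_analysis <- function(command = c("base-case", "elasticity", "tornado",
                                     "scenarios", "evppi", "validate"),
                         run = load_config(), out_dir = ".",
                         seed = NULL, n_iterations = NULL,
                         n_replicates = NULL) {
  command <- match.arg(command)
  if (is.character(run)) run <- load_config(run)
  stopifnot(inherits(run, "run_config"))
  if (is.null(seed)) seed <- run$seed
  if (is.null(n_iterations)) n_iterations <- run$n_iterations
  if (is.null(n_replicates)) n_replicates <- run$n_replicates
  cfg <- run$config
  results <- switch(
    command,
    "base-case" = {
      rs <- replicate_psa(run$specs, run$hti, cfg, n_iterations,
                          n_replicates, seed = seed, pop = run$pop)
      psa <- run_psa(run$specs, run$hti, cfg, n_iterations, seed = seed)
      sm <- rs$summary
      list(summary = lapply(split(sm[, c("mean", "cri_low", "cri_high")],
                                  sm$statistic), as.list),
           psa_draws = as.data.frame(psa),
           ceac = data.frame(
             threshold = cfg$thresholds,
             probability = sm$mean[match(paste0("ceac_", cfg$thresholds),
                                         sm$statistic)],
             cri_low = sm$cri_low[match(paste0("ceac_", cfg$thresholds),
                                        sm$statistic)],
             cri_high = sm$cri_high[match(paste0("ceac_", cfg$thresholds),
                                          sm$statistic)]),
           evpi = data.frame(
             threshold = cfg$thresholds,
             per_person = sm$mean[match(paste0("evpi_pp_", cfg$thresholds),
                                        sm$statistic)],
             population = sm$mean[match(paste0("evpi_pop_", cfg$thresholds),
                                        sm$statistic)]))
    },
    "elasticity" = {
      pts <- lapply(cfg$thresholds, function(l) {
        ec <- elasticity_curve(run$specs, cfg, lambda = l,
                               n_iterations = n_iterations, seed = seed)
        cbind(threshold = l, ec$points, fitted_slope = ec$fitted_slope)
      })
      list(elasticity = do.call(rbind, pts))
    },
    "tornado" = {
      to <- tornado_one_way(run$specs, run$hti, cfg,
                            n_iterations = n_iterations, seed = seed)
      list(tornado = as.data.frame(to))
    },
    "scenarios" = {
      sc <- scenario_rrr(run$specs, cfg, n_iterations = n_iterations,
                         seed = seed, pop = run$pop)
      list(summary = lapply(sc, summary_to_list))
    },
    "evppi" = {
      ev <- evppi(run$specs,
                  hti_efficacy("bounded_normal", mu = 0.5, sigma = 0.15),
                  cfg, focal_id = 4L, n_outer = max(2L, n_replicates),
                  n_inner = n_iterations, lambda = cfg$thresholds,
                  seed = seed, pop = run$pop)
      list(evpi = data.frame(
        threshold = ev$lambda, per_person = ev$per_person,
        population = ev$population))
    },
    "validate" = {
      set.seed(seed)
      checks <- lapply(seq_len(3), function(j) {
        tab <- random_parameter_table()
        draw <- sample_draw(tab, run$hti)
        cohort_vs_microsim_check(draw, cfg, n_patients = n_iterations)
      })
      rep <- do.call(rbind, checks)
      if (!all(rep$pass)) stop("validation failed:\n",
                               paste(utils::capture.output(print(rep)),
                                     collapse = "\n"))
      list(validation = rep)
    })
  files <- write_outputs(results, out_dir)
  manifest <- list(
    command = command, seed = seed, n_iterations = n_iterations,
    n_replicates = n_replicates,
    horizon_years = cfg$n_cycles * cfg$cycle_years,
    software_version = as.character(utils::packageVersion("coilcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  missing <- !file.exists(files)
  if (any(missing)) stop("outputs missing: ",
                         paste(files[missing], collapse = ", "))
  invisible(manifest)
}
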