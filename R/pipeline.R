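#' Assemble a pipeline run configuration
#'
#' @param mode "synthetic" (generate a survey from `population`) or
#'   "external-csv" (read `diaries_path`, `individuals_path`,
#'   `composition_path`).
#' @param outdir Output directory for the artifact bundle.
#' @param seed Integer seed; mandatory in synthetic mode (overrides the
#'   seed inside `population`).
#' @param population A [population_config()] (synthetic mode).
#' @param scenarios Named list of [scenario_spec()]s.
#' @param schedule A [pri_schedule()].
#' @param z Normal quantile for the significance rule.
#' @param diaries_path,individuals_path,composition_path CSV inputs for
#'   external mode.
#' @param log_level "normal" or "quiet".
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "external-csv"),
                       outdir = NULL, seed = NULL,
                       population = NULL,
                       scenarios = default_scenarios(),
                       schedule = pri_schedule(), z = 1.96,
                       diaries_path = NULL, individuals_path = NULL,
                       composition_path = NULL,
                       log_level = c("normal", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (is.null(outdir))
    stop("run_config: 'outdir' is required", call. = FALSE)
  if (mode == "synthetic") {
    if (is.null(seed))
      stop("run_config: 'seed' is mandatory in synthetic mode",
           call. = FALSE)
    if (is.null(population))
      population <- population_config(seed = seed)
    else
      population$seed <- as.integer(seed)
  } else {
    for (p in c(diaries_path, individuals_path, composition_path))
      if (is.null(p) || !file.exists(p))
        stop("run_config: external-csv mode needs existing ",
             "diaries/individuals/composition files", call. = FALSE)
  }
  structure(
    list(mode = mode, outdir = outdir, seed = seed,
         population = population, scenarios = scenarios,
         schedule = schedule, z = z, diaries_path = diaries_path,
         individuals_path = individuals_path,
         composition_path = composition_path, log_level = log_level),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat-key YAML: `mode`, `outdir`, `seed`, optional `population:`
#' overrides (any [population_config()] argument except `targets`),
#' optional `scenarios:` overrides (`depletion`, `biofort`,
#' `wholegrain_target`, `brown_target`), `z`, and the external-mode
#' paths (relative paths are resolved against the YAML file's
#' directory).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^/", p)) file.path(base, p) else p
  }
  pop <- NULL
  if (identical(y$mode, "synthetic") || is.null(y$mode)) {
    pop_args <- y$population
    if (is.null(pop_args)) pop_args <- list()
    pop_args$seed <- y$seed
    pop <- do.call(population_config, pop_args)
  }
  sc_args <- y$scenarios
  scenarios <- if (is.null(sc_args)) default_scenarios()
    else do.call(default_scenarios, sc_args)
  run_config(
    mode = if (is.null(y$mode)) "synthetic" else y$mode,
    outdir = resolve(y$outdir), seed = y$seed, population = pop,
    scenarios = scenarios,
    z = if (is.null(y$z)) 1.96 else y$z,
    diaries_path = resolve(y$diaries_path),
    individuals_path = resolve(y$individuals_path),
    composition_path = resolve(y$composition_path),
    log_level = if (is.null(y$log_level)) "normal" else y$log_level
  )
}

#' Write a simulated survey as CSV files
#'
#' @param sim Result of [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$diaries, file.path(dir, "diaries.csv"),
                   row.names = FALSE)
  write_composition_table(sim$composition,
                          file.path(dir, "composition.csv"))
  invisible(dir)
}

pipeline_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(...)
}

#' Run the full analysis pipeline
#'
#' Generate (or load) the survey, estimate intakes, assess adequacy,
#' project the scenarios, and write the artifact bundle: per-individual
#' intakes, the intake+adequacy table, the wheat/rice component summary,
#' the cereal-contribution table, the significance table (half-widths,
#' cumulative-scenario deltas, flags), the figure-ready adequacy series,
#' the Kruskal-Wallis comparisons, and a JSON manifest (seed, config
#' hash, package version) sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `fit` (the [iron_intake()] object),
#'   `projection` (the [predict.iron_intake()] object), `files` (paths
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "synthetic") {
    pipeline_log(config, "stage simulate: seed ", config$population$seed)
    sim <- simulate_survey(config$population)
    individuals <- sim$individuals
    diaries <- sim$diaries
    composition <- sim$composition
  } else {
    pipeline_log(config, "stage load: reading external CSVs")
    individuals <- utils::read.csv(config$individuals_path,
                                   stringsAsFactors = FALSE)
    diaries <- utils::read.csv(config$diaries_path,
                               stringsAsFactors = FALSE)
    composition <- load_composition_table(config$composition_path)
  }
  pipeline_log(config, "stage intake: ", nrow(individuals),
               " individuals, ", nrow(diaries), " diary records")
  fit <- iron_intake(diaries, composition, individuals, config$schedule)
  pipeline_log(config, "stage scenarios: ",
               length(config$scenarios), " scenarios")
  proj <- stats::predict(fit, scenarios = config$scenarios, z = config$z)

  files <- c(
    intakes = "intakes.csv",
    table1 = "table1_intake_adequacy.csv",
    table2 = "table2_wheat_rice.csv",
    table3 = "table3_cereal_contribution.csv",
    table4 = "table4_significance.csv",
    figures = "figure_adequacy_series.csv",
    tests = "kruskal_wallis_tests.csv",
    manifest = "manifest.json"
  )
  files <- vapply(files, function(f) file.path(config$outdir, f), "")

  utils::write.csv(fit$intakes, files["intakes"], row.names = FALSE)
  utils::write.csv(pipeline_table1(fit), files["table1"],
                   row.names = FALSE)
  utils::write.csv(pipeline_table2(fit), files["table2"],
                   row.names = FALSE)
  utils::write.csv(pipeline_table3(fit), files["table3"],
                   row.names = FALSE)
  utils::write.csv(pipeline_table4(proj, config$scenarios),
                   files["table4"], row.names = FALSE)
  utils::write.csv(proj$figure_series, files["figures"],
                   row.names = FALSE)
  utils::write.csv(fit$tests, files["tests"], row.names = FALSE)

  cfg_file <- tempfile()
  saveRDS(config[c("mode", "seed", "z")], cfg_file)
  manifest <- list(
    package = "ironintake",
    version = as.character(utils::packageVersion("ironintake")),
    mode = config$mode,
    seed = config$seed,
    z = config$z,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_individuals = nrow(individuals),
    n_diary_records = nrow(diaries),
    scenarios = names(config$scenarios)
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  pipeline_log(config, "stage report: bundle written to ", config$outdir)
  invisible(list(fit = fit, projection = proj, files = files))
}

# intake + adequacy by group (per-cell rows only)
pipeline_table1 <- function(fit) {
  g <- fit$groups
  wide <- NULL
  for (v in c("total_g_day", "energy_kcal_day", "iron_mg_day")) {
    sub <- g[g$variable == v & g$age_class != "all", ]
    names(sub)[names(sub) %in%
                 c("mean", "sd", "median", "p5", "p95")] <-
      paste(v, c("mean", "sd", "median", "p5", "p95"), sep = "_")
    sub$variable <- NULL
    wide <- if (is.null(wide)) sub
      else merge(wide, sub[-match("n", names(sub))],
                 by = c("sex", "age_class"), sort = FALSE)
  }
  out <- merge(wide, fit$adequacy[-match("n", names(fit$adequacy))],
               by = c("sex", "age_class"), sort = FALSE)
  out[order(out$sex, match(out$age_class, age_class_labels())), ]
}

pipeline_table2 <- function(fit) {
  g <- fit$groups
  vars <- c("wheat_g_day", "wheat_kcal_day", "wheat_iron_mg_day",
            "rice_g_day", "rice_kcal_day", "rice_iron_mg_day")
  out <- g[g$variable %in% vars, ]
  out$grain <- ifelse(grepl("^wheat", out$variable), "wheat", "rice")
  out$measure <- sub("^(wheat|rice)_", "", out$variable)
  out[c("sex", "age_class", "grain", "measure", "n", "mean", "sd",
        "median", "p5", "p95")]
}

# wheat/rice contribution to cereal intake; headline percentages are
# ratio-of-group-means, mean-of-individual-ratios also emitted
pipeline_table3 <- function(fit) {
  it <- fit$intakes
  cells <- unique(it[c("sex", "age_class")])
  cells <- cells[order(cells$sex, match(cells$age_class,
                                        age_class_labels())), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- it$sex == cells$sex[i] & it$age_class == cells$age_class[i]
    s <- group_summary(it$cereal_g_day[sel])
    pos <- sel & it$cereal_g_day > 0
    cbind(data.frame(sex = cells$sex[i], age_class = cells$age_class[i],
                     stringsAsFactors = FALSE),
          s,
          data.frame(
            wheat_pct = 100 * mean(it$wheat_g_day[sel]) / s$mean,
            rice_pct = 100 * mean(it$rice_g_day[sel]) / s$mean,
            wheat_pct_mean_of_ratios =
              100 * mean(it$wheat_g_day[pos] / it$cereal_g_day[pos]),
            rice_pct_mean_of_ratios =
              100 * mean(it$rice_g_day[pos] / it$cereal_g_day[pos])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pipeline_table4 <- function(proj, scenarios) {
  last <- utils::tail(names(scenarios), 1L)
  out <- proj$results[proj$results$scenario == last,
                      c("sex", "age_class", "n", "half_width",
                        "mean_delta_vs_baseline", "significant")]
  names(out)[4:5] <- c("least_significant_delta",
                       paste0("delta_", last))
  rownames(out) <- NULL
  out
}
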