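# Pipeline orchestration: runs the analysis stages in dependency order on a
# specimen table, writes per-stage CSV artifacts, and records a manifest
# echoing the resolved configuration, the seed, and a content hash of every
# output file.

#' Build a pipeline run configuration
#'
#' @param input path to a specimen CSV, or `NULL` to simulate the default
#'   synthetic community (stage `"simulate"`).
#' @param atmosphere_path path to an atmosphere CSV, or `NULL` for the
#'   bundled/simulated series.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for every stochastic stage.
#' @param n_draws Monte-Carlo draws per species.
#' @param constants constant set from [eb_constants()].
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, atmosphere_path = NULL,
                       out_dir = tempfile("herbiwue_run_"), seed = 1,
                       n_draws = 10000, constants = eb_constants()) {
  out <- list(input = input, atmosphere_path = atmosphere_path,
              out_dir = out_dir, seed = seed, n_draws = n_draws,
              constants = constants)
  class(out) <- "run_config"
  out
}

.pipeline_stages <- c("simulate", "gsmax", "iwue", "eb", "mc", "trends",
                      "phenospace")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> gsmax -> iwue -> eb -> mc -> trends -> phenospace), writing
#' one CSV artifact per stage plus a JSON manifest with the resolved
#' configuration, the seed, per-stage record/skip counts and an md5 hash of
#' every output file. Identical configuration and seed give byte-identical
#' numeric outputs. Requesting a stage whose prerequisite columns are absent
#' (e.g. `mc` on a table without anatomy) raises an error naming the stage
#' to run first.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run; prerequisites among the requested
#'   input columns are checked, not auto-run.
#' @return list with `records` (final augmented table), `artifacts` (named
#'   file paths), `manifest` (path), and stage results (`eb`, `mc`, `trends`,
#'   `phenospace` where run).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = .pipeline_stages) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  counts <- list()
  results <- list()

  atmosphere <- if (!is.null(config$atmosphere_path)) {
    read_atmosphere_series(config$atmosphere_path)
  } else if (is.null(config$input)) {
    generate_atmosphere()
  } else {
    read_atmosphere_series()
  }

  if (!is.null(config$input)) {
    records <- read_specimen_table(config$input)
  } else if ("simulate" %in% stages) {
    records <- generate_community(atmosphere = atmosphere, seed = config$seed)
  } else {
    stop("no input table: run the 'simulate' stage first or set config$input")
  }
  val <- validate_records(records, atmosphere)
  records <- val$records
  counts$input <- list(n = nrow(records), rejected = nrow(val$rejected))
  emit <- function(name, df) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    write_specimen_table(df, path)
    artifacts[[name]] <<- path
  }
  if ("simulate" %in% stages && is.null(config$input)) {
    emit("specimens", records)
  }

  if ("gsmax" %in% stages) {
    records <- augment_gsmax(records, config$constants)
    counts$gsmax <- list(n = sum(!is.na(records$gsmax_mol)))
    emit("gsmax", records)
  }
  if ("iwue" %in% stages) {
    records <- augment_iwue(records, atmosphere,
                            a = config$constants$frac_a,
                            b = config$constants$frac_b)
    counts$iwue <- list(n = sum(!is.na(records$iwue)),
                        flagged = sum(records$ci_ca_flag, na.rm = TRUE))
    emit("iwue", records)
  }

  model <- NULL
  need_model <- any(c("eb", "mc") %in% stages)
  if (need_model) {
    training <- generate_vcmax_training(seed = config$seed)
    model <- fit_vcmax_model(training)
  }
  if (any(c("eb", "mc", "phenospace") %in% stages) &&
      !("gsmax_mol" %in% names(records))) {
    stop("stage prerequisites missing: run stage 'gsmax' first")
  }
  if ("eb" %in% stages) {
    eb <- eb_simulate(records, atmosphere, model, config$constants)
    counts$eb <- list(n = nrow(eb), skipped = attr(eb, "n_skipped"))
    emit("eb", eb)
    results$eb <- eb
  }
  if ("mc" %in% stages) {
    mc <- mc_species_responses(records, atmosphere, model,
                               n_draws = config$n_draws, seed = config$seed,
                               constants = config$constants)
    counts$mc <- list(n_species = length(unique(mc$species)),
                      n_draws = config$n_draws)
    emit("mc", mc)
    results$mc <- mc
  }
  if ("trends" %in% stages) {
    if (!("iwue" %in% names(records))) {
      stop("stage prerequisites missing: run stage 'iwue' first")
    }
    trends <- do.call(rbind, lapply(
      intersect(c("iwue", "gsmax_mmol", "stomatal_density", "amax_um2"),
                names(records)),
      function(tr) trend_table(records, tr)))
    counts$trends <- list(n = nrow(trends))
    emit("trends", trends)
    results$trends <- trends
  }
  if ("phenospace" %in% stages) {
    grid <- density_grid(records$amax_um2, records$stomatal_density)
    path <- file.path(config$out_dir, "phenospace_grid.csv")
    write_density_grid(grid, path)
    artifacts[["phenospace_grid"]] <- path
    results$phenospace <- grid
  }

  manifest <- list(
    seed = config$seed,
    n_draws = config$n_draws,
    stages = stages,
    constants = config$constants[
      !vapply(config$constants, is.function, logical(1))],
    counts = counts,
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(list(records = records, artifacts = artifacts,
         manifest = manifest_path), results)
}
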