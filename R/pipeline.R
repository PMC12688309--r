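# End-to-end pipeline driver: simulate (or load) -> describe -> model ladder
# -> mediation -> bootstrap -> report, with a seed/provenance manifest.

#' Run the full mediation analysis pipeline
#'
#' Executes the complete workflow from one configuration: generate a
#' synthetic cohort (or load one from CSV), build the descriptive
#' comparison table, fit the sequential random-intercept model ladder with
#' its AIC/BIC comparison, assemble the parallel multiple-mediator model,
#' decompose effects, and attach percentile-bootstrap confidence intervals.
#' All tables are written as CSV under `out_dir` together with a JSON run
#' manifest recording the configuration snapshot, the per-stage seeds,
#' package version, file checksums and wall-clock per stage; a rerun from
#' the same configuration reproduces the outputs bit-identically.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised keys: `outcome` (`overweight`/`obesity`), `seed`,
#'   `out_dir`, `data` (optional cohort CSV: load instead of simulate),
#'   `generator` (overrides passed to [generator_config()]),
#'   `covariates`, `quadrature_points` (outcome-equation quadrature for the
#'   ladder and path model), `temperature_column` (sensitivity switch:
#'   analyse a different per-province temperature summary, e.g. a median
#'   column, in place of `mean_temp_c`), `variance_se` (compute the SE of
#'   the province variance in the path model; default `TRUE`), and
#'   `bootstrap` (`n_reps`, `resample_size`, `quadrature_points`).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_invalid("'config' must be a list or a YAML path")
  outcome <- match.arg(config$outcome %||% "overweight",
                       c("overweight", "obesity"))
  seed <- assert_count(config$seed %||% 1L, "seed", min = 0L)
  out_dir <- config$out_dir %||% "climmed_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  covariates <- config$covariates %||% .default_covariates
  qp <- config$quadrature_points %||% 7L
  bs <- config$bootstrap %||% list()
  manifest <- list(
    package = "climmed",
    version = as.character(utils::packageVersion("climmed")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, outcome = outcome, seed = seed,
    stage_seconds = list(), outputs = character(), seeds = list(),
    checksums = list())
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      manifest$error <- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stage_seconds[[name]] <<-
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(obj, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  cohort <- stage("data", {
    if (!is.null(config$data)) {
      manifest$checksums$input <- unname(tools::md5sum(config$data))
      load_cohort_csv(config$data)
    } else {
      gen_args <- config$generator %||% list()
      gen_args$seed <- gen_args$seed %||% seed
      cfg <- do.call(generator_config, gen_args)
      manifest$seeds$generator <- cfg$seed
      sim <- simulate_cohort(cfg)
      write_cohort_csv(sim$cohort, file.path(out_dir, "cohort.csv"))
      outputs <- c(outputs, file.path(out_dir, "cohort.csv"))
      sim$cohort
    }
  })
  tc <- config$temperature_column %||% "mean_temp_c"
  if (tc != "mean_temp_c") {
    if (!tc %in% names(cohort))
      stop_invalid("temperature_column '%s' not found", tc)
    cohort$mean_temp_c <- cohort[[tc]]
  }

  stage("describe", {
    desc <- describe_by_outcome(cohort, outcome,
                                c("age", "sex", "education", "pa_level",
                                  "fv_adequate"))
    emit(desc, "descriptives.csv")
  })

  ladder <- stage("model_ladder", fit_model_ladder(cohort, outcome, qp))
  emit(ladder$table, "model_ladder.csv")

  path <- stage("mediate",
                assemble_path_model(cohort, outcome, covariates, qp,
                                    variance_se = isTRUE(config$variance_se %||% TRUE)))
  dec <- decompose_effects(path)
  emit(data.frame(
    quantity = c("a1", "a21", "a22", "b1", "b21", "b22", "c", "sigma2",
                 paste0("indirect_", names(dec$indirect)),
                 paste0("total_", names(dec$total)),
                 paste0("raw_diff_", names(dec$raw_diff))),
    value = c(path$a1, path$a21, path$a22, path$b1, path$b21, path$b22,
              path$c, path$sigma2, dec$indirect, dec$total, dec$raw_diff)),
    "effects.csv")

  boot <- stage("bootstrap", {
    bseed <- bs$seed %||% (seed + 1L)
    manifest$seeds$bootstrap <- bseed
    bootstrap_effects(cohort, outcome,
                      n_reps = bs$n_reps %||% 200L,
                      resample_size = bs$resample_size %||% NULL,
                      seed = bseed,
                      quadrature_points = bs$quadrature_points %||% 0L,
                      covariates = covariates)
  })
  emit(bootstrap_table(boot), "bootstrap_effects.csv")
  emit(as.data.frame(attr(boot, "replicates")), "bootstrap_replicates.csv")

  manifest$outputs <- outputs
  manifest$checksums$outputs <- as.list(tools::md5sum(outputs))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
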