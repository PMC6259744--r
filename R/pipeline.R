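# End-to-end orchestration: one seeded configuration drives simulation,
# kinetics, descriptors, the correlation screen, the QSPR line and the
# activity regression, and every output is written with a manifest of
# checksums so identical runs are verifiably identical.

.table_schemas <- list(
  calibration_standards = c("concentration", "peak_area"),
  time_course = c("time_h", "fa_peak_area"),
  charges = c("ester", "level", "q_C", "q_O1", "q_O2"),
  geometry = c("ester", "d_C_O2", "d_C_O1"),
  rate_fits = c("ester", "K_per_h", "r", "n_points"),
  screen = c("descriptor", "level", "quantity", "r", "n")
)

#' Read a validated delimited table
#'
#' Comma-separated, UTF-8, `"."` decimal, mandatory header row. The column
#' set is validated against a named schema and malformed numeric cells are
#' reported with their line numbers.
#'
#' @param path file to read.
#' @param schema_id one of `"calibration_standards"`, `"time_course"`,
#'   `"charges"`, `"geometry"`, `"rate_fits"`, `"screen"`.
#' @return A `data.frame` with at least the schema's columns.
#' @export
read_table <- function(path, schema_id) {
  cols <- .table_schemas[[schema_id]]
  if (is.null(cols))
    ek_stop(paste0("unknown schema '", schema_id, "'"), "esterkin_schema_error")
  if (!file.exists(path))
    ek_stop(paste0("file not found: ", path), "esterkin_io_error")
  if (file.size(path) == 0L)
    ek_stop(paste0("empty input file: ", path), "esterkin_empty_input_error")
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(tab) == 0L)
    ek_stop(paste0("no data rows in ", path), "esterkin_empty_input_error")
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    ek_stop(paste0(path, " lacks column(s): ", paste(miss, collapse = ", ")),
            "esterkin_schema_error")
  numeric_cols <- setdiff(cols, c("ester", "level", "descriptor", "quantity"))
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !is.na(tab[[cn]]))
    if (length(bad))
      ek_stop(sprintf("%s: non-numeric '%s' at line(s) %s", path, cn,
                      paste(bad + 1L, collapse = ", ")),
              "esterkin_schema_error")
    tab[[cn]] <- v
  }
  tab
}

#' Write a table at full double precision
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param table a `data.frame`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  dir <- dirname(path)
  if (!dir.exists(dir))
    ek_stop(paste0("output directory does not exist: ", dir),
            "esterkin_io_error")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Configure a pipeline run
#'
#' Validates every setting up front; unknown arguments are rejected rather
#' than silently ignored.
#'
#' @param seed master integer seed; per-stage seeds are derived from it so
#'   stages are independently reproducible.
#' @param noise_sd_frac multiplicative peak-area noise fraction.
#' @param time_grid solvolysis sampling times (hours), starting at 0.
#' @param esters named list of [ester_record()]s to simulate.
#' @param descriptor_levels theory/solvation levels to tabulate.
#' @param output_dir directory for the run's output files.
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @param ... unused; supplying any unknown setting is an error.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, noise_sd_frac = 0.01,
                            time_grid = c(0, 2, 4, 6, 8, 24),
                            esters = fa_esters(),
                            descriptor_levels = table1_levels(),
                            output_dir = file.path(tempdir(), "esterkin_run"),
                            log_level = c("info", "quiet"), ...) {
  extra <- list(...)
  if (length(extra))
    ek_stop(paste0("unknown configuration key(s): ",
                   paste(names(extra), collapse = ", ")),
            "esterkin_schema_error")
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(noise_sd_frac, "noise_sd_frac", nonnegative = TRUE)
  validate_times(time_grid)
  if (!length(esters) || !all(vapply(esters, inherits, logical(1), "ester_record")))
    ek_stop("'esters' must be a list of ester_record objects",
            "esterkin_validation_error")
  bad <- setdiff(descriptor_levels, table1_levels())
  if (length(bad))
    ek_stop(paste0("unknown descriptor level(s): ", paste(bad, collapse = "; ")),
            "esterkin_validation_error")
  log_level <- match.arg(log_level)
  structure(list(seed = as.integer(seed), noise_sd_frac = noise_sd_frac,
                 time_grid = time_grid, esters = esters,
                 descriptor_levels = descriptor_levels,
                 output_dir = output_dir, log_level = log_level),
            class = "pipeline_config")
}

#' Run the whole solvolysis/QSPR pipeline
#'
#' Chains every stage under one seeded configuration: simulate calibration
#' standards and fit the calibration line; simulate each ester's time
#' course, quantify FA, apply the mass balance and fit the rate constant;
#' build the descriptor table from the packaged charges and geometry;
#' screen descriptors against the measured (fixture) rate constants; fit
#' the single-descriptor QSPR line on the top-ranked descriptor; simulate
#' activity data and fit the activity multiple regression. All tables are
#' written to `config$output_dir` together with a JSON manifest of inputs,
#' seeds, package version and per-file md5 checksums — identical
#' configurations give identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (class `pipeline_manifest`), with the
#'   fitted objects attached as attribute `"fits"`.
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(pipeline_config(seed = 1))
#' man$outputs
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    ek_stop("'config' must come from pipeline_config()",
            "esterkin_validation_error")
  say <- function(...) if (config$log_level == "info") message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, esterkin_error = function(e)
      ek_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              class(e)[1]))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  # one master seed, sub-streamed per stage so stages re-run identically
  seeds <- list(calibration = config$seed,
                time_course = config$seed + seq_along(config$esters),
                activity = config$seed + length(config$esters) + 1L)

  say("stage simulate+fit-calibration (seed %d)", seeds$calibration)
  standards <- stage("simulate-calibration",
    simulate_calibration(noise_sd_frac = config$noise_sd_frac,
                         seed = seeds$calibration))
  curve <- stage("fit-calibration", fit_calibration(standards))
  write_table(standards, file.path(config$output_dir, "calibration_standards.csv"))

  say("stage fit-kinetics (%d esters)", length(config$esters))
  rate_fits <- list()
  solvolysis <- list()
  for (i in seq_along(config$esters)) {
    es <- config$esters[[i]]
    tc <- stage("simulate-time-course",
      simulate_time_course(es, times = config$time_grid, calibration = curve,
                           noise_sd_frac = config$noise_sd_frac,
                           seed = seeds$time_course[i]))
    series <- stage("quantify", suppressWarnings(
      ester_concentration(quantify_fa(tc$fa_peak_area, curve),
                          c0 = initial_concentration(es),
                          times = tc$time_h)))
    rate_fits[[es$name]] <- stage("fit-rate", fit_rate_constant(series))
    solvolysis[[es$name]] <- solvolysis_percentage(series)
    write_table(tc, file.path(config$output_dir,
                              paste0("timecourse_", es$name, ".csv")))
  }
  rate_tab <- data.frame(
    ester = names(rate_fits),
    K_per_h = vapply(rate_fits, `[[`, numeric(1), "K"),
    r = vapply(rate_fits, `[[`, numeric(1), "r"),
    n_points = vapply(rate_fits, `[[`, integer(1), "n_points"))
  write_table(rate_tab, file.path(config$output_dir, "rate_fits.csv"))

  say("stage build-descriptors (%d levels)", length(config$descriptor_levels))
  t1 <- load_table1()
  desc <- stage("build-descriptors", suppressWarnings(
    build_descriptor_table(t1$charges, t1$geometry,
                           steric = t1$esters$steric_hindrance,
                           clogp = t1$esters$cLogP,
                           levels = config$descriptor_levels,
                           annotations = t1$annotations)))
  write_table(desc, file.path(config$output_dir, "descriptors.csv"))

  say("stage screen + fit-qspr (printed table vs the measured K)")
  desc_printed <- table1_descriptors()
  screen <- stage("screen", suppressWarnings(
    screen_descriptors(desc_printed, t1$K)))
  write_table(screen, file.path(config$output_dir, "screen.csv"))
  top <- screen[1, ]
  xvals <- as.numeric(as.data.frame(desc_printed)[
    desc_printed$level == top$level & desc_printed$quantity == top$quantity,
    attr(desc_printed, "esters")])
  qspr <- stage("fit-qspr",
    fit_slr(xvals, as.numeric(t1$K), xname = top$descriptor, yname = "K"))

  say("stage simulate+fit-activity")
  act <- stage("simulate-activity",
    simulate_activity(t1$K, t1$esters$cLogP, seed = seeds$activity))
  mlr <- stage("fit-activity-mlr", fit_mlr(act[c("K", "cLogP")],
                                           act$edema_reduction))
  write_table(act, file.path(config$output_dir, "activity.csv"))

  models <- list(
    calibration = unclass(curve),
    qspr = list(descriptor = top$descriptor, slope = qspr$slope,
                intercept = qspr$intercept, se_slope = qspr$se_slope,
                se_intercept = qspr$se_intercept, r = qspr$r,
                se_est = qspr$se_est, F = qspr$F, n = qspr$n),
    activity_mlr = list(coefficients = as.list(mlr$coefficients),
                        multiple_r = mlr$multiple_r, n = mlr$n))
  jsonlite::write_json(models, file.path(config$output_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(config$output_dir), "manifest.json"))
  paths <- file.path(config$output_dir, files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("esterkin")),
    seed = config$seed,
    noise_sd_frac = config$noise_sd_frac,
    time_grid = config$time_grid,
    esters = names(config$esters),
    descriptor_levels = config$descriptor_levels,
    fixture_md5 = as.list(.table1_md5),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)), files))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d output files in %s", length(files) + 1L, config$output_dir)
  structure(manifest, class = "pipeline_manifest",
            fits = list(calibration = curve, rate_fits = rate_fits,
                        solvolysis = solvolysis, screen = screen,
                        qspr = qspr, activity_mlr = mlr))
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> esterkin %s, seed %d\n",
              x$package_version, x$seed))
  cat(sprintf("  %d outputs:\n", length(x$outputs)))
  for (f in names(x$outputs)) cat(sprintf("  %s  %s\n", x$outputs[[f]], f))
  invisible(x)
}
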