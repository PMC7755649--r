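# End-to-end pipeline: generate population -> calibrate model -> solve
# required Epo per patient -> life-span bin summaries -> life-span x Epo
# grid, with all outputs written as CSV plus the echoed effective config.

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [", level, "] ",
            ...)
  }
}

write_output_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full required-Epo pipeline
#'
#' Executes generate, calibrate, solve, bin and grid in sequence and writes
#' `population.csv`, `results.csv`, `bin_summary.csv`, `grid.csv` and the
#' echoed `effective_config.yaml` to the configured output directory.
#' Identical configuration and seed yield byte-identical output files. On
#' any stage failure, partially written outputs are removed and the error
#' is re-raised with the stage named.
#'
#' @param cfg A `run_config` from [load_run_config()], or `NULL` for the
#'   defaults.
#' @param output_dir Override of the configured output directory.
#' @return Invisibly, a list with the in-memory `population`, `results`,
#'   `bins`, `grid` tables and the vector of written `files`.
#' @export
run_pipeline <- function(cfg = NULL, output_dir = NULL) {
  if (is.null(cfg)) cfg <- load_run_config(NULL)
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("population.csv", "results.csv",
                                "bin_summary.csv", "grid.csv",
                                "effective_config.yaml"))
  names(files) <- c("population", "results", "bins", "grid", "config")

  stage <- "setup"
  tryCatch({
    stage <- "generate"
    log_msg(cfg, "info", "generating population (n = ", cfg$population$n,
            ")")
    seed <- cfg$population$seed %||% cfg$seed
    pop <- sample_population(cfg$population$n, specs_from_config(cfg),
                             seed = seed)

    stage <- "calibrate"
    model <- model_from_config(cfg)
    log_msg(cfg, "debug", "kappa = ", format(model$hb_per_flux))

    stage <- "solve"
    acfg <- analysis_from_config(cfg)
    log_msg(cfg, "info", "solving required Epo for ", nrow(pop),
            " patients")
    results <- solve_population(pop, model, acfg)

    stage <- "bins"
    bins <- bin_by_lifespan(results, acfg)

    stage <- "grid"
    grid <- lifespan_epo_grid(results, acfg)

    stage <- "write"
    write_output_csv(pop, files[["population"]])
    write_output_csv(results, files[["results"]])
    write_output_csv(bins, files[["bins"]])
    write_output_csv(grid, files[["grid"]])
    write_run_config(cfg, files[["config"]])
    log_msg(cfg, "info", "wrote ", length(files), " files to ", out_dir)

    invisible(list(population = pop, results = results, bins = bins,
                   grid = grid, files = files))
  }, error = function(e) {
    unlink(files[file.exists(files)])
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Read or write a trajectory CSV
#'
#' Trajectories from [simulate_rbc()] and [hematocrit_trajectory()] share
#' one CSV dialect: a `time_days` column followed by the series columns.
#'
#' @param traj A `trajectory` data.frame.
#' @param path File path.
#' @return `write_trajectory_csv()` returns the path; `read_trajectory_csv`
#'   the data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_output_csv(as.data.frame(traj), path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- utils::read.csv(path)
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Read an ESA schedule CSV
#'
#' Expects columns `time_days,concentration_increment_u_per_l`.
#'
#' @param path File path.
#' @param half_life ESA half-life in hours.
#' @return An [esa_schedule()].
#' @export
read_esa_schedule_csv <- function(path, half_life = 20) {
  x <- utils::read.csv(path)
  esa_schedule(x$time_days, x$concentration_increment_u_per_l, half_life)
}
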