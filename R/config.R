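# Configuration loading and validation. Config files are JSON or YAML with
# three blocks (population, model, analysis) plus output_dir, seed and
# log_level; absent keys take the documented defaults and unknown keys are
# rejected with the offending key named.

default_run_config <- function() {
  list(
    population = list(
      n = 6659L,
      seed = NULL,  # falls back to the top-level seed
      life_span = list(mean = 76, sd = 21, min = 33, max = 137),
      endogenous_epo = list(median = 15, q25 = 10.2, q75 = 21.1),
      esa_half_life = list(median = 20, log_sd = 0.3),
      apoptosis_sensitivity = list(median = 30, log_sd = 0.4),
      maturation_factor = list(median = 0.5, log_sd = 0.4)
    ),
    model = list(
      stem_influx = 1,
      proliferation_rate = 0.7,
      apoptosis_max = 0.35,
      hill_exponent = 2,
      cfu_residence = 6,
      proliferation_window = 5,
      maturation_delay = 3,
      epo_cap = 10000,
      hct_per_hb = 3.0,
      calibration = list(life_span = 120, epo = 15, hb = 14.0),
      neocytolysis = list(enabled = FALSE, age_cutoff = 14,
                          epo_threshold = 10, extra_rate = 0.05)
    ),
    analysis = list(
      hb_lo = 10.49, hb_hi = 10.51,
      lifespan_bin_width = 10,
      epo_bin_start = 5, epo_bin_width = 10,
      min_cell_count = 25L,
      clamp_negative_delta = TRUE
    ),
    output_dir = "erythrosim_output",
    seed = 1L,
    log_level = "info"
  )
}

# Recursively merge user values over defaults, erroring on unknown keys.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config error: `", paste(path, collapse = "."),
         "` must be a block, not a scalar")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("config error: unknown key `",
         paste(c(path, unknown[1]), collapse = "."), "`")
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      # [k]<- with list() so an explicit null keeps the key present
      defaults[k] <- list(user[[k]])
    }
  }
  defaults
}

check_that <- function(ok, key, msg) {
  if (!isTRUE(ok)) stop("config error: `", key, "` ", msg)
}

validate_run_config <- function(cfg) {
  pop <- cfg$population
  check_that(is.numeric(pop$n) && pop$n >= 1, "population.n",
             "must be an integer >= 1")
  ls <- pop$life_span
  check_that(ls$min < ls$mean && ls$mean < ls$max, "population.life_span",
             "must satisfy min < mean < max")
  check_that(ls$sd > 0, "population.life_span.sd", "must be positive")
  ep <- pop$endogenous_epo
  check_that(0 < ep$q25 && ep$q25 < ep$median && ep$median < ep$q75,
             "population.endogenous_epo",
             "must satisfy 0 < q25 < median < q75")
  for (blk in c("esa_half_life", "apoptosis_sensitivity",
                "maturation_factor")) {
    b <- pop[[blk]]
    check_that(b$median > 0 && b$log_sd > 0, paste0("population.", blk),
               "must have positive median and log_sd")
  }
  m <- cfg$model
  check_that(m$epo_cap > 0, "model.epo_cap", "must be positive")
  check_that(m$hill_exponent >= 1, "model.hill_exponent", "must be >= 1")
  check_that(all(c(m$stem_influx, m$hct_per_hb) > 0) &&
               all(c(m$proliferation_rate, m$apoptosis_max, m$cfu_residence,
                     m$proliferation_window, m$maturation_delay) >= 0),
             "model", "rates and durations must be non-negative")
  cal <- m$calibration
  check_that(all(c(cal$life_span, cal$epo, cal$hb) > 0), "model.calibration",
             "anchor values must be positive")
  an <- cfg$analysis
  check_that(an$hb_lo < an$hb_hi, "analysis.hb_lo", "must be below hb_hi")
  check_that(an$lifespan_bin_width > 0, "analysis.lifespan_bin_width",
             "must be positive")
  check_that(an$epo_bin_width > 0, "analysis.epo_bin_width",
             "must be positive")
  check_that(an$min_cell_count >= 1, "analysis.min_cell_count",
             "must be >= 1")
  check_that(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
             "must be a single integer")
  check_that(cfg$log_level %in% c("debug", "info", "warn", "error"),
             "log_level", "must be one of debug/info/warn/error")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration file,
#' fills in documented defaults for absent keys, rejects unknown keys, and
#' validates every constraint, naming the offending key in the error. An
#' empty file yields the full default configuration.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @seealso [run_pipeline()], [write_run_config()]
#' @export
load_run_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else {
      # keep bare y/n keys (e.g. population.n) as strings rather than YAML
      # 1.1 booleans, while still reading yes/no/true/false values as
      # logicals
      yn <- function(x) {
        if (x %in% c("y", "Y", "n", "N")) x
        else x %in% c("yes", "Yes", "YES", "true", "True", "TRUE",
                      "on", "On", "ON")
      }
      yaml::read_yaml(path, handlers = list("bool#yes" = yn,
                                            "bool#no" = yn))
    }
  }
  cfg <- merge_config(default_run_config(), user)
  cfg$population$n <- as.integer(cfg$population$n)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$population$seed))
    cfg$population$seed <- as.integer(cfg$population$seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write the effective configuration to a file
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @param path Destination (`.json` or `.yaml`).
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# Build module-level objects from a run_config.
specs_from_config <- function(cfg) {
  pop <- cfg$population
  default_population_specs(
    life_span_mean = pop$life_span$mean, life_span_sd = pop$life_span$sd,
    life_span_min = pop$life_span$min, life_span_max = pop$life_span$max,
    epo_median = pop$endogenous_epo$median,
    epo_q25 = pop$endogenous_epo$q25, epo_q75 = pop$endogenous_epo$q75,
    esa_half_life = lognorm_spec(log(pop$esa_half_life$median),
                                 pop$esa_half_life$log_sd),
    apoptosis_sensitivity =
      lognorm_spec(log(pop$apoptosis_sensitivity$median),
                   pop$apoptosis_sensitivity$log_sd),
    maturation_factor = lognorm_spec(log(pop$maturation_factor$median),
                                     pop$maturation_factor$log_sd))
}

model_from_config <- function(cfg) {
  m <- cfg$model
  mod <- model_params(stem_influx = m$stem_influx,
                      proliferation_rate = m$proliferation_rate,
                      apoptosis_max = m$apoptosis_max,
                      hill_exponent = m$hill_exponent,
                      cfu_residence = m$cfu_residence,
                      proliferation_window = m$proliferation_window,
                      maturation_delay = m$maturation_delay,
                      epo_cap = m$epo_cap,
                      hct_per_hb = m$hct_per_hb,
                      neocytolysis = m$neocytolysis)
  calibrate_kappa(mod, m$calibration$life_span, m$calibration$epo,
                  m$calibration$hb)
}

analysis_from_config <- function(cfg) {
  a <- cfg$analysis
  analysis_config(hb_lo = a$hb_lo, hb_hi = a$hb_hi,
                  lifespan_bin_width = a$lifespan_bin_width,
                  epo_bin_start = a$epo_bin_start,
                  epo_bin_width = a$epo_bin_width,
                  min_cell_count = a$min_cell_count,
                  clamp_negative_delta = a$clamp_negative_delta)
}
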