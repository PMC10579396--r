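# Configuration and output serialization --------------------------------------

CONFIG_BLOCKS <- c("parameters", "copy_numbers", "geometry", "scenario",
                   "task", "seed", "out_dir")

#' Assemble a run configuration
#'
#' @param params A [parameter_set()].
#' @param targets A [copy_numbers()].
#' @param geom A [geometry()].
#' @param scenario Scenario name(s).
#' @param knobs Scenario knobs.
#' @param task Task name (informational; e.g. `"steady"`, `"dispersion"`,
#'   `"diagram"`, `"threshold"`, `"sample"`, `"simulate"`).
#' @param task_options Named list of task options.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return An object of class `"cdc42_config"`.
#' @export
run_config <- function(params, targets, geom, scenario = "WT", knobs = list(),
                       task = "steady", task_options = list(), seed = 1L,
                       out_dir = ".") {
  structure(list(parameters = params, copy_numbers = targets, geometry = geom,
                 scenario = list(name = scenario, knobs = knobs),
                 task = list(name = task, options = task_options),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cdc42_config")
}

#' Write a configuration to JSON
#'
#' Keys are the symbol names used throughout the model (`k_D`, `k_tD`, ...,
#' `D_c`, `D_m`, `N_Cdc42`, ..., `R`); numbers are written in full double
#' precision so that a save/load round trip is lossless.
#'
#' @param config A [run_config()] (or a bare [parameter_set()], which is
#'   wrapped with default blocks).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "cdc42_params"))
    config <- run_config(config, copy_numbers(), geometry(2.5))
  stopifnot(inherits(config, "cdc42_config"))
  x <- list(
    parameters = c(as.list(config$parameters$rates),
                   list(D_c = config$parameters$D_c,
                        D_m = as.list(config$parameters$D_m))),
    copy_numbers = as.list(unclass(config$copy_numbers)),
    geometry = list(R = config$geometry$R),
    scenario = config$scenario,
    task = config$task,
    seed = config$seed,
    out_dir = config$out_dir)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a configuration from JSON
#'
#' Unknown top-level keys and unknown rate names are rejected with an error
#' naming the offending key; omitted blocks are filled with defaults
#' (`D_c = 10`, `D_m = 0.01`, `R = 2.5`, WT scenario, zero copy numbers) and
#' the names of defaulted values are recorded in the `defaulted` attribute.
#'
#' @param path JSON file written by [save_config()] or hand-authored.
#' @return A [run_config()] object with attribute `defaulted`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), CONFIG_BLOCKS)
  if (length(unknown))
    stop("load_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaulted <- character(0)
  pb <- x$parameters
  if (is.null(pb)) stop("load_config: missing 'parameters' block",
                        call. = FALSE)
  rate_keys <- intersect(names(pb), RATE_NAMES)
  extra <- setdiff(names(pb), c(RATE_NAMES, "D_c", "D_m"))
  if (length(extra))
    stop("load_config: unknown parameter key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (k in rate_keys)
    if (!is.numeric(pb[[k]]) || pb[[k]] < 0)
      stop("load_config: rate '", k, "' must be a nonnegative number",
           call. = FALSE)
  if (is.null(pb$D_c)) { pb$D_c <- 10; defaulted <- c(defaulted, "D_c") }
  if (is.null(pb$D_m)) { pb$D_m <- 0.01; defaulted <- c(defaulted, "D_m") }
  D_m <- pb$D_m
  if (is.list(D_m)) D_m <- unlist(D_m)
  params <- do.call(parameter_set,
                    c(pb[rate_keys], list(D_c = pb$D_c, D_m = D_m)))
  cn <- x$copy_numbers
  if (is.null(cn)) { cn <- list() ; defaulted <- c(defaulted, "copy_numbers") }
  bad_cn <- setdiff(names(cn), names(PROTEIN_POOLS))
  if (length(bad_cn))
    stop("load_config: unknown copy-number key(s): ",
         paste(bad_cn, collapse = ", "), call. = FALSE)
  targets <- do.call(copy_numbers, cn)
  Rg <- x$geometry$R
  if (is.null(Rg)) { Rg <- 2.5; defaulted <- c(defaulted, "R") }
  geom <- geometry(Rg)
  scen <- x$scenario
  if (is.null(scen)) { scen <- list(name = "WT", knobs = list())
                       defaulted <- c(defaulted, "scenario") }
  if (is.null(scen$knobs)) scen$knobs <- list()
  if (length(scen$knobs) && is.null(names(scen$knobs)))
    stop("load_config: scenario knobs must be named", call. = FALSE)
  task <- x$task
  if (is.null(task)) { task <- list(name = "steady", options = list())
                       defaulted <- c(defaulted, "task") }
  seed <- if (is.null(x$seed)) { defaulted <- c(defaulted, "seed"); 1L }
          else as.integer(x$seed)
  out_dir <- if (is.null(x$out_dir)) { defaulted <- c(defaulted, "out_dir"); "." }
             else x$out_dir
  cfg <- run_config(params, targets, geom, scenario = scen$name,
                    knobs = as.list(scen$knobs), task = task$name,
                    task_options = as.list(task$options), seed = seed,
                    out_dir = out_dir)
  attr(cfg, "defaulted") <- defaulted
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write analysis results with a manifest
#'
#' Tabular results (stability diagrams, dispersion tables, screening tables,
#' metric time series) are written as CSV; scalar results as JSON; and a
#' `manifest.json` records the configuration hash, seed, package version and
#' the files written. File naming is deterministic.
#'
#' @param results Named list of result objects. Supported classes:
#'   `cdc42_diagram`, `cdc42_dispersion`, `cdc42_steady`, `cdc42_trajectory`,
#'   data frames, and plain lists of scalars.
#' @param out_dir Output directory (created if missing).
#' @param config Optional [run_config()] recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, config = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "cdc42_diagram")) {
      fp <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(obj$cells, fp, row.names = FALSE)
    } else if (inherits(obj, "cdc42_dispersion")) {
      fp <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(obj$modes, fp, row.names = FALSE)
    } else if (inherits(obj, "cdc42_steady")) {
      fp <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(list(c = as.list(obj$point$c),
                                m = as.list(obj$point$m),
                                residual_f = obj$residual_f,
                                residual_g = obj$residual_g,
                                converged = obj$converged),
                           fp, auto_unbox = TRUE, digits = NA)
    } else if (inherits(obj, "cdc42_trajectory")) {
      fp <- file.path(out_dir, paste0(nm, "_metrics.csv"))
      utils::write.csv(obj$metrics, fp, row.names = FALSE)
      files <- c(files, fp)
      final <- obj$states[[length(obj$states)]]
      fp <- file.path(out_dir, paste0(nm, "_final_membrane.csv"))
      utils::write.csv(data.frame(theta = final$grid$theta_centers, final$M),
                       fp, row.names = FALSE)
      files <- c(files, fp)
      # final bulk fields in long format with named dimensions
      fp <- file.path(out_dir, paste0(nm, "_final_bulk.csv"))
      g <- final$grid
      long <- data.frame(
        r = rep(rep(g$r_centers, g$n_theta), 3),
        theta = rep(rep(g$theta_centers, each = g$n_r), 3),
        species = rep(CYT_SPECIES, each = g$n_r * g$n_theta),
        concentration = as.numeric(final$C))
      utils::write.csv(long, fp, row.names = FALSE)
    } else if (is.data.frame(obj)) {
      fp <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(obj, fp, row.names = FALSE)
    } else {
      fp <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, fp, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    files <- c(files, fp)
  }
  manifest <- list(
    package = "cdc42rd",
    version = as.character(utils::packageVersion("cdc42rd")),
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    seed = if (!is.null(config)) config$seed else NA,
    files = basename(unique(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
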