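#' Load a configuration file
#'
#' Reads a flat `key: value` YAML document. Scalar keys named after
#' [sim_params()] fields override the defaults; the grid keys
#' `disruption_levels`, `durations`, `replicates` and `seed_base` define a
#' sweep. Unknown keys are rejected with the offending name.
#'
#' @param path Path to the configuration file.
#' @return List with `params` (a `sim_params`) and `sweep` (a `sweep_spec`,
#'   or `NULL` when no grid keys are present).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  sweep_keys <- c("disruption_levels", "durations", "replicates", "seed_base")
  unknown <- setdiff(names(cfg), c(param_names(), sweep_keys))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  pkeys <- intersect(names(cfg), param_names())
  for (k in pkeys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1)
      stop("configuration key '", k, "' must be a single number")
  }
  params <- do.call(sim_params, cfg[pkeys])
  sweep <- NULL
  if (any(sweep_keys %in% names(cfg))) {
    args <- cfg[intersect(names(cfg), sweep_keys)]
    args$base_params <- params
    args$preference_mutation <- params$preference_mutation
    sweep <- do.call(sweep_spec, args)
  }
  list(params = params, sweep = sweep)
}

#' Write a configuration file
#'
#' Serialises a parameter set to the flat YAML form read by
#' [load_config()]; the round trip is lossless field by field.
#'
#' @param p A `sim_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  validate_params(p)
  fields <- unclass(p)
  fields <- fields[!vapply(fields, is.null, logical(1))]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Write results to disk
#'
#' Sweep tables are written as CSV with a stable column order and empty
#' fields (not sentinel numbers) for observables absent after extinction;
#' single runs are written as JSON (parameters, schedule, records and
#' outcome; the final population is omitted).
#'
#' @param x A sweep table (data frame) or a `sim_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "sim_run")) {
    payload <- list(params = unclass(x$params)[
                      !vapply(unclass(x$params), is.null, logical(1))],
                    schedule = unclass(x$schedule),
                    seed = x$seed,
                    extinct = x$extinct,
                    extinction_time = x$extinction_time,
                    records = x$records,
                    generation_time_estimate = x$generation_time_estimate)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (is.data.frame(x)) {
    write.csv(x, path, row.names = FALSE, na = "")
  } else {
    stop("don't know how to write an object of class ",
         paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Read a sweep table back from CSV
#'
#' Inverse of [write_results()] for sweep tables; empty fields become `NA`.
#'
#' @param path CSV path written by [write_results()].
#' @return The sweep table data frame.
#' @export
read_sweep_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           na.strings = c("NA", ""))
}
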