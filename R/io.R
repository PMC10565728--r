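## Serialisation: tidy TSV with "#"-prefixed header comments carrying the
## resolved configuration, a JSON events sidecar, Newick for phylogenies.
## All writers are plain text and deterministic given identical inputs.

config_header <- function(trajectory) {
  cfg <- trajectory$config
  env <- unclass(trajectory$env)
  if (!is.null(env$steps)) env$steps <- as.list(env$steps)
  meta <- list(
    params = unclass(trajectory$params),
    env = env,
    t_end = cfg$t_end, record_dt = cfg$record_dt,
    seed = cfg$seed, rtol = cfg$rtol, atol = cfg$atol,
    initial = as.list(cfg$initial)
  )
  extra <- setdiff(names(cfg), c("t_end", "record_dt", "seed", "rtol",
                                 "atol", "initial"))
  meta <- c(meta, cfg[extra])
  as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Long (tidy) form of a trajectory
#'
#' One row per recorded sample per living-or-extinct species; samples
#' before a species is born are omitted.
#'
#' @param trajectory An `evodyn_trajectory`.
#' @return A data frame with columns `time`, `species_id`, `density`,
#'   `strategy`, `gamma`.
#' @export
trajectory_long <- function(trajectory) {
  ids <- colnames(trajectory$density)
  out <- do.call(rbind, lapply(seq_along(ids), function(j) {
    keep <- !is.na(trajectory$density[, j])
    data.frame(
      time = trajectory$times[keep],
      species_id = ids[j],
      density = trajectory$density[keep, j],
      strategy = trajectory$strategy[keep, j],
      gamma = trajectory$gamma[keep],
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$time, match(out$species_id, ids)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a trajectory as tidy TSV
#'
#' Columns `time`, `species_id`, `density`, `strategy`, `gamma`; header
#' comments (`#`) embed the fully resolved configuration (parameters,
#' environment, seed, initial conditions) for reproducibility.
#'
#' @param trajectory An `evodyn_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [read_trajectory_tsv()], [write_events_json()]
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# evodyn trajectory",
               paste0("# config: ", config_header(trajectory))), con)
  utils::write.table(trajectory_long(trajectory), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory_tsv()]
#'
#' @param path File path.
#' @return The tidy data frame, with the parsed header configuration
#'   attached as attribute `"config"`.
#' @export
read_trajectory_tsv <- function(path) {
  header <- character(0)
  con <- file(path, open = "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con); on.exit()
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cfg_line <- grep("^# config: ", header, value = TRUE)
  if (length(cfg_line))
    attr(out, "config") <- jsonlite::fromJSON(sub("^# config: ", "", cfg_line[1]))
  out
}

#' Write the event log of a trajectory as JSON
#'
#' @param trajectory An `evodyn_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(trajectory, path) {
  jsonlite::write_json(
    list(config = jsonlite::fromJSON(config_header(trajectory)),
         events = trajectory$events),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    pretty = TRUE)
  invisible(path)
}

#' Write adaptive-landscape frames as tidy TSV
#'
#' Long format: one row per frame time, focal evolvability and grid point.
#'
#' @param frames An `evodyn_landscape_series` from [landscape_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(frames, path) {
  stopifnot(inherits(frames, "evodyn_landscape_series"))
  long <- do.call(rbind, lapply(frames, function(fr) {
    do.call(rbind, lapply(seq_along(fr$k_values), function(i) {
      data.frame(time = fr$time, k_focal = fr$k_values[i], v = fr$v,
                 G = fr$G[i, ], gamma = fr$gamma, stringsAsFactors = FALSE)
    }))
  }))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# evodyn adaptive landscape", con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an extinction summary as TSV
#' @param summary Data frame from [extinction_summary()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file maps directly onto [scenario_config()] arguments; `params` is
#' a mapping of [model_params()] arguments and `env` a mapping with a
#' `mode` key (`constant`, `stochastic`, `sinusoidal`, `step`) plus that
#' mode's fields (`times`/`gammas` for steps).
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An `evodyn_scenario`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$params)) raw$params <- do.call(model_params, raw$params)
  if (!is.null(raw$env)) {
    env <- raw$env
    mode <- env$mode
    env$mode <- NULL
    ctor <- switch(mode,
                   constant = env_constant, stochastic = env_stochastic,
                   sinusoidal = env_sinusoidal, step = env_steps,
                   stop("unknown env mode in config: ", mode, call. = FALSE))
    if (mode == "step") env$times <- unlist(env$times)
    if (mode == "step") env$gammas <- unlist(env$gammas)
    raw$env <- do.call(ctor, env)
  }
  raw <- raw[names(raw) %in% names(formals(scenario_config))]
  do.call(scenario_config, raw)
}
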