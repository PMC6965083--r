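# File formats: versioned CSV tables, stimulus/response archives
# (CSV matrix + JSON metadata sidecar), YAML configs. All text-based;
# write -> read round-trips are identities on every field.

SCHEMA_VERSIONS <- c(
  spike_table = "contrastLN spike_table v1",
  unit_response = "contrastLN unit_response v1",
  drc_stimulus = "contrastLN drc_stimulus v1"
)

write_versioned_csv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSIONS[[schema]]), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_versioned_csv <- function(path, schema) {
  header <- readLines(path, n = 1)
  expected <- paste0("# ", SCHEMA_VERSIONS[[schema]])
  if (!identical(header, expected)) {
    stop("schema mismatch in ", path, ": found '", header,
         "', expected '", expected, "'")
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#"),
    warning = function(w) stop("malformed CSV in ", path, ": ",
                               conditionMessage(w)),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e))
  )
  # report ragged rows with their line numbers
  raw <- utils::count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(raw)) > 1) {
    bad <- which(raw != raw[1]) + 1L # +1 for the schema header line
    stop("malformed CSV in ", path, ": inconsistent field count at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  df
}

#' Write / read a spike-time table
#'
#' CSV with columns `unit_id`, `trial`, `condition`, `time_ms` and a schema
#' version declared on the first line.
#'
#' @param tbl Data frame with the columns above.
#' @param path File path.
#' @return `read_spike_table` returns the data frame.
#' @export
write_spike_table <- function(tbl, path) {
  need <- c("unit_id", "trial", "condition", "time_ms")
  stopifnot(all(need %in% names(tbl)))
  write_versioned_csv(tbl[, need], path, "spike_table")
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  read_versioned_csv(path, "spike_table")
}

#' Write / read a unit response archive
#'
#' Counts go to `<path>.csv` (one row per repeat) and metadata (bin
#' duration, per-bin condition labels, schema) to `<path>.json`.
#'
#' @param response A [unit_response()].
#' @param path Base path (without extension).
#' @return `read_unit_response` returns the `unit_response`.
#' @export
write_unit_response <- function(response, path) {
  stopifnot(inherits(response, "unit_response"))
  df <- as.data.frame(response$counts)
  names(df) <- paste0("bin", seq_len(ncol(df)))
  write_versioned_csv(df, paste0(path, ".csv"), "unit_response")
  meta <- list(
    schema = SCHEMA_VERSIONS[["unit_response"]],
    bin_ms = response$bin_ms,
    contrast = response$contrast,
    state = response$state
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_unit_response
#' @export
read_unit_response <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA_VERSIONS[["unit_response"]])) {
    stop("schema mismatch in ", path, ".json: found '", meta$schema, "'")
  }
  counts <- as.matrix(read_versioned_csv(paste0(path, ".csv"),
                                         "unit_response"))
  dimnames(counts) <- NULL
  unit_response(counts, as.numeric(meta$bin_ms), as.character(meta$contrast),
                if (is.null(meta$state)) NULL else as.character(meta$state))
}

#' Write / read a DRC stimulus archive
#'
#' The level matrix goes to `<path>.csv` and metadata (grid, regimes,
#' contrast track, seed, schema) to `<path>.json`.
#'
#' @param drc A `drc_stimulus`.
#' @param path Base path (without extension).
#' @return `read_drc` returns the `drc_stimulus`.
#' @export
write_drc <- function(drc, path) {
  stopifnot(inherits(drc, "drc_stimulus"))
  df <- as.data.frame(drc$levels)
  names(df) <- paste0("f", seq_len(ncol(df)))
  write_versioned_csv(df, paste0(path, ".csv"), "drc_stimulus")
  meta <- list(
    schema = SCHEMA_VERSIONS[["drc_stimulus"]],
    chord_ms = drc$chord_ms,
    ramp_ms = drc$ramp_ms,
    grid = list(
      f_min = drc$grid$f_min, f_max = drc$grid$f_max,
      steps_per_octave = drc$grid$steps_per_octave
    ),
    regimes = lapply(drc$regimes, function(r) {
      list(mean_level = r$mean_level, width = r$width, label = r$label)
    }),
    contrast_track = drc$contrast_track,
    level_matched = isTRUE(drc$level_matched),
    seed = drc$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_drc
#' @export
read_drc <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA_VERSIONS[["drc_stimulus"]])) {
    stop("schema mismatch in ", path, ".json: found '", meta$schema, "'")
  }
  levels <- as.matrix(read_versioned_csv(paste0(path, ".csv"),
                                         "drc_stimulus"))
  dimnames(levels) <- NULL
  grid <- make_frequency_grid(meta$grid$f_min, meta$grid$f_max,
                              meta$grid$steps_per_octave)
  regimes <- lapply(meta$regimes, function(r) {
    contrast_regime(r$width, r$mean_level, r$label)
  })
  structure(
    list(
      levels = levels, chord_ms = meta$chord_ms, ramp_ms = meta$ramp_ms,
      grid = grid, regimes = regimes,
      contrast_track = as.character(meta$contrast_track),
      level_matched = isTRUE(meta$level_matched),
      seed = meta$seed
    ),
    class = "drc_stimulus"
  )
}

#' Write / read a run configuration
#'
#' YAML round-trip of a [run_config()]; every field survives losslessly.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  # named vectors must go out as maps; plain YAML sequences drop names
  out$widths <- as.list(config$widths)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
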