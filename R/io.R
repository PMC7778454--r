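#' Write a BSM report table as CSV
#'
#' Long-format table with columns scenario, method, spot, time_ms, bias_mm,
#' spread_mm2, bsm_mm, detected.
#'
#' @param report `eegdot_report` from [run_two_source_scenario()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bsm_csv <- function(report, path) {
  stopifnot(inherits(report, "eegdot_report"))
  tab <- cbind(scenario = report$config$preset, report$bsm)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a reconstruction map as CSV
#'
#' Columns: voxel_id, x, y, z, value (plus a time column for map series).
#'
#' @param map `eegdot_map`.
#' @param sources `eegdot_source_space`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, sources, path) {
  stopifnot(inherits(map, "eegdot_map"),
            inherits(sources, "eegdot_source_space"))
  v <- map$values
  base <- data.frame(
    voxel_id = sources$voxel_ids,
    x = sources$positions[, 1],
    y = sources$positions[, 2],
    z = sources$positions[, 3]
  )
  if (ncol(v) == 1) {
    tab <- cbind(base, value = v[, 1])
  } else {
    tt <- if (!is.null(map$time)) map$time else seq_len(ncol(v))
    tab <- do.call(rbind, lapply(seq_len(ncol(v)), function(j) {
      cbind(base, value = v[, j], time = tt[j])
    }))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a scenario configuration to YAML
#' @param config `eegdot_scenario`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "eegdot_scenario"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path YAML file written by [write_scenario_yaml()] (or hand-edited).
#' @return `eegdot_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[names(raw) %in% names(formals(scenario_config))]
  if (!is.null(args$snr)) args$snr <- unlist(args$snr)
  do.call(scenario_config, args)
}

#' Export a cortical surface with per-vertex scalars as ASCII PLY
#'
#' Minimal PLY writer for visualizing reconstruction maps in external viewers
#' (vertices only, a `quality` property carries the scalar).
#'
#' @param sources `eegdot_source_space`.
#' @param values per-voxel scalars (defaults to zeros).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_surface_ply <- function(sources, values = NULL, path) {
  stopifnot(inherits(sources, "eegdot_source_space"))
  n <- nrow(sources$positions)
  if (is.null(values)) values <- numeric(n)
  stopifnot(length(values) == n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property float quality", "end_header"
  ), con)
  utils::write.table(
    cbind(sources$positions, values), con,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write per-run assessment rows as CSV
#' @param assessment `eegdot_assessment`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_assessment_csv <- function(assessment, path) {
  stopifnot(inherits(assessment, "eegdot_assessment"))
  utils::write.csv(assessment$runs, path, row.names = FALSE)
  invisible(path)
}
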