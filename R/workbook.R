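# Measurement-workbook dialect.
#
# Sheet 1 "metadata": key-value rows with fixed keys
#   channel_width_um, channel_height_um, wall_thickness_um, analyte_flow_ul_min,
#   buffer_flow_ul_min, temperature_K, viscosity_Pa_s, exposure_s
# Each further sheet is one measurement point (P00, P01, ...) with columns
#   position_um | brightfield | fluorescent | distance_um
# where distance_um carries a single value (first row): the point's distance
# from the channel origin. Sheet order is front of channel -> outlet.

.metadata_keys <- c("channel_width_um", "channel_height_um", "wall_thickness_um",
                    "analyte_flow_ul_min", "buffer_flow_ul_min", "temperature_K",
                    "viscosity_Pa_s", "exposure_s")

#' Aligned intensity traces at one measurement point
#'
#' @param label Measurement-point identifier (the sheet name, e.g. `"P03"`).
#' @param position Distance of the point from the channel origin (um).
#' @param x Sample positions along the cross-channel vector (um); strictly
#'   increasing with uniform spacing.
#' @param brightfield,fluorescent Intensity traces (camera counts), same length
#'   as `x`, non-negative.
#' @return An object of class `"profile_pair"`.
#' @export
profile_pair <- function(label, position, x, brightfield, fluorescent) {
  if (length(x) < 2L || length(brightfield) != length(x) ||
      length(fluorescent) != length(x)) {
    stop("traces must be non-trivial and the same length as `x`", call. = FALSE)
  }
  dx <- diff(x)
  if (any(dx <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  if (diff(range(dx)) > 1e-6 * mean(dx)) {
    stop(sprintf("profile '%s': `x` spacing is not uniform", label),
         call. = FALSE)
  }
  if (any(brightfield < 0) || any(fluorescent < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(label = as.character(label), position = as.numeric(position),
                 x = as.numeric(x), brightfield = as.numeric(brightfield),
                 fluorescent = as.numeric(fluorescent)),
            class = "profile_pair")
}

#' A full diffusional-sizing experiment
#'
#' Metadata plus the ordered per-point profile pairs, front of channel first.
#'
#' @param metadata A list with elements `geometry` ([device_geometry()]),
#'   `flow` ([flow_config()]), `conditions` ([conditions()]), `exposure` (s)
#'   and `omit` (character vector of omitted point labels).
#' @param profiles List of [profile_pair()] objects in channel order.
#' @return An object of class `"measurement_set"`.
#' @export
measurement_set <- function(metadata, profiles) {
  stopifnot(inherits(metadata$geometry, "device_geometry"),
            inherits(metadata$flow, "flow_config"),
            inherits(metadata$conditions, "conditions"))
  if (is.null(metadata$omit)) metadata$omit <- character()
  if (!all(vapply(profiles, inherits, logical(1), "profile_pair"))) {
    stop("`profiles` must be a list of profile_pair objects", call. = FALSE)
  }
  if (length(profiles) < 3L) {
    stop("need at least 3 measurement points (a variance-time line needs ",
         "more than 2 usable points)", call. = FALSE)
  }
  pos <- vapply(profiles, `[[`, numeric(1), "position")
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("profile positions must be strictly increasing along the channel",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(pos, metadata$geometry$positions, tolerance = 1e-9))) {
    stop("profile positions do not match the geometry's measurement-point ",
         "positions", call. = FALSE)
  }
  structure(list(metadata = metadata, profiles = profiles),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  g <- x$metadata$geometry
  cat(sprintf("Measurement set: %d points, channel %g x %g um, T = %g K\n",
              length(x$profiles), g$channel_width, g$channel_height,
              x$metadata$conditions$temperature))
  cat(" points:", paste(vapply(x$profiles, `[[`, character(1), "label"),
                        collapse = " "), "\n")
  invisible(x)
}

labels_of <- function(ms) vapply(ms$profiles, `[[`, character(1), "label")

#' Read a measurement workbook
#'
#' Reads an XLSX workbook in the dialect described in the package README:
#' a `metadata` key-value sheet followed by one sheet per measurement point
#' with `position_um | brightfield | fluorescent | distance_um` columns.
#' Sheet order (front of channel to outlet) is preserved; omission is by
#' sheet label, never by index.
#'
#' @param path Path to the workbook.
#' @param omit Character vector of measurement-point labels to exclude from
#'   evaluation (e.g. a point disturbed by a contaminant).
#' @return A [measurement_set()].
#' @export
read_measurement_workbook <- function(path, omit = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sheets <- readxl::excel_sheets(path)
  if (sheets[1L] != "metadata") {
    stop("workbook dialect error: first sheet must be 'metadata'", call. = FALSE)
  }
  meta_df <- as.data.frame(readxl::read_excel(path, sheet = "metadata",
                                              col_types = c("text", "numeric")))
  kv <- stats::setNames(meta_df[[2L]], meta_df[[1L]])
  missing <- setdiff(.metadata_keys, names(kv))
  if (length(missing)) {
    stop("metadata sheet is missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  point_sheets <- sheets[-1L]
  unknown <- setdiff(omit, point_sheets)
  if (length(unknown)) {
    stop("omit label(s) not present in workbook: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(point_sheets, omit)
  if (length(keep) < 3L) {
    stop("fewer than 3 usable measurement points after omission", call. = FALSE)
  }

  profiles <- lapply(keep, function(sh) {
    df <- as.data.frame(readxl::read_excel(path, sheet = sh))
    need <- c("position_um", "brightfield", "fluorescent", "distance_um")
    if (!all(need %in% names(df))) {
      stop(sprintf("sheet '%s' lacks column(s): %s", sh,
                   paste(setdiff(need, names(df)), collapse = ", ")),
           call. = FALSE)
    }
    dist <- df$distance_um[!is.na(df$distance_um)][1L]
    if (is.na(dist)) stop(sprintf("sheet '%s' has no distance_um value", sh),
                          call. = FALSE)
    profile_pair(sh, dist, df$position_um, df$brightfield, df$fluorescent)
  })

  positions <- vapply(profiles, `[[`, numeric(1), "position")
  geom <- device_geometry(kv[["channel_width_um"]], kv[["channel_height_um"]],
                          kv[["wall_thickness_um"]], positions)
  metadata <- list(
    geometry = geom,
    flow = flow_config(kv[["analyte_flow_ul_min"]], kv[["buffer_flow_ul_min"]]),
    conditions = conditions(kv[["temperature_K"]], kv[["viscosity_Pa_s"]]),
    exposure = unname(kv[["exposure_s"]]),
    omit = omit)
  measurement_set(metadata, profiles)
}

#' Write a measurement workbook
#'
#' Inverse of [read_measurement_workbook()]: writes the dialect so that a
#' read-back reproduces the set bit-exactly for intensities stored as doubles.
#' Used by the simulator to emit test workbooks.
#'
#' @param ms A [measurement_set()].
#' @param path Output path (`.xlsx`).
#' @return The path, invisibly.
#' @export
write_measurement_workbook <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  m <- ms$metadata
  meta_df <- data.frame(
    key = .metadata_keys,
    value = c(m$geometry$channel_width, m$geometry$channel_height,
              m$geometry$wall_thickness, m$flow$analyte_flow,
              m$flow$buffer_flow, m$conditions$temperature,
              m$conditions$viscosity, m$exposure),
    stringsAsFactors = FALSE)
  sheets <- c(list(metadata = meta_df),
              stats::setNames(lapply(ms$profiles, function(p) {
                dist <- c(p$position, rep(NA_real_, length(p$x) - 1L))
                data.frame(position_um = p$x, brightfield = p$brightfield,
                           fluorescent = p$fluorescent, distance_um = dist)
              }), labels_of(ms)))
  write_xlsx_sheets(sheets, path)
}

#' Write a radius report to disk
#'
#' @param report A `radius_report` (see [summarize_tracks()]).
#' @param path Output path.
#' @param format `"json"` (full report incl. provenance) or `"csv"` (one row
#'   per component).
#' @return The path, invisibly.
#' @export
write_results <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "radius_report"))
  format <- match.arg(format)
  if (format == "json") {
    out <- list(results = report$results,
                higher_radius_nm = report$higher,
                lower_radius_nm = report$lower,
                mean_radius_nm = report$mean_radius,
                provenance = report$provenance)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    utils::write.csv(report$results, path, row.names = FALSE)
  }
  invisible(path)
}
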