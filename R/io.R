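# Plain-text readers and writers for every pipeline format. All files are
# UTF-8, decimal-point, header-mandatory CSV/TSV (GMT and JSON aside);
# readers validate shape and report offending records with their line
# number (header = line 1).

read_delim_checked <- function(path, need, sep = ",") {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = NULL, data.table = TRUE)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop_bad("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  dt
}

bad_rows <- function(path, dt, cols) {
  for (cl in cols) {
    v <- dt[[cl]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop_bad("%s: non-numeric or missing '%s' at line %d", path, cl,
               bad[1] + 1L)
    }
  }
  invisible(dt)
}

#' Read / write a cell-track table
#'
#' Track CSV dialect: `track_id,t_min,x_um,y_um`, one row per sample.
#' Reading validates numeric columns (with line numbers), at least two
#' samples per track and strictly increasing times.
#'
#' @param path file path.
#' @return data.table track table.
#' @export
read_tracks_csv <- function(path) {
  dt <- read_delim_checked(path, c("track_id", "t_min", "x_um", "y_um"))
  bad_rows(path, dt, c("t_min", "x_um", "y_um"))
  validate_tracks(dt)
}

#' @rdname read_tracks_csv
#' @param tracks track table.
#' @export
write_tracks_csv <- function(tracks, path) {
  data.table::fwrite(tracks[, c("track_id", "t_min", "x_um", "y_um")], path)
  invisible(path)
}

#' Read / write a contour table
#'
#' Contour CSV dialect: `contour_id,frame,vertex_index,x_um,y_um`
#' (`frame` optional on read).
#'
#' @param path file path.
#' @return data.table contour table.
#' @export
read_contours_csv <- function(path) {
  dt <- read_delim_checked(path, c("contour_id", "vertex_index",
                                   "x_um", "y_um"))
  bad_rows(path, dt, c("vertex_index", "x_um", "y_um"))
  dt
}

#' @rdname read_contours_csv
#' @param contours contour table.
#' @export
write_contours_csv <- function(contours, path) {
  data.table::fwrite(contours, path)
  invisible(path)
}

#' Read / write a fluorescence line profile
#'
#' Profile CSV dialect: `distance_um,<channel1>,<channel2>,...` with
#' strictly monotone distances and at least one channel.
#'
#' @param path file path.
#' @return profile data.frame.
#' @export
read_profile_csv <- function(path) {
  dt <- read_delim_checked(path, "distance_um")
  if (ncol(dt) < 2L) stop_bad("%s: profile needs at least one channel column", path)
  bad_rows(path, dt, names(dt))
  d <- dt$distance_um
  if (!(all(diff(d) > 0) || all(diff(d) < 0))) {
    bad <- which(diff(d) * sign(d[2] - d[1]) <= 0)[1]
    stop_bad("%s: non-monotone distance at line %d", path, bad + 2L)
  }
  as.data.frame(dt)
}

#' @rdname read_profile_csv
#' @param profile profile data.frame.
#' @export
write_profile_csv <- function(profile, path) {
  data.table::fwrite(profile, path)
  invisible(path)
}

#' Read / write a 6-plex peptide table
#'
#' Peptide TSV dialect: `protein_id,peptide_id,c1,c2,c3,c4,c5,c6`. A table
#' with the wrong channel count is a validation error.
#'
#' @param path file path.
#' @return data.table peptide table.
#' @export
read_peptide_tsv <- function(path) {
  dt <- read_delim_checked(path, c("protein_id", "peptide_id"), sep = "\t")
  got <- grep("^c[0-9]+$", names(dt), value = TRUE)
  if (!setequal(got, CHANNELS)) {
    stop_bad("%s: expected channels c1..c6, found: %s", path,
             paste(got, collapse = ", "))
  }
  bad_rows(path, dt, CHANNELS)
  validate_peptide_table(dt)
  dt
}

#' @rdname read_peptide_tsv
#' @param table peptide table.
#' @export
write_peptide_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' Read / write sample metadata as JSON
#'
#' JSON dialect: an object mapping each channel to
#' `{"group": <label>, "concentration": <mg/ml>}`.
#'
#' @param path file path.
#' @return [sample_meta()] data.frame.
#' @export
read_sample_meta_json <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(CHANNELS, names(obj))
  if (length(miss)) {
    stop_bad("%s: missing channel(s): %s", path, paste(miss, collapse = ", "))
  }
  sample_meta(
    groups = vapply(CHANNELS, function(ch) obj[[ch]]$group, character(1)),
    concentrations = vapply(CHANNELS, function(ch) {
      as.numeric(obj[[ch]]$concentration)
    }, numeric(1))
  )
}

#' @rdname read_sample_meta_json
#' @param meta [sample_meta()] data.frame.
#' @export
write_sample_meta_json <- function(meta, path) {
  obj <- setNames(lapply(seq_len(nrow(meta)), function(i) {
    list(group = meta$group[i], concentration = meta$concentration[i])
  }), meta$channel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write vessel polylines
#'
#' Vessel CSV dialect: `polyline_id,vertex_index,x_um,y_um`; the field
#' extents come from the caller (they are config, not data).
#'
#' @param path file path.
#' @param xlim,ylim field extents in µm.
#' @return [vessel_map()].
#' @export
read_vessels_csv <- function(path, xlim, ylim) {
  dt <- read_delim_checked(path, c("polyline_id", "vertex_index",
                                   "x_um", "y_um"))
  bad_rows(path, dt, c("vertex_index", "x_um", "y_um"))
  data.table::setorder(dt, polyline_id, vertex_index)
  polylines <- lapply(split(dt, by = "polyline_id"), function(p) {
    cbind(p$x_um, p$y_um)
  })
  vessel_map(polylines, xlim, ylim)
}

#' @rdname read_vessels_csv
#' @param vessels [vessel_map()].
#' @export
write_vessels_csv <- function(vessels, path) {
  rows <- lapply(seq_along(vessels$polylines), function(i) {
    p <- vessels$polylines[[i]]
    data.table::data.table(polyline_id = sprintf("v%03d", i),
                           vertex_index = seq_len(nrow(p)),
                           x_um = p[, 1], y_um = p[, 2])
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read / write a point set
#'
#' Point CSV dialect: `x_um,y_um`.
#'
#' @param path file path.
#' @return n x 2 numeric matrix.
#' @export
read_points_csv <- function(path) {
  dt <- read_delim_checked(path, c("x_um", "y_um"))
  bad_rows(path, dt, c("x_um", "y_um"))
  cbind(dt$x_um, dt$y_um)
}

#' @rdname read_points_csv
#' @param points n x 2 matrix.
#' @export
write_points_csv <- function(points, path) {
  p <- as_points(points)
  data.table::fwrite(data.table::data.table(x_um = p[, 1], y_um = p[, 2]),
                     path)
  invisible(path)
}

#' Read / write a particle-size histogram
#'
#' Histogram CSV dialect: `bin_lo_nm,bin_hi_nm,conc_per_ml`.
#'
#' @param path file path.
#' @return data.frame histogram.
#' @export
read_histogram_csv <- function(path) {
  dt <- read_delim_checked(path, c("bin_lo_nm", "bin_hi_nm", "conc_per_ml"))
  bad_rows(path, dt, c("bin_lo_nm", "bin_hi_nm", "conc_per_ml"))
  as.data.frame(dt)
}

#' @rdname read_histogram_csv
#' @param histogram data.frame histogram.
#' @export
write_histogram_csv <- function(histogram, path) {
  data.table::fwrite(histogram, path)
  invisible(path)
}

#' Read / write a transwell standard curve
#'
#' Standard-curve CSV dialect: `fluorescence,cell_count`.
#'
#' @param path file path.
#' @return data.frame standard curve.
#' @export
read_standard_curve_csv <- function(path) {
  dt <- read_delim_checked(path, c("fluorescence", "cell_count"))
  bad_rows(path, dt, c("fluorescence", "cell_count"))
  as.data.frame(dt)
}

#' @rdname read_standard_curve_csv
#' @param curve data.frame standard curve.
#' @export
write_standard_curve_csv <- function(curve, path) {
  data.table::fwrite(curve, path)
  invisible(path)
}

#' Read / write adhesion presence events
#'
#' Events CSV dialect: `cell_id,frame,present` (present is 0/1).
#'
#' @param path file path.
#' @return data.table events table.
#' @export
read_events_csv <- function(path) {
  dt <- read_delim_checked(path, c("cell_id", "frame", "present"))
  bad_rows(path, dt, c("frame", "present"))
  dt$present <- as.logical(as.integer(dt$present))
  dt
}

#' @rdname read_events_csv
#' @param events events table.
#' @export
write_events_csv <- function(events, path) {
  ev <- data.table::as.data.table(events)
  ev$present <- as.integer(ev$present)
  data.table::fwrite(ev, path)
  invisible(path)
}
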