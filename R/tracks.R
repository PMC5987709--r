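# Cell-track migration statistics.
#
# A track table is a data.frame with columns track_id, t_min, x_um, y_um,
# one row per sample, times strictly increasing within a track. All metrics
# are 2D, in minutes / micrometres / degrees.

#' Construct an upgradient frame
#'
#' The gradient frame fixes the upgradient direction against which
#' chemotactic displacement and the chemotactic index are measured.
#'
#' @param dx,dy components of the upgradient direction (need not be
#'   normalized; zero vector is rejected).
#' @param origin optional 2D reference point (µm); unused by the metrics but
#'   carried for plotting.
#' @return object of class `gradient_frame`: list with unit `direction` and
#'   `origin`.
#' @examples
#' gradient_frame(1, 0)
#' @export
gradient_frame <- function(dx, dy, origin = NULL) {
  assert_finite_num(c(dx, dy), "gradient direction")
  n <- sqrt(dx^2 + dy^2)
  if (n == 0) stop_bad("gradient direction must be non-zero")
  structure(list(direction = c(dx, dy) / n, origin = origin),
            class = "gradient_frame")
}

as_gradient <- function(gradient) {
  if (inherits(gradient, "gradient_frame")) return(gradient$direction)
  assert_finite_num(gradient, "gradient direction")
  if (length(gradient) != 2L) stop_bad("gradient direction must have length 2")
  n <- sqrt(sum(gradient^2))
  if (abs(n - 1) > 1e-9) {
    stop_bad("gradient direction must be a unit vector (use gradient_frame())")
  }
  gradient
}

validate_tracks <- function(tracks) {
  need <- c("track_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    stop_bad("track table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(tracks)
  if (anyNA(dt[, .(t_min, x_um, y_um)]) ||
      !all(is.finite(dt$t_min), is.finite(dt$x_um), is.finite(dt$y_um))) {
    stop_bad("track table contains non-finite coordinates or times")
  }
  bad_n <- dt[, .N, by = track_id][N < 2L]
  if (nrow(bad_n)) {
    stop_bad("track '%s' has fewer than 2 samples", bad_n$track_id[1])
  }
  bad_t <- dt[, .(ok = all(diff(t_min) > 0)), by = track_id][!ok == TRUE]
  if (nrow(bad_t)) {
    stop_bad("track '%s' has non-increasing times", bad_t$track_id[1])
  }
  dt
}

track_metrics_one <- function(t, x, y, dir) {
  dxs <- diff(x)
  dys <- diff(y)
  steps <- sqrt(dxs^2 + dys^2)
  track_length <- sum(steps)
  end <- c(x[length(x)] - x[1], y[length(y)] - y[1])
  displacement <- sqrt(sum(end^2))
  upg <- sum(end * dir)
  cd <- if (track_length > 0) upg / track_length else NA_real_
  ci <- if (displacement > 0) upg / displacement else NA_real_
  speed <- track_length / (t[length(t)] - t[1])
  # headings only defined for non-zero steps
  nz <- steps > 0
  head_deg <- atan2(dys[nz], dxs[nz]) * 180 / pi
  mac <- if (length(head_deg) >= 2L) {
    mean(abs(wrap_deg(diff(head_deg))))
  } else {
    NA_real_
  }
  list(track_length = track_length, displacement = displacement,
       upgradient_displacement = upg, chemotactic_displacement = cd,
       speed = speed, chemotactic_index = ci, mean_angle_change = mac)
}

#' Per-track migration metrics
#'
#' Computes for every track: total path (track) length, net displacement,
#' signed displacement along the upgradient direction, chemotactic
#' displacement (upgradient displacement / track length), speed
#' (track length / elapsed time), chemotactic index (cosine of the angle
#' between the upgradient direction and the start-to-end vector) and mean
#' migratory angle change (mean over consecutive step pairs of the absolute
#' heading change, wrapped into \[0°, 180°\]).
#'
#' Tracks of zero path length get missing (`NA`) chemotactic displacement,
#' and single-step tracks missing angle change; neither is silently zeroed.
#' Zero-length steps carry no heading and are skipped in the angle-change
#' sequence.
#'
#' @param tracks track table (`track_id`, `t_min`, `x_um`, `y_um`).
#' @param gradient a [gradient_frame()] or 2D unit vector.
#' @return data.table, one row per track, columns `track_id`,
#'   `track_length`, `displacement`, `upgradient_displacement`,
#'   `chemotactic_displacement`, `speed`, `chemotactic_index`,
#'   `mean_angle_change`.
#' @examples
#' tr <- data.frame(track_id = "a", t_min = 0:2,
#'                  x_um = c(0, 10, 20), y_um = 0)
#' track_metrics(tr, gradient_frame(1, 0))
#' @export
track_metrics <- function(tracks, gradient = gradient_frame(1, 0)) {
  dir <- as_gradient(gradient)
  dt <- validate_tracks(tracks)
  data.table::setorder(dt, track_id, t_min)
  dt[, track_metrics_one(t_min, x_um, y_um, dir), by = track_id]
}

#' Per-step heading changes
#'
#' Exposes the unaggregated per-time-point angle changes behind
#' `mean_angle_change`, for analyses that pool time points across cells
#' rather than averaging per cell first.
#'
#' @inheritParams track_metrics
#' @return data.table with `track_id`, `t_min` (time at the end of the
#'   second step of each pair) and `angle_change` in degrees \[0, 180\].
#' @export
step_angle_changes <- function(tracks) {
  dt <- validate_tracks(tracks)
  data.table::setorder(dt, track_id, t_min)
  dt[, {
    dxs <- diff(x_um); dys <- diff(y_um)
    steps <- sqrt(dxs^2 + dys^2)
    nz <- steps > 0
    hd <- atan2(dys[nz], dxs[nz]) * 180 / pi
    tt <- t_min[-1][nz]
    if (length(hd) >= 2L) {
      list(t_min = tt[-1], angle_change = abs(wrap_deg(diff(hd))))
    } else {
      list(t_min = numeric(0), angle_change = numeric(0))
    }
  }, by = track_id]
}

#' Filter tracks by net displacement
#'
#' Keeps tracks whose start-to-end displacement is at least
#' `min_displacement` (inclusive). The 3D-collagen assay convention is a
#' 24.1 µm minimum; confined assays use a caller-chosen threshold.
#'
#' @inheritParams track_metrics
#' @param min_displacement threshold in µm, >= 0.
#' @return the filtered track table (same columns, original row order).
#' @export
filter_by_displacement <- function(tracks, min_displacement = 24.1) {
  if (!is.numeric(min_displacement) || min_displacement < 0) {
    stop_bad("min_displacement must be >= 0")
  }
  dt <- validate_tracks(tracks)
  if (nrow(dt) == 0L) return(tracks)
  data.table::setorder(dt, track_id, t_min)
  disp <- dt[, .(displacement = sqrt((x_um[.N] - x_um[1])^2 +
                                     (y_um[.N] - y_um[1])^2)),
             by = track_id]
  keep <- disp$track_id[disp$displacement >= min_displacement]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Endpoint-angle histogram (rose-plot fractions)
#'
#' Bins each track's endpoint direction, measured relative to the
#' upgradient direction, into `n_bins` equal sectors. Sectors are centred
#' so that 0° (straight upgradient) lies in the middle of the first sector.
#' Zero-displacement tracks carry no direction and are dropped.
#'
#' @inheritParams track_metrics
#' @param n_bins number of sectors (>= 2, must divide 360).
#' @return data.table with `bin_center`, `bin_lo`, `bin_hi` (degrees,
#'   relative to upgradient) and `fraction`; fractions sum to 1.
#' @export
angle_histogram <- function(tracks, gradient = gradient_frame(1, 0),
                            n_bins = 8) {
  if (n_bins < 2 || 360 %% n_bins != 0) {
    stop_bad("n_bins must be >= 2 and divide 360")
  }
  dir <- as_gradient(gradient)
  dt <- validate_tracks(tracks)
  data.table::setorder(dt, track_id, t_min)
  ends <- dt[, .(ex = x_um[.N] - x_um[1], ey = y_um[.N] - y_um[1]),
             by = track_id]
  ends <- ends[ex != 0 | ey != 0]
  if (nrow(ends) == 0L) stop_bad("no tracks with non-zero displacement")
  # angle of endpoint vector relative to upgradient, in (-180, 180]
  ang <- atan2(ends$ey * dir[1] - ends$ex * dir[2],
               ends$ex * dir[1] + ends$ey * dir[2]) * 180 / pi
  width <- 360 / n_bins
  idx <- floor(((ang + width / 2) %% 360) / width)  # 0 .. n_bins-1
  counts <- tabulate(idx + 1L, nbins = n_bins)
  centers <- (seq_len(n_bins) - 1L) * width
  centers <- wrap_deg(centers)
  data.table::data.table(
    bin_center = centers,
    bin_lo = centers - width / 2,
    bin_hi = centers + width / 2,
    fraction = counts / sum(counts)
  )
}

#' Group comparison of per-track metrics
#'
#' For each numeric metric column, reports group mean, SEM and n, the fold
#' change of each group over the reference group mean, and a two-sided
#' Welch t-test p-value against the reference. Missing metric values
#' (e.g. undefined ratios of zero-length tracks) are excluded.
#'
#' @param metrics data.frame with a `group` column plus numeric metric
#'   columns (e.g. the output of [track_metrics()] with a group label
#'   joined on).
#' @param reference name of the reference group (default: first level
#'   encountered).
#' @return data.table with columns `metric`, `group`, `n`, `mean`, `sem`,
#'   `fold_change`, `p_value`. The reference rows have `fold_change` 1 and
#'   `p_value` NA.
#' @export
group_compare <- function(metrics, reference = NULL) {
  if (!"group" %in% names(metrics)) stop_bad("metrics needs a 'group' column")
  dt <- data.table::as.data.table(metrics)
  groups <- unique(as.character(dt$group))
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop_bad("reference group '%s' not found", reference)
  num_cols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  if (!length(num_cols)) stop_bad("no numeric metric columns")
  small <- dt[, .N, by = group][N < 2L]
  if (nrow(small)) {
    stop_bad("group '%s' has fewer than 2 observations", small$group[1])
  }
  out <- list()
  for (m in num_cols) {
    ref_vals <- dt[[m]][dt$group == reference]
    ref_vals <- ref_vals[is.finite(ref_vals)]
    for (g in groups) {
      v <- dt[[m]][dt$group == g]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.table::data.table(
        metric = m, group = g, n = length(v),
        mean = mean(v), sem = sem(v),
        fold_change = if (g == reference) 1 else mean(v) / mean(ref_vals),
        p_value = if (g == reference) NA_real_ else welch_p(v, ref_vals)
      )
    }
  }
  data.table::rbindlist(out)
}
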