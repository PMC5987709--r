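# Bespoke assay quantitations: point-to-vessel distances with a CSR
# normalization, microfluidic adhesion counting, transwell calibration,
# NTA histogram averaging and membrane pore geometry.

#' Construct a vessel map
#'
#' @param polylines list of n x 2 matrices (vertices in µm, >= 2 each).
#' @param xlim,ylim field extents in µm (the rectangular imaging field the
#'   points live in; used by the CSR normalization).
#' @return object of class `vessel_map` with `polylines`, `xlim`, `ylim`,
#'   `field_area` (µm²) and `vessel_length` (summed polyline length, µm).
#' @export
vessel_map <- function(polylines, xlim, ylim) {
  if (!length(polylines)) stop_bad("vessel map needs at least one polyline")
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 2L) {
      stop_bad("each polyline needs >= 2 points in 2 columns")
    }
    assert_finite_num(p, "polyline vertices")
    p
  })
  assert_finite_num(c(xlim, ylim), "field extents")
  if (diff(xlim) <= 0 || diff(ylim) <= 0) stop_bad("degenerate field extents")
  len <- sum(vapply(polylines, function(p) {
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1)))
  structure(list(polylines = polylines, xlim = xlim, ylim = ylim,
                 field_area = diff(xlim) * diff(ylim),
                 vessel_length = len),
            class = "vessel_map")
}

# distance from points (n x 2) to one segment a-b, vectorized over points
dist_point_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]
  vy <- b[2] - a[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / l2))
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

#' Minimum distance from points to the nearest vessel
#'
#' Euclidean distance from each point to the nearest point on any polyline
#' segment of the vessel map.
#'
#' @param points n x 2 matrix (or data.frame with `x_um`, `y_um`) in µm.
#' @param vessels a [vessel_map()].
#' @return numeric vector of distances (µm), one per point.
#' @export
min_distance_to_vessels <- function(points, vessels) {
  if (!inherits(vessels, "vessel_map")) stop_bad("vessels must be a vessel_map")
  p <- as_points(points)
  if (nrow(p) == 0L) stop_bad("at least one point required")
  d <- rep(Inf, nrow(p))
  for (pl in vessels$polylines) {
    for (i in seq_len(nrow(pl) - 1L)) {
      d <- pmin(d, dist_point_segment(p[, 1], p[, 2], pl[i, ], pl[i + 1L, ]))
    }
  }
  d
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_um", "y_um") %in% names(points))) {
      points <- cbind(points$x_um, points$y_um)
    } else {
      points <- as.matrix(points)
    }
  }
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop_bad("points must have 2 columns")
  assert_finite_num(p, "points")
  p
}

#' Vessel-density-normalized mean distance
#'
#' Mean minimum point-to-vessel distance divided by its expectation under
#' complete spatial randomness (CSR), estimated by seeded Monte-Carlo with
#' uniformly random points in the field. The statistic is 1 for uniformly
#' placed cells, below 1 when cells accumulate near vessels and above 1
#' when they avoid them, and is invariant under joint rescaling of points,
#' vessels and field. The raw mean distance and the vessel length density
#' (total polyline length / field area) are reported alongside.
#'
#' @inheritParams min_distance_to_vessels
#' @param n_mc number of CSR reference points (>= 1000; default 10000).
#' @param seed RNG seed for the Monte-Carlo reference.
#' @return list with `normalized`, `mean_distance` (µm), `csr_expected`
#'   (µm), `vessel_density` (µm / µm²) and `n_points`.
#' @export
normalized_mean_distance <- function(points, vessels, n_mc = 10000,
                                     seed = 1L) {
  if (n_mc < 1000) stop_bad("n_mc must be >= 1000")
  d <- min_distance_to_vessels(points, vessels)
  ref <- with_seed(seed, {
    rp <- cbind(runif(n_mc, vessels$xlim[1], vessels$xlim[2]),
                runif(n_mc, vessels$ylim[1], vessels$ylim[2]))
    mean(min_distance_to_vessels(rp, vessels))
  })
  list(normalized = mean(d) / ref,
       mean_distance = mean(d),
       csr_expected = ref,
       vessel_density = vessels$vessel_length / vessels$field_area,
       n_points = length(d))
}

#' Count adherent cell tracks
#'
#' A cell counts as an adherent track iff its presence series contains a
#' run of consecutive detections whose total dwell time (run length x
#' frame interval) reaches `min_duration_s`. With 1-s frames and the
#' default 3-s rule, a run of three consecutive frames counts and a run of
#' two does not; interrupted runs do not add up.
#'
#' @param events data.frame with `cell_id`, `frame` (integer frame index)
#'   and logical `present`, or a named list of logical presence vectors.
#' @param min_duration_s minimum dwell time in seconds (default 3).
#' @param frame_interval_s seconds per frame (> 0; default 1).
#' @return integer count of adherent tracks.
#' @export
adherent_tracks <- function(events, min_duration_s = 3,
                            frame_interval_s = 1) {
  if (frame_interval_s <= 0) stop_bad("frame_interval_s must be > 0")
  if (is.data.frame(events)) {
    need <- c("cell_id", "frame", "present")
    miss <- setdiff(need, names(events))
    if (length(miss)) {
      stop_bad("events table is missing column(s): %s",
               paste(miss, collapse = ", "))
    }
    dt <- data.table::as.data.table(events)
    data.table::setorder(dt, cell_id, frame)
    series <- split(as.logical(dt$present), dt$cell_id)
  } else {
    series <- lapply(events, as.logical)
  }
  need_frames <- ceiling(min_duration_s / frame_interval_s - 1e-9)
  adherent <- vapply(series, function(p) {
    if (!any(p)) return(FALSE)
    r <- rle(p)
    any(r$lengths[r$values] >= need_frames)
  }, logical(1))
  sum(adherent)
}

#' Calibrate transwell fluorescence readings to cell counts
#'
#' Fits an ordinary least-squares line (free intercept) of cell count on
#' fluorescence through the standard-curve points, inverse-maps the
#' readings to transmigrated cell counts (clipped at zero), and summarizes
#' replicate wells as mean +/- SEM per time point.
#'
#' @param curve data.frame with `fluorescence` and `cell_count` (>= 2
#'   distinct fluorescence values).
#' @param readings data.frame with `time_min`, `replicate`, `fluorescence`.
#' @return list with `slope`, `intercept` (count scale), `counts` (the
#'   readings with a `cell_count` column) and `kinetics` (data.table:
#'   `time_min`, `mean_count`, `sem_count`, `n`).
#' @export
calibrate_transwell <- function(curve, readings) {
  if (!all(c("fluorescence", "cell_count") %in% names(curve))) {
    stop_bad("standard curve needs 'fluorescence' and 'cell_count' columns")
  }
  if (nrow(curve) < 2L || length(unique(curve$fluorescence)) < 2L) {
    stop_bad("standard curve is degenerate: need >= 2 distinct fluorescence values")
  }
  fit <- lm(cell_count ~ fluorescence, data = curve)
  cf <- coef(fit)
  need <- c("time_min", "replicate", "fluorescence")
  miss <- setdiff(need, names(readings))
  if (length(miss)) {
    stop_bad("readings table is missing column(s): %s",
             paste(miss, collapse = ", "))
  }
  counts <- data.table::as.data.table(readings)
  counts[, cell_count := pmax(0, cf[[1]] + cf[[2]] * fluorescence)]
  kin <- counts[, .(mean_count = mean(cell_count),
                    sem_count = if (.N >= 2L) sd(cell_count) / sqrt(.N) else NA_real_,
                    n = .N),
                by = time_min][order(time_min)]
  list(slope = unname(cf[[2]]), intercept = unname(cf[[1]]),
       counts = counts[], kinetics = kin)
}

#' Average replicate particle-size histograms (NTA)
#'
#' Bin-wise mean concentration over replicate histograms with identical
#' binning, plus summary statistics: concentration-weighted mean diameter,
#' mode diameter (centre of the highest mean bin) and total concentration.
#'
#' @param replicates list of data.frames with `bin_lo_nm`, `bin_hi_nm`,
#'   `conc_per_ml` (identical bin edges across replicates; the instrument
#'   convention is five replicates but any number >= 1 is accepted).
#' @return list with `histogram` (averaged data.table) and `summary`
#'   (`mean_diameter_nm`, `mode_diameter_nm`, `total_concentration`).
#' @export
nta_average <- function(replicates) {
  if (!length(replicates)) stop_bad("no replicate histograms given")
  ref <- replicates[[1]]
  need <- c("bin_lo_nm", "bin_hi_nm", "conc_per_ml")
  for (i in seq_along(replicates)) {
    r <- replicates[[i]]
    miss <- setdiff(need, names(r))
    if (length(miss)) {
      stop_bad("replicate %d is missing column(s): %s", i,
               paste(miss, collapse = ", "))
    }
    if (nrow(r) != nrow(ref) ||
        any(r$bin_lo_nm != ref$bin_lo_nm) ||
        any(r$bin_hi_nm != ref$bin_hi_nm)) {
      stop_bad("replicate %d has mismatched bin edges", i)
    }
    if (any(r$conc_per_ml < 0)) stop_bad("replicate %d has negative concentrations", i)
  }
  conc <- rowMeans(vapply(replicates, function(r) r$conc_per_ml,
                          numeric(nrow(ref))))
  centers <- (ref$bin_lo_nm + ref$bin_hi_nm) / 2
  total <- sum(conc)
  list(
    histogram = data.table::data.table(bin_lo_nm = ref$bin_lo_nm,
                                       bin_hi_nm = ref$bin_hi_nm,
                                       conc_per_ml = conc),
    summary = list(
      mean_diameter_nm = if (total > 0) sum(conc * centers) / total else NA_real_,
      mode_diameter_nm = if (total > 0) centers[which.max(conc)] else NA_real_,
      total_concentration = total
    )
  )
}

#' Membrane pore area coverage
#'
#' Percentage of a transwell membrane covered by cylindrical pores:
#' 100 x pi (d/2)^2 x density, with the pore diameter in µm and the pore
#' density in pores/cm² (1 cm² = 1e8 µm²). A 3-µm pore at 8e5 pores/cm²
#' covers 5.65% of the membrane.
#'
#' @param pore_diameter_um pore diameter in µm (> 0).
#' @param pore_density_per_cm2 pores per cm² (> 0).
#' @return coverage in percent.
#' @examples
#' pore_coverage(3, 8e5)
#' @export
pore_coverage <- function(pore_diameter_um, pore_density_per_cm2) {
  assert_finite_num(c(pore_diameter_um, pore_density_per_cm2), "pore geometry")
  if (pore_diameter_um <= 0 || pore_density_per_cm2 <= 0) {
    stop_bad("pore diameter and density must be > 0")
  }
  100 * pi * (pore_diameter_um / 2)^2 * pore_density_per_cm2 / 1e8
}
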