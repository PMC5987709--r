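# Perivascular fluorescence-halo quantitation from cross-sectional line
# profiles. A profile is a data.frame with a strictly monotone
# `distance_um` column plus one intensity column per channel.

validate_profile <- function(profile) {
  if (!"distance_um" %in% names(profile)) {
    stop_bad("profile needs a 'distance_um' column")
  }
  d <- profile$distance_um
  assert_finite_num(d, "profile distances")
  if (length(d) < 16L) stop_bad("profile needs at least 16 samples")
  if (all(diff(d) < 0)) {
    # reversed axis: re-orient (sigma is invariant under reversal)
    profile <- profile[rev(seq_len(nrow(profile))), , drop = FALSE]
  } else if (!all(diff(d) > 0)) {
    stop_bad("profile distances must be strictly monotone")
  }
  profile
}

moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

local_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
}

# walk outward from peak index `from` in direction `dir` (-1 left, +1 right);
# the adjacent minimum is the first sample reaching the channel floor (to
# within the prominence cut) or the first valley from which the signal
# rises again by at least the prominence — plain noise dips are ignored.
# The running minimum up to the profile edge is the fallback.
outward_minimum <- function(s, from, dir, thresh, prom) {
  n <- length(s)
  i <- from + dir
  runmin <- from
  while (i >= 1L && i <= n) {
    if (s[i] <= thresh) return(i)
    if (s[i] < s[runmin]) {
      runmin <- i
    } else if (s[i] - s[runmin] >= prom) {
      return(runmin)
    }
    i <- i + dir
  }
  runmin
}

#' Fluorescence band width (sigma) of one profile channel
#'
#' After moving-average smoothing, the two dominant intensity maxima
#' flanking the profile midline are located (the vessel-wall / halo bands);
#' outward of each, the adjacent fluorescence minimum is found (first local
#' minimum, or the first sample within `prominence_fraction` of the channel
#' floor, whichever comes first; the profile edge is the fallback). The
#' default `sigma_mode = "band"` reports the summed per-side max-to-minimum
#' distances; `"span"` reports the full separation between the two outer
#' minima. Detection failure (flat profile, or no prominent maximum on one
#' side of the midline) is an explicit status, never a number.
#'
#' @param profile line-profile data.frame (`distance_um` + channel columns).
#' @param channel name of the intensity column to measure.
#' @param smoothing_window moving-average width in samples (odd; default 3).
#' @param prominence_fraction fraction of the channel dynamic range a
#'   maximum must rise above the floor to count, and the floor-proximity
#'   cut used for the outward minimum (default 0.1).
#' @param sigma_mode `"band"` (summed per-side widths, default) or `"span"`
#'   (outer-minima separation).
#' @return list with `sigma` (µm, NA on failure), `status` (`"ok"`,
#'   `"flat"`, or `"no_flanking_peaks"`) and `diagnostics` (positions in µm
#'   of left/right maxima and adjacent minima).
#' @export
measure_sigma <- function(profile, channel,
                          smoothing_window = 3,
                          prominence_fraction = 0.1,
                          sigma_mode = c("band", "span")) {
  sigma_mode <- match.arg(sigma_mode)
  profile <- validate_profile(profile)
  if (!channel %in% names(profile)) {
    stop_bad("channel '%s' not present in profile", channel)
  }
  d <- profile$distance_um
  y <- profile[[channel]]
  assert_finite_num(y, sprintf("channel '%s'", channel))
  s <- moving_average(y, smoothing_window)
  rng <- max(s) - min(s)
  fail <- function(status) {
    list(sigma = NA_real_, status = status,
         diagnostics = list(left_max = NA_real_, left_min = NA_real_,
                            right_max = NA_real_, right_min = NA_real_))
  }
  if (rng <= 0) return(fail("flat"))
  floor_thresh <- min(s) + prominence_fraction * rng
  peaks <- local_maxima(s)
  peaks <- peaks[s[peaks] >= floor_thresh]
  mid <- (d[1] + d[length(d)]) / 2
  left <- peaks[d[peaks] < mid]
  right <- peaks[d[peaks] > mid]
  if (!length(left) || !length(right)) return(fail("no_flanking_peaks"))
  pick <- function(idx) {
    top <- idx[s[idx] == max(s[idx])]
    top[which.min(abs(d[top] - mid))]
  }
  iL <- pick(left)
  iR <- pick(right)
  prom <- prominence_fraction * rng
  iLmin <- outward_minimum(s, iL, -1L, floor_thresh, prom)
  iRmin <- outward_minimum(s, iR, +1L, floor_thresh, prom)
  sig <- switch(sigma_mode,
    band = (d[iL] - d[iLmin]) + (d[iRmin] - d[iR]),
    span = d[iRmin] - d[iLmin]
  )
  list(sigma = sig, status = "ok",
       diagnostics = list(left_max = d[iL], left_min = d[iLmin],
                          right_max = d[iR], right_min = d[iRmin]))
}

#' Halo diameter ratio between a marker and a vessel channel
#'
#' Ratio of the exosome-marker band width to the vessel-marker band width,
#' sigma(marker) / sigma(vessel), e.g. CD9 over podoplanin. Detection
#' failure in either channel propagates as a failed measurement.
#'
#' @inheritParams measure_sigma
#' @param marker_channel,vessel_channel intensity column names.
#' @return list of class `halo_measurement`: `sigma_per_channel` (named
#'   numeric), `ratio`, `status` and per-channel `diagnostics`.
#' @export
diameter_ratio <- function(profile, marker_channel, vessel_channel,
                           smoothing_window = 3, prominence_fraction = 0.1,
                           sigma_mode = c("band", "span")) {
  sigma_mode <- match.arg(sigma_mode)
  m <- measure_sigma(profile, marker_channel, smoothing_window,
                     prominence_fraction, sigma_mode)
  v <- measure_sigma(profile, vessel_channel, smoothing_window,
                     prominence_fraction, sigma_mode)
  ok <- m$status == "ok" && v$status == "ok" && v$sigma > 0
  structure(list(
    sigma_per_channel = c(
      setNames(m$sigma, marker_channel),
      setNames(v$sigma, vessel_channel)
    ),
    ratio = if (ok) m$sigma / v$sigma else NA_real_,
    status = if (ok) "ok" else "failed",
    diagnostics = setNames(list(m$diagnostics, v$diagnostics),
                           c(marker_channel, vessel_channel))
  ), class = "halo_measurement")
}
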