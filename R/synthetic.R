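# Seeded synthetic generators for every input class of the pipeline.
# Each generator states its ground truth so downstream estimators can be
# tested by parameter recovery; all randomness flows through one explicit
# seed per call and global RNG state is never touched.

#' Simulate biased persistent random-walk cell tracks
#'
#' Headings follow a wrapped-normal step model: the mean heading of each
#' step is the direction of the vector sum of the previous heading (weight
#' `persistence`) and the upgradient direction (weight
#' `bias * (1 + protrusion)`), plus wrapped-normal noise with standard
#' deviation `heading_sd_deg * (1 + protrusion)`. The protrusion parameter
#' is a minimal chemokinesis mechanism: it raises angular exploration and
#' gradient coupling while reducing the realized speed,
#' `base_speed / (1 + protrusion)` — trading speed against navigation.
#'
#' @param n_cells number of tracks.
#' @param n_steps steps per track (each track has `n_steps + 1` samples).
#' @param dt frame interval in minutes (> 0).
#' @param base_speed undamped speed in µm/min (>= 0).
#' @param persistence directional memory in \[0, 1).
#' @param bias gradient coupling (>= 0; 0 = unbiased walk).
#' @param protrusion protrusiveness (>= 0; see above).
#' @param heading_sd_deg baseline wrapped-normal heading noise (degrees).
#' @param gradient a [gradient_frame()] or 2D unit vector (rejected if not
#'   unit length).
#' @param seed RNG seed; identical seeds give identical tracks.
#' @return track table (`track_id`, `t_min`, `x_um`, `y_um`) with the
#'   generating parameters attached as attribute `params`.
#' @export
simulate_tracks <- function(n_cells, n_steps, dt = 1, base_speed = 4,
                            persistence = 0.5, bias = 0, protrusion = 0,
                            heading_sd_deg = 40,
                            gradient = gradient_frame(1, 0), seed = 1L) {
  dir <- as_gradient(gradient)
  if (persistence < 0 || persistence >= 1) stop_bad("persistence must be in [0, 1)")
  if (dt <= 0) stop_bad("dt must be > 0")
  if (base_speed < 0 || bias < 0 || protrusion < 0) {
    stop_bad("base_speed, bias and protrusion must be >= 0")
  }
  grad_ang <- atan2(dir[2], dir[1])
  speed <- base_speed / (1 + protrusion)
  w_bias <- bias * (1 + protrusion)
  sd_rad <- heading_sd_deg * (1 + protrusion) * pi / 180
  step_len <- speed * dt

  out <- with_seed(seed, {
    tracks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      theta <- runif(1, -pi, pi)
      x <- numeric(n_steps + 1L)
      y <- numeric(n_steps + 1L)
      noise <- rnorm(n_steps, 0, sd_rad)
      u <- runif(n_steps, -pi, pi)  # fallback headings, drawn unconditionally
      for (k in seq_len(n_steps)) {
        mx <- persistence * cos(theta) + w_bias * cos(grad_ang)
        my <- persistence * sin(theta) + w_bias * sin(grad_ang)
        mu <- if (mx == 0 && my == 0) u[k] else atan2(my, mx)
        theta <- mu + noise[k]
        x[k + 1L] <- x[k] + step_len * cos(theta)
        y[k + 1L] <- y[k] + step_len * sin(theta)
      }
      tracks[[i]] <- data.table::data.table(
        track_id = sprintf("cell%04d", i),
        t_min = seq(0, by = dt, length.out = n_steps + 1L),
        x_um = x, y_um = y
      )
    }
    data.table::rbindlist(tracks)
  })
  data.table::setattr(out, "params",
                      list(n_cells = n_cells, n_steps = n_steps, dt = dt,
                           base_speed = base_speed, persistence = persistence,
                           bias = bias, protrusion = protrusion,
                           heading_sd_deg = heading_sd_deg, seed = seed))
  out[]
}

#' Simulate a 6-plex peptide-level reporter-intensity table
#'
#' Peptide intensity in a channel is protein base abundance (log-normal) x
#' group fold change x peptide ionization efficiency (log-normal) x
#' multiplicative log-normal noise of coefficient of variation
#' `peptide_cv`. The 3-vs-3 design, per-channel input protein
#' concentrations and spiked per-protein log2 fold changes are recorded as
#' retrievable ground truth.
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein integer vector (recycled) of peptide counts,
#'   or NULL to draw 1 + Poisson(4) per protein; every protein needs >= 1.
#' @param log2_fold_changes per-protein spiked log2 fold change
#'   (treated/reference), recycled; default 0 (null design).
#' @param peptide_cv multiplicative noise CV (>= 0; 0 is noise-free).
#' @param concentrations measured input protein concentration per channel
#'   (mg/ml), default all 1.
#' @param groups 6 group labels in channel order, 3 + 3 (default three
#'   `"ss"` then three `"TNFa"`; the second sorted label is treated).
#' @param base_meanlog,base_sdlog log-normal parameters of protein base
#'   abundance; `base_abundance` overrides with explicit per-protein values.
#' @param base_abundance optional explicit base abundances (recycled).
#' @param seed RNG seed.
#' @return list with `table` (peptide table), `meta` ([sample_meta()]) and
#'   `truth` (data.table: `protein_id`, `log2_fold_change`,
#'   `base_abundance`, `n_peptides`).
#' @export
simulate_peptide_table <- function(n_proteins = 1000,
                                   peptides_per_protein = NULL,
                                   log2_fold_changes = 0,
                                   peptide_cv = 0.2,
                                   concentrations = rep(1, 6),
                                   groups = c("ss", "ss", "ss",
                                              "TNFa", "TNFa", "TNFa"),
                                   base_meanlog = log(1e6),
                                   base_sdlog = 1,
                                   base_abundance = NULL,
                                   seed = 1L) {
  if (peptide_cv < 0) stop_bad("peptide_cv must be >= 0")
  meta <- sample_meta(groups, concentrations)
  # the treated group is the one of the last channel (channel order is the
  # design convention; never rely on locale-dependent label sorting)
  treated <- groups[6]
  fc <- rep_len(2^log2_fold_changes, n_proteins)
  with_seed(seed, {
    npep <- if (is.null(peptides_per_protein)) {
      1L + rpois(n_proteins, 4)
    } else {
      rep_len(as.integer(peptides_per_protein), n_proteins)
    }
    if (any(npep < 1L)) stop_bad("every protein needs at least 1 peptide")
    base <- if (is.null(base_abundance)) {
      rlnorm(n_proteins, base_meanlog, base_sdlog)
    } else {
      rep_len(base_abundance, n_proteins)
    }
    prot_ids <- sprintf("P%05d", seq_len(n_proteins))
    total <- sum(npep)
    pidx <- rep(seq_len(n_proteins), npep)
    eff <- rlnorm(total, 0, 0.5)
    sdlog_noise <- sqrt(log(1 + peptide_cv^2))
    clean <- base[pidx] * eff
    tab <- data.table::data.table(
      protein_id = prot_ids[pidx],
      peptide_id = sprintf("%s_pep%02d", prot_ids[pidx],
                           sequence(npep))
    )
    for (i in seq_along(CHANNELS)) {
      mu <- clean * if (groups[i] == treated) fc[pidx] else 1
      tab[[CHANNELS[i]]] <- if (peptide_cv > 0) {
        mu * exp(rnorm(total, 0, sdlog_noise))
      } else {
        mu
      }
    }
    list(table = tab,
         meta = meta,
         truth = data.table::data.table(protein_id = prot_ids,
                                        log2_fold_change = log2(fc),
                                        base_abundance = base,
                                        n_peptides = npep))
  })
}

#' Simulate a two-band perivascular fluorescence line profile
#'
#' Per channel: intensity = background + two Gaussian bands centred at
#' `vessel_center - halfwidth` and `vessel_center + halfwidth` (the two
#' vessel walls / the halo shell on either side), plus optional Gaussian
#' noise. The band shape scales with the band position: the Gaussian sd of
#' each band defaults to `halfwidth / 4`, so a channel with twice the
#' halfwidth has twice the measurable band width and the downstream
#' diameter ratio recovers the halfwidth ratio.
#'
#' @param halfwidths named numeric vector: band-centre offset (µm) per
#'   channel (> 0); names become profile channel columns.
#' @param amplitudes band amplitudes per channel (recycled; default 100).
#' @param band_sd Gaussian sd of the bands per channel (recycled; default
#'   `halfwidths / 4`).
#' @param vessel_center centre position (µm) of the vessel on the axis.
#' @param background baseline intensity (default 10).
#' @param noise_sd additive Gaussian noise sd (default 0).
#' @param sampling_step sample spacing (µm, > 0; default 0.2).
#' @param extent half-length of the profile (µm); default
#'   `2.5 * max(halfwidths)`.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return profile data.frame (`distance_um` + one column per channel)
#'   with attribute `truth` (halfwidths and band sds).
#' @export
simulate_profile <- function(halfwidths, amplitudes = 100, band_sd = NULL,
                             vessel_center = 0, background = 10,
                             noise_sd = 0, sampling_step = 0.2,
                             extent = NULL, seed = 1L) {
  if (is.null(names(halfwidths)) || any(!nzchar(names(halfwidths)))) {
    stop_bad("halfwidths must be a named vector (names are channel names)")
  }
  if (any(halfwidths <= 0)) stop_bad("halfwidths must be > 0")
  if (sampling_step <= 0) stop_bad("sampling_step must be > 0")
  nch <- length(halfwidths)
  amplitudes <- rep_len(amplitudes, nch)
  if (is.null(band_sd)) band_sd <- halfwidths / 4
  band_sd <- setNames(rep_len(band_sd, nch), names(halfwidths))
  if (is.null(extent)) extent <- 2.5 * max(halfwidths)
  d <- seq(vessel_center - extent, vessel_center + extent, by = sampling_step)
  prof <- data.frame(distance_um = d)
  noise <- if (noise_sd > 0) {
    with_seed(seed, replicate(nch, rnorm(length(d), 0, noise_sd),
                              simplify = FALSE))
  } else {
    NULL
  }
  for (i in seq_len(nch)) {
    ctr <- vessel_center + c(-1, 1) * halfwidths[i]
    y <- background +
      amplitudes[i] * exp(-(d - ctr[1])^2 / (2 * band_sd[i]^2)) +
      amplitudes[i] * exp(-(d - ctr[2])^2 / (2 * band_sd[i]^2))
    if (!is.null(noise)) y <- y + noise[[i]]
    prof[[names(halfwidths)[i]]] <- y
  }
  attr(prof, "truth") <- list(halfwidths = halfwidths, band_sd = band_sd,
                              vessel_center = vessel_center)
  prof
}

#' Simulate a vessel field with cell points
#'
#' Draws a few smooth polyline vessels through a rectangular field and a
#' Poisson number of cell points that are either scattered near the
#' vessels (`"near"`, Gaussian displacement of sd `spread`), uniformly at
#' random (`"csr"`), or repelled from vessels (`"repelled"`,
#' rejection-sampled with acceptance probability increasing with
#' distance).
#'
#' @param n_polylines number of vessels (default 3).
#' @param xlim,ylim field extents in µm (default 0–500).
#' @param expected_points Poisson mean of the number of cells.
#' @param mode placement mode (see above).
#' @param spread Gaussian displacement sd for `"near"` (µm).
#' @param seed RNG seed.
#' @return list with `points` (n x 2 matrix) and `vessels`
#'   ([vessel_map()]).
#' @export
simulate_vessel_field <- function(n_polylines = 3, xlim = c(0, 500),
                                  ylim = c(0, 500), expected_points = 100,
                                  mode = c("near", "csr", "repelled"),
                                  spread = 15, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    polylines <- lapply(seq_len(n_polylines), function(i) {
      # a wiggly left-to-right polyline at a random height
      xs <- seq(xlim[1], xlim[2], length.out = 24)
      y0 <- runif(1, ylim[1] + 0.1 * diff(ylim), ylim[2] - 0.1 * diff(ylim))
      ys <- y0 + cumsum(rnorm(24, 0, diff(ylim) / 60))
      ys <- pmin(pmax(ys, ylim[1]), ylim[2])
      cbind(xs, ys)
    })
    vm <- vessel_map(polylines, xlim, ylim)
    n <- rpois(1, expected_points)
    n <- max(n, 1L)
    pts <- switch(mode,
      csr = cbind(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2])),
      near = {
        pl <- polylines[[1]]
        res <- matrix(NA_real_, n, 2)
        which_pl <- sample.int(n_polylines, n, replace = TRUE)
        for (i in seq_len(n)) {
          pl <- polylines[[which_pl[i]]]
          seg <- sample.int(nrow(pl) - 1L, 1L)
          t <- runif(1)
          base <- pl[seg, ] + t * (pl[seg + 1L, ] - pl[seg, ])
          res[i, ] <- base + rnorm(2, 0, spread)
        }
        res[, 1] <- pmin(pmax(res[, 1], xlim[1]), xlim[2])
        res[, 2] <- pmin(pmax(res[, 2], ylim[1]), ylim[2])
        res
      },
      repelled = {
        res <- matrix(NA_real_, 0, 2)
        dmax <- sqrt(diff(xlim)^2 + diff(ylim)^2) / 4
        while (nrow(res) < n) {
          cand <- cbind(runif(2 * n, xlim[1], xlim[2]),
                        runif(2 * n, ylim[1], ylim[2]))
          d <- min_distance_to_vessels(cand, vm)
          keep <- runif(2 * n) < pmin(1, (d / dmax)^2)
          res <- rbind(res, cand[keep, , drop = FALSE])
        }
        res[seq_len(n), , drop = FALSE]
      }
    )
    list(points = pts, vessels = vm)
  })
}

#' Simulate replicate particle-size histograms
#'
#' Particle diameters are drawn from a log-normal mixture (defaults mimic
#' an exosome-scale peak); each replicate is an independent draw binned on
#' a common grid, concentration-scaled, emulating replicate video
#' histograms of a nanoparticle tracking analysis.
#'
#' @param n_replicates number of replicate histograms (default 5).
#' @param components data.frame with `meanlog`, `sdlog`, `weight`
#'   (defaults to a single component whose density mode is 83 nm — the
#'   log-normal mode is `exp(meanlog - sdlog^2)` — with sdlog 0.35).
#' @param bin_edges_nm histogram bin edges (default 0–400 by 10 nm).
#' @param n_particles particles tracked per replicate (default 2000).
#' @param conc_per_particle concentration represented by one tracked
#'   particle (particles/ml; default 1e5).
#' @param seed RNG seed.
#' @return list with `replicates` (list of histogram data.frames) and
#'   `truth` (the component table).
#' @export
simulate_size_histograms <- function(n_replicates = 5,
                                     components = data.frame(
                                       meanlog = log(83) + 0.35^2,
                                       sdlog = 0.35, weight = 1),
                                     bin_edges_nm = seq(0, 400, by = 10),
                                     n_particles = 2000,
                                     conc_per_particle = 1e5,
                                     seed = 1L) {
  w <- components$weight / sum(components$weight)
  with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      comp <- sample.int(nrow(components), n_particles, replace = TRUE,
                         prob = w)
      dia <- rlnorm(n_particles, components$meanlog[comp],
                    components$sdlog[comp])
      dia <- dia[dia >= min(bin_edges_nm) & dia < max(bin_edges_nm)]
      counts <- tabulate(findInterval(dia, bin_edges_nm),
                         nbins = length(bin_edges_nm) - 1L)
      data.frame(bin_lo_nm = head(bin_edges_nm, -1),
                 bin_hi_nm = tail(bin_edges_nm, -1),
                 conc_per_ml = counts * conc_per_particle)
    })
    list(replicates = reps, truth = components)
  })
}

#' Simulate star-shaped cell contours
#'
#' Radial star polygons r(phi) = R (1 + a cos(k phi)): `a` is the
#' protrusion amplitude (0 gives a regular polygon approximating a disk,
#' larger `a` gives deeper spikes and lower circularity; `a < 1` keeps the
#' polygon simple).
#'
#' @param n_cells number of contours.
#' @param protrusion_amplitude spike depth `a` in \[0, 1) (recycled).
#' @param n_spikes number of spikes `k` (default 7).
#' @param base_radius mean radius R in µm (default 8.5, a ~17 µm cell).
#' @param n_vertices vertices per contour (default 180).
#' @param radius_jitter multiplicative radial noise sd (default 0).
#' @param seed RNG seed.
#' @return long data.frame `contour_id`, `vertex_index`, `x_um`, `y_um`
#'   with attribute `truth` (per-contour amplitudes).
#' @export
simulate_contours <- function(n_cells = 1, protrusion_amplitude = 0.3,
                              n_spikes = 7, base_radius = 8.5,
                              n_vertices = 180, radius_jitter = 0,
                              seed = 1L) {
  a <- rep_len(protrusion_amplitude, n_cells)
  if (any(a < 0 | a >= 1)) stop_bad("protrusion_amplitude must be in [0, 1)")
  with_seed(seed, {
    rows <- lapply(seq_len(n_cells), function(i) {
      phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
      r <- base_radius * (1 + a[i] * cos(n_spikes * phi))
      if (radius_jitter > 0) r <- r * exp(rnorm(n_vertices, 0, radius_jitter))
      data.frame(contour_id = sprintf("cell%03d", i),
                 vertex_index = seq_len(n_vertices),
                 x_um = r * cos(phi), y_um = r * sin(phi))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(contour_id = sprintf("cell%03d",
                                                          seq_len(n_cells)),
                                     protrusion_amplitude = a)
    out
  })
}

#' Simulate transwell arrival kinetics with a fluorescence standard curve
#'
#' Transmigrated-cell counts follow a logistic arrival curve
#' `plateau / (1 + exp(-(t - t_half) / tau))`; the plate-reader
#' fluorescence is a linear map of the count plus Gaussian noise. A clean
#' standard curve over the count range is returned alongside replicate
#' readings, so the calibration can be tested by recovery.
#'
#' @param times_min reading times (minutes).
#' @param plateau asymptotic transmigrated-cell count.
#' @param t_half time of half-maximal arrival (minutes).
#' @param tau logistic time scale (minutes).
#' @param fluor_per_cell slope of the fluorescence map.
#' @param fluor_background intercept of the fluorescence map.
#' @param noise_sd fluorescence noise sd (default 0).
#' @param n_replicates replicate wells (default 3).
#' @param seed RNG seed.
#' @return list with `curve` (standard-curve data.frame), `readings`
#'   (`time_min`, `replicate`, `fluorescence`) and `truth` (the true count
#'   series).
#' @export
simulate_transwell_kinetics <- function(times_min = seq(0, 120, by = 15),
                                        plateau = 1000, t_half = 30,
                                        tau = 10, fluor_per_cell = 0.1,
                                        fluor_background = 5,
                                        noise_sd = 0, n_replicates = 3,
                                        seed = 1L) {
  true_counts <- plateau / (1 + exp(-(times_min - t_half) / tau))
  curve_counts <- seq(0, plateau, length.out = 11)
  curve <- data.frame(
    fluorescence = fluor_background + fluor_per_cell * curve_counts,
    cell_count = curve_counts
  )
  readings <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      f <- fluor_background + fluor_per_cell * true_counts
      if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
      data.frame(time_min = times_min, replicate = r, fluorescence = f)
    }))
  })
  list(curve = curve, readings = readings,
       truth = data.frame(time_min = times_min, cell_count = true_counts))
}
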