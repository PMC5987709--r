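# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# straight track along +x: (0,0) -> (10,0) -> (20,0), dt = 1 min
straight_track <- function(id = "s") {
  data.frame(track_id = id, t_min = 0:2, x_um = c(0, 10, 20), y_um = 0)
}

# right-angle track: (0,0) -> (10,0) -> (10,10)
elbow_track <- function(id = "e") {
  data.frame(track_id = id, t_min = 0:2, x_um = c(0, 10, 10),
             y_um = c(0, 0, 10))
}

# random track with n points, coordinates ~ U(-50, 50)
random_track <- function(id, n = 5) {
  data.frame(track_id = id, t_min = seq_len(n) - 1,
             x_um = runif(n, -50, 50), y_um = runif(n, -50, 50))
}

# brute-force oracle written directly from the formula text, independent
# of the package implementation (plain loops, no shared helpers)
oracle_metrics <- function(tr, dir) {
  tr <- tr[order(tr$t_min), ]
  n <- nrow(tr)
  len <- 0
  for (i in 2:n) {
    len <- len + sqrt((tr$x_um[i] - tr$x_um[i - 1])^2 +
                      (tr$y_um[i] - tr$y_um[i - 1])^2)
  }
  ex <- tr$x_um[n] - tr$x_um[1]
  ey <- tr$y_um[n] - tr$y_um[1]
  disp <- sqrt(ex^2 + ey^2)
  upg <- ex * dir[1] + ey * dir[2]
  angles <- c()
  for (i in 2:n) {
    dx <- tr$x_um[i] - tr$x_um[i - 1]
    dy <- tr$y_um[i] - tr$y_um[i - 1]
    if (dx != 0 || dy != 0) angles <- c(angles, atan2(dy, dx) * 180 / pi)
  }
  dtheta <- c()
  if (length(angles) >= 2) {
    for (i in 2:length(angles)) {
      d <- angles[i] - angles[i - 1]
      while (d > 180) d <- d - 360
      while (d <= -180) d <- d + 360
      dtheta <- c(dtheta, sqrt(d^2))  # |x| = sqrt(x^2)
    }
  }
  list(track_length = len, displacement = disp,
       upgradient_displacement = upg,
       chemotactic_displacement = upg / len,
       speed = len / (tr$t_min[n] - tr$t_min[1]),
       chemotactic_index = upg / disp,
       mean_angle_change = if (length(dtheta)) mean(dtheta) else NA_real_)
}

# tiny peptide table with explicit intensities (one protein, one peptide
# per row block); intensities is a named list protein -> 6-vector
toy_peptide_table <- function(intensities, n_peptides = 1) {
  rows <- list()
  for (p in names(intensities)) {
    for (k in seq_len(n_peptides)) {
      v <- intensities[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, peptide_id = sprintf("%s_%d", p, k),
        c1 = v[1], c2 = v[2], c3 = v[3], c4 = v[4], c5 = v[5], c6 = v[6])
    }
  }
  do.call(rbind, rows)
}

toy_meta <- function(conc = rep(1, 6)) {
  sample_meta(c("ss", "ss", "ss", "TNFa", "TNFa", "TNFa"), conc)
}

# regular n-gon of given radius, optionally scaled/rotated
regular_polygon <- function(n, radius = 1) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(phi), radius * sin(phi))
}
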