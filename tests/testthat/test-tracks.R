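test_that("track metrics match hand geometry", {
  g <- gradient_frame(1, 0)

  m <- track_metrics(straight_track(), g)
  expect_equal(m$track_length, 20)
  expect_equal(m$displacement, 20)
  expect_equal(m$chemotactic_displacement, 1)
  expect_equal(m$chemotactic_index, 1)
  expect_equal(m$speed, 10)
  expect_equal(m$mean_angle_change, 0)

  # orthogonal to the gradient
  up <- data.frame(track_id = "u", t_min = 0:2, x_um = 0,
                   y_um = c(0, 10, 20))
  m <- track_metrics(up, g)
  expect_equal(m$chemotactic_displacement, 0)
  expect_equal(m$chemotactic_index, 0)

  m <- track_metrics(elbow_track(), g)
  expect_equal(m$track_length, 20)
  expect_equal(m$displacement, sqrt(200), tolerance = 1e-12)
  expect_equal(m$upgradient_displacement, 10)
  expect_equal(m$chemotactic_displacement, 0.5)
  expect_equal(m$chemotactic_index, cos(pi / 4), tolerance = 1e-12)
  expect_equal(m$mean_angle_change, 90)
})

test_that("metrics match an independent brute-force oracle on random tracks", {
  set.seed(71)
  dir <- c(1, 0)
  for (i in 1:25) {
    tr <- random_track(sprintf("r%02d", i), n = 5)
    got <- track_metrics(tr, gradient_frame(dir[1], dir[2]))
    want <- oracle_metrics(tr, dir)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("chemotactic displacement identity and rigid-motion invariance hold", {
  set.seed(72)
  for (i in 1:20) {
    tr <- random_track("x", n = 6)
    m <- track_metrics(tr, gradient_frame(1, 0))
    # CD = CI * displacement / track_length, algebraically
    expect_equal(m$chemotactic_displacement,
                 m$chemotactic_index * m$displacement / m$track_length,
                 tolerance = 1e-12)
    # translation invariance
    tr2 <- transform(tr, x_um = x_um + 123.4, y_um = y_um - 77.7)
    m2 <- track_metrics(tr2, gradient_frame(1, 0))
    expect_equal(as.data.frame(m2)[-1], as.data.frame(m)[-1],
                 tolerance = 1e-9)
    # joint rotation of track and gradient
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    xy <- as.matrix(tr[, c("x_um", "y_um")]) %*% t(R)
    tr3 <- data.frame(track_id = tr$track_id, t_min = tr$t_min,
                      x_um = xy[, 1], y_um = xy[, 2])
    gd <- R %*% c(1, 0)
    m3 <- track_metrics(tr3, gradient_frame(gd[1], gd[2]))
    expect_equal(as.data.frame(m3)[-1], as.data.frame(m)[-1],
                 tolerance = 1e-9)
  }
})

test_that("degenerate tracks give missing values, not zeros", {
  still <- data.frame(track_id = "z", t_min = 0:2, x_um = 0, y_um = 0)
  m <- track_metrics(still, gradient_frame(1, 0))
  expect_true(is.na(m$chemotactic_displacement))
  expect_true(is.na(m$chemotactic_index))
  expect_equal(m$speed, 0)

  one_step <- data.frame(track_id = "o", t_min = 0:1, x_um = c(0, 5), y_um = 0)
  expect_true(is.na(track_metrics(one_step)$mean_angle_change))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(track_metrics(straight_track(), c(1, 1)), "unit vector")
  expect_error(gradient_frame(0, 0), "non-zero")
  bad <- data.frame(track_id = "b", t_min = c(0, 0, 1), x_um = 0:2, y_um = 0)
  expect_error(track_metrics(bad), "non-increasing")
  expect_error(track_metrics(straight_track()[1, ]), "fewer than 2")
})

test_that("displacement filter is inclusive at the threshold", {
  mk <- function(id, d) data.frame(track_id = id, t_min = 0:1,
                                   x_um = c(0, d), y_um = 0)
  tr <- rbind(mk("at", 24.1), mk("below", 24.0999), mk("above", 30))
  kept <- filter_by_displacement(tr, 24.1)
  expect_setequal(unique(kept$track_id), c("at", "above"))
  expect_equal(nrow(filter_by_displacement(tr[0, ], 24.1)), 0)
})

test_that("angle histogram bins endpoint angles and normalizes", {
  g <- gradient_frame(1, 0)
  tr <- do.call(rbind, lapply(1:5, function(i) straight_track(paste0("s", i))))
  h <- angle_histogram(tr, g, n_bins = 8)
  expect_equal(h$fraction[h$bin_center == 0], 1)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)

  # isotropic straight tracks: each of 8 sectors gets 1/8 +- 0.02
  set.seed(5)
  n <- 4000
  ang <- runif(n, -pi, pi)
  iso <- data.frame(track_id = rep(sprintf("i%04d", 1:n), each = 2),
                    t_min = rep(0:1, n),
                    x_um = as.vector(rbind(0, 10 * cos(ang))),
                    y_um = as.vector(rbind(0, 10 * sin(ang))))
  h <- angle_histogram(iso, g, n_bins = 8)
  expect_true(all(abs(h$fraction - 0.125) < 0.02))
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_error(angle_histogram(tr, g, n_bins = 7), "divide 360")
})

test_that("group comparison reports means, folds and Welch p-values", {
  m <- data.frame(group = rep(c("ctrl", "eev"), each = 4),
                  speed = c(1, 2, 3, 4, 1, 2, 3, 4))
  gc <- group_compare(m, reference = "ctrl")
  expect_equal(gc$fold_change, c(1, 1))
  expect_equal(gc$p_value[gc$group == "eev"], 1, tolerance = 1e-12)

  set.seed(42)
  shifted <- data.frame(group = rep(c("a", "b"), each = 100),
                        v = c(rnorm(100), rnorm(100, mean = 1)))
  gc <- group_compare(shifted, reference = "a")
  expect_lt(gc$p_value[gc$group == "b"], 1e-3)

  expect_error(group_compare(data.frame(group = c("a", "a", "b"), v = 1:3)),
               "'b'")
})
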