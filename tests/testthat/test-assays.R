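test_that("point-to-vessel distances match hand geometry", {
  vm <- vessel_map(list(rbind(c(-10, 0), c(10, 0))), c(-20, 20), c(-20, 20))
  pts <- rbind(c(0, 0),     # on the vessel
               c(0, 5),     # perpendicular foot
               c(20, 5))    # nearest endpoint
  d <- min_distance_to_vessels(pts, vm)
  expect_equal(d, c(0, 5, sqrt(125)), tolerance = 1e-12)
  expect_error(min_distance_to_vessels(pts[0, , drop = FALSE], vm),
               "at least one point")
  expect_error(vessel_map(list(), c(0, 1), c(0, 1)), "at least one polyline")
})

test_that("distances are invariant under joint rigid motions", {
  set.seed(19)
  vm <- simulate_vessel_field(expected_points = 50, seed = 6)
  pts <- vm$points
  d0 <- min_distance_to_vessels(pts, vm$vessels)
  a <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  shift <- c(111, -222)
  mv <- function(p) sweep(p %*% t(R), 2, shift, "+")
  vm2 <- vessel_map(lapply(vm$vessels$polylines, mv),
                    xlim = c(-1e4, 1e4), ylim = c(-1e4, 1e4))
  expect_equal(min_distance_to_vessels(mv(pts), vm2), d0, tolerance = 1e-9)
})

test_that("CSR-normalized distance behaves as a spatial statistic", {
  # uniform points -> 1 +- 0.05 at fixed seed
  f <- simulate_vessel_field(mode = "csr", expected_points = 1500, seed = 1)
  r <- normalized_mean_distance(f$points, f$vessels, n_mc = 20000, seed = 101)
  expect_lt(abs(r$normalized - 1), 0.05)

  # all points on vessels -> 0
  pl <- f$vessels$polylines[[1]]
  on_v <- normalized_mean_distance(pl, f$vessels, seed = 101)
  expect_equal(on_v$normalized, 0, tolerance = 1e-12)

  # repelled points -> > 1; attracted -> < 1
  rep_f <- simulate_vessel_field(mode = "repelled", expected_points = 400,
                                 seed = 2)
  expect_gt(normalized_mean_distance(rep_f$points, rep_f$vessels,
                                     seed = 101)$normalized, 1)
  near_f <- simulate_vessel_field(mode = "near", expected_points = 400,
                                  spread = 10, seed = 3)
  expect_lt(normalized_mean_distance(near_f$points, near_f$vessels,
                                     seed = 101)$normalized, 1)

  # scale invariance under joint rescaling
  k <- 3.5
  vmk <- vessel_map(lapply(f$vessels$polylines, function(p) p * k),
                    f$vessels$xlim * k, f$vessels$ylim * k)
  rk <- normalized_mean_distance(f$points * k, vmk, n_mc = 20000, seed = 101)
  expect_equal(rk$normalized, r$normalized, tolerance = 1e-9)
})

test_that("adhesion rule counts sustained runs only", {
  ev <- list(three = c(TRUE, TRUE, TRUE),
             two = c(FALSE, TRUE, TRUE, FALSE),
             split = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(adherent_tracks(ev, 3, 1), 1)
  # data.frame interface
  df <- data.frame(cell_id = rep(c("a", "b"), each = 4),
                   frame = rep(1:4, 2),
                   present = c(TRUE, TRUE, TRUE, FALSE,
                               TRUE, FALSE, TRUE, TRUE))
  expect_equal(adherent_tracks(df, 3, 1), 1)
  # monotone non-increasing in min_duration_s
  counts <- vapply(1:5, function(s) adherent_tracks(ev, s, 1), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # frame interval scales dwell time: 2 frames at 2 s span 4 s >= 3 s
  expect_equal(adherent_tracks(list(a = c(TRUE, TRUE)), 3, 2), 1)
  expect_error(adherent_tracks(ev, 3, 0), "> 0")
})

test_that("transwell calibration inverts the standard curve", {
  curve <- data.frame(fluorescence = c(0, 100), cell_count = c(0, 1000))
  rd <- data.frame(time_min = rep(c(0, 30), each = 3),
                   replicate = rep(1:3, 2),
                   fluorescence = c(50, 50, 50, -10, -10, -10))
  res <- calibrate_transwell(curve, rd)
  expect_equal(res$counts$cell_count[1], 500)
  expect_equal(res$counts$cell_count[4], 0)  # clipped below intercept
  expect_equal(res$kinetics$sem_count, c(0, 0))  # identical replicates
  bad <- data.frame(fluorescence = c(5, 5), cell_count = c(0, 10))
  expect_error(calibrate_transwell(bad, rd), "degenerate")
})

test_that("transwell kinetics recovery from the synthetic generator", {
  sim <- simulate_transwell_kinetics(noise_sd = 0, seed = 2)
  res <- calibrate_transwell(sim$curve, sim$readings)
  expect_equal(res$kinetics$mean_count, sim$truth$cell_count,
               tolerance = 1e-9)
})

test_that("NTA averaging is linear and recovers the generator mode", {
  sim <- simulate_size_histograms(seed = 9)
  # five identical histograms average to themselves
  same <- nta_average(rep(sim$replicates[1], 5))
  expect_equal(same$histogram$conc_per_ml, sim$replicates[[1]]$conc_per_ml)
  # total of the average = mean of totals
  avg <- nta_average(sim$replicates)
  expect_equal(avg$summary$total_concentration,
               mean(vapply(sim$replicates, function(r) sum(r$conc_per_ml),
                           numeric(1))),
               tolerance = 1e-9)
  # log-normal density mode 83 nm: the modal bin contains 83
  modal <- avg$histogram[which.max(avg$histogram$conc_per_ml), ]
  expect_true(modal$bin_lo_nm <= 83 && 83 < modal$bin_hi_nm)
  # mismatched binning is an error
  shifted <- sim$replicates
  shifted[[2]]$bin_lo_nm <- shifted[[2]]$bin_lo_nm + 1
  expect_error(nta_average(shifted), "mismatched")
})

test_that("pore coverage follows the disc-area formula", {
  expect_equal(pore_coverage(3, 8e5), 5.654867, tolerance = 1e-6)
  expect_equal(round(pore_coverage(3, 8e5), 1), 5.7)
  expect_equal(pore_coverage(3, 1.6e6), 2 * pore_coverage(3, 8e5),
               tolerance = 1e-12)
  expect_lt(pore_coverage(1e-6, 8e5), 1e-12)  # d -> 0 limit
  expect_error(pore_coverage(-1, 8e5), "> 0")
})
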