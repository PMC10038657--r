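test_that("Bhattacharyya coefficient matches its closed form and bounds", {
  expect_equal(bhattacharyya_coefficient(rep(0.25, 4), rep(0.25, 4)), 1)
  expect_equal(bhattacharyya_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya_coefficient(c(0.5, 0.5), c(0.9, 0.1)),
               sqrt(0.45) + sqrt(0.05))
  # symmetric
  p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.1, 0.3)
  expect_identical(bhattacharyya_coefficient(p, q),
                   bhattacharyya_coefficient(q, p))
  # strict about grids and normalization
  expect_error(bhattacharyya_coefficient(c(0.5, 0.5), c(1, 1)), "normalized")
  expect_error(bhattacharyya_coefficient(c(0.5, 0.5), c(0.3, 0.3, 0.4)),
               "different grids")
  d1 <- tibble::tibble(start_year = c(1500, 1525), end_year = c(1525, 1550),
                       weight = c(0.5, 0.5))
  d2 <- dplyr::mutate(d1, start_year = start_year + 25,
                      end_year = end_year + 25)
  expect_error(bhattacharyya_coefficient(d1, d2), "bin grids")
})

test_that("record normalization keeps the grid and zero bins", {
  rec <- tibble::tibble(start_year = c(1500, 1525, 1550),
                        end_year = c(1525, 1550, 1575),
                        count = c(10, 30, 0))
  d <- normalize_record(rec)
  expect_equal(d$weight, c(0.25, 0.75, 0))
  expect_equal(normalize_record(dplyr::mutate(rec, count = 5))$weight,
               rep(1 / 3, 3))
  expect_error(normalize_record(dplyr::mutate(rec, count = 0)), "positive")
})

test_that("migration mass is distributed by calendar overlap", {
  s <- scaling_factor(1e-8, 0.1, present_year = 2000)
  rec <- tibble::tibble(start_year = c(1500, 1600), end_year = c(1600, 1700),
                        count = c(1, 1))
  spt <- s$mu / s$g # scaled time per calendar year
  # one segment wholly inside the first bin
  traj1 <- tibble::tibble(left_time_boundary = c(0, (2000 - 1580) * spt),
                          right_time_boundary = c((2000 - 1580) * spt,
                                                  (2000 - 1520) * spt),
                          m = c(0, 1), M = c(0, 1))
  traj1$M <- c(0, 1) # mass normalized internally
  d1 <- migration_density_in_years(traj1, s, rec)
  expect_equal(d1$weight, c(1, 0))
  # one uniform segment straddling the two equal bins equally
  traj2 <- tibble::tibble(left_time_boundary = c(0, (2000 - 1650) * spt),
                          right_time_boundary = c((2000 - 1650) * spt,
                                                  (2000 - 1550) * spt),
                          m = c(0, 1), M = c(0, 1))
  d2 <- migration_density_in_years(traj2, s, rec)
  expect_equal(d2$weight, c(0.5, 0.5))
  # trajectory entirely outside the window
  traj3 <- tibble::tibble(left_time_boundary = c(0, (2000 - 1200) * spt),
                          right_time_boundary = c((2000 - 1200) * spt,
                                                  (2000 - 1100) * spt),
                          m = c(0, 1), M = c(0, 1))
  expect_error(migration_density_in_years(traj3, s, rec), "no overlap")
})

test_that("a trajectory manufactured from a record maps back onto it", {
  rec <- generate_historical_record(peak_year = 1780, width = 70)
  s0 <- scaling_factor(4.85e-9, 0.067)
  traj <- generate_migration_trajectory(rec, s0)
  d <- migration_density_in_years(traj, s0, rec)
  tv <- sum(abs(d$weight - normalize_record(rec)$weight)) / 2
  expect_lt(tv, 0.01)
})

test_that("the scaling-grid scan recovers the true mu/g ridge", {
  rec <- generate_historical_record()
  s0 <- scaling_factor(4.85e-9, 0.067)
  traj <- generate_migration_trajectory(rec, s0)
  mu_grid <- exp(seq(log(1e-9), log(1e-8), length.out = 25))
  g_grid <- seq(0.05, 0.1, length.out = 12)
  surf <- scan_scaling_grid(traj, rec, mu_grid, g_grid)
  expect_true(all(surf$bc >= 0 & surf$bc <= 1))
  true_ratio <- s0$mu / s0$g
  step <- mu_grid[2] / mu_grid[1]
  expect_lt(abs(log(surf$ridge_ratio / true_ratio)),
            log(step) + log(g_grid[2] / g_grid[1]))
  # tidy/glance expose the grid and argmax
  td <- tidy(surf)
  expect_equal(nrow(td), length(mu_grid) * length(g_grid))
  expect_equal(glance(surf)$bc_max, surf$argmax$bc_max)
})

test_that("calibrating mu recovers the generating value and scales linearly", {
  rec <- generate_historical_record()
  s0 <- scaling_factor(4.85e-9, 0.067)
  traj <- generate_migration_trajectory(rec, s0)
  cal <- calibrate_mu(traj, rec, g_fixed = 0.067)
  expect_lt(abs(cal$mu_hat - 4.85e-9) / 4.85e-9, 0.01)
  # compressing the trajectory's time axis by 2 doubles mu_hat
  traj2 <- dplyr::mutate(traj,
                         left_time_boundary = left_time_boundary / 2,
                         right_time_boundary = right_time_boundary / 2,
                         m = m * 2)
  cal2 <- calibrate_mu(traj2, rec, g_fixed = 0.067)
  expect_equal(cal2$mu_hat / cal$mu_hat, 0.5, tolerance = 0.02)
  # halving g halves mu_hat
  cal3 <- calibrate_mu(traj, rec, g_fixed = 0.067 / 2)
  expect_equal(cal3$mu_hat / cal$mu_hat, 0.5, tolerance = 0.02)
})

test_that("calibrated dates rescale inversely with the mutation rate", {
  expect_equal(rescale_calibrated_date(5000, 4.85e-9, 4.85e-9), 5000)
  expect_equal(rescale_calibrated_date(5000, 4.85e-9 * 0.6, 4.85e-9), 3000)
  expect_error(rescale_calibrated_date(-1, 1e-9, 1e-9), "positive")
})
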