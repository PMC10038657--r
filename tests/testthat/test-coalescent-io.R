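test_that("coalescent rate tables round-trip through files", {
  tbl <- tibble::tibble(
    time_index = 0:2,
    left_time_boundary = c(0, 1e-6, 5e-6),
    right_time_boundary = c(1e-6, 5e-6, Inf),
    lambda00 = c(2.5, 1.25, 0.8),
    lambda01 = c(0.1, 0.6, 0.8),
    lambda11 = c(3.0, 1.0, 0.8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coal_rate_table(tbl, path)
  back <- read_coal_rate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))

  # one-lambda file populates lambda00 only
  one <- tbl[, 1:4]
  write_coal_rate_table(one, path)
  back1 <- read_coal_rate_table(path)
  expect_named(back1, c("time_index", "left_time_boundary",
                        "right_time_boundary", "lambda00"))
  expect_equal(back1$lambda00, one$lambda00)
})

test_that("malformed rate tables are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_index\tleft_time_boundary\tright_time_boundary\tlambda_00",
               "0\t0\t1e-6\t2.0",
               "1\t1e-6\t5e-7\t1.0"), path)
  expect_error(read_coal_rate_table(path), "line 2")
  writeLines(c("time_index\tleft_time_boundary\tright_time_boundary\tlambda_00",
               "0\t0\t1e-6\t-2.0"), path)
  expect_error(read_coal_rate_table(path), "negative rate")
  writeLines(c("time_index\tleft_boundary\tright_time_boundary\tlambda_00",
               "0\t0\t1e-6\t2.0"), path)
  expect_error(read_coal_rate_table(path), "header")
})

test_that("relative cross-coalescence follows 2*l01/(l00+l11)", {
  tbl <- tibble::tibble(
    time_index = 0:2, left_time_boundary = c(0, 1, 2),
    right_time_boundary = c(1, 2, 3),
    lambda00 = c(1, 2, 1), lambda01 = c(1, 1.5, 0), lambda11 = c(1, 4, 5))
  r <- relative_cross_coalescence(tbl)$rccr
  expect_equal(r, c(1, 0.5, 0))
  # invariant under joint rescaling of all rates
  scaled <- dplyr::mutate(tbl, dplyr::across(dplyr::starts_with("lambda"), ~ .x * 7.3))
  expect_equal(relative_cross_coalescence(scaled)$rccr, r)
  # missing cross term and zero denominator are errors
  expect_error(relative_cross_coalescence(tbl[, 1:4]), "lambda01")
  zero <- dplyr::mutate(tbl, lambda00 = 0, lambda11 = 0)
  expect_error(relative_cross_coalescence(zero), "segment 1")
})

test_that("effective size and time conversion follow the stated conventions", {
  s <- scaling_factor(4.85e-9, 0.067)
  tbl <- tibble::tibble(time_index = 0L, left_time_boundary = 0,
                        right_time_boundary = 1e-6, lambda00 = 1)
  expect_equal(effective_size(tbl, s)$ne, 1 / (2 * 1 * 4.85e-9))
  # reciprocal in lambda, reciprocal in mu
  expect_equal(effective_size(dplyr::mutate(tbl, lambda00 = 2), s)$ne,
               effective_size(tbl, s)$ne / 2)
  s2 <- scaling_factor(2 * 4.85e-9, 0.067)
  expect_equal(effective_size(tbl, s2)$ne, effective_size(tbl, s)$ne / 2)
  expect_error(effective_size(dplyr::mutate(tbl, lambda00 = 0), s), "zero")

  expect_equal(scale_to_years(3.25e-4, s), 3.25e-4 / 4.85e-9 * 0.067)
  expect_equal(scale_to_years(3.25e-4, s), 4489.7, tolerance = 1e-4)
  expect_equal(scale_to_years(0, s), 0)
  expect_error(scale_to_years(-1e-8, s), "non-negative")
})

test_that("year conversion depends on (mu, g) only through g/mu", {
  times <- c(0, 1e-8, 3.25e-7, 2e-6)
  for (c_fac in c(0.5, 2, 10)) {
    s1 <- scaling_factor(4.85e-9, 0.067)
    s2 <- scaling_factor(c_fac * 4.85e-9, c_fac * 0.067)
    expect_equal(scale_to_years(times, s2), scale_to_years(times, s1))
  }
})

test_that("migration trajectories validate and round-trip", {
  s <- scaling_factor(4.85e-9, 0.067)
  traj <- generate_migration_trajectory(generate_historical_record(), s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_migration_trajectory(traj, path)
  back <- read_migration_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj))

  bad <- traj
  bad$M <- rev(bad$M)
  expect_error(write_migration_trajectory(bad, path), "non-decreasing")
})
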