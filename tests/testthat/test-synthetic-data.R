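test_that("panel simulation responds to the differentiation parameter", {
  p0 <- simulate_panel_freqs(500, fst = 0, seed = 1)
  expect_identical(p0$pA, p0$pB)
  mean_diff <- vapply(c(0.05, 0.15, 0.3), function(f) {
    p <- simulate_panel_freqs(10000, fst = f, seed = 42)
    mean(abs(p$pA - p$pB))
  }, numeric(1))
  expect_true(all(diff(mean_diff) > 0))
  # positions strictly increasing within chromosome, genetic map monotone
  p <- simulate_panel_freqs(2000, fst = 0.2, seed = 7)
  by_chrom <- split(p, p$chrom)
  for (sub in by_chrom) {
    expect_true(all(diff(sub$pos) > 0))
    expect_true(all(diff(sub$genetic_pos) >= 0))
  }
  # deterministic given the seed
  expect_identical(simulate_panel_freqs(100, 0.2, seed = 5),
                   simulate_panel_freqs(100, 0.2, seed = 5))
})

test_that("informative-site fraction matches a brute-force Balding-Nichols draw", {
  f <- 0.2
  p <- simulate_panel_freqs(10000, fst = f, seed = 99)
  frac <- mean(abs(p$pA - p$pB) > 0.3)
  # independent oracle: direct beta sampling outside the package
  oracle <- withr::with_seed(123, {
    anc <- runif(40000, 0.05, 0.95)
    shape <- (1 - f) / f
    qa <- rbeta(40000, anc * shape, (1 - anc) * shape)
    qb <- rbeta(40000, anc * shape, (1 - anc) * shape)
    mean(abs(qa - qb) > 0.3)
  })
  se <- sqrt(oracle * (1 - oracle) * (1 / 10000 + 1 / 40000))
  expect_lt(abs(frac - oracle), 2 * se + 1e-12)
})

test_that("admixed genomes have the expected dosage and tract structure", {
  panel <- simulate_panel_freqs(1500, fst = 0.3, seed = 2)
  # alpha -> 0: no specialist tracts, genotypes from the generalist panel
  sim0 <- simulate_admixed_genomes(panel, t_gen = 100, alpha = 0, n_ind = 2,
                                   seed = 3)
  expect_false(any(sim0$truth$tracts$ancestry == "specialist"))
  # mean dosage ~ 2 alpha
  alpha <- 0.3
  sim <- simulate_admixed_genomes(panel, t_gen = 450, alpha = alpha,
                                  n_ind = 50, error_rate = 0, seed = 4)
  spec_frac <- with(sim$truth$tracts,
                    sum((end_bp - start_bp)[ancestry == "specialist"]) /
                      sum(end_bp - start_bp))
  se <- sqrt(alpha * (1 - alpha) / (50 * 2 * 3)) # rough: per-chromosome draws
  expect_lt(abs(spec_frac - alpha), 3 * se)
  expect_error(simulate_admixed_genomes(panel[0, ], 100, 0.5, 1), "no sites")
})

test_that("specialist tract lengths are exponential with rate (1-alpha)T", {
  t_gen <- 450; alpha <- 0.3
  # ~200 Morgans of genome across individuals at 1 cM/Mb
  panel <- simulate_panel_freqs(60, fst = 0.3, seed = 5)
  sim <- simulate_admixed_genomes(panel, t_gen, alpha, n_ind = 34, seed = 6)
  tr <- sim$truth$tracts
  spec <- tr[tr$ancestry == "specialist", ]
  # interior tracts only (chromosome ends censor the exponential)
  interior <- spec[spec$start_bp > 0 & spec$end_bp < 100e6, ]
  len_m <- (interior$end_bp - interior$start_bp) * 1e-8 # uniform 1 cM/Mb map
  expect_gt(length(len_m), 5000)
  expect_equal(mean(len_m), 1 / ((1 - alpha) * t_gen), tolerance = 0.05)
  ks <- suppressWarnings(
    stats::ks.test(len_m, "pexp", rate = (1 - alpha) * t_gen))
  expect_gt(ks$p.value, 0.01)
})

test_that("tract-length law holds across (T, alpha) settings", {
  for (cfg in list(c(50, 0.5), c(450, 0.3), c(2000, 0.1))) {
    t_gen <- cfg[1]; alpha <- cfg[2]
    panel <- simulate_panel_freqs(30, fst = 0.3, seed = 8)
    n_ind <- ceiling(t_gen / 40) + 5
    sim <- simulate_admixed_genomes(panel, t_gen, alpha, n_ind = n_ind,
                                    seed = 9 + t_gen)
    tr <- sim$truth$tracts
    spec <- tr[tr$ancestry == "specialist" & tr$start_bp > 0 &
                 tr$end_bp < 100e6, ]
    len_m <- (spec$end_bp - spec$start_bp) * 1e-8
    ks <- suppressWarnings(
      stats::ks.test(len_m, "pexp", rate = (1 - alpha) * t_gen))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("synthetic records sit on the fixed 25-year grid", {
  rec <- generate_historical_record(peak_year = 1790, width = 80, total = 12345)
  expect_equal(rec$start_year, seq(1500, 1850, by = 25))
  expect_equal(rec$end_year, seq(1525, 1875, by = 25))
  expect_equal(sum(rec$count), 12345)
  expect_equal(rec$start_year[which.max(rec$count)], 1775) # mode bin holds the peak
  expect_error(generate_historical_record(width = -1), "positive")
  expect_error(generate_historical_record(peak_year = 1400), "window")
})

test_that("generated trajectories plateau at 1 and scale with g", {
  rec <- generate_historical_record()
  s <- scaling_factor(4.85e-9, 0.067)
  traj <- generate_migration_trajectory(rec, s)
  expect_equal(max(traj$M), 1)
  expect_equal(traj$M[nrow(traj)], 1)
  # halving g at fixed mu halves all scaled boundaries
  s2 <- scaling_factor(4.85e-9, 0.067 / 2)
  traj2 <- generate_migration_trajectory(rec, s2)
  fin <- is.finite(traj$right_time_boundary)
  expect_equal(traj2$right_time_boundary[fin] / traj$right_time_boundary[fin],
               rep(2, sum(fin)))
  # Gaussian-pulse variant
  trajp <- generate_migration_trajectory(pulse = c(1780, 50), s = s)
  expect_equal(max(trajp$M), 1)
  expect_error(generate_migration_trajectory(pulse = c(1780, -2), s = s),
               "positive")
})

test_that("recombination maps are monotone and conserve total length", {
  map <- generate_recomb_map(c(chrA = 10e6), rate_cM_per_Mb = 1)
  expect_equal(genetic_position(map, "chrA", 10e6), 0.1) # 10 Mb at 1 cM/Mb
  het <- generate_recomb_map(c(chrA = 10e6), rate_cM_per_Mb = 1,
                             heterogeneity = 0.5, seed = 3)
  expect_true(all(diff(het$cM) >= 0))
  expect_equal(max(het$cM), max(map$cM))
  expect_error(generate_recomb_map(c(chrA = 1e6), rate_cM_per_Mb = 0),
               "positive")
})
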