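test_that("informative-site selection applies strict filters and greedy thinning", {
  panel <- tibble::tibble(
    chrom = "chr1", pos = c(1e4, 2e4, 3e4, 4e4),
    genetic_pos = c(1, 2, 3, 4) * 1e-4,
    pA = c(0.8, 0.3, 0.9, 0.5), pB = c(0.4, 0.0, 0.2, 0.5),
    nA = c(20, 20, 8, 20), nB = c(20, 20, 20, 20))
  kept <- select_informative_sites(panel, thin_bp = 0)
  # |0.4| kept, |0.3| exactly dropped (strict), low allele count dropped, 0 dropped
  expect_equal(kept$pos, 1e4)
  expect_error(select_informative_sites(panel[4, , drop = FALSE]),
               "no sites survive")

  dense <- dense_panel(n_sites = 100, spacing = 1000)
  thinned <- select_informative_sites(dense)
  expect_true(all(diff(thinned$pos) >= 10000))
  expect_equal(unique(diff(thinned$pos)), 10000) # greedy keeps the densest legal set
})

test_that("transition matrix obeys its limits and the semigroup property", {
  p <- hmm_params(450, 0.3)
  expect_equal(transition_matrix(0, p), diag(3), ignore_attr = TRUE)
  stat <- c(0.7^2, 2 * 0.3 * 0.7, 0.3^2)
  far <- transition_matrix(1e6, p)
  for (i in 1:3) expect_equal(unname(far[i, ]), stat)
  # hand-computed haploid persistence at d = 0.01, T = 450
  q_ss <- exp(-4.5) + (1 - exp(-4.5)) * 0.3
  expect_equal(transition_matrix(0.01, p)["d2", "d2"], q_ss^2)
  expect_error(transition_matrix(-0.1, p), "non-negative")

  # Chapman-Kolmogorov over random (d, T, alpha)
  withr::with_seed(11, {
    for (i in 1:20) {
      pp <- hmm_params(runif(1, 1, 2000), runif(1, 0.05, 0.95))
      d1 <- runif(1, 0, 0.05); d2 <- runif(1, 0, 0.05)
      expect_equal(transition_matrix(d1, pp) %*% transition_matrix(d2, pp),
                   transition_matrix(d1 + d2, pp), tolerance = 1e-12)
    }
  })
  # rows always sum to 1
  expect_equal(rowSums(transition_matrix(0.003, p)), rep(1, 3),
               ignore_attr = TRUE)
})

test_that("emission probabilities match the binomial mixture model", {
  expect_equal(emission_probs(2, 2, p_a = 1, p_b = 0, error_rate = 0), 1)
  expect_equal(emission_probs(1, 1, p_a = 1, p_b = 0, error_rate = 0), 1)
  expect_equal(emission_probs(0:2, 0, p_a = 0.9, p_b = 0.5, error_rate = 0),
               c(0.25, 0.5, 0.25))
  # missing genotype is uninformative
  expect_equal(emission_probs(NA, 0:2, 0.9, 0.1), rep(1, 3))
  expect_error(emission_probs(3, 0, 0.5, 0.5), "genotypes")
  expect_error(emission_probs(0, 5, 0.5, 0.5), "dosage")
})

test_that("forward-backward matches brute-force enumeration and log-space", {
  sites <- toy_sites()
  p <- hmm_params(450, 0.3, 0.01)
  for (g in list(c(2, 1, 0), c(0, 0, 0), c(2, 2, 2), c(1, NA, 2))) {
    fb <- forward_backward(g, sites, p)
    oracle <- enumerate_hmm(g, sites, p)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(fb$loglik, logspace_forward(g, sites, p), tolerance = 1e-9)
    expect_equal(fb$posteriors$p0 + fb$posteriors$p1 + fb$posteriors$p2,
                 rep(1, 3), tolerance = 1e-9)
  }
  # all-missing data: posteriors equal the stationary distribution
  fb_na <- forward_backward(c(NA, NA, NA), sites, p)
  stat <- c(0.49, 0.42, 0.09)
  for (i in 1:3)
    expect_equal(unlist(fb_na$posteriors[i, c("p0", "p1", "p2")]), stat,
                 ignore_attr = TRUE)
  # chromosome restarts: likelihood factorizes over chromosomes
  two <- dplyr::mutate(toy_sites(), chrom = c("chr1", "chr2", "chr2"))
  fb2 <- forward_backward(c(2, 1, 0), two, p)
  expect_equal(fb2$loglik, logspace_forward(c(2, 1, 0), two, p),
               tolerance = 1e-9)
})

test_that("viterbi matches enumeration, breaks ties low, and flips on evidence", {
  sites <- toy_sites()
  p <- hmm_params(450, 0.3, 0.01)
  for (g in list(c(2, 1, 0), c(2, 2, 2), c(0, 1, 1))) {
    v <- viterbi(g, sites, p)
    oracle <- enumerate_hmm(g, sites, p)
    expect_equal(v$dosage, oracle$best_path)
    expect_equal(attr(v, "logprob"), oracle$best_logprob, tolerance = 1e-10)
  }
  # uninformative data decodes to the modal stationary state (dosage 0)
  v_na <- viterbi(c(NA, NA, NA), sites, p)
  expect_equal(v_na$dosage, c(0, 0, 0))
  # a long specialist-diagnostic run flips the path to dosage 2
  n <- 40
  run_sites <- tibble::tibble(chrom = "chr1", pos = seq_len(n) * 1e4,
                              genetic_pos = seq_len(n) * 1e-4,
                              pA = 0.95, pB = 0.05)
  g_run <- c(rep(0, 15), rep(2, 10), rep(0, 15))
  v_run <- viterbi(g_run, run_sites, p)
  expect_true(all(v_run$dosage[16:25] == 2))
  expect_true(all(v_run$dosage[c(1:14, 27:40)] == 0))
})

test_that("pulse-time likelihood recovers T and scales with genetic distance", {
  panel <- simulate_panel_freqs(3000, fst = 0.3, seed = 21)
  sim <- simulate_admixed_genomes(panel, t_gen = 450, alpha = 0.3, n_ind = 10,
                                  seed = 22)
  est <- estimate_pulse_time(sim$genotypes, sim$sites, alpha = 0.3)
  expect_lt(abs(est$t_hat - 450) / 450, 0.15)
  expect_false(est$flat)
  # monotone separation between fast and slow pulses
  sim_fast <- simulate_admixed_genomes(panel, t_gen = 1000, alpha = 0.3,
                                       n_ind = 10, seed = 23)
  sim_slow <- simulate_admixed_genomes(panel, t_gen = 100, alpha = 0.3,
                                       n_ind = 10, seed = 24)
  t_fast <- estimate_pulse_time(sim_fast$genotypes, sim_fast$sites, 0.3)$t_hat
  t_slow <- estimate_pulse_time(sim_slow$genotypes, sim_slow$sites, 0.3)$t_hat
  expect_lt(t_slow, t_fast)
  # d.T identifiability: doubling distances halves the estimate
  sites2 <- dplyr::mutate(sim$sites, genetic_pos = genetic_pos * 2)
  est2 <- estimate_pulse_time(sim$genotypes, sites2, alpha = 0.3)
  expect_equal(est2$t_hat / est$t_hat, 0.5, tolerance = 0.02)
})

test_that("masking removes sites from timing estimation", {
  panel <- simulate_panel_freqs(600, fst = 0.3, seed = 31)
  sim <- simulate_admixed_genomes(panel, t_gen = 300, alpha = 0.3, n_ind = 4,
                                  seed = 32)
  mask <- tibble::tibble(chrom = "chr1", start = 0, end = 100e6)
  est <- estimate_pulse_time(sim$genotypes, sim$sites, 0.3, mask = mask)
  expect_equal(est$n_sites, sum(sim$sites$chrom != "chr1"))
})

test_that("block bootstrap yields percentile intervals with sane behavior", {
  panel <- simulate_panel_freqs(1200, fst = 0.3, seed = 41)
  sim <- simulate_admixed_genomes(panel, t_gen = 450, alpha = 0.3, n_ind = 8,
                                  seed = 42)
  bs <- bootstrap_pulse_time(sim$genotypes, sim$sites, alpha = 0.3,
                             block_sites = 100, n_boot = 40, seed = 43)
  expect_true(bs$ci_low <= bs$t_hat && bs$t_hat <= bs$ci_high)
  expect_equal(bs$n_blocks, 12)
  # CI narrows when the site count is quadrupled
  panel4 <- simulate_panel_freqs(4800, fst = 0.3, seed = 44)
  sim4 <- simulate_admixed_genomes(panel4, t_gen = 450, alpha = 0.3, n_ind = 8,
                                   seed = 45)
  bs4 <- bootstrap_pulse_time(sim4$genotypes, sim4$sites, alpha = 0.3,
                              block_sites = 100, n_boot = 40, seed = 46)
  expect_lt(bs4$ci_high - bs4$ci_low, bs$ci_high - bs$ci_low)
  expect_error(bootstrap_pulse_time(sim$genotypes, sim$sites, alpha = 0.3,
                                    block_sites = 1e6), "fewer than 2")
})

test_that("tract calling follows the midpoint convention", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(1, 2, 3, 4, 5) * 1e4)
  tr <- call_tracts(c(0, 0, 1, 1, 0), sites)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start_bp, 25000)
  expect_equal(tr$end_bp, 45000)
  expect_equal(tr$dosage_class, "heterozygous")
  # all-reference path: nothing called
  expect_equal(nrow(call_tracts(rep(0, 5), sites)), 0)
  # all-homozygous path: het and hom tracts spanning the site span
  tr2 <- call_tracts(rep(2, 5), sites)
  expect_equal(nrow(tr2), 2)
  expect_setequal(tr2$dosage_class, c("heterozygous", "homozygous"))
  expect_equal(unique(tr2$start_bp), 1e4 - 1)
  expect_equal(unique(tr2$end_bp), 5e4)
  # min_sites filters single-site blips
  expect_equal(nrow(call_tracts(c(0, 1, 0, 0, 0), sites)), 0)
  expect_equal(nrow(call_tracts(c(0, 1, 0, 0, 0), sites, min_sites = 1)), 1)
})

test_that("alpha estimation recovers the simulated admixture proportion", {
  panel <- simulate_panel_freqs(1500, fst = 0.3, seed = 51)
  sim <- simulate_admixed_genomes(panel, t_gen = 450, alpha = 0.3, n_ind = 6,
                                  seed = 52)
  ea <- estimate_alpha(sim$genotypes, sim$sites)
  expect_lt(abs(ea$alpha - 0.3), 0.03)
  # unadmixed data drives alpha to (near) zero
  sim0 <- simulate_admixed_genomes(panel, t_gen = 450, alpha = 0, n_ind = 6,
                                   seed = 53)
  ea0 <- estimate_alpha(sim0$genotypes, sim0$sites)
  expect_lt(ea0$alpha, 0.02)
})
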