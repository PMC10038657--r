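# Independent oracles and small fixture builders shared across tests.

# three informative sites on one chromosome; handy for brute-force checks
toy_sites <- function() {
  tibble::tibble(chrom = "chr1", pos = c(1e4, 2e4, 3e4),
                 genetic_pos = c(0, 1e-4, 3e-4),
                 pA = c(0.9, 0.8, 0.95), pB = c(0.1, 0.2, 0.05))
}

# enumerate all 3^n hidden dosage paths; returns total likelihood and the
# argmax path (ties toward lower dosage via enumeration order)
enumerate_hmm <- function(genotypes, sites, params) {
  n <- nrow(sites)
  states <- 0:2
  stat <- c((1 - params$alpha)^2, 2 * params$alpha * (1 - params$alpha),
            params$alpha^2)
  grid <- expand.grid(rep(list(states), n))[, n:1, drop = FALSE] # lowest-dosage first
  probs <- apply(grid, 1, function(k) {
    pr <- stat[k[1] + 1] *
      emission_probs(genotypes[1], k[1], sites$pA[1], sites$pB[1], params$error_rate)
    for (i in seq_len(n)[-1]) {
      P <- transition_matrix(sites$genetic_pos[i] - sites$genetic_pos[i - 1], params)
      pr <- pr * P[k[i - 1] + 1, k[i] + 1] *
        emission_probs(genotypes[i], k[i], sites$pA[i], sites$pB[i], params$error_rate)
    }
    pr
  })
  list(loglik = log(sum(probs)),
       best_path = as.integer(grid[which.max(probs), ]),
       best_logprob = log(max(probs)))
}

# pure-R log-space forward pass (independent of the scaled C++ core)
logspace_forward <- function(genotypes, sites, params) {
  n <- nrow(sites)
  stat <- log(c((1 - params$alpha)^2, 2 * params$alpha * (1 - params$alpha),
                params$alpha^2))
  la <- stat + log(emission_probs(genotypes[1], 0:2, sites$pA[1], sites$pB[1],
                                  params$error_rate))
  for (i in seq_len(n)[-1]) {
    restart <- sites$chrom[i] != sites$chrom[i - 1]
    le <- log(emission_probs(genotypes[i], 0:2, sites$pA[i], sites$pB[i],
                             params$error_rate))
    if (restart) {
      tot <- logsumexp(la)
      la <- tot + stat + le
    } else {
      P <- transition_matrix(sites$genetic_pos[i] - sites$genetic_pos[i - 1], params)
      la <- vapply(1:3, function(s) logsumexp(la + log(P[, s])), numeric(1)) + le
    }
  }
  logsumexp(la)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# dense panel: one site every `spacing` bp, all passing the default filters
dense_panel <- function(n_sites = 200, spacing = 1000, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = seq_len(n_sites) * spacing,
                 genetic_pos = seq_len(n_sites) * spacing * 1e-8,
                 pA = 0.75, pB = 0.25, nA = 20, nB = 20)
}

# ancestry profile with sharp hotspots at fixed positions plus small noise
hotspot_profile <- function(seed, n_loci = 500, centers = c(100, 250, 400),
                            noise_sd = 0.02) {
  withr::with_seed(seed, purrr::map_dfr(1:3, function(ch) {
    x <- seq_len(n_loci)
    tibble::tibble(chrom = paste0("chr", ch), pos = x * 1e4,
                   prop = pmin(1, 0.05 + 0.8 * exp(-((x - centers[ch]) / 10)^2) +
                                 abs(stats::rnorm(n_loci, 0, noise_sd))))
  }))
}

# unadmixed background + specialist donor haplotype on an informative site grid
make_power_fixture <- function(n_sites = 3000, seed = 90, thin_bp = 0) {
  panel <- simulate_panel_freqs(n_sites, fst = 0.3, seed = seed)
  sites <- select_informative_sites(panel, thin_bp = thin_bp)
  bg <- simulate_admixed_genomes(sites, t_gen = 2, alpha = 0, n_ind = 1,
                                 seed = seed + 1)
  donor <- withr::with_seed(seed + 2, stats::rbinom(nrow(sites), 1, sites$pA))
  list(sites = sites, background = bg$genotypes[, 1], donor = donor)
}

# allele-count fixture: focal exactly intermediate between differentiated sources
admixed_f3_fixture <- function(seed, n = 5000, n_alleles = 40) {
  withr::with_seed(seed, {
    pa <- stats::runif(n, 0.05, 0.95)
    pb <- pmin(pmax(pa + sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.2, 0.5),
                    0.01), 0.99)
    px <- (pa + pb) / 2
    sites <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = n / 2),
                            pos = rep(seq_len(n / 2) * 1000, 2))
    list(
      focal = dplyr::mutate(sites, alt = stats::rbinom(n, n_alleles, px),
                            total = n_alleles),
      outgroup = dplyr::mutate(sites,
                               alt = stats::rbinom(n, n_alleles,
                                                   pmin(pmax(pa + stats::rnorm(n, 0, 0.15),
                                                             0.01), 0.99)),
                               total = n_alleles),
      source_a = dplyr::mutate(sites, alt = stats::rbinom(n, n_alleles, pa),
                               total = n_alleles),
      source_b = dplyr::mutate(sites, alt = stats::rbinom(n, n_alleles, pb),
                               total = n_alleles))
  })
}
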