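#' Parameters of the single-pulse local-ancestry HMM
#'
#' @param t_gen Generations since the admixture pulse (> 0).
#' @param alpha Specialist ancestry proportion in (0, 1).
#' @param error_rate Per-allele genotype error probability in `[0, 0.5)`.
#'   Default 0.01.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(t_gen, alpha, error_rate = 0.01) {
  if (!is.numeric(t_gen) || t_gen <= 0) stop("t_gen must be positive", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  structure(list(t_gen = t_gen, alpha = alpha, error_rate = error_rate),
            class = "hmm_params")
}

#' Select ancestry-informative sites
#'
#' Applies the standard ancestry-informative-marker filter: keep sites
#' whose panel allele-frequency difference exceeds `min_freq_diff`
#' (strictly) with at least `min_alleles` sampled alleles in each panel,
#' then thin greedily left-to-right within each chromosome so that
#' consecutive retained sites are at least `thin_bp` apart.
#'
#' @param panel Panel tibble (`chrom`, `pos`, `genetic_pos`, `pA`, `pB`,
#'   `nA`, `nB`), sorted by position within chromosome.
#' @param min_freq_diff Strict lower bound on `|pA - pB|` (default 0.3).
#' @param min_alleles Minimum sampled alleles per panel (default 10).
#' @param thin_bp Minimum distance between retained sites (default 10000).
#' @return The filtered panel tibble.
#' @export
select_informative_sites <- function(panel, min_freq_diff = 0.3,
                                     min_alleles = 10, thin_bp = 10000) {
  n0 <- nrow(panel)
  kept_freq <- panel[abs(panel$pA - panel$pB) > min_freq_diff, ]
  kept_n <- kept_freq[kept_freq$nA >= min_alleles & kept_freq$nB >= min_alleles, ]
  out <- dplyr::group_by(kept_n, .data$chrom)
  out <- dplyr::filter(out, greedy_thin(.data$pos, thin_bp))
  out <- dplyr::ungroup(out)
  if (nrow(out) == 0)
    stop(sprintf(paste0("no sites survive selection: %d input, %d after ",
                        "frequency-difference filter, %d after allele-count ",
                        "filter, 0 after thinning"),
                 n0, nrow(kept_freq), nrow(kept_n)), call. = FALSE)
  out
}

greedy_thin <- function(pos, thin_bp) {
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= thin_bp) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}

#' Transition matrix of the diploid dosage chain
#'
#' Single-pulse kinetics: the haploid ancestry chain over a genetic
#' distance `d` (Morgans) is `Q(d) = exp(-d T) I + (1 - exp(-d T)) Pi`
#' with stationary row `(alpha, 1 - alpha)`; the diploid matrix is the
#' product chain of two independent haploids collapsed to specialist
#' dosage `{0, 1, 2}`. Rows sum to 1; `d = 0` gives the identity and
#' `d -> Inf` the stationary binomial `((1-a)^2, 2a(1-a), a^2)` in every
#' row.
#'
#' @param d Genetic distance in Morgans (>= 0).
#' @param params An [hmm_params()].
#' @return A 3x3 stochastic matrix over dosage states 0, 1, 2.
#' @export
transition_matrix <- function(d, params) {
  stopifnot(inherits(params, "hmm_params"))
  if (d < 0) stop("genetic distance must be non-negative", call. = FALSE)
  m <- cpp_diploid_transition(d, params$t_gen, params$alpha)
  dimnames(m) <- list(paste0("d", 0:2), paste0("d", 0:2))
  m
}

#' Emission probability of a diploid genotype given ancestry dosage
#'
#' With `a = pA (1 - e) + (1 - pA) e` and `b = pB (1 - e) + (1 - pB) e`
#' (panel frequencies convolved with the genotype error rate), dosage 2
#' emits Binomial(2, a), dosage 0 emits Binomial(2, b), and dosage 1 emits
#' the law of one draw at `a` plus one at `b`. Missing genotypes (`NA`)
#' emit probability 1 under every dosage.
#'
#' @param g Genotype in `{0, 1, 2}` or `NA`; vectorized.
#' @param k Ancestry dosage in `{0, 1, 2}`; vectorized (recycled).
#' @param p_a,p_b Panel allele frequencies (specialist, generalist).
#' @param error_rate Genotype error probability.
#' @return Emission probabilities.
#' @export
emission_probs <- function(g, k, p_a, p_b, error_rate = 0.01) {
  if (any(!(g %in% c(0, 1, 2)) & !is.na(g)))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  if (any(!(k %in% c(0, 1, 2)))) stop("dosage must be 0, 1 or 2", call. = FALSE)
  a <- p_a * (1 - error_rate) + (1 - p_a) * error_rate
  b <- p_b * (1 - error_rate) + (1 - p_b) * error_rate
  n <- max(length(g), length(k), length(a), length(b))
  g <- rep_len(g, n); k <- rep_len(k, n); a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  hom <- ifelse(k == 2, a, b)
  out[k != 1] <- stats::dbinom(g[k != 1], 2, hom[k != 1])
  k1 <- which(k == 1)
  if (length(k1)) {
    gg <- g[k1]; aa <- a[k1]; bb <- b[k1]
    out[k1] <- ifelse(gg == 0, (1 - aa) * (1 - bb),
                      ifelse(gg == 1, aa * (1 - bb) + bb * (1 - aa), aa * bb))
  }
  out[is.na(g)] <- 1
  out
}

# n x 3 emission matrix for one individual's genotypes over the site table
emission_matrix <- function(genotypes, sites, error_rate) {
  cbind(emission_probs(genotypes, 0, sites$pA, sites$pB, error_rate),
        emission_probs(genotypes, 1, sites$pA, sites$pB, error_rate),
        emission_probs(genotypes, 2, sites$pA, sites$pB, error_rate))
}

# genetic distances between consecutive sites plus chromosome-restart flags
site_steps <- function(sites) {
  if (nrow(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  new_chrom <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)])
  d <- c(0, diff(sites$genetic_pos))
  d[new_chrom] <- 0
  if (any(d < 0)) stop("genetic positions must be non-decreasing within chromosome",
                       call. = FALSE)
  list(d = d, new_chrom = new_chrom)
}

#' Posterior local-ancestry decoding (forward-backward)
#'
#' Exact posterior probabilities of specialist dosage 0/1/2 at every site
#' for one diploid individual, with per-site scaling constants (numerically
#' equivalent to log-space computation), plus the total log-likelihood.
#' Chromosomes are independent chains each starting from the stationary
#' dosage distribution.
#'
#' @param genotypes Integer vector of diploid genotypes (0/1/2 or `NA`),
#'   one per site row.
#' @param sites Site tibble (`chrom`, `pos`, `genetic_pos`, `pA`, `pB`).
#' @param params An [hmm_params()].
#' @return A list with `posteriors` (tibble `chrom`, `pos`, `p0`, `p1`,
#'   `p2`) and `loglik`.
#' @export
forward_backward <- function(genotypes, sites, params) {
  stopifnot(inherits(params, "hmm_params"), length(genotypes) == nrow(sites))
  st <- site_steps(sites)
  E <- emission_matrix(genotypes, sites, params$error_rate)
  res <- cpp_forward_backward(E, st$d, st$new_chrom, params$t_gen, params$alpha)
  post <- res$posteriors
  list(posteriors = tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                                   p0 = post[, 1], p1 = post[, 2], p2 = post[, 3]),
       loglik = res$loglik)
}

#' Viterbi local-ancestry path
#'
#' Maximum a-posteriori dosage path for one diploid individual, ties broken
#' toward the lower dosage (conservative toward no admixture).
#'
#' @inheritParams forward_backward
#' @return A tibble (`chrom`, `pos`, `dosage`) with attribute `logprob`,
#'   the joint log-probability of the returned path.
#' @export
viterbi <- function(genotypes, sites, params) {
  stopifnot(inherits(params, "hmm_params"), length(genotypes) == nrow(sites))
  st <- site_steps(sites)
  E <- emission_matrix(genotypes, sites, params$error_rate)
  res <- cpp_viterbi(E, st$d, st$new_chrom, params$t_gen, params$alpha)
  out <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                        dosage = as.integer(res$path))
  attr(out, "logprob") <- res$logprob
  out
}

#' Maximum-likelihood admixture pulse time
#'
#' Maximizes the summed HMM log-likelihood across individuals over the
#' generations-since-pulse parameter, holding the admixture proportion
#' fixed: a coarse 40-point log-spaced grid over `t_bounds` locates the
#' basin, then golden-section search refines it. Deterministic for fixed
#' inputs. Sites inside `mask` intervals (selection outliers) are removed
#' before estimation, mirroring the practice of masking regions under
#' selection when dating admixture.
#'
#' @param genotypes Matrix of diploid genotypes, sites x individuals.
#' @param sites Site tibble (`chrom`, `pos`, `genetic_pos`, `pA`, `pB`).
#' @param alpha Admixture proportion used by the HMM.
#' @param error_rate Genotype error probability (default 0.01).
#' @param t_bounds Search interval in generations (default `c(1, 10000)`).
#' @param mask Optional BED tibble (`chrom`, `start`, `end`, 0-based
#'   half-open) of regions to exclude.
#' @return A one-row tibble of class `pulse_time_estimate`: `t_hat`,
#'   `loglik`, `alpha_used`, `n_sites`, `n_ind`, `flat` (TRUE when the
#'   likelihood was flat over the bounds and the midpoint was returned).
#' @export
estimate_pulse_time <- function(genotypes, sites, alpha, error_rate = 0.01,
                                t_bounds = c(1, 10000), mask = NULL) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, ncol = 1)
  stopifnot(nrow(genotypes) == nrow(sites), length(t_bounds) == 2,
            all(t_bounds > 0), t_bounds[1] < t_bounds[2])
  if (!is.null(mask)) {
    keep <- !sites_in_bed(sites, mask)
    sites <- sites[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  if (nrow(sites) < 2) stop("fewer than 2 sites after masking", call. = FALSE)
  st <- site_steps(sites)
  E_list <- lapply(seq_len(ncol(genotypes)), function(j)
    emission_matrix(genotypes[, j], sites, error_rate))
  core <- pulse_time_core(E_list, st$d, st$new_chrom, alpha, t_bounds)
  structure(tibble::tibble(t_hat = core$t_hat, loglik = core$loglik,
                           alpha_used = alpha, n_sites = nrow(sites),
                           n_ind = ncol(genotypes), flat = core$flat),
            class = c("pulse_time_estimate", "tbl_df", "tbl", "data.frame"))
}

# grid-then-golden-section maximizer of the summed forward log-likelihood
pulse_time_core <- function(E_list, d, new_chrom, alpha, t_bounds) {
  obj <- function(log_t) cpp_forward_loglik(E_list, d, new_chrom,
                                            exp(log_t), alpha)
  grid <- seq(log(t_bounds[1]), log(t_bounds[2]), length.out = 40)
  vals <- vapply(grid, obj, numeric(1))
  flat <- (max(vals) - min(vals)) < 1e-8 * max(1, abs(max(vals)))
  if (flat) {
    warning("likelihood is flat over t_bounds; returning the (log-scale) midpoint")
    t_hat <- exp(mean(range(grid)))
    return(list(t_hat = t_hat, loglik = obj(log(t_hat)), flat = TRUE))
  }
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-4)
  if (opt$objective >= vals[k]) {
    list(t_hat = exp(opt$maximum), loglik = opt$objective, flat = FALSE)
  } else {
    list(t_hat = exp(grid[k]), loglik = vals[k], flat = FALSE)
  }
}

# TRUE for sites covered by any BED interval (0-based half-open vs 1-based pos)
sites_in_bed <- function(sites, bed) {
  hit <- logical(nrow(sites))
  for (i in seq_len(nrow(bed))) {
    hit <- hit | (sites$chrom == bed$chrom[i] &
                    sites$pos > bed$start[i] & sites$pos <= bed$end[i])
  }
  hit
}

#' Block-bootstrap confidence interval for the pulse time
#'
#' Partitions the (masked) sites into contiguous blocks of `block_sites`
#' ancestry-informative sites (the last block may be short), resamples
#' blocks with replacement `n_boot` times, re-estimates the pulse time on
#' each resample — each resampled block restarts the chain, so no
#' artificial linkage is created across block joins — and reports the 2.5
#' and 97.5 percentiles.
#'
#' @inheritParams estimate_pulse_time
#' @param block_sites Sites per bootstrap block (default 1000).
#' @param n_boot Bootstrap replicates (default 80).
#' @param seed RNG seed for the resampling.
#' @param chrom_label Label stored in the output (default collapses the
#'   site table's chromosomes).
#' @return A one-row tibble of class `pulse_time_estimate` with columns
#'   `chrom`, `t_hat`, `ci_low`, `ci_high`, `alpha_used`, `n_sites`,
#'   `n_ind`, `n_blocks`, `n_boot`.
#' @export
bootstrap_pulse_time <- function(genotypes, sites, alpha, error_rate = 0.01,
                                 t_bounds = c(1, 10000), mask = NULL,
                                 block_sites = 1000, n_boot = 80, seed = NULL,
                                 chrom_label = NULL) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, ncol = 1)
  if (!is.null(mask)) {
    keep <- !sites_in_bed(sites, mask)
    sites <- sites[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  n <- nrow(sites)
  block_id <- (seq_len(n) - 1) %/% block_sites + 1
  n_blocks <- max(block_id)
  if (n_blocks < 2)
    stop("fewer than 2 bootstrap blocks; reduce block_sites or add sites",
         call. = FALSE)
  point <- estimate_pulse_time(genotypes, sites, alpha, error_rate, t_bounds)
  blocks <- split(seq_len(n), block_id)
  st <- site_steps(sites)
  E_list <- lapply(seq_len(ncol(genotypes)), function(j)
    emission_matrix(genotypes[, j], sites, error_rate))
  t_boot <- with_seed_if(seed, vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    # each resampled block restarts the chain; chromosome breaks inside a
    # block keep their original restart flags and distances
    nc <- st$new_chrom[idx]
    nc[cumsum(c(1, lengths(blocks[pick])[-n_blocks]))] <- TRUE
    d <- st$d[idx]
    d[nc] <- 0
    E_sub <- lapply(E_list, function(E) E[idx, , drop = FALSE])
    suppressWarnings(
      pulse_time_core(E_sub, d, nc, alpha, t_bounds)$t_hat)
  }, numeric(1)))
  ci <- stats::quantile(t_boot, c(0.025, 0.975), names = FALSE, type = 7)
  structure(tibble::tibble(
    chrom = chrom_label %||% paste(unique(sites$chrom), collapse = ","),
    t_hat = point$t_hat, ci_low = ci[1], ci_high = ci[2],
    alpha_used = alpha, n_sites = n, n_ind = ncol(genotypes),
    n_blocks = n_blocks, n_boot = n_boot, flat = point$flat),
    class = c("pulse_time_estimate", "tbl_df", "tbl", "data.frame"),
    t_boot = t_boot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call ancestry tracts from a decoded dosage path
#'
#' Maximal runs of dosage >= 1 become heterozygous tracts; maximal
#' sub-runs of dosage 2 additionally become homozygous tracts. Tract
#' bounds are placed midway between the last inside-site and the first
#' outside-site (unbiased under uniform site placement); runs touching a
#' chromosome end are bounded by the outermost site. Output follows BED
#' conventions (0-based, half-open).
#'
#' @param path Tibble from [viterbi()] (`chrom`, `pos`, `dosage`), or an
#'   integer dosage vector paired with `sites`.
#' @param sites Site tibble; only needed when `path` is a bare vector.
#' @param min_sites Minimum run length in sites for a tract to be emitted
#'   (default 2).
#' @param individual Identifier recorded in the output.
#' @return A tibble (`chrom`, `start_bp`, `end_bp`, `dosage_class`,
#'   `n_sites`, `individual`).
#' @export
call_tracts <- function(path, sites = NULL, min_sites = 2, individual = "ind01") {
  if (!is.data.frame(path)) {
    stopifnot(!is.null(sites), length(path) == nrow(sites))
    path <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                           dosage = as.integer(path))
  }
  res <- list()
  for (ch in unique(path$chrom)) {
    sub <- path[path$chrom == ch, ]
    res[[length(res) + 1L]] <- tract_runs(sub, sub$dosage >= 1L,
                                          "heterozygous", min_sites, individual)
    res[[length(res) + 1L]] <- tract_runs(sub, sub$dosage == 2L,
                                          "homozygous", min_sites, individual)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0)
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), dosage_class = character(),
                          n_sites = integer(), individual = character()))
  dplyr::arrange(out, .data$chrom, .data$start_bp, .data$dosage_class)
}

tract_runs <- function(sub, flag, label, min_sites, individual) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_sites)
  if (!length(keep)) return(NULL)
  pos <- sub$pos
  n <- length(pos)
  tibble::tibble(
    chrom = sub$chrom[1],
    start_bp = vapply(keep, function(k) {
      i <- starts[k]
      if (i == 1) pos[1] - 1 else (pos[i - 1] + pos[i]) / 2
    }, numeric(1)),
    end_bp = vapply(keep, function(k) {
      j <- ends[k]
      if (j == n) pos[n] else (pos[j] + pos[j + 1]) / 2
    }, numeric(1)),
    dosage_class = label,
    n_sites = r$lengths[keep],
    individual = individual)
}

#' Estimate the admixture proportion by EM-style iteration
#'
#' Alternates between re-estimating the pulse time at the current
#' admixture proportion and updating the proportion as the mean posterior
#' dosage over all individuals and sites divided by two, until the change
#' drops below `tol` or `max_iter` iterations.
#'
#' @inheritParams estimate_pulse_time
#' @param alpha_init Starting proportion (default 0.5).
#' @param tol Convergence tolerance on the proportion (default 1e-4).
#' @param max_iter Iteration cap (default 50); non-convergence raises a
#'   warning carrying the iteration trajectory.
#' @return A list with `alpha`, `t_hat`, `converged`, `trajectory`.
#' @export
estimate_alpha <- function(genotypes, sites, error_rate = 0.01,
                           t_bounds = c(1, 10000), alpha_init = 0.5,
                           tol = 1e-4, max_iter = 50) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, ncol = 1)
  if (nrow(sites) < 100) stop("need at least 100 sites to estimate alpha", call. = FALSE)
  alpha <- alpha_init
  traj <- alpha
  t_hat <- NA_real_
  for (it in seq_len(max_iter)) {
    est <- suppressWarnings(
      estimate_pulse_time(genotypes, sites, alpha, error_rate, t_bounds))
    t_hat <- est$t_hat
    params <- hmm_params(t_hat, alpha, error_rate)
    mean_dos <- mean(vapply(seq_len(ncol(genotypes)), function(j) {
      fb <- forward_backward(genotypes[, j], sites, params)
      mean(fb$posteriors$p1 + 2 * fb$posteriors$p2)
    }, numeric(1)))
    alpha_new <- min(max(mean_dos / 2, 1e-4), 1 - 1e-4)
    traj <- c(traj, alpha_new)
    done <- abs(alpha_new - alpha) < tol
    alpha <- alpha_new
    if (done) {
      return(list(alpha = alpha, t_hat = t_hat, converged = TRUE,
                  trajectory = traj))
    }
  }
  warning("alpha estimation did not converge in ", max_iter,
          " iterations; trajectory: ",
          paste(signif(traj, 4), collapse = " -> "))
  list(alpha = alpha, t_hat = t_hat, converged = FALSE, trajectory = traj)
}
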