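#' Default chromosome layout for synthetic genomes
#'
#' Three chromosomes of 100 Mb each: a desk-scale echo of the three large
#' metacentric chromosomes of the *Aedes aegypti* genome.
#' @return Named integer vector of chromosome lengths in bp.
#' @export
default_chrom_lengths <- function() {
  c(chr1 = 100e6, chr2 = 100e6, chr3 = 100e6)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Generate a recombination map
#'
#' Builds a monotone bp-to-centimorgan map per chromosome, either uniform
#' at `rate_cM_per_Mb` or with multiplicative lognormal rate heterogeneity
#' between anchor points. Heterogeneous maps are rescaled so each
#' chromosome's total genetic length equals the uniform total at the same
#' mean rate.
#'
#' @param chrom_lengths_bp Named vector of chromosome lengths in bp.
#' @param rate_cM_per_Mb Mean recombination rate (> 0). Default 1 cM/Mb.
#' @param n_anchors Anchor points per chromosome (>= 2).
#' @param heterogeneity Standard deviation of log rate multipliers between
#'   anchors; 0 (default) gives a uniform map.
#' @param seed Optional RNG seed (only used when `heterogeneity > 0`).
#' @return A tibble with columns `chrom`, `pos` (bp), `cM` (cumulative
#'   centimorgans from the chromosome start), non-decreasing in `pos`.
#' @export
generate_recomb_map <- function(chrom_lengths_bp = default_chrom_lengths(),
                                rate_cM_per_Mb = 1, n_anchors = 11,
                                heterogeneity = 0, seed = NULL) {
  if (rate_cM_per_Mb <= 0) stop("recombination rate must be positive", call. = FALSE)
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  with_seed_if(seed, {
    purrr::imap_dfr(as.list(chrom_lengths_bp), function(len, chrom) {
      pos <- round(seq(0, len, length.out = max(2, n_anchors)))
      widths <- diff(pos)
      rates <- rep(rate_cM_per_Mb, length(widths))
      if (heterogeneity > 0) {
        rates <- rates * exp(stats::rnorm(length(widths), 0, heterogeneity))
        # preserve the chromosome's total genetic length
        rates <- rates * (rate_cM_per_Mb * len) / sum(rates * widths)
      }
      tibble::tibble(chrom = chrom, pos = pos,
                     cM = c(0, cumsum(rates * widths / 1e6)))
    })
  })
}

#' Interpolate genetic position (Morgans) from a recombination map
#'
#' Linear interpolation of cumulative map distance at physical positions;
#' positions beyond the last anchor extrapolate at the terminal rate.
#'
#' @param map Recombination map tibble (`chrom`, `pos`, `cM`).
#' @param chrom,pos Vectors of equal length.
#' @return Genetic positions in Morgans.
#' @export
genetic_position <- function(map, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) < 2) stop("map has fewer than 2 anchors for chromosome ", ch, call. = FALSE)
    idx <- chrom == ch
    out[idx] <- stats::approx(sub$pos, sub$cM, xout = pos[idx], rule = 2)$y / 100
  }
  out
}

# inverse of genetic_position for one chromosome: Morgans -> bp
physical_position <- function(map, chrom, morgans) {
  sub <- map[map$chrom == chrom, ]
  stats::approx(sub$cM / 100, sub$pos, xout = morgans, rule = 2, ties = "ordered")$y
}

#' Simulate differentiated allele-frequency panels
#'
#' Draws ancestry-informative site frequencies for two source panels
#' (specialist and generalist) under a Balding–Nichols model: a shared
#' ancestral frequency per site from Uniform(0.05, 0.95), then independent
#' panel frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F) so that `fst`
#' controls how differentiated the panels are. `fst = 0` returns identical
#' panels.
#'
#' @param n_sites Total number of sites (>= 1), spread over chromosomes
#'   proportionally to length.
#' @param fst Differentiation parameter in `[0, 1)`.
#' @param seed RNG seed.
#' @param n_a,n_b Sampled allele counts recorded for each panel (default
#'   20, i.e. 10 diploids).
#' @param chrom_lengths_bp Named chromosome lengths.
#' @param map Optional recombination map; default uniform 1 cM/Mb.
#' @return A panel tibble with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `genetic_pos` (Morgans), `pA`
#'   (specialist), `pB` (generalist), `nA`, `nB`.
#' @export
simulate_panel_freqs <- function(n_sites, fst = 0.2, seed = NULL,
                                 n_a = 20, n_b = 20,
                                 chrom_lengths_bp = default_chrom_lengths(),
                                 map = NULL) {
  stopifnot(n_sites >= 1, fst >= 0, fst < 1)
  if (is.null(map)) map <- generate_recomb_map(chrom_lengths_bp)
  with_seed_if(seed, {
    n_per <- round(n_sites * chrom_lengths_bp / sum(chrom_lengths_bp))
    n_per[length(n_per)] <- n_sites - sum(n_per[-length(n_per)])
    sites <- purrr::imap_dfr(as.list(chrom_lengths_bp), function(len, ch) {
      k <- n_per[[ch]]
      tibble::tibble(chrom = ch,
                     pos = sort(sample.int(len, k, replace = FALSE)))
    })
    p <- stats::runif(nrow(sites), 0.05, 0.95)
    if (fst == 0) {
      pa <- p; pb <- p
    } else {
      shape <- (1 - fst) / fst
      pa <- stats::rbeta(length(p), p * shape, (1 - p) * shape)
      pb <- stats::rbeta(length(p), p * shape, (1 - p) * shape)
    }
    dplyr::mutate(sites,
                  genetic_pos = genetic_position(map, .data$chrom, .data$pos),
                  pA = pa, pB = pb, nA = n_a, nB = n_b)
  })
}

# alternating-exponential ancestry tracts for one haplotype on one chromosome;
# single-pulse model: specialist tract lengths ~ Exp((1 - alpha) * T) Morgans,
# generalist ~ Exp(alpha * T), chromosome start state Bernoulli(alpha)
simulate_haplotype_tracts <- function(len_morgans, t_gen, alpha) {
  state <- stats::rbinom(1, 1, alpha) == 1  # TRUE = specialist
  starts <- numeric(0); ends <- numeric(0); anc <- logical(0)
  at <- 0
  while (at < len_morgans) {
    rate <- if (state) (1 - alpha) * t_gen else alpha * t_gen
    seg <- stats::rexp(1, rate)
    starts <- c(starts, at); ends <- c(ends, min(at + seg, len_morgans))
    anc <- c(anc, state)
    at <- at + seg
    state <- !state
  }
  list(start = starts, end = ends, specialist = anc)
}

#' Simulate admixed diploid genomes from a single pulse
#'
#' Generates unphased diploid genotypes at the panel's sites for `n_ind`
#' individuals whose ancestry derives from a single admixture pulse
#' `t_gen` generations ago with specialist proportion `alpha`. Each
#' haplotype's ancestry along a chromosome is a two-state Markov process in
#' genetic distance — exactly the generative model the local-ancestry HMM
#' assumes — with specialist tract lengths Exponential with rate
#' `(1 - alpha) * t_gen` per Morgan and generalist tracts Exponential with
#' rate `alpha * t_gen`. Alleles are drawn from the local ancestry's panel
#' frequency and flipped with probability `error_rate`; the diploid
#' genotype is the sum of the two haplotypes.
#'
#' @param panel Panel tibble from [simulate_panel_freqs()] (or real data in
#'   the same shape).
#' @param t_gen Generations since the pulse (>= 1).
#' @param alpha Specialist ancestry proportion in (0, 1); the boundary
#'   values 0 and 1 are accepted and give unadmixed genomes.
#' @param n_ind Number of diploid individuals.
#' @param error_rate Per-allele genotype error probability (default 0.01).
#' @param seed RNG seed.
#' @param map Optional recombination map used to express tract bounds in
#'   bp; default uniform 1 cM/Mb over the panel's span.
#' @param chrom_lengths_bp Chromosome lengths (bp) delimiting the tracts.
#' @return A list with elements `genotypes` (integer matrix, sites x
#'   individuals, values 0/1/2), `sites` (the panel), and `truth`: a list
#'   with `t_gen`, `alpha` and a `tracts` tibble (`individual`, `haplotype`,
#'   `chrom`, `start_bp`, `end_bp`, `ancestry`) tiling each chromosome.
#' @export
simulate_admixed_genomes <- function(panel, t_gen, alpha, n_ind,
                                     error_rate = 0.01, seed = NULL,
                                     map = NULL,
                                     chrom_lengths_bp = default_chrom_lengths()) {
  if (nrow(panel) == 0) stop("panel has no sites", call. = FALSE)
  stopifnot(t_gen >= 1, alpha >= 0, alpha <= 1, n_ind >= 1)
  chroms <- intersect(names(chrom_lengths_bp), unique(panel$chrom))
  if (!length(chroms)) stop("panel chromosomes not found in chrom_lengths_bp", call. = FALSE)
  if (is.null(map)) map <- generate_recomb_map(chrom_lengths_bp[chroms])
  with_seed_if(seed, {
    geno <- matrix(0L, nrow(panel), n_ind,
                   dimnames = list(NULL, sprintf("ind%02d", seq_len(n_ind))))
    tracts <- vector("list", 0)
    for (ind in seq_len(n_ind)) {
      for (hap in 1:2) {
        hap_alleles <- integer(nrow(panel))
        for (ch in chroms) {
          idx <- which(panel$chrom == ch)
          len_m <- genetic_position(map, ch, chrom_lengths_bp[[ch]])
          if (alpha <= 0) {
            tr <- list(start = 0, end = len_m, specialist = FALSE)
          } else if (alpha >= 1) {
            tr <- list(start = 0, end = len_m, specialist = TRUE)
          } else {
            tr <- simulate_haplotype_tracts(len_m, t_gen, alpha)
          }
          start_bp <- floor(physical_position(map, ch, tr$start))
          end_bp <- c(start_bp[-1], chrom_lengths_bp[[ch]])
          tracts[[length(tracts) + 1L]] <- tibble::tibble(
            individual = colnames(geno)[ind], haplotype = hap, chrom = ch,
            start_bp = start_bp, end_bp = end_bp,
            ancestry = ifelse(tr$specialist, "specialist", "generalist"))
          if (length(idx)) {
            gp <- panel$genetic_pos[idx]
            # local ancestry at each site: which tract contains it
            ti <- findInterval(gp, tr$start, rightmost.closed = FALSE)
            ti[ti < 1] <- 1L
            spec <- tr$specialist[ti]
            freq <- ifelse(spec, panel$pA[idx], panel$pB[idx])
            a <- stats::rbinom(length(idx), 1, freq)
            flip <- stats::rbinom(length(idx), 1, error_rate) == 1
            a[flip] <- 1L - a[flip]
            hap_alleles[idx] <- a
          }
        }
        geno[, ind] <- geno[, ind] + hap_alleles
      }
    }
    list(genotypes = geno, sites = panel,
         truth = list(t_gen = t_gen, alpha = alpha,
                      tracts = dplyr::bind_rows(tracts)))
  })
}

#' Generate a unimodal synthetic historical record
#'
#' Counts on the fixed 25-year grid from 1500 to 1875 (15 bins), shaped as
#' a Gaussian bump truncated to the window, scaled to `total` and rounded
#' by largest remainder so the total is preserved exactly. This is a
#' stand-in for a real event record (the package never ships one); users
#' supply real records as 3-column TSV.
#'
#' @param peak_year Mode of the bump, within `[1500, 1875]`.
#' @param width Gaussian standard deviation in years (> 0).
#' @param total Total count to distribute.
#' @param start_year,end_year,bin_width Grid definition (defaults 1500,
#'   1875, 25).
#' @return A record tibble (`start_year`, `end_year`, `count`).
#' @export
generate_historical_record <- function(peak_year = 1790, width = 80,
                                       total = 1e6, start_year = 1500,
                                       end_year = 1875, bin_width = 25) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (peak_year < start_year || peak_year > end_year)
    stop("peak_year must lie within the record window", call. = FALSE)
  edges <- seq(start_year, end_year, by = bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  dens <- stats::dnorm(mids, peak_year, width)
  raw <- dens / sum(dens) * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  tibble::tibble(start_year = edges[-length(edges)], end_year = edges[-1],
                 count = counts)
}

#' Generate a migration trajectory with known scaling
#'
#' Manufactures an isolation-with-migration trajectory whose calendar-time
#' shape equals a given historical record (or a Gaussian pulse), placed on
#' mutation-scaled time via a known scaling factor — the ground truth for
#' clock-calibration round trips. The scaled segment grid is log-spaced and
#' augmented with the exact scaled images of the record's bin edges, so the
#' piecewise-constant density represents the source exactly; a leading
#' zero-migration segment covers `[0, youngest)` and a trailing
#' zero-migration segment with an open right boundary carries the plateau,
#' so the noise-free cumulative migration reaches exactly 1 at the oldest
#' finite boundary.
#'
#' @param record Historical record tibble, or `NULL` to use `pulse`.
#' @param s The true [scaling_factor()].
#' @param n_segments Number of log-spaced segments (>= 4) before bin-edge
#'   augmentation. Default 32.
#' @param pulse Optional `c(center_year, width_years)` Gaussian pulse used
#'   when `record` is `NULL`.
#' @param noise_sd Standard deviation of multiplicative lognormal noise on
#'   per-segment densities (total mass renormalized to 1); 0 = noise-free.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A migration trajectory tibble (`left_time_boundary`,
#'   `right_time_boundary`, `m`, `M`).
#' @export
generate_migration_trajectory <- function(record = NULL, s = scaling_factor(4.85e-9, 0.067),
                                          n_segments = 32, pulse = NULL,
                                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(s, "scaling_factor"), n_segments >= 4)
  if (is.null(record)) {
    if (is.null(pulse) || length(pulse) != 2)
      stop("supply either a record or a pulse = c(center_year, width_years)", call. = FALSE)
    if (pulse[2] <= 0) stop("pulse width must be positive", call. = FALSE)
    lo <- pulse[1] - 4 * pulse[2]; hi <- min(pulse[1] + 4 * pulse[2], s$present_year - 1)
    edges_cal <- seq(lo, hi, length.out = 41)
    mids <- (edges_cal[-1] + edges_cal[-length(edges_cal)]) / 2
    wts <- stats::dnorm(mids, pulse[1], pulse[2])
    record <- tibble::tibble(start_year = edges_cal[-length(edges_cal)],
                             end_year = edges_cal[-1], count = wts)
  }
  record <- historical_record(record)
  dens <- record$count / sum(record$count)  # mass per bin
  spt <- s$mu / s$g  # scaled time per year
  # calendar bin [a, b) -> scaled [ (present - b)*spt, (present - a)*spt )
  t_edges_bins <- (s$present_year - c(record$end_year[nrow(record)],
                                      rev(record$start_year))) * spt
  t_lo <- t_edges_bins[1]; t_hi <- t_edges_bins[length(t_edges_bins)]
  if (t_lo <= 0) stop("record window must predate the present year", call. = FALSE)
  grid <- exp(seq(log(t_lo), log(t_hi), length.out = n_segments + 1))
  grid <- sort(unique(c(grid, t_edges_bins)))
  # per-bin calendar density (per year), oldest bin first in scaled time
  dens_per_year <- rev(dens / (record$end_year - record$start_year))
  bin_left <- t_edges_bins[-length(t_edges_bins)]
  seg_l <- grid[-length(grid)]; seg_r <- grid[-1]
  mass <- numeric(length(seg_l))
  for (k in seq_along(bin_left)) {
    bl <- t_edges_bins[k]; br <- t_edges_bins[k + 1]
    ov <- pmax(0, pmin(seg_r, br) - pmax(seg_l, bl))
    mass <- mass + ov / spt * dens_per_year[k] # overlap in years * density/yr
  }
  if (noise_sd > 0) {
    mass <- with_seed_if(seed, mass * exp(stats::rnorm(length(mass), 0, noise_sd)))
    mass <- mass / sum(mass)
  }
  m <- mass / (seg_r - seg_l)
  out <- tibble::tibble(
    left_time_boundary = c(0, seg_l, t_hi),
    right_time_boundary = c(t_lo, seg_r, Inf),
    m = c(0, m, 0))
  out$M <- cumsum(c(0, mass, 0))
  out$M <- pmin(out$M / max(out$M), 1)  # guard rounding; noise already renormalized
  validate_migration_trajectory(out)
}
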