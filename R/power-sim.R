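#' Implant heterozygous donor tracts onto an unadmixed background
#'
#' Samples non-overlapping intervals of a fixed length uniformly along
#' each chromosome (rejection sampling) and, inside each interval,
#' replaces the background diploid genotype with the sum of one background
#' allele and the donor haplotype allele; outside the intervals the
#' background is unchanged. When phased background haplotypes are
#' supplied, one is chosen at random per tract and its allele used;
#' otherwise the background allele is drawn from the unphased genotype
#' (Bernoulli(g/2)).
#'
#' @param background Integer vector of background diploid genotypes
#'   (0/1/2), one per site.
#' @param donor Integer vector of donor haplotype alleles (0/1), same site
#'   grid.
#' @param sites Site tibble (`chrom`, `pos`, ...).
#' @param tract_length_bp Tract length in bp (the reference experiment
#'   uses 500 kb, 1 Mb, 2 Mb and 10 Mb).
#' @param n_tracts_per_chrom Tracts per chromosome (default 5).
#' @param chrom_lengths_bp Named chromosome lengths.
#' @param seed RNG seed.
#' @param background_haps Optional 2-column matrix of phased background
#'   haplotype alleles.
#' @param max_attempts Rejection-sampling cap per chromosome (default
#'   1000); exceeding it raises an error suggesting fewer or shorter
#'   tracts.
#' @return A list with `genotypes` (simulated vector) and `truth`
#'   (BED-style tibble `chrom`, `start`, `end`).
#' @export
place_tracts <- function(background, donor, sites, tract_length_bp,
                         n_tracts_per_chrom = 5,
                         chrom_lengths_bp = default_chrom_lengths(),
                         seed = NULL, background_haps = NULL,
                         max_attempts = 1000) {
  stopifnot(length(background) == nrow(sites), length(donor) == nrow(sites))
  with_seed_if(seed, {
    truth <- list()
    sim <- as.integer(background)
    for (ch in intersect(names(chrom_lengths_bp), unique(sites$chrom))) {
      len <- chrom_lengths_bp[[ch]]
      if (n_tracts_per_chrom == 0) next
      if (tract_length_bp > len)
        stop("tract longer than chromosome ", ch, call. = FALSE)
      placed <- matrix(numeric(0), ncol = 2)
      attempts <- 0
      while (nrow(placed) < n_tracts_per_chrom) {
        attempts <- attempts + 1
        if (attempts > max_attempts)
          stop("could not place non-overlapping tracts after ", max_attempts,
               " attempts; use fewer or shorter tracts", call. = FALSE)
        start <- floor(stats::runif(1, 0, len - tract_length_bp))
        end <- start + tract_length_bp
        if (nrow(placed) == 0 ||
            all(end <= placed[, 1] | start >= placed[, 2])) {
          placed <- rbind(placed, c(start, end))
        }
      }
      placed <- placed[order(placed[, 1]), , drop = FALSE]
      for (r in seq_len(nrow(placed))) {
        idx <- which(sites$chrom == ch & sites$pos > placed[r, 1] &
                       sites$pos <= placed[r, 2])
        if (length(idx)) {
          if (!is.null(background_haps)) {
            hap <- sample(1:2, 1)
            bg_allele <- background_haps[idx, hap]
          } else {
            bg_allele <- stats::rbinom(length(idx), 1, background[idx] / 2)
          }
          sim[idx] <- as.integer(bg_allele + donor[idx])
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          chrom = ch, start = placed[r, 1], end = placed[r, 2])
      }
    }
    list(genotypes = sim,
         truth = if (length(truth)) dplyr::bind_rows(truth)
                 else tibble::tibble(chrom = character(), start = numeric(),
                                     end = numeric()))
  })
}

# total overlap (bp) between two BED-style interval tables, half-open
overlap_bp <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0)
  tot <- 0
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- x[x$chrom == ch, ]; yi <- y[y$chrom == ch, ]
    for (i in seq_len(nrow(xi))) {
      tot <- tot + sum(pmax(0, pmin(xi$end[i], yi$end) - pmax(xi$start[i], yi$start)))
    }
  }
  tot
}

bed_total_bp <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

#' Tract-placement power experiment
#'
#' For each tract length: repeatedly implant donor tracts on the
#' unadmixed background, decode local ancestry with the single-pulse HMM
#' (Viterbi), call heterozygous tracts, and score bp-level sensitivity
#' (fraction of truth bp recovered) and precision (fraction of called bp
#' inside truth) with half-open interval arithmetic. Sites called
#' specialist in at least `recurrence` of the replicates are flagged as
#' recurrent regions — candidate tracts of specialist ancestry present in
#' the background itself rather than artifacts of any single placement.
#'
#' @inheritParams place_tracts
#' @param lengths_bp Tract lengths to test (default 500 kb, 1 Mb, 2 Mb,
#'   10 Mb).
#' @param n_replicates Replicates per length (default 100).
#' @param params [hmm_params()] used for decoding.
#' @param recurrence Fraction-of-replicates threshold for recurrent
#'   regions (default 0.95).
#' @param min_sites Minimum sites per called tract (default 2).
#' @return An object of class `power_result`: list with `summary` (tibble
#'   `tract_length_bp`, `n_replicates`, `sensitivity`, `precision`) and
#'   `recurrent_regions` (tibble `tract_length_bp`, `chrom`, `start`,
#'   `end`).
#' @export
run_power_experiment <- function(background, donor, sites, params,
                                 lengths_bp = c(5e5, 1e6, 2e6, 1e7),
                                 n_replicates = 100, n_tracts_per_chrom = 5,
                                 chrom_lengths_bp = default_chrom_lengths(),
                                 recurrence = 0.95, min_sites = 2,
                                 seed = NULL, background_haps = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  base_seed <- if (is.null(seed)) 0L else as.integer(seed)
  summaries <- list()
  recurrent <- list()
  for (li in seq_along(lengths_bp)) {
    len <- lengths_bp[li]
    truth_tot <- 0; called_tot <- 0; hit_tot <- 0
    called_count <- integer(nrow(sites))
    for (rep in seq_len(n_replicates)) {
      rep_seed <- base_seed + 7919L * li + rep  # fixed per-replicate splitting
      pl <- place_tracts(background, donor, sites, len, n_tracts_per_chrom,
                         chrom_lengths_bp, seed = rep_seed,
                         background_haps = background_haps)
      path <- viterbi(pl$genotypes, sites, params)
      called_count <- called_count + (path$dosage >= 1L)
      calls <- call_tracts(path, min_sites = min_sites)
      calls <- calls[calls$dosage_class == "heterozygous", ]
      calls <- dplyr::rename(calls, start = "start_bp", end = "end_bp")
      truth_tot <- truth_tot + bed_total_bp(pl$truth)
      called_tot <- called_tot + bed_total_bp(calls)
      hit_tot <- hit_tot + overlap_bp(pl$truth, calls)
    }
    summaries[[li]] <- tibble::tibble(
      tract_length_bp = len, n_replicates = n_replicates,
      sensitivity = if (truth_tot > 0) hit_tot / truth_tot else NA_real_,
      precision = if (called_tot > 0) hit_tot / called_tot else NA_real_)
    rec_sites <- called_count / n_replicates >= recurrence
    recurrent[[li]] <- flagged_regions(sites, rec_sites, len)
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 recurrent_regions = dplyr::bind_rows(recurrent)),
            class = "power_result")
}

# merge runs of flagged sites into BED intervals (site-span bounds)
flagged_regions <- function(sites, flag, tract_length_bp) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    r <- rle(flag[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        tract_length_bp = tract_length_bp, chrom = ch,
        start = sites$pos[idx[starts[k]]] - 1,
        end = sites$pos[idx[ends[k]]])
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(tract_length_bp = numeric(), chrom = character(),
                      start = numeric(), end = numeric())
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result>\n")
  print(x$summary)
  cat(nrow(x$recurrent_regions), "recurrent region(s)\n")
  invisible(x)
}
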