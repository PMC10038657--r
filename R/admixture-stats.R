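#' f3 admixture test with block-jackknife standard error
#'
#' Tests whether a focal population's allele frequencies are consistently
#' intermediate between two candidate source populations. The per-site
#' statistic is `(px - pa)(px - pb) - hx / nx` with
#' `hx = px (1 - px) nx / (nx - 1)`, the Patterson-style finite-sample
#' correction on the focal population; the genome-wide value is the mean
#' over retained sites. A delete-one block jackknife over contiguous
#' blocks of `block_size` SNPs gives the standard error and the Z-score;
#' a significantly negative Z is evidence that the focal population is
#' admixed between sources related to A and B.
#'
#' Sites are joined on `chrom` and `pos`; sites where any population has
#' zero sampled alleles are dropped, and a pooled minor-allele-frequency
#' filter (`maf`, strict) is applied.
#'
#' @param focal,source_a,source_b Allele-count tibbles with columns
#'   `chrom`, `pos`, `alt` (alt allele count) and `total` (sampled allele
#'   count).
#' @param block_size SNPs per jackknife block (default 500).
#' @param maf Pooled minor-allele-frequency threshold (default 0.05,
#'   strict: sites with pooled MAF > `maf` are kept).
#' @return A one-row tibble of class `f3_result`: `f3`, `se`, `z`,
#'   `n_blocks`, `n_sites`.
#' @export
f3_test <- function(focal, source_a, source_b, block_size = 500, maf = 0.05) {
  d <- dplyr::inner_join(
    dplyr::inner_join(
      dplyr::rename(focal, alt_x = "alt", n_x = "total"),
      dplyr::rename(source_a, alt_a = "alt", n_a = "total"),
      by = c("chrom", "pos")),
    dplyr::rename(source_b, alt_b = "alt", n_b = "total"),
    by = c("chrom", "pos"))
  d <- d[d$n_x > 0 & d$n_a > 0 & d$n_b > 0, ]
  pooled <- (d$alt_x + d$alt_a + d$alt_b) / (d$n_x + d$n_a + d$n_b)
  d <- d[pmin(pooled, 1 - pooled) > maf, ]
  if (nrow(d) < 2)
    stop("too few sites after filtering for an f3 test", call. = FALSE)
  d <- dplyr::arrange(d, .data$chrom, .data$pos)
  px <- d$alt_x / d$n_x; pa <- d$alt_a / d$n_a; pb <- d$alt_b / d$n_b
  hx <- px * (1 - px) * d$n_x / (d$n_x - 1)
  site_f3 <- (px - pa) * (px - pb) - hx / d$n_x
  n <- length(site_f3)
  block_id <- (seq_len(n) - 1) %/% block_size + 1
  n_blocks <- max(block_id)
  if (n_blocks < 2)
    stop("fewer than 2 jackknife blocks; reduce block_size", call. = FALSE)
  total <- sum(site_f3)
  block_sum <- tapply(site_f3, block_id, sum)
  block_n <- tabulate(block_id)
  theta_del <- (total - block_sum) / (n - block_n)  # delete-one-block means
  f3 <- total / n
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta_del - mean(theta_del))^2))
  structure(tibble::tibble(f3 = f3, se = se, z = f3 / se,
                           n_blocks = n_blocks, n_sites = n),
            class = c("f3_result", "tbl_df", "tbl", "data.frame"))
}

#' Population local-ancestry proportion profile
#'
#' Collapses per-individual decoded dosage paths into a per-site
#' population profile: the summed specialist dosage divided by twice the
#' number of individuals, so values lie in `[0, 1]`.
#'
#' @param paths Long tibble with columns `chrom`, `pos`, `individual`,
#'   `dosage` — e.g. row-bound [viterbi()] outputs with an `individual`
#'   column added.
#' @return A tibble (`chrom`, `pos`, `prop`), one row per site.
#' @export
ancestry_profile <- function(paths) {
  need <- c("chrom", "pos", "individual", "dosage")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("paths need column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  n_ind <- length(unique(paths$individual))
  counts <- dplyr::count(paths, .data$chrom, .data$pos)
  if (any(counts$n != n_ind))
    stop("individuals are not on a shared site grid", call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(paths, .data$chrom, .data$pos),
                          prop = sum(.data$dosage) / (2 * n_ind),
                          .groups = "drop")
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Circular-chromosome permutation test for shared ancestry hotspots
#'
#' Tests whether local-ancestry proportions are more spatially correlated
#' between two populations than expected by chance, while preserving each
#' chromosome's internal autocorrelation: each permutation rotates every
#' chromosome of the second profile by an independent uniform offset
#' (moving the preceding sequence to the end) and records the Pearson
#' correlation across all loci. The p-value uses the add-one convention,
#' `p = (1 + #{r_null >= r_obs}) / (1 + n_perm)` for the one-sided test of
#' excess similarity.
#'
#' @param profile_a,profile_b Profile tibbles (`chrom`, `pos`, `prop`) on
#'   an identical locus grid.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default; excess positive correlation)
#'   or `"two.sided"`.
#' @return An object of class `perm_test_result`: list with `r_obs`,
#'   `null_r`, `p`, `n_perm`, `alternative`, `seed`.
#' @export
circular_permutation_test <- function(profile_a, profile_b, n_perm = 1000,
                                      seed = NULL,
                                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (nrow(profile_a) != nrow(profile_b) ||
      any(profile_a$chrom != profile_b$chrom) ||
      any(profile_a$pos != profile_b$pos))
    stop("profiles must share an identical locus grid", call. = FALSE)
  a <- profile_a$prop; b <- profile_b$prop
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant profile: correlation undefined", call. = FALSE)
  chrom <- profile_a$chrom
  idx_by_chrom <- split(seq_along(b), chrom)
  r_obs <- stats::cor(a, b)
  null_r <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    bp <- b
    for (idx in idx_by_chrom) {
      k <- sample.int(length(idx), 1) - 1L  # offset 0 .. n-1
      if (k > 0) bp[idx] <- b[idx][c((k + 1):length(idx), 1:k)]
    }
    stats::cor(a, bp)
  }, numeric(1)))
  exceed <- if (alternative == "greater") sum(null_r >= r_obs)
            else sum(abs(null_r) >= abs(r_obs))
  structure(list(r_obs = r_obs, null_r = null_r,
                 p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
                 alternative = alternative, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "<perm_test_result> r_obs = %.4f, p = %.4g (%s, %d circular permutations)\n",
    x$r_obs, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Read / write allele-count tables
#'
#' Tab-separated with header: `chrom`, `pos`, `alt`, `total`.
#' @param path File path.
#' @return Reader: a tibble; writer: `path` invisibly.
#' @export
read_allele_counts <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = c(chrom = "character")))
}

#' @rdname read_allele_counts
#' @param x Allele-count tibble.
#' @export
write_allele_counts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
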