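#' Read / write site-major genotype tables
#'
#' Tab-separated with header: `chrom`, `pos`, then one 0/1/2 column per
#' individual (`NA` for missing).
#'
#' @param path File path.
#' @return Reader: a list with `sites` (tibble `chrom`, `pos`) and
#'   `genotypes` (integer matrix, sites x individuals). Writer: `path`,
#'   invisibly.
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(chrom = "character"))
  geno <- as.matrix(d[, setdiff(names(d), c("chrom", "pos")), drop = FALSE])
  storage.mode(geno) <- "integer"
  list(sites = tibble::tibble(chrom = d$chrom, pos = d$pos), genotypes = geno)
}

#' @rdname read_genotypes_tsv
#' @param genotypes Integer matrix, sites x individuals (column names kept).
#' @param sites Site tibble with `chrom`, `pos`.
#' @export
write_genotypes_tsv <- function(genotypes, sites, path) {
  stopifnot(nrow(genotypes) == nrow(sites))
  d <- cbind(data.frame(chrom = sites$chrom, pos = sites$pos),
             as.data.frame(genotypes))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Unphased diploid genotypes (`0/0`, `0/1`, `1/1`, `./.`) with dummy
#' REF/ALT alleles; enough for round-tripping ancestry-informative
#' dosages, not a general-purpose VCF writer.
#'
#' @inheritParams write_genotypes_tsv
#' @param path Output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, sites, path) {
  stopifnot(nrow(genotypes) == nrow(sites))
  ids <- colnames(genotypes) %||% sprintf("ind%02d", seq_len(ncol(genotypes)))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L], nrow(genotypes))
  gt[is.na(gt)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    vapply(seq_len(nrow(sites)), function(i) {
      paste(c(sites$chrom[i], sites$pos[i], ".", "A", "T", ".", "PASS", ".",
              "GT", gt[i, ]), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Uses `vcfR` to parse the file and converts GT strings to 0/1/2 alt
#' dosages (`NA` for missing).
#'
#' @param path VCF path.
#' @return A list with `sites` (`chrom`, `pos`) and `genotypes` matrix.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean == "0/0"] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  list(sites = tibble::tibble(chrom = as.character(fix[, "CHROM"]),
                              pos = as.numeric(fix[, "POS"])),
       genotypes = counts)
}

#' Read / write allele-frequency panels
#'
#' Tab-separated with header: `chrom`, `pos`, `genetic_pos`, `pA`, `pB`,
#' `nA`, `nB`.
#' @param path File path.
#' @return Reader: a panel tibble; writer: `path` invisibly.
#' @export
read_panel_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = c(chrom = "character")))
}

#' @rdname read_panel_tsv
#' @param panel Panel tibble.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED interval tables (0-based half-open)
#'
#' Three required columns (`chrom`, `start`, `end`); extra columns are
#' preserved on write and named generically on read.
#' @param path File path.
#' @return Reader: a tibble; writer: `path` invisibly.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         colClasses = c(V1 = "character"))
  names(d)[1:3] <- c("chrom", "start", "end")
  tibble::as_tibble(d)
}

#' @rdname read_bed
#' @param x Interval tibble whose first three columns are `chrom`,
#'   `start`, `end`.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write recombination maps
#'
#' Tab-separated with header: `chrom`, `pos` (bp), `cM` (cumulative).
#' @param path File path.
#' @return Reader: a map tibble; writer: `path` invisibly.
#' @export
read_recomb_map <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = c(chrom = "character")))
}

#' @rdname read_recomb_map
#' @param map Map tibble.
#' @export
write_recomb_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
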