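#' Coalescent scaling factor
#'
#' Bundles the per-generation mutation rate and the generation time that
#' together convert mutation-scaled coalescent time into calendar years,
#' plus the calendar year that anchors "years before present".
#'
#' Coalescent tables carry time pre-multiplied by the mutation rate
#' ("mutation-scaled" time). Conversion to generations divides by `mu`;
#' conversion to years then multiplies by `g`, so calendar age depends on
#' the pair only through the ratio `g / mu`.
#'
#' @param mu Mutations per site per generation (> 0).
#' @param g Years per generation (> 0). The common literature value for
#'   *Aedes aegypti* of 15 generations per year corresponds to `g = 0.067`.
#' @param present_year Calendar year treated as "the present" when mapping
#'   years before present onto calendar years. Default 2017.
#'
#' @return An object of class `scaling_factor`: a named list with elements
#'   `mu`, `g`, `present_year`.
#' @examples
#' s <- scaling_factor(mu = 4.85e-9, g = 0.067)
#' scale_to_years(3.25e-7, s)
#' @export
scaling_factor <- function(mu, g, present_year = 2017) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(g), length(g) == 1L)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be a positive number", call. = FALSE)
  if (!is.finite(g) || g <= 0) stop("`g` must be a positive number", call. = FALSE)
  structure(list(mu = mu, g = g, present_year = present_year),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf(
    "<scaling_factor> mu = %.4g mut/site/gen, g = %.4g yr/gen (ratio g/mu = %.4g), present year %d\n",
    x$mu, x$g, x$g / x$mu, as.integer(x$present_year)))
  invisible(x)
}

# shared validation for rate tables and migration trajectories
validate_time_segments <- function(x, what) {
  lb <- x$left_time_boundary
  rb <- x$right_time_boundary
  if (any(!is.finite(lb)))
    stop(what, ": non-finite left boundary at line ", which(!is.finite(lb))[1], call. = FALSE)
  bad <- which(rb <= lb)
  if (length(bad))
    stop(what, ": right boundary not greater than left boundary at line ", bad[1], call. = FALSE)
  if (abs(lb[1]) > 0)
    stop(what, ": first left boundary must be 0, got ", lb[1], call. = FALSE)
  if (nrow(x) > 1) {
    gap <- which(abs(lb[-1] - rb[-nrow(x)]) > 1e-12 * pmax(1, abs(rb[-nrow(x)])))
    if (length(gap))
      stop(what, ": segments not contiguous at line ", gap[1] + 1L, call. = FALSE)
    if (any(!is.finite(rb[-nrow(x)])))
      stop(what, ": only the last right boundary may be infinite", call. = FALSE)
  }
  invisible(x)
}

#' Read a coalescent rate table
#'
#' Parses tab-separated cross-coalescence output in the combined-output
#' dialect of MSMC2-style tools: a header line, then columns `time_index`,
#' `left_time_boundary`, `right_time_boundary` and either one lambda column
#' (`lambda` or `lambda_00`; within-population runs) or three
#' (`lambda_00`, `lambda_01`, `lambda_11`). Times are mutation-scaled.
#' The string `inf` encodes an open last right boundary.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `time_index`, `left_time_boundary`,
#'   `right_time_boundary`, `lambda00`, and (when present) `lambda01`,
#'   `lambda11`. Boundaries are strictly increasing starting from 0; rates
#'   are non-negative.
#' @seealso [write_coal_rate_table()], [relative_cross_coalescence()],
#'   [effective_size()]
#' @export
read_coal_rate_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  nm <- names(raw)
  canon <- gsub("[ ._]", "", tolower(nm))
  pick <- function(key) {
    i <- match(key, canon)
    if (is.na(i)) stop("malformed header: missing column `", key, "` in ", path, call. = FALSE)
    i
  }
  to_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(ifelse(tolower(v) %in% c("inf", "+inf", "infinity"), "Inf", v)))
    if (any(is.na(out)))
      stop("non-numeric value in column `", col, "` at line ", which(is.na(out))[1], call. = FALSE)
    out
  }
  has3 <- all(c("lambda01", "lambda11") %in% canon)
  out <- tibble::tibble(
    time_index = as.integer(to_num(raw[[pick("timeindex")]], "time_index")),
    left_time_boundary = to_num(raw[[pick("lefttimeboundary")]], "left_time_boundary"),
    right_time_boundary = to_num(raw[[pick("righttimeboundary")]], "right_time_boundary")
  )
  lam0 <- if ("lambda00" %in% canon) "lambda00" else "lambda"
  if (!lam0 %in% canon) stop("malformed header: no lambda column in ", path, call. = FALSE)
  out$lambda00 <- to_num(raw[[match(lam0, canon)]], "lambda_00")
  if (has3) {
    out$lambda01 <- to_num(raw[[match("lambda01", canon)]], "lambda_01")
    out$lambda11 <- to_num(raw[[match("lambda11", canon)]], "lambda_11")
  }
  validate_time_segments(out, "coalescent rate table")
  lam_cols <- intersect(c("lambda00", "lambda01", "lambda11"), names(out))
  for (cl in lam_cols) {
    bad <- which(out[[cl]] < 0)
    if (length(bad)) stop("negative rate in `", cl, "` at line ", bad[1], call. = FALSE)
  }
  out
}

#' Write a coalescent rate table
#'
#' Inverse of [read_coal_rate_table()]: writes the MSMC2-style tab-separated
#' dialect, encoding an infinite last right boundary as the string `inf`.
#'
#' @param x Tibble as returned by [read_coal_rate_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coal_rate_table <- function(x, path) {
  validate_time_segments(x, "coalescent rate table")
  cols <- c(time_index = "time_index",
            left_time_boundary = "left_time_boundary",
            right_time_boundary = "right_time_boundary",
            lambda_00 = "lambda00")
  if (all(c("lambda01", "lambda11") %in% names(x)))
    cols <- c(cols, lambda_01 = "lambda01", lambda_11 = "lambda11")
  fmt <- function(v) ifelse(is.infinite(v), "inf", formatC(v, format = "g", digits = 17))
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(vapply(cols, function(cl) {
      v <- x[[cl]][i]
      if (cl == "time_index") as.character(as.integer(v)) else fmt(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(names(cols), collapse = "\t"), body), path)
  invisible(path)
}

#' Relative cross-coalescence rate
#'
#' The rate at which haplotypes from the two populations coalesce with each
#' other relative to the rate at which haplotypes from the same population
#' coalesce: `rccr = 2 * lambda01 / (lambda00 + lambda11)` per time segment.
#' Values near 1 indicate a single merged population; values near 0,
#' complete isolation.
#'
#' @param x Coalescent rate table with all three lambda columns.
#' @return The input tibble with an added `rccr` column.
#' @examples
#' tbl <- tibble::tibble(time_index = 0:1,
#'                       left_time_boundary = c(0, 1e-6),
#'                       right_time_boundary = c(1e-6, Inf),
#'                       lambda00 = c(2, 1), lambda01 = c(1.5, 1), lambda11 = c(4, 1))
#' relative_cross_coalescence(tbl)$rccr
#' @export
relative_cross_coalescence <- function(x) {
  if (!all(c("lambda00", "lambda01", "lambda11") %in% names(x)))
    stop("cross-coalescence requires lambda00, lambda01 and lambda11 columns", call. = FALSE)
  denom <- x$lambda00 + x$lambda11
  bad <- which(denom <= 0)
  if (length(bad))
    stop("zero within-population coalescence rate in segment ", bad[1],
         "; rCCR undefined there", call. = FALSE)
  dplyr::mutate(x, rccr = 2 * .data$lambda01 / (.data$lambda00 + .data$lambda11))
}

#' Per-segment effective population size
#'
#' Converts within-population scaled coalescence rates into diploid
#' effective sizes, `Ne = 1 / (2 * lambda00 * mu)`, and segment boundaries
#' into years before present. The factor-of-two convention (rates are per
#' pair of lineages, scaled by the mutation rate) is fixed here and stated
#' because tools in this space differ by factors of 2.
#'
#' @param x Coalescent rate table (needs `lambda00 > 0`).
#' @param s A [scaling_factor()].
#' @return A tibble with columns `years_left`, `years_right` (years before
#'   present) and `ne` (diploid individuals), one row per segment.
#' @export
effective_size <- function(x, s) {
  stopifnot(inherits(s, "scaling_factor"))
  bad <- which(x$lambda00 <= 0)
  if (length(bad))
    stop("zero coalescence rate in segment ", bad[1], "; Ne undefined", call. = FALSE)
  tibble::tibble(
    years_left = scale_to_years(x$left_time_boundary, s),
    years_right = scale_to_years(x$right_time_boundary, s),
    ne = 1 / (2 * x$lambda00 * s$mu)
  )
}

#' Convert mutation-scaled time to years before present
#'
#' `years = (t / mu) * g`: dividing by the mutation rate gives generations,
#' multiplying by the generation time gives years. Depends on `(mu, g)`
#' only through the ratio `g / mu`.
#'
#' @param scaled_times Non-negative numeric vector of mutation-scaled times.
#' @param s A [scaling_factor()].
#' @return Numeric vector of years before present, in input order.
#' @export
scale_to_years <- function(scaled_times, s) {
  stopifnot(inherits(s, "scaling_factor"))
  if (any(scaled_times < 0, na.rm = TRUE))
    stop("scaled times must be non-negative", call. = FALSE)
  scaled_times / s$mu * s$g
}

#' Read / write a migration-rate trajectory
#'
#' An isolation-with-migration trajectory in the tab-separated dialect of
#' MSMC-IM-style output: per mutation-scaled time segment, a
#' piecewise-constant migration density `m` and the cumulative migration
#' probability `M` (unitless, non-decreasing, in `[0, 1]`, expected to
#' plateau at 1 going backwards in time once the populations have merged).
#'
#' @param path File path.
#' @return A tibble with columns `left_time_boundary`, `right_time_boundary`,
#'   `m`, `M`.
#' @export
read_migration_trajectory <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  canon <- gsub("[ ._]", "", tolower(names(raw)))
  need <- c("lefttimeboundary", "righttimeboundary", "m", "cumulativem")
  miss <- setdiff(need, canon)
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  num <- function(key) {
    v <- raw[[match(key, canon)]]
    suppressWarnings(as.numeric(ifelse(tolower(v) %in% c("inf", "+inf"), "Inf", v)))
  }
  out <- tibble::tibble(
    left_time_boundary = num("lefttimeboundary"),
    right_time_boundary = num("righttimeboundary"),
    m = num("m"), M = num("cumulativem")
  )
  validate_migration_trajectory(out)
}

#' @rdname read_migration_trajectory
#' @param x Trajectory tibble.
#' @export
write_migration_trajectory <- function(x, path) {
  validate_migration_trajectory(x)
  fmt <- function(v) ifelse(is.infinite(v), "inf", formatC(v, format = "g", digits = 17))
  writeLines(c(
    "left_time_boundary\tright_time_boundary\tm\tcumulative_M",
    paste(fmt(x$left_time_boundary), fmt(x$right_time_boundary),
          fmt(x$m), fmt(x$M), sep = "\t")
  ), path)
  invisible(path)
}

validate_migration_trajectory <- function(x) {
  validate_time_segments(x, "migration trajectory")
  if (any(x$m < 0)) stop("migration density m must be non-negative", call. = FALSE)
  if (any(x$M < -1e-9 | x$M > 1 + 1e-9))
    stop("cumulative migration M must lie in [0, 1]", call. = FALSE)
  if (any(diff(x$M) < -1e-9))
    stop("cumulative migration M must be non-decreasing in time", call. = FALSE)
  x
}
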