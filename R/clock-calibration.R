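#' Historical event record on a calendar bin grid
#'
#' Validates (and optionally builds) an event record binned on contiguous,
#' equal-width calendar intervals — the shape of the trans-Atlantic
#' shipping record used to calibrate the coalescent clock: counts in
#' 25-year bins between 1500 and 1875.
#'
#' @param x A data frame with columns `start_year` (inclusive), `end_year`
#'   (exclusive) and `count` (non-negative).
#' @return A validated tibble with those three columns.
#' @seealso [read_historical_record()], [generate_historical_record()]
#' @export
historical_record <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("start_year", "end_year", "count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("record is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x <- tibble::as_tibble(x)[need]
  if (nrow(x) < 2) stop("record needs at least 2 bins", call. = FALSE)
  w <- x$end_year - x$start_year
  if (any(w <= 0)) stop("record bins must have end_year > start_year", call. = FALSE)
  if (max(abs(w - w[1])) > 1e-9) stop("record bins must have equal width", call. = FALSE)
  if (any(abs(x$start_year[-1] - x$end_year[-nrow(x)]) > 1e-9))
    stop("record bins must be contiguous and increasing", call. = FALSE)
  if (any(x$count < 0)) stop("record counts must be non-negative", call. = FALSE)
  if (sum(x$count) <= 0) stop("record total count must be positive", call. = FALSE)
  x
}

#' Read / write a historical record as 3-column TSV
#'
#' Columns `start_year`, `end_year`, `count`, tab-separated with a header.
#'
#' @param path File path.
#' @return For the reader, a validated record tibble; the writer returns
#'   `path` invisibly.
#' @export
read_historical_record <- function(path) {
  historical_record(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' @rdname read_historical_record
#' @param x Record tibble.
#' @export
write_historical_record <- function(x, path) {
  x <- historical_record(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a historical record to a discrete density
#'
#' @param record A record tibble (see [historical_record()]).
#' @return A tibble with columns `start_year`, `end_year`, `weight`, the
#'   weights summing to 1 on the record's bin grid.
#' @export
normalize_record <- function(record) {
  record <- historical_record(record)
  tot <- sum(record$count)
  tibble::tibble(start_year = record$start_year, end_year = record$end_year,
                 weight = record$count / tot)
}

density_weights <- function(p) {
  if (is.data.frame(p)) {
    if (!"weight" %in% names(p)) stop("density tibble needs a `weight` column", call. = FALSE)
    p$weight
  } else as.numeric(p)
}

density_grid <- function(p) {
  if (is.data.frame(p) && all(c("start_year", "end_year") %in% names(p)))
    cbind(p$start_year, p$end_year) else NULL
}

#' Bhattacharyya coefficient of two discrete densities
#'
#' `BC = sum_i sqrt(p_i * q_i)` over a shared bin grid: 1 for identical
#' distributions, 0 for disjoint support. Used to score the correspondence
#' between the rescaled migration trajectory and the historical record.
#'
#' Inputs must already be normalized (weights summing to 1 within `1e-8`);
#' there is no silent renormalization. Densities may be bare numeric
#' vectors or tibbles with a `weight` column (and optionally
#' `start_year`/`end_year`, in which case the grids must match).
#'
#' @param p,q Discrete densities on the same bin grid.
#' @return A scalar in `[0, 1]`, symmetric in its arguments.
#' @examples
#' bhattacharyya_coefficient(c(0.5, 0.5), c(0.9, 0.1)) # sqrt(.45) + sqrt(.05)
#' @export
bhattacharyya_coefficient <- function(p, q) {
  wp <- density_weights(p); wq <- density_weights(q)
  if (length(wp) != length(wq))
    stop("densities are on different grids (lengths ", length(wp), " vs ",
         length(wq), ")", call. = FALSE)
  gp <- density_grid(p); gq <- density_grid(q)
  if (!is.null(gp) && !is.null(gq) && max(abs(gp - gq)) > 1e-9)
    stop("densities are on different bin grids", call. = FALSE)
  if (any(wp < 0) || any(wq < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(wp) - 1) > 1e-8 || abs(sum(wq) - 1) > 1e-8)
    stop("densities must be normalized to sum 1 (no silent renormalization)", call. = FALSE)
  sum(sqrt(wp * wq))
}

# core overlap sum without normalization checks; used on the no-truncation path
bc_core <- function(wp, wq) sum(sqrt(pmax(wp, 0) * pmax(wq, 0)))

#' Project a migration trajectory onto a calendar bin grid
#'
#' Rescales each mutation-scaled trajectory segment to a calendar interval
#' (via the scaling factor and `present_year`), then distributes each
#' segment's migration mass (`m` times scaled width, piecewise-constant in
#' time) onto the record's bins proportionally to calendar overlap.
#'
#' With `truncate = TRUE` (default) mass falling outside the record window
#' is discarded before normalizing, so the result sums to 1 over the
#' window; with `truncate = FALSE` the weights are normalized by the total
#' mass over all time and sum to the in-window fraction.
#'
#' @param traj Migration trajectory tibble (see [read_migration_trajectory()]).
#' @param s A [scaling_factor()]; its `present_year` anchors the calendar.
#' @param record Record tibble defining the bin grid.
#' @param truncate Normalize over the record window only (default) or over
#'   all time.
#' @return A density tibble (`start_year`, `end_year`, `weight`).
#' @export
migration_density_in_years <- function(traj, s, record, truncate = TRUE) {
  stopifnot(inherits(s, "scaling_factor"))
  record <- historical_record(record)
  w <- migration_bin_mass(traj, s, record)
  if (w$inside <= 0)
    stop("no overlap: trajectory mass falls entirely outside the record window",
         call. = FALSE)
  denom <- if (truncate) w$inside else w$total
  tibble::tibble(start_year = record$start_year, end_year = record$end_year,
                 weight = w$bin_mass / denom)
}

# mass of each trajectory segment landing in each record bin (calendar overlap)
migration_bin_mass <- function(traj, s, record) {
  ypg <- s$g / s$mu  # years per unit scaled time
  seg_l <- traj$left_time_boundary; seg_r <- traj$right_time_boundary
  m <- traj$m
  finite <- is.finite(seg_r)
  if (any(!finite & m > 0))
    warning("segment with infinite width and positive migration density; its mass is dropped")
  mass <- ifelse(finite, m * (seg_r - seg_l), 0)
  # calendar interval of each segment: older scaled time = earlier calendar year
  cal_a <- s$present_year - seg_r * ypg  # early edge
  cal_b <- s$present_year - seg_l * ypg  # late edge
  bin_mass <- numeric(nrow(record))
  for (i in seq_along(mass)) {
    if (mass[i] <= 0 || !is.finite(cal_a[i])) next
    width <- cal_b[i] - cal_a[i]
    if (width <= 0) next
    ov <- pmax(0, pmin(record$end_year, cal_b[i]) - pmax(record$start_year, cal_a[i]))
    bin_mass <- bin_mass + mass[i] * ov / width
  }
  list(bin_mass = bin_mass, inside = sum(bin_mass), total = sum(mass))
}

default_mu_grid <- function() exp(seq(log(1e-9), log(1e-8), length.out = 60))
default_g_grid <- function() seq(1 / 20, 1 / 10, length.out = 30)

#' Scan a (mu, g) grid for Bhattacharyya overlap
#'
#' Computes the Bhattacharyya coefficient between the rescaled migration
#' trajectory and the normalized historical record at every combination of
#' mutation rate and generation time. Because calendar rescaling depends on
#' `(mu, g)` only through `g / mu`, the surface is constant along rays of
#' constant ratio; the best-matching ratio is reported as `ridge_ratio`
#' (`mu* / g*` at the argmax).
#'
#' @param traj Migration trajectory tibble.
#' @param record Historical record tibble.
#' @param mu_grid Positive sorted mutation rates (default: 60 log-spaced
#'   values in `[1e-9, 1e-8]`).
#' @param g_grid Positive sorted generation times in years (default: 30
#'   linear values in `[0.05, 0.1]`, the range of plausible generation
#'   times for a fast-breeding mosquito).
#' @param present_year Calendar anchor (default 2017).
#' @param truncate See [migration_density_in_years()].
#' @return An object of class `bc_surface`: list with `mu_grid`, `g_grid`,
#'   `bc` (matrix, rows = mu), `argmax` (`mu_star`, `g_star`, `bc_max`) and
#'   `ridge_ratio` (`mu_star / g_star`). Grid points where the trajectory
#'   misses the record window entirely score 0.
#' @seealso [tidy.bc_surface()], [autoplot.bc_surface()], [calibrate_mu()]
#' @export
scan_scaling_grid <- function(traj, record, mu_grid = default_mu_grid(),
                              g_grid = default_g_grid(), present_year = 2017,
                              truncate = TRUE) {
  stopifnot(all(mu_grid > 0), all(g_grid > 0),
            !is.unsorted(mu_grid), !is.unsorted(g_grid))
  record <- historical_record(record)
  q <- record$count / sum(record$count)
  bc <- matrix(0, length(mu_grid), length(g_grid),
               dimnames = list(NULL, NULL))
  for (i in seq_along(mu_grid)) for (j in seq_along(g_grid)) {
    s <- scaling_factor(mu_grid[i], g_grid[j], present_year)
    w <- migration_bin_mass(traj, s, record)
    if (w$inside <= 0) next
    denom <- if (truncate) w$inside else w$total
    bc[i, j] <- bc_core(w$bin_mass / denom, q)
  }
  am <- arrayInd(which.max(bc), dim(bc))
  structure(list(mu_grid = mu_grid, g_grid = g_grid, bc = bc,
                 argmax = list(mu_star = mu_grid[am[1]], g_star = g_grid[am[2]],
                               bc_max = bc[am[1], am[2]]),
                 ridge_ratio = mu_grid[am[1]] / g_grid[am[2]],
                 present_year = present_year),
            class = "bc_surface")
}

#' @export
print.bc_surface <- function(x, ...) {
  cat(sprintf(
    "<bc_surface> %d x %d grid; max BC = %.4f at mu = %.3g, g = %.4g (mu/g = %.3g)\n",
    length(x$mu_grid), length(x$g_grid), x$argmax$bc_max,
    x$argmax$mu_star, x$argmax$g_star, x$ridge_ratio))
  invisible(x)
}

#' Calibrate the mutation rate at fixed generation time
#'
#' One-dimensional maximization of the Bhattacharyya overlap over the
#' mutation rate, holding the generation time fixed (e.g. at the common
#' literature value of 15 generations per year, `g = 0.067`). A coarse
#' log-spaced grid locates the basin; golden-section search refines the
#' optimum to a relative tolerance of `1e-3`. Deterministic for fixed
#' inputs.
#'
#' @param traj Migration trajectory tibble.
#' @param record Historical record tibble.
#' @param g_fixed Generation time in years.
#' @param mu_bounds Positive bracketing interval for the mutation rate.
#' @param present_year Calendar anchor (default 2017).
#' @param truncate See [migration_density_in_years()].
#' @param n_coarse Number of coarse log-grid points (default 60).
#' @return A list with `mu_hat` and `bc` (the overlap at the optimum).
#' @export
calibrate_mu <- function(traj, record, g_fixed = 0.067,
                         mu_bounds = c(1e-9, 1e-8), present_year = 2017,
                         truncate = TRUE, n_coarse = 60) {
  stopifnot(length(mu_bounds) == 2, all(mu_bounds > 0), mu_bounds[1] < mu_bounds[2])
  record <- historical_record(record)
  q <- record$count / sum(record$count)
  objective <- function(log_mu) {
    s <- scaling_factor(exp(log_mu), g_fixed, present_year)
    w <- migration_bin_mass(traj, s, record)
    if (w$inside <= 0) return(0)
    denom <- if (truncate) w$inside else w$total
    bc_core(w$bin_mass / denom, q)
  }
  grid <- seq(log(mu_bounds[1]), log(mu_bounds[2]), length.out = n_coarse)
  vals <- vapply(grid, objective, numeric(1))
  if (all(vals <= 0))
    stop("no overlap anywhere: BC is zero across the whole mu range", call. = FALSE)
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(n_coarse, k + 1)]
  opt <- stats::optimize(objective, c(lo, hi), maximum = TRUE, tol = 1e-3 / 2)
  if (opt$objective >= vals[k]) {
    list(mu_hat = exp(opt$maximum), bc = opt$objective)
  } else {
    list(mu_hat = exp(grid[k]), bc = vals[k])
  }
}

#' Rescale a calibrated calendar date to an alternative mutation rate
#'
#' At fixed generation time, calendar dates scale inversely with the
#' mutation rate: `date_new = date_years * mu_old / mu_new`. Used to
#' translate a dated event under the primary calibration into the date it
#' would take under an alternative mutation-rate scenario (e.g. a
#' ~5000-year-old divergence under `mu = 4.85e-9` moves to roughly 10,000
#' years under `mu = 2.4e-9`).
#'
#' @param date_years Positive date(s) in years before present.
#' @param mu_old,mu_new Positive mutation rates.
#' @return Rescaled date(s) in years before present.
#' @export
rescale_calibrated_date <- function(date_years, mu_old, mu_new) {
  if (any(date_years <= 0) || mu_old <= 0 || mu_new <= 0)
    stop("dates and mutation rates must be positive", call. = FALSE)
  date_years * mu_old / mu_new
}
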