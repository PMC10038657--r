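#' Run the full analysis pipeline from a config
#'
#' Wires the stages — `simulate` (synthetic inputs with known ground
#' truth), `calibrate` (clock calibration against the record), `ancestry`
#' (local-ancestry HMM, pulse dating, tract calling), `stats` (f3 and
#' circular permutation test) and `power` (tract-placement power
#' experiment) — into one reproducible run. Every stochastic stage draws
#' its seed from the config; completed stages leave a `<stage>.done`
#' marker plus a `<stage>.json` partial summary in the run directory, and
#' a rerun with `resume = TRUE` skips them. A provenance log
#' (`pipeline.log`) records ISO timestamps, the package version, seeds and
#' the config hash.
#'
#' @param config A named list, or a path to a YAML or JSON file. Required
#'   field: `out_dir`. Optional: `seed` (default 1), `stages` (default all
#'   five, in order), and per-stage parameter blocks `simulate`,
#'   `calibrate`, `ancestry`, `stats`, `power` overriding the defaults
#'   documented in the stage functions.
#' @param resume Skip stages whose marker files exist (default TRUE).
#' @return The summary (named list, also written to `summary.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  cfg <- load_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf("%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                paste0(...)), file = log_file, append = TRUE)
  }
  log_line("run start; admixclock ",
           as.character(utils::packageVersion("admixclock")),
           "; seed ", cfg$seed, "; config sha ", cfg$config_hash)
  summary <- list()
  for (stage in cfg$stages) {
    marker <- file.path(out, paste0(stage, ".done"))
    part_file <- file.path(out, paste0(stage, ".json"))
    if (resume && file.exists(marker) && file.exists(part_file)) {
      log_line("stage ", stage, ": resumed from completed run")
      summary[[stage]] <- jsonlite::read_json(part_file, simplifyVector = TRUE)
      next
    }
    log_line("stage ", stage, ": start")
    part <- tryCatch(
      switch(stage,
             simulate = stage_simulate(cfg, out),
             calibrate = stage_calibrate(cfg, out),
             ancestry = stage_ancestry(cfg, out),
             stats = stage_stats(cfg, out),
             power = stage_power(cfg, out)),
      error = function(e) stop("stage `", stage, "` failed: ",
                               conditionMessage(e), call. = FALSE))
    jsonlite::write_json(part, part_file, auto_unbox = TRUE, digits = NA)
    writeLines(format(Sys.time()), marker)
    log_line("stage ", stage, ": done")
    summary[[stage]] <- part
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("run complete")
  invisible(summary)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    cfg <- if (grepl("\\.json$", config)) jsonlite::fromJSON(txt, simplifyVector = TRUE)
           else yaml::yaml.load(txt)
    cfg$config_hash <- substr(rlang::hash(txt), 1, 12)
  } else if (is.list(config)) {
    cfg <- config
    cfg$config_hash <- substr(rlang::hash(config), 1, 12)
  } else stop("config must be a list or a file path", call. = FALSE)
  if (is.null(cfg$out_dir))
    stop("config validation: required field `out_dir` is missing", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  all_stages <- c("simulate", "calibrate", "ancestry", "stats", "power")
  cfg$stages <- cfg$stages %||% all_stages
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad))
    stop("config validation: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

cfg_get <- function(cfg, stage, key, default) {
  v <- cfg[[stage]][[key]]
  if (is.null(v)) default else v
}

stage_simulate <- function(cfg, out) {
  g <- function(key, default) cfg_get(cfg, "simulate", key, default)
  s0 <- scaling_factor(g("mu_true", 4.85e-9), g("g_true", 0.067),
                       g("present_year", 2017))
  record <- generate_historical_record(g("peak_year", 1790), g("width", 80),
                                       g("total", 1e6))
  traj <- generate_migration_trajectory(record, s0,
                                        n_segments = g("n_segments", 32),
                                        noise_sd = g("noise_sd", 0),
                                        seed = cfg$seed)
  chrom_lengths <- unlist(g("chrom_lengths_bp", default_chrom_lengths()))
  map <- generate_recomb_map(chrom_lengths, g("rate_cM_per_Mb", 1))
  panel <- simulate_panel_freqs(g("n_sites", 3000), g("fst", 0.3),
                                seed = cfg$seed + 1L,
                                chrom_lengths_bp = chrom_lengths, map = map)
  informative <- select_informative_sites(panel,
                                          thin_bp = g("thin_bp", 10000))
  pops <- list()
  for (p in 1:2) {
    pops[[p]] <- simulate_admixed_genomes(
      informative, g("t_gen", 450), g("alpha", 0.3), g("n_ind", 10),
      g("error_rate", 0.01), seed = cfg$seed + 10L + p, map = map,
      chrom_lengths_bp = chrom_lengths)
    write_genotypes_tsv(pops[[p]]$genotypes, informative,
                        file.path(out, sprintf("pop%d_genotypes.tsv", p)))
    write_bed(dplyr::select(pops[[p]]$truth$tracts, "chrom", "start_bp",
                            "end_bp", "ancestry", "individual", "haplotype"),
              file.path(out, sprintf("pop%d_truth_tracts.bed", p)))
  }
  write_historical_record(record, file.path(out, "record.tsv"))
  write_migration_trajectory(traj, file.path(out, "trajectory.tsv"))
  write_panel_tsv(panel, file.path(out, "panel.tsv"))
  write_panel_tsv(informative, file.path(out, "panel_informative.tsv"))
  write_recomb_map(map, file.path(out, "recomb_map.tsv"))
  jsonlite::write_json(list(t_gen = g("t_gen", 450), alpha = g("alpha", 0.3),
                            mu_true = s0$mu, g_true = s0$g),
                       file.path(out, "truth.json"), auto_unbox = TRUE)
  list(n_panel_sites = nrow(panel), n_informative_sites = nrow(informative),
       n_ind = g("n_ind", 10), t_gen_true = g("t_gen", 450),
       alpha_true = g("alpha", 0.3), mu_true = s0$mu, g_true = s0$g)
}

stage_calibrate <- function(cfg, out) {
  g <- function(key, default) cfg_get(cfg, "calibrate", key, default)
  traj <- read_migration_trajectory(file.path(out, "trajectory.tsv"))
  record <- read_historical_record(file.path(out, "record.tsv"))
  cal <- calibrate_mu(traj, record, g("g_fixed", 0.067),
                      unlist(g("mu_bounds", c(1e-9, 1e-8))),
                      g("present_year", 2017), g("truncate", TRUE))
  surf <- scan_scaling_grid(
    traj, record,
    mu_grid = exp(seq(log(1e-9), log(1e-8), length.out = g("n_mu", 30))),
    g_grid = seq(0.05, 0.1, length.out = g("n_g", 15)),
    present_year = g("present_year", 2017), truncate = g("truncate", TRUE))
  utils::write.table(surf$bc, file.path(out, "bc_surface.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  list(mu_hat = cal$mu_hat, bc_at_mu_hat = cal$bc,
       ridge_ratio = surf$ridge_ratio, bc_max = surf$argmax$bc_max)
}

stage_ancestry <- function(cfg, out) {
  g <- function(key, default) cfg_get(cfg, "ancestry", key, default)
  sites <- read_panel_tsv(file.path(out, "panel_informative.tsv"))
  geno <- read_genotypes_tsv(file.path(out, "pop1_genotypes.tsv"))$genotypes
  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  alpha <- g("alpha", truth$alpha)
  err <- g("error_rate", 0.01)
  estimates <- list()
  tracts <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    estimates[[ch]] <- bootstrap_pulse_time(
      geno[idx, , drop = FALSE], sites[idx, ], alpha, err,
      t_bounds = unlist(g("t_bounds", c(1, 10000))),
      block_sites = g("block_sites", 500), n_boot = g("n_boot", 40),
      seed = cfg$seed + 20L, chrom_label = ch)
  }
  params <- hmm_params(mean(vapply(estimates, function(e) e$t_hat, 1)),
                       alpha, err)
  for (j in seq_len(ncol(geno))) {
    path <- viterbi(geno[, j], sites, params)
    tracts[[j]] <- call_tracts(path, individual = colnames(geno)[j])
  }
  est <- dplyr::bind_rows(estimates)
  utils::write.table(est, file.path(out, "pulse_times.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  all_tracts <- dplyr::bind_rows(tracts)
  write_bed(all_tracts, file.path(out, "called_tracts.bed"))
  list(t_hat_mean = mean(est$t_hat), t_hat = as.list(stats::setNames(est$t_hat, est$chrom)),
       ci_low = as.list(stats::setNames(est$ci_low, est$chrom)),
       ci_high = as.list(stats::setNames(est$ci_high, est$chrom)),
       n_tracts_called = nrow(all_tracts))
}

stage_stats <- function(cfg, out) {
  g <- function(key, default) cfg_get(cfg, "stats", key, default)
  sites <- read_panel_tsv(file.path(out, "panel_informative.tsv"))
  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  pops <- lapply(1:2, function(p)
    read_genotypes_tsv(file.path(out, sprintf("pop%d_genotypes.tsv", p)))$genotypes)
  params <- hmm_params(truth$t_gen, truth$alpha, g("error_rate", 0.01))
  profiles <- lapply(pops, function(gm) {
    paths <- purrr::map_dfr(seq_len(ncol(gm)), function(j)
      dplyr::mutate(viterbi(gm[, j], sites, params),
                    individual = colnames(gm)[j]))
    ancestry_profile(paths)
  })
  perm <- circular_permutation_test(profiles[[1]], profiles[[2]],
                                    n_perm = g("n_perm", 1000),
                                    seed = cfg$seed + 30L)
  focal <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                          alt = rowSums(pops[[1]]), total = 2 * ncol(pops[[1]]))
  src_a <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                          alt = round(sites$pA * sites$nA), total = sites$nA)
  src_b <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                          alt = round(sites$pB * sites$nB), total = sites$nB)
  f3 <- f3_test(focal, src_a, src_b, block_size = g("f3_block_size", 100))
  list(f3 = f3$f3, f3_z = f3$z, perm_r = perm$r_obs, perm_p = perm$p)
}

stage_power <- function(cfg, out) {
  g <- function(key, default) cfg_get(cfg, "power", key, default)
  sites <- read_panel_tsv(file.path(out, "panel_informative.tsv"))
  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  chrom_lengths <- unlist(cfg_get(cfg, "simulate", "chrom_lengths_bp",
                                  default_chrom_lengths()))
  bg <- simulate_admixed_genomes(sites, t_gen = 2, alpha = 0, n_ind = 1,
                                 error_rate = g("error_rate", 0.01),
                                 seed = cfg$seed + 40L,
                                 chrom_lengths_bp = chrom_lengths)
  donor <- with_seed_if(cfg$seed + 41L,
                        stats::rbinom(nrow(sites), 1, sites$pA))
  params <- hmm_params(g("t_gen", 100), g("alpha", 0.1),
                       g("error_rate", 0.01))
  res <- run_power_experiment(
    bg$genotypes[, 1], donor, sites, params,
    lengths_bp = unlist(g("lengths_bp", c(5e5, 1e6, 2e6, 1e7))),
    n_replicates = g("n_replicates", 100),
    n_tracts_per_chrom = g("n_tracts_per_chrom", 5),
    chrom_lengths_bp = chrom_lengths, seed = cfg$seed + 42L)
  utils::write.table(res$summary, file.path(out, "power_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$recurrent_regions))
    write_bed(dplyr::select(res$recurrent_regions, "chrom", "start", "end",
                            "tract_length_bp"),
              file.path(out, "recurrent_regions.bed"))
  list(sensitivity = as.list(stats::setNames(res$summary$sensitivity,
                                             paste0("bp", res$summary$tract_length_bp))),
       n_recurrent_regions = nrow(res$recurrent_regions))
}
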