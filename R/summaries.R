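#' Replicate mean and sample standard deviation
#'
#' The footer arithmetic of per-trajectory summary tables: arithmetic mean
#' and sample (n-1) standard deviation over replicate trajectories, rounded
#' half-up at the printed precision.
#'
#' @param values Numeric vector of per-trajectory values (>= 2 for an SD).
#' @param decimals Decimals to round to.
#' @return One-row tibble with `mean` and `sd` (`sd` is `NA` when fewer than
#'   two values are given).
#' @export
summarize_replicates <- function(values, decimals = 2) {
  if (length(values) < 1) abort("no values")
  m <- round_half_up(mean(values), decimals)
  s <- if (length(values) >= 2) round_half_up(sd(values), decimals)
       else NA_real_
  tibble::tibble(mean = m, sd = s)
}

#' Integer percent decrease between two window means
#'
#' `round(100 * (first - last) / first)` with half-up rounding; the
#' "Difference (%)" column of SASA summary tables.
#'
#' @param first,last Window means; `first` must be positive.
#' @return Integer percent.
#' @export
percent_decrease <- function(first, last) {
  if (any(first <= 0)) abort("first-window mean must be positive")
  as.integer(round_half_up(100 * (first - last) / first))
}

#' Replicate summary table
#'
#' Builds the usual trajectory x system table with Average and Standard
#' Deviation footer rows from per-trajectory values.
#'
#' @param values Named list: one numeric vector of per-trajectory values per
#'   system (columns).
#' @param decimals Rounding for the footer rows.
#' @return Tibble with a `row` column (`I`, `II`, ..., `Average`,
#'   `Standard Deviation`) and one column per system.
#' @export
summary_table <- function(values, decimals = 2) {
  n <- unique(lengths(values))
  if (length(n) != 1) abort("all systems need the same number of trajectories")
  rows <- c(as.character(utils::as.roman(seq_len(n))), "Average",
            "Standard Deviation")
  cols <- lapply(values, function(v) {
    s <- summarize_replicates(v, decimals)
    c(round_half_up(v, decimals), s$mean, s$sd)
  })
  tibble::as_tibble(c(list(row = rows), cols))
}

#' Run the full analysis pipeline from a config
#'
#' Executes the analyses named in the config on a simulated (or loaded)
#' trajectory and writes TSV tables plus a run-metadata JSON into `out_dir`.
#' The bundle is a pure function of (inputs, config, seed): identical reruns
#' produce byte-identical TSVs.
#'
#' @param config Path to a YAML config, or an equivalent named list. Keys:
#'   `seed`; either `simulate` (with `n_abeta`, `abeta_species`, `n_scp`,
#'   `scp_species`, `box`, `n_frames`, `dt`, optional `schedule` events) or
#'   `trajectory`/`structure` paths; `analyses` (subset of `hbonds`, `ss`,
#'   `sasa`, `aggregates`, `ecd`); `window` (e.g. `"last:20ns"`); optional
#'   per-analysis parameter blocks.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list of the computed result objects.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  analyses <- cfg$analyses %||% c("hbonds", "ss", "sasa", "aggregates", "ecd")
  if (!is.null(cfg$trajectory) && !file.exists(cfg$trajectory)) {
    abort(sprintf("trajectory file '%s' does not exist", cfg$trajectory))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1
  results <- list()
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    sys <- build_mixture(
      n_abeta = sc$n_abeta %||% 8, abeta_species = sc$abeta_species %||% "ABETA42",
      n_scp = sc$n_scp %||% 8, scp_species = sc$scp_species %||% "SST14",
      box = sc$box %||% 7.5, seed = seed)
    sched <- if (!is.null(sc$schedule)) {
      aggregation_schedule(dplyr::bind_rows(lapply(sc$schedule, tibble::as_tibble)))
    } else {
      aggregation_schedule()
    }
    modes <- list()
    if (!is.null(sc$modes)) {
      modes <- lapply(sc$modes, function(m) {
        latent_mode(select_atoms(sys, chains = m$chains),
                    sigma = m$sigma %||% 0.05, tau = m$tau %||% 20,
                    direction = m$direction %||% c(1, 0, 0))
      })
    }
    sim <- simulate_trajectory(sys, modes = modes, schedule = sched,
                               noise_sd = sc$noise_sd %||% 0.01,
                               n_frames = sc$n_frames %||% 500,
                               dt = sc$dt %||% 10, seed = seed)
    traj <- sim$traj
    results$truth <- sim$truth
  } else {
    sys <- read_structure(cfg$structure)
    traj <- read_trajectory(cfg$trajectory, sys, dt = cfg$dt)
  }
  window <- cfg$window %||% "all"
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("hbonds" %in% analyses) {
    hb <- hbond_census(traj)
    results$hbonds <- hb
    tsv(hb, "hbonds")
    tsv(hbond_window_means(hb, window), "hbonds_means")
  }
  if ("ss" %in% analyses) {
    ssc <- ss_content(traj)
    results$ss <- ssc
    tsv(ssc, "ss_content")
    results$beta <- beta_content(traj, window = window)
  }
  if ("sasa" %in% analyses) {
    sa <- sasa_timeseries(traj,
                          first = cfg$sasa$first %||% "first:5ns",
                          last = cfg$sasa$last %||% "last:5ns",
                          n_points = cfg$sasa$n_points %||% 240)
    results$sasa <- sa
    tsv(sa$series, "sasa_series")
    tsv(sa$summary, "sasa_summary")
  }
  if ("aggregates" %in% analyses) {
    tl <- aggregate_timeline(traj,
                             cutoff = cfg$aggregates$cutoff %||% 0.45,
                             window_frames = cfg$aggregates$window_frames %||% 10)
    results$aggregates <- tl
    tsv(tl, "aggregates_timeline")
    writeLines(
      c("Final aggregation status:", tl$composition[nrow(tl)],
        paste("free:", tl$free[nrow(tl)])),
      file.path(out_dir, "final_status.txt"))
  }
  if ("ecd" %in% analyses) {
    seg <- cfg$ecd$seg_len %||% 200
    d <- cfg$ecd$d %||% 10
    rho <- ecd_pair_correlation(traj, seg_len = seg, window = window, d = d)
    flex <- ecd_flexibility(traj, seg_len = seg, window = window, d = d)
    results$pair_correlation <- rho
    results$flexibility <- flex
    utils::write.table(unclass(rho), file.path(out_dir, "pair_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    tsv(flex, "flexibility")
  }
  meta <- list(
    package = "ecdyn",
    version = as.character(utils::packageVersion("ecdyn")),
    seed = seed, window = window, analyses = analyses,
    config = cfg
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
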