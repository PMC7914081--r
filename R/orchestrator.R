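#' Read a simulation configuration file
#'
#' YAML key/value text covering the [community_config()] fields; keys not
#' present fall back to the defaults.  `overrides` (e.g. CLI flags) take
#' precedence over file values.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @param overrides Named list of values overriding the file.
#' @return A `community_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration error: file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(community_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(community_config, vals)
}

#' @rdname read_config
#' @param cfg A `community_config` to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full seeded simulation experiment
#'
#' Pipeline: sample the species pool, seed the lattice, step the automaton
#' with strided snapshotting, then write the standard outputs (species
#' table, population series, Simpson series, event log, snapshot grids) and
#' a JSON run manifest.  Identical seeds give identical outputs.
#'
#' @param config A `community_config`, or a path to a YAML config file.
#' @param overrides Named list overriding config values.
#' @param out_dir Output directory (created if needed); `NULL` runs without
#'   writing files.
#' @param snapshots_png Also render PNG rasters of the stored snapshots.
#' @return Invisibly, a list with `manifest`, `run` (the `ca_run`),
#'   `species`, and `config`.
#' @export
run_simulation <- function(config, overrides = list(), out_dir = NULL,
                           snapshots_png = FALSE) {
  cfg <- if (inherits(config, "community_config")) {
    if (length(overrides)) read_config_from(config, overrides) else config
  } else read_config(config, overrides)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  species <- sample_community(cfg, seed = NULL)
  lat <- seed_lattice(species, cfg, seed = NULL)
  run <- run_ca(lat, species, steps = cfg$steps,
                snapshot_stride = cfg$snapshot_stride,
                lag_enabled = cfg$lag_enabled, literal = cfg$mll_literal)

  manifest <- list(config = unclass(cfg), config_hash = .config_hash(cfg),
                   seed = cfg$seed, version = as.character(utils::packageVersion("oralca")),
                   steps_completed = cfg$steps, outputs = list(), complete = TRUE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      species = file.path(out_dir, "species.csv"),
      series = file.path(out_dir, "population_series.csv"),
      simpson = file.path(out_dir, "simpson_series.csv"),
      events = file.path(out_dir, "events.csv"),
      config = file.path(out_dir, "config.yml"),
      manifest = file.path(out_dir, "manifest.json"))
    write_species_table(species, paths$species)
    ser <- data.frame(step = as.integer(colnames(run$counts)), t(run$counts))
    names(ser) <- c("step", paste0("species_", rownames(run$counts)))
    write_series(ser, paths$series)
    write_series(simpson_series(run), paths$simpson)
    utils::write.csv(run$events, paths$events, row.names = FALSE, quote = FALSE)
    write_config(cfg, paths$config)
    for (nm in names(run$snapshots)) {
      sp_path <- file.path(out_dir, sprintf("snapshot_%s.csv", nm))
      write_snapshot(run$snapshots[[nm]], sp_path)
      paths[[paste0("snapshot_", nm)]] <- sp_path
      if (snapshots_png) {
        png_path <- file.path(out_dir, sprintf("snapshot_%s.png", nm))
        write_snapshot_png(run$snapshots[[nm]], species, png_path)
        paths[[paste0("snapshot_png_", nm)]] <- png_path
      }
    }
    manifest$outputs <- paths
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(manifest = manifest, run = run, species = species, config = cfg))
}

# apply overrides to an existing config object
read_config_from <- function(cfg, overrides) {
  vals <- utils::modifyList(unclass(cfg), overrides)
  do.call(community_config, vals)
}

#' Controlled comparison: lag rules on vs off
#'
#' Runs the same community twice — identical species draw and initial
#' lattice — once with the lag-induction rules active and once with them
#' disabled (the lag-relevant probabilities contribute nothing), then
#' summarizes final richness, late-window Simpson diversity, and the
#' fluctuation signature (species with multiple post-transient population
#' peaks vs monotone dominance/extinction).
#'
#' @inheritParams run_simulation
#' @param late_window Fraction of steps (from the end) for the late Simpson
#'   mean.
#' @return Invisibly, a list with `lag_on`, `lag_off` (each with `run` and
#'   `manifest`), `species`, `comparison` (one-row data frame), `config`.
#' @export
run_delay_comparison <- function(config, overrides = list(), out_dir = NULL,
                                 late_window = 0.25) {
  cfg <- if (inherits(config, "community_config")) {
    if (length(overrides)) read_config_from(config, overrides) else config
  } else read_config(config, overrides)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  species <- sample_community(cfg, seed = NULL)
  lat0 <- seed_lattice(species, cfg, seed = NULL)
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)
  rng_state <- get(".Random.seed", envir = .GlobalEnv)

  run_on <- run_ca(lat0, species, steps = cfg$steps,
                   snapshot_stride = cfg$snapshot_stride,
                   lag_enabled = TRUE, literal = cfg$mll_literal)
  assign(".Random.seed", rng_state, envir = .GlobalEnv)
  run_off <- run_ca(lat0, species, steps = cfg$steps,
                    snapshot_stride = cfg$snapshot_stride,
                    lag_enabled = FALSE, literal = cfg$mll_literal)

  summarize <- function(run) {
    n <- ncol(run$counts)
    idx <- seq.int(max(1L, n - ceiling(late_window * n) + 1L), n)
    simp <- simpson_series(run)$simpson_alpha[idx]
    peaks <- apply(run$counts, 1, count_peaks)
    list(final_richness = sum(run$counts[, n] > 0),
         late_simpson = mean(simp, na.rm = TRUE),
         n_multi_peak = sum(peaks >= 2))
  }
  s_on <- summarize(run_on)
  s_off <- summarize(run_off)
  comparison <- data.frame(
    condition = c("lag_on", "lag_off"),
    final_richness = c(s_on$final_richness, s_off$final_richness),
    late_simpson = c(s_on$late_simpson, s_off$late_simpson),
    n_multi_peak_species = c(s_on$n_multi_peak, s_off$n_multi_peak))

  init_hash <- {
    tmp <- tempfile(fileext = ".csv")
    write_snapshot(lat0, tmp)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
    h
  }
  out <- list(lag_on = list(run = run_on), lag_off = list(run = run_off),
              species = species, comparison = comparison, config = cfg,
              initial_lattice_hash = init_hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    for (cond in c("lag_on", "lag_off")) {
      run <- out[[cond]]$run
      ser <- data.frame(step = as.integer(colnames(run$counts)), t(run$counts))
      names(ser) <- c("step", paste0("species_", rownames(run$counts)))
      write_series(ser, file.path(out_dir, paste0("series_", cond, ".csv")))
      write_series(simpson_series(run),
                   file.path(out_dir, paste0("simpson_", cond, ".csv")))
    }
  }
  invisible(out)
}

#' Identify delays for one taxon of an abundance series file
#'
#' Reads a `time,<taxon>,...` CSV, fixes `mu` (from the exponential phase)
#' and `K` (from the series plateau) unless supplied, runs
#' [identify_delays()], and writes/returns a report row shaped like a
#' published delay table: point estimates and 95% intervals for the
#' reproductive and reaction delay plus the residual sum of squares.
#'
#' @param series_path Path to the series CSV.
#' @param taxon Column to analyse.
#' @param mu,K Fixed externally when given; otherwise estimated from the
#'   series (`mu` over the initial exponential window, `K` as the mean of
#'   the last 10% of samples).
#' @param bounds,n_boot,seed Passed to [identify_delays()].
#' @param out Optional CSV path for the report.
#' @return Invisibly, a list with `estimate` (the `delay_estimate`) and
#'   `report` (one-row data frame).
#' @export
run_delay_identification <- function(series_path, taxon, mu = NULL, K = NULL,
                                     bounds = list(tau1 = c(0, 6), tau2 = c(0, 12)),
                                     n_boot = 0, seed = NULL, out = NULL) {
  df <- read_series(series_path)
  traj <- series_trajectory(df, taxon)
  if (is.null(K)) K <- mean(tail(traj$value, max(2L, ceiling(0.1 * nrow(traj)))))
  if (is.null(mu)) {
    # exponential window: samples below 20% of the plateau
    w <- which(traj$value < 0.2 * K)
    if (length(w) < 3) w <- seq_len(min(10L, nrow(traj)))
    mu <- specific_growth_rate(traj, window = w)
  }
  est <- identify_delays(traj, mu = mu, K = K, bounds = bounds,
                         n_boot = n_boot, seed = seed)
  report <- data.frame(taxon = taxon,
                       tau1_hat = est$tau1_hat, tau1_lo = est$tau1_ci[1],
                       tau1_hi = est$tau1_ci[2], tau2_hat = est$tau2_hat,
                       tau2_lo = est$tau2_ci[1], tau2_hi = est$tau2_ci[2],
                       rss = est$objective)
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE, quote = FALSE)
  invisible(list(estimate = est, report = report))
}
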