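#' Run configuration for a full simulated study
#'
#' Bundles everything one end-to-end run needs: the cohort configuration,
#' engine settings, per-group frequency grids and the ratio-analysis
#' window mode.  Serialises losslessly to YAML ([save_run_config()] /
#' [load_run_config()]), and its content hash stamps every output
#' manifest.
#'
#' @param cohort A [cohort_config()].
#' @param engine A [qcsf_config()].
#' @param sf_amblyope,sf_control Grid specs `c(f_min, f_max, n_levels)`.
#' @param n_repetitions Repetitions per condition.
#' @param window Ratio window mode, `"printed"` or `"auto"`.
#' @param seed Master seed (also seeds the cohort unless the cohort
#'   config sets its own).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       engine = qcsf_config(),
                       sf_amblyope = c(0.31, 11.77, 12),
                       sf_control = c(0.31, 32.31, 12),
                       n_repetitions = 2L,
                       window = "printed",
                       seed = 2024L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, engine = engine,
                 sf_amblyope = sf_amblyope, sf_control = sf_control,
                 n_repetitions = as.integer(n_repetitions),
                 window = window, seed = as.integer(seed)),
            class = "run_config")
}

#' Reduced-resolution engine configuration for cohort-scale simulation
#'
#' A coarser posterior grid (10 x 8 x 6 x 6 nodes) that keeps a full
#' 21-subject, 12-run study tractable on one CPU while preserving the
#' estimator's behaviour; the default [param_grid()] resolution is used
#' for single-run work.
#'
#' @param ... Overrides forwarded to [qcsf_config()].
#' @return A `qcsf_config`.
#' @export
study_engine_config <- function(...) {
  qcsf_config(grid = param_grid(gain = c(1.2, 2000, 10),
                                peak_sf = c(0.2, 20, 8),
                                bandwidth = c(1, 9, 6),
                                truncation = c(0.02, 2, 6)),
              n_contrasts = 30L, ...)
}

config_to_list <- function(x) {
  if (inherits(x, "param_grid"))
    return(list(gain = range_spec(x$axes$gain, TRUE),
                peak_sf = range_spec(x$axes$peak_sf, TRUE),
                bandwidth = range_spec(x$axes$bandwidth, TRUE),
                truncation = range_spec(x$axes$truncation, FALSE)))
  if (is.list(x)) return(lapply(unclass(x), config_to_list))
  x
}
range_spec <- function(v, log) c(v[1], v[length(v)], length(v))

#' Save / load a run configuration as YAML
#'
#' `load_run_config(save_run_config(cfg, path))` reconstructs an
#' equivalent configuration (round-trip identity on all settings).
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   returns a `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  eng <- raw$engine
  grid <- param_grid(gain = as.numeric(eng$grid$gain),
                     peak_sf = as.numeric(eng$grid$peak_sf),
                     bandwidth = as.numeric(eng$grid$bandwidth),
                     truncation = as.numeric(eng$grid$truncation))
  psy <- do.call(psy_config, raw$engine$psy)
  engine <- qcsf_config(grid = grid, psy = psy,
                        n_trials = eng$n_trials,
                        n_practice = eng$n_practice,
                        n_contrasts = eng$n_contrasts,
                        c_min = eng$c_min, c_max = eng$c_max,
                        edge_warn_frac = eng$edge_warn_frac)
  coh <- raw$cohort
  coh$psy <- do.call(psy_config, coh$psy)
  cohort <- do.call(cohort_config, coh)
  run_config(cohort = cohort, engine = engine,
             sf_amblyope = as.numeric(raw$sf_amblyope),
             sf_control = as.numeric(raw$sf_control),
             n_repetitions = raw$n_repetitions,
             window = raw$window, seed = raw$seed)
}

#' Stable content hash of a run configuration
#'
#' @param cfg A [run_config()].
#' @return An md5 string over the canonical serialised settings.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a full study and write it to disk
#'
#' Generates the cohort and all adaptive runs and writes: the cohort
#' ground truth (`ground_truth.json`), the trial log (`trials.csv`, one
#' row per trial), per-run and repetition-averaged estimates
#' (`runs.csv`, `estimates.csv`), and a run manifest
#' (`manifest.json`) listing every output with an md5 checksum plus the
#' config hash and seed.  Idempotent: the same config and seed reproduce
#' byte-identical CSVs.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param progress Passed to [generate_study()].
#' @return The `study_dataset`, invisibly.
#' @export
simulate_study <- function(cfg, out_dir, progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(cfg$cohort,
                        sf_grid_amblyope = do.call(make_sf_grid,
                                                   as.list(cfg$sf_amblyope)),
                        sf_grid_control = do.call(make_sf_grid,
                                                  as.list(cfg$sf_control)))
  dataset <- generate_study(cohort, cfg$engine, cfg$n_repetitions,
                            progress = progress)
  truth <- lapply(cohort$observers, function(ob)
    list(subject_id = ob$subject_id, group = ob$group,
         target_ratio = ob$target_ratio,
         csf = lapply(ob$csf, function(eye) lapply(eye, unclass))))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_num_csv(dataset$trials, file.path(out_dir, "trials.csv"))
  write_num_csv(dataset$runs, file.path(out_dir, "runs.csv"))
  write_num_csv(dataset$estimates, file.path(out_dir, "estimates.csv"))
  files <- c("ground_truth.json", "trials.csv", "runs.csv",
             "estimates.csv")
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   created = "simulate_study",
                   files = lapply(files, function(f)
                     list(name = f, md5 = unname(tools::md5sum(
                       file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  save_run_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(dataset)
}

# CSVs with numeric fields at 9 significant digits for cross-platform
# byte stability.
write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Re-load a simulated study from disk
#'
#' Reads the estimates table and ground truth written by
#' [simulate_study()] and rebuilds the `study_dataset` pieces the
#' analysis stage needs.  Validates the estimates schema and reports the
#' first offending row on corruption.
#'
#' @param dir Dataset directory.
#' @return A `study_dataset` (without the trial-level log unless present).
#' @export
load_study <- function(dir) {
  est_path <- file.path(dir, "estimates.csv")
  if (!file.exists(est_path)) stop("missing estimates.csv in ", dir)
  est <- utils::read.csv(est_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "eye", "condition", "aulcsf")
  miss <- setdiff(required, names(est))
  if (length(miss))
    stop("estimates.csv lacks columns: ", paste(miss, collapse = ", "))
  au <- suppressWarnings(as.numeric(est$aulcsf))
  bad <- which(!is.finite(au))
  if (length(bad))
    stop("estimates.csv row ", bad[1], " (subject ",
         est$subject_id[bad[1]], "): non-numeric aulcsf")
  est$aulcsf <- au
  cfg <- load_run_config(file.path(dir, "config.yaml"))
  grids <- list(amblyope = do.call(make_sf_grid, as.list(cfg$sf_amblyope)),
                control = do.call(make_sf_grid, as.list(cfg$sf_control)))
  runs_path <- file.path(dir, "runs.csv")
  runs <- if (file.exists(runs_path))
    utils::read.csv(runs_path, stringsAsFactors = FALSE) else NULL
  structure(list(estimates = est, runs = runs, trials = NULL,
                 cohort = structure(list(observers = NULL,
                                         config = cfg$cohort,
                                         sf_grids = grids),
                                    class = "cohort"),
                 engine_config = cfg$engine,
                 n_repetitions = cfg$n_repetitions),
            class = "study_dataset")
}

#' Analyse a simulated (or re-loaded) study and write report tables
#'
#' Runs [study_report()] and writes each table as CSV plus a JSON
#' summary; deterministic for fixed inputs.
#'
#' @param dataset A `study_dataset`, or a directory to [load_study()].
#' @param out_dir Report directory.
#' @param window Ratio window mode.
#' @return The `study_report`, invisibly.
#' @export
analyze_study <- function(dataset, out_dir, window = "printed") {
  if (is.character(dataset)) dataset <- load_study(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- study_report(dataset, window = window)
  for (nm in c("interocular", "condition", "ratio", "correlation",
               "ratio_table", "ratio_summary", "aulcsf_table", "mean_csf"))
    write_num_csv(as.data.frame(rep[[nm]]),
                  file.path(out_dir, paste0(nm, ".csv")))
  summary_json <- list(
    mean_interocular_ratio = stats::setNames(
      lapply(split(rep$aulcsf_table, rep$aulcsf_table$group), function(d) {
        a <- d[d$condition == "balanced" & d$eye == "affected", ]
        b <- d[d$condition == "balanced" & d$eye == "better", ]
        a <- a[order(a$subject_id), ]; b <- b[order(b$subject_id), ]
        mean(a$aulcsf / b$aulcsf)
      }), unique(sort(rep$aulcsf_table$group))))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Export the three stimulus classes for one frequency and seed
#'
#' Writes one balanced, one increment and one decrement PNG (with JSON
#' sidecars) synthesised from the same noise seed.
#'
#' @param sf Spatial frequency, cycles/degree.
#' @param out_dir Output directory.
#' @param seed Noise seed.
#' @param contrast Nominal peak Weber contrast.
#' @param sigma_deg Gaussian window sigma, degrees.
#' @param ... Passed to [make_bandpass_noise()].
#' @return Invisibly, the sidecar list per mode.
#' @export
export_stimuli <- function(sf, out_dir, seed = 1L, contrast = 0.5,
                           sigma_deg = 2, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- make_bandpass_noise(sf, seed = seed, ...)
  base <- apply_gaussian_window(base, sigma_deg)
  out <- lapply(c(balanced = "balanced", increment = "increment",
                  decrement = "decrement"), function(mode) {
    img <- polarize(base, mode, contrast)
    write_stimulus_png(img, file.path(out_dir,
                                      sprintf("stim_%s_sf%.2f_s%d.png",
                                              mode, sf, seed)))
  })
  invisible(out)
}
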