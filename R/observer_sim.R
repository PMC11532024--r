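#' Simulated-observer cohort configuration
#'
#' Defines the population the synthetic study draws from: cohort sizes, the
#' target interocular AULCSF ratios, the ON-pathway (increment) deficit
#' profile of the amblyopic eye, the unipolar-to-balanced sensitivity
#' factor, and between-subject variability.
#'
#' The defaults encode the study conditions being emulated: 11 amblyopes
#' with a mean amblyopic-eye/fellow-eye AULCSF ratio of 0.67, 10 controls
#' with a non-dominant/dominant ratio of 0.91, and an amblyopic-eye
#' increment/decrement sensitivity ratio that declines from ~1 at
#' 0.31 c/deg to ~0.7 at 2.25 c/deg.
#'
#' @param n_amblyopes,n_controls Cohort sizes (>= 2).
#' @param ratio_amblyope,ratio_control Target ground-truth interocular
#'   AULCSF ratios (affected/better eye), in (0, 2].
#' @param ratio_sd Between-subject SD of the interocular ratio (draws are
#'   recentred so the cohort mean equals the target exactly).
#' @param on_deficit_floor Increment/decrement sensitivity ratio reached at
#'   `on_deficit_knee_sf` in the amblyopic eye (1 = no deficit).
#' @param on_deficit_start_sf,on_deficit_knee_sf Frequencies (c/deg)
#'   bracketing the log-linear decline of the deficit profile; below the
#'   start the ratio is 1, beyond the knee it stays at the floor.
#' @param unipolar_gain_factor Multiplicative factor on linear gain for
#'   increment/decrement relative to balanced (in (0, 1]).
#' @param gain_sd_log10,peak_sf_sd_log10 Between-subject SDs of log10
#'   balanced gain and log10 peak frequency.
#' @param condition_jitter_log10 Independent per-condition log10-gain
#'   jitter applied to unipolar CSFs (measurement-independent trait noise).
#' @param mean_gain,mean_peak_sf,mean_bandwidth,mean_truncation Population
#'   means of the balanced fellow/dominant-eye CSF parameters.
#' @param psy A [psy_config()] shared by all observers.
#' @param seed Master seed for cohort generation.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_amblyopes = 11L, n_controls = 10L,
                          ratio_amblyope = 0.67, ratio_control = 0.91,
                          ratio_sd = 0.06,
                          on_deficit_floor = 0.7,
                          on_deficit_start_sf = 0.31,
                          on_deficit_knee_sf = 2.25,
                          unipolar_gain_factor = 0.5,
                          gain_sd_log10 = 0.15, peak_sf_sd_log10 = 0.1,
                          condition_jitter_log10 = 0.03,
                          mean_gain = 120, mean_peak_sf = 2.5,
                          mean_bandwidth = 3.5, mean_truncation = 0.5,
                          psy = psy_config(), seed = 2024L) {
  stopifnot(n_amblyopes >= 2, n_controls >= 2,
            ratio_amblyope > 0, ratio_amblyope <= 2,
            ratio_control > 0, ratio_control <= 2,
            on_deficit_floor > 0, on_deficit_floor <= 2,
            unipolar_gain_factor > 0, unipolar_gain_factor <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Null cohort configuration
#'
#' Convenience wrapper: identical eyes and conditions (interocular ratios
#' 1, no ON deficit, no condition jitter), used for type-I-error and
#' unbiasedness checks.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cohort_config(ratio_amblyope = 1, ratio_control = 1, ratio_sd = 0,
                on_deficit_floor = 1, condition_jitter_log10 = 0, ...)
}

# Increment/decrement target ratio profile at frequency f (vectorised):
# 1 up to start_sf, log-linear decline to `floor` at knee_sf, flat beyond.
on_deficit_profile <- function(cfg, f) {
  lf <- log2(f / cfg$on_deficit_start_sf)
  span <- log2(cfg$on_deficit_knee_sf / cfg$on_deficit_start_sf)
  frac <- pmin(pmax(lf / span, 0), 1)
  exp(log(cfg$on_deficit_floor) * frac)
}

# Scale a CSF's gain so that aulcsf(scaled)/aulcsf(reference) == ratio on
# [f_min, f_max]. Monotone in gain, solved by uniroot on log10 gain.
scale_gain_to_aulcsf_ratio <- function(ref_params, ratio, f_min, f_max) {
  target <- aulcsf(ref_params, f_min, f_max) * ratio
  obj <- function(lg) {
    p <- csf_params(10^lg, ref_params$peak_sf, ref_params$bandwidth,
                    ref_params$truncation)
    aulcsf(p, f_min, f_max) - target
  }
  sol <- stats::uniroot(obj, lower = log10(1.0001), upper = log10(1e5),
                        tol = 1e-10)
  csf_params(10^sol$root, ref_params$peak_sf, ref_params$bandwidth,
             ref_params$truncation)
}

# Fit an increment CSF to a target per-SF inc/dec sensitivity ratio by
# least squares over (log10 gain, log10 bandwidth), holding peak frequency
# and truncation at the decrement values.
fit_increment_to_ratio <- function(dec_params, ratio_at_sf, sf_values) {
  target_log <- log_sensitivity(dec_params, sf_values) + log10(ratio_at_sf)
  obj <- function(th) {
    p <- csf_params(10^th[1], dec_params$peak_sf, 10^th[2],
                    dec_params$truncation)
    sum((log_sensitivity(p, sf_values) - target_log)^2)
  }
  start <- c(log10(dec_params$gain), log10(dec_params$bandwidth))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  csf_params(10^fit$par[1], dec_params$peak_sf, 10^fit$par[2],
             dec_params$truncation)
}

#' Generate a simulated cohort
#'
#' Draws per-subject balanced fellow/dominant-eye CSFs from log-normal
#' population distributions, derives the affected (amblyopic or
#' non-dominant) eye by scaling gain so the ground-truth interocular
#' AULCSF ratio hits a per-subject target (draws recentred so the cohort
#' mean equals the configured target exactly), derives increment and
#' decrement CSFs via the unipolar gain factor plus per-condition jitter,
#' and imposes the configured ON-deficit ratio profile on the amblyopic
#' eye's increment CSF by a least-squares gain-and-bandwidth adjustment.
#' Deterministic given the master seed.
#'
#' @param cfg A [cohort_config()].
#' @param sf_grid_amblyope,sf_grid_control [make_sf_grid()] objects used
#'   for the AULCSF calibration range and the deficit-profile fit.
#' @return A list of class `cohort`: element `observers` is a list of
#'   observer profiles, each with `subject_id`, `group`, `psy`, `seed` and
#'   `csf[[eye]][[condition]]` ground-truth parameters (eyes `"affected"`,
#'   `"better"`; conditions `"balanced"`, `"increment"`, `"decrement"`).
#' @export
make_cohort <- function(cfg = cohort_config(),
                        sf_grid_amblyope = make_sf_grid(0.31, 11.77, 12),
                        sf_grid_control = make_sf_grid(0.31, 32.31, 12)) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(as.integer(cfg$seed))
  groups <- c(rep("amblyope", cfg$n_amblyopes),
              rep("control", cfg$n_controls))
  make_group <- function(group, n, target_ratio) {
    grid <- if (group == "amblyope") sf_grid_amblyope else sf_grid_control
    ratio_dev <- stats::rnorm(n, 0, cfg$ratio_sd)
    ratio_dev <- ratio_dev - mean(ratio_dev)   # cohort mean hits the target
    ratios <- pmin(pmax(target_ratio + ratio_dev, 0.05), 2)
    lapply(seq_len(n), function(i) tryCatch({
      better_bal <- csf_params(
        gain = 10^stats::rnorm(1, log10(cfg$mean_gain), cfg$gain_sd_log10),
        peak_sf = 10^stats::rnorm(1, log10(cfg$mean_peak_sf),
                                  cfg$peak_sf_sd_log10),
        bandwidth = cfg$mean_bandwidth,
        truncation = cfg$mean_truncation)
      affected_bal <- scale_gain_to_aulcsf_ratio(
        better_bal, ratios[i], grid$f_min, grid$f_max)
      unipolar <- function(bal) {
        jit <- function() 10^stats::rnorm(1, 0, cfg$condition_jitter_log10)
        g <- function() max(min(bal$gain * cfg$unipolar_gain_factor * jit(),
                                bal$gain), 1.01)
        list(increment = csf_params(g(), bal$peak_sf, bal$bandwidth,
                                    bal$truncation),
             decrement = csf_params(g(), bal$peak_sf, bal$bandwidth,
                                    bal$truncation))
      }
      bet_uni <- unipolar(better_bal)
      aff_uni <- unipolar(affected_bal)
      if (group == "amblyope" && cfg$on_deficit_floor < 1) {
        # impose the inc/dec ratio profile on the amblyopic eye by
        # refitting the increment CSF against the decrement CSF; the fit
        # runs over the ratio-analysis window (start to knee), where the
        # two-parameter (gain, bandwidth) adjustment can track the decline
        win <- grid$values[grid$values <= cfg$on_deficit_knee_sf * 1.001]
        aff_uni$increment <- fit_increment_to_ratio(
          aff_uni$decrement, on_deficit_profile(cfg, win), win)
      }
      csf <- list(
        better = list(balanced = better_bal,
                      increment = bet_uni$increment,
                      decrement = bet_uni$decrement),
        affected = list(balanced = affected_bal,
                        increment = aff_uni$increment,
                        decrement = aff_uni$decrement))
      # enforce the unipolar <= balanced gain invariant
      for (eye in names(csf)) {
        bal_gain <- csf[[eye]]$balanced$gain
        for (cond in c("increment", "decrement")) {
          if (csf[[eye]][[cond]]$gain > bal_gain) {
            p <- csf[[eye]][[cond]]
            csf[[eye]][[cond]] <- csf_params(bal_gain, p$peak_sf,
                                             p$bandwidth, p$truncation)
          }
        }
      }
      list(subject_id = sprintf("%s%02d",
                                if (group == "amblyope") "A" else "C", i),
           group = group, csf = csf, psy = cfg$psy,
           target_ratio = ratios[i],
           seed = as.integer(cfg$seed))
    }, error = function(e) {
      stop(sprintf("cohort generation failed for subject %s%02d: %s",
                   if (group == "amblyope") "A" else "C", i,
                   conditionMessage(e)), call. = FALSE)
    }))
  }
  observers <- c(make_group("amblyope", cfg$n_amblyopes, cfg$ratio_amblyope),
                 make_group("control", cfg$n_controls, cfg$ratio_control))
  structure(list(observers = observers, config = cfg,
                 sf_grids = list(amblyope = sf_grid_amblyope,
                                 control = sf_grid_control)),
            class = "cohort")
}

#' Ground-truth interocular AULCSF ratios of a cohort
#'
#' @param cohort A [make_cohort()] result.
#' @return Data frame with `subject_id`, `group`, `aulcsf_affected`,
#'   `aulcsf_better`, `ratio`.
#' @export
cohort_truth_ratios <- function(cohort) {
  do.call(rbind, lapply(cohort$observers, function(ob) {
    grid <- cohort$sf_grids[[ob$group]]
    a <- aulcsf(ob$csf$affected$balanced, grid$f_min, grid$f_max)
    b <- aulcsf(ob$csf$better$balanced, grid$f_min, grid$f_max)
    data.frame(subject_id = ob$subject_id, group = ob$group,
               aulcsf_affected = a, aulcsf_better = b, ratio = a / b)
  }))
}

#' Simulated 2AFC response
#'
#' Bernoulli draw through the observer's psychometric function for the
#' ground-truth CSF matching the stimulated eye and condition.  Uses the
#' current RNG stream, so responses are deterministic given the seed state.
#'
#' @param observer One element of a cohort's `observers` list.
#' @param eye `"affected"` or `"better"`.
#' @param stim A [stimulus_point()]; its `polarity` selects the condition
#'   CSF (`"balanced"`, `"increment"`, `"decrement"`).
#' @return Logical, `TRUE` for a correct response.
#' @export
respond <- function(observer, eye, stim) {
  params <- observer$csf[[eye]][[stim$polarity]]
  if (is.null(params)) stop("unknown eye or condition: ", eye, "/",
                            stim$polarity)
  stats::runif(1) < p_correct(params, observer$psy, stim)
}

# Deterministic child seed for (subject, eye, condition, repetition),
# derived from the master seed; stays within 32-bit signed range.
child_seed <- function(master, subject_idx, eye, condition, repetition) {
  eye_i <- match(eye, c("affected", "better"))
  cond_i <- match(condition, c("balanced", "increment", "decrement"))
  as.integer((as.double(master) * 48271 + subject_idx * 10007 +
                eye_i * 1009 + cond_i * 101 + repetition) %% 2147483629)
}

#' Run the full simulated study
#'
#' For every subject x eye x condition x repetition, runs one adaptive
#' measurement ([run_qcsf()]) with the subject's simulated responder: 12
#' runs per subject (3 conditions x 2 eyes x 2 repetitions by default).
#' Likelihood tables are precomputed once per group.  Repetition-averaged
#' derived metrics are computed per the averaging convention: AULCSF and
#' log10 grid sensitivities and log10 cut-off averaged across repetitions.
#'
#' @param cohort A [make_cohort()] result.
#' @param engine_config A [qcsf_config()].
#' @param n_repetitions Repetitions per condition (default 2).
#' @param progress Print one line per subject.
#' @return A list of class `study_dataset` with `estimates` (one row per
#'   subject x eye x condition, repetition-averaged), `runs` (one row per
#'   run), `trials` (one row per trial), `cohort`, and `engine_config`.
#' @export
generate_study <- function(cohort, engine_config = qcsf_config(),
                           n_repetitions = 2L, progress = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  tables <- lapply(cohort$sf_grids, function(g)
    likelihood_tables(engine_config$grid, engine_config$psy,
                      make_candidates(g, engine_config$n_contrasts,
                                      engine_config$c_min,
                                      engine_config$c_max)))
  eyes <- c("affected", "better")
  conds <- c("balanced", "increment", "decrement")
  est_rows <- list(); run_rows <- list(); trial_rows <- list()
  master <- cohort$config$seed
  for (si in seq_along(cohort$observers)) {
    ob <- cohort$observers[[si]]
    grid <- cohort$sf_grids[[ob$group]]
    tab <- tables[[ob$group]]
    for (eye in eyes) for (cond in conds) {
      per_rep <- vector("list", n_repetitions)
      for (rep_i in seq_len(n_repetitions)) {
        seed <- child_seed(master, si, eye, cond, rep_i)
        tag <- sprintf("%s/%s/%s/r%d/s%d", ob$subject_id, eye, cond,
                       rep_i, seed)
        responder <- function(stim) respond(ob, eye, stim)
        run <- run_qcsf(responder, grid, engine_config, polarity = cond,
                        seed = seed, tables = tab, seed_tag = tag)
        per_rep[[rep_i]] <- run$estimate
        tr <- run$trials
        tr$subject_id <- ob$subject_id; tr$group <- ob$group
        tr$eye <- eye; tr$condition <- cond; tr$repetition <- rep_i
        trial_rows[[length(trial_rows) + 1L]] <- tr
        run_rows[[length(run_rows) + 1L]] <- data.frame(
          subject_id = ob$subject_id, group = ob$group, eye = eye,
          condition = cond, repetition = rep_i, seed = seed,
          gain = run$estimate$params$gain,
          peak_sf = run$estimate$params$peak_sf,
          bandwidth = run$estimate$params$bandwidth,
          truncation = run$estimate$params$truncation,
          aulcsf = run$estimate$aulcsf,
          cutoff_sf = run$estimate$cutoff_sf,
          cutoff_flag = run$estimate$cutoff_flag,
          edge_warning = run$estimate$edge_warning)
      }
      log_sens <- rowMeans(vapply(per_rep, function(e)
        log10(e$grid_sensitivities), numeric(grid$n_levels)))
      truth <- ob$csf[[eye]][[cond]]
      row <- data.frame(
        subject_id = ob$subject_id, group = ob$group, eye = eye,
        condition = cond,
        aulcsf = mean(vapply(per_rep, `[[`, numeric(1), "aulcsf")),
        cutoff_sf = 10^mean(vapply(per_rep, function(e)
          log10(e$cutoff_sf), numeric(1))),
        any_censored = any(vapply(per_rep, function(e)
          e$cutoff_flag != "ok", logical(1))),
        edge_warning = any(vapply(per_rep, `[[`, logical(1),
                                  "edge_warning")),
        true_gain = truth$gain, true_peak_sf = truth$peak_sf,
        true_bandwidth = truth$bandwidth, true_truncation = truth$truncation,
        true_aulcsf = aulcsf(truth, grid$f_min, grid$f_max))
      sens <- as.data.frame(t(log_sens))
      names(sens) <- sprintf("log_sens_%02d", seq_len(grid$n_levels))
      est_rows[[length(est_rows) + 1L]] <- cbind(row, sens)
    }
    if (progress)
      message(sprintf("subject %s done (%d/%d)", ob$subject_id, si,
                      length(cohort$observers)))
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 runs = do.call(rbind, run_rows),
                 trials = do.call(rbind, trial_rows),
                 cohort = cohort, engine_config = engine_config,
                 n_repetitions = n_repetitions),
            class = "study_dataset")
}
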