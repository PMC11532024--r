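# Cohort-scale simulation helpers shared by the observer-simulation and
# acceptance tests.  Heavy results are computed once per session and
# cached, so the same batch backs several assertions.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache))
    assign(key, force(expr), envir = .study_cache)
  get(key, envir = .study_cache)
}

# One replicate of the amblyopic-eye increment/decrement measurement:
# 11 amblyopes x 2 conditions x 2 repetitions, returning the per-subject
# repetition-averaged log10 inc/dec ratio at the windowed frequencies
# (first 7 grid values, 0.31-2.25 c/deg).
ae_ratio_replicate <- function(master_seed, null = FALSE,
                               eng = study_engine_config(),
                               n_reps = 2L) {
  cfg <- if (null) null_cohort_config(seed = master_seed)
         else cohort_config(seed = master_seed)
  cohort <- make_cohort(cfg)
  g <- cohort$sf_grids$amblyope
  tab <- likelihood_tables(eng$grid, eng$psy,
                           make_candidates(g, eng$n_contrasts,
                                           eng$c_min, eng$c_max))
  t(vapply(seq_len(cfg$n_amblyopes), function(si) {
    ob <- cohort$observers[[si]]
    ls <- sapply(c("increment", "decrement"), function(cond) {
      rowMeans(vapply(seq_len(n_reps), function(rep_i) {
        seed <- onoffcsf:::child_seed(cfg$seed, si, "affected", cond, rep_i)
        run <- run_qcsf(function(s) respond(ob, "affected", s), g, eng,
                        polarity = cond, seed = seed, tables = tab)
        log10(run$estimate$grid_sensitivities)
      }, numeric(g$n_levels)))
    })
    (ls[, "increment"] - ls[, "decrement"])[1:7]
  }, numeric(7)))
}

# Batches of replicates under the default and null cohorts (20 seeds).
default_ae_replicates <- function() cached("def_reps", {
  lapply(1:20, function(k) ae_ratio_replicate(k * 37 + 5))
})

null_ae_replicates <- function() cached("null_reps", {
  lapply(1:20, function(k) ae_ratio_replicate(k * 53 + 7, null = TRUE))
})

# Control-group non-dominant-eye inc/dec ratios (default cohorts, three
# seeds, 2 repetitions): the no-bias comparison group for the amblyopic
# eye's deficit.
control_ratio_batch <- function() cached("control_reps", {
  eng <- study_engine_config()
  unlist(lapply(c(201, 202, 203), function(ms) {
    cfg <- cohort_config(seed = ms)
    cohort <- make_cohort(cfg)
    g <- cohort$sf_grids$control
    tab <- likelihood_tables(eng$grid, eng$psy,
                             make_candidates(g, eng$n_contrasts,
                                             eng$c_min, eng$c_max))
    win <- seq_len(sum(g$values <= 11.97))
    vapply(cfg$n_amblyopes + seq_len(cfg$n_controls), function(si) {
      ob <- cohort$observers[[si]]
      ls <- sapply(c("increment", "decrement"), function(cond) {
        rowMeans(vapply(1:2, function(rep_i) {
          seed <- onoffcsf:::child_seed(cfg$seed, si, "affected", cond,
                                        rep_i)
          run <- run_qcsf(function(s) respond(ob, "affected", s), g, eng,
                          polarity = cond, seed = seed, tables = tab)
          log10(run$estimate$grid_sensitivities)
        }, numeric(g$n_levels)))
      })
      mean((ls[, "increment"] - ls[, "decrement"])[win])
    }, numeric(1))
  }))
})

# Balanced-condition study (both groups, both eyes, 2 repetitions):
# repetition-averaged AULCSF per subject x eye plus the cohort's ground
# truth, for the interocular-ratio recovery check.
balanced_study <- function() cached("balanced", {
  cfg <- cohort_config(seed = 911L)
  cohort <- make_cohort(cfg)
  eng <- study_engine_config()
  tabs <- lapply(cohort$sf_grids, function(g)
    likelihood_tables(eng$grid, eng$psy,
                      make_candidates(g, eng$n_contrasts, eng$c_min,
                                      eng$c_max)))
  est <- do.call(rbind, lapply(seq_along(cohort$observers), function(si) {
    ob <- cohort$observers[[si]]
    g <- cohort$sf_grids[[ob$group]]
    do.call(rbind, lapply(c("affected", "better"), function(eye) {
      au <- mean(vapply(1:2, function(rep_i) {
        seed <- onoffcsf:::child_seed(cfg$seed, si, eye, "balanced", rep_i)
        run_qcsf(function(s) respond(ob, eye, s), g, eng,
                 polarity = "balanced", seed = seed,
                 tables = tabs[[ob$group]])$estimate$aulcsf
      }, numeric(1)))
      data.frame(subject_id = ob$subject_id, group = ob$group, eye = eye,
                 aulcsf = au)
    }))
  }))
  list(estimates = est, truth = cohort_truth_ratios(cohort))
})

# Parameter-recovery batch at the default engine configuration: a
# mid-bandwidth observer displaced from the prior anchors, 20 seeds,
# measured after 25 and after 100 trials.
recovery_batch <- function() cached("recovery", {
  g <- make_sf_grid(0.31, 11.77, 12)
  truth <- csf_params(gain = 150, peak_sf = 3, bandwidth = 2,
                      truncation = 0.3)
  cfg100 <- qcsf_config()
  cfg25 <- qcsf_config(n_trials = 25L)
  tab <- likelihood_tables(cfg100$grid, cfg100$psy,
                           make_candidates(g, cfg100$n_contrasts,
                                           cfg100$c_min, cfg100$c_max))
  err <- function(est) abs(c(
    gain = log10(est$params$gain / truth$gain),
    peak_sf = log10(est$params$peak_sf / truth$peak_sf),
    bandwidth = log10(est$params$bandwidth / truth$bandwidth),
    truncation = est$params$truncation - truth$truncation))
  n_seeds <- 20
  e100 <- matrix(NA_real_, n_seeds, 4)
  e25 <- matrix(NA_real_, n_seeds, 4)
  traces <- matrix(NA_real_, n_seeds, 100)
  for (s in seq_len(n_seeds)) {
    set.seed(1e6 + s)
    r <- run_qcsf(make_responder(truth), g, cfg100, seed = 500 + s,
                  tables = tab)
    e100[s, ] <- err(r$estimate)
    traces[s, ] <- r$estimate$posterior_entropy_trace
    set.seed(2e6 + s)
    r25 <- run_qcsf(make_responder(truth), g, cfg25, seed = 700 + s,
                    tables = tab)
    e25[s, ] <- err(r25$estimate)
  }
  colnames(e100) <- colnames(e25) <- c("gain", "peak_sf", "bandwidth",
                                       "truncation")
  list(e100 = e100, e25 = e25, traces = traces, truth = truth)
})
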