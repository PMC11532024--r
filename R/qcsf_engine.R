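#' Psychometric configuration for the 2AFC orientation task
#'
#' Probability correct follows a Weibull function of stimulus contrast,
#' \eqn{\Psi(c) = g + (1 - g - \lambda)(1 - e^{-(c S(f))^\beta})}, where
#' `S(f)` is the observer's linear sensitivity at the stimulus frequency,
#' `g` the guess rate, `\lambda` the lapse rate and `\beta` the slope.
#' The task is two-alternative forced choice (horizontal vs vertical), so
#' the guess rate defaults to 0.5.
#'
#' @param guess_rate Lower asymptote, probability in [0, 1).
#' @param lapse_rate Lapse probability in [0, 0.5).
#' @param slope Weibull shape exponent (> 0).
#' @return An object of class `psy_config`.
#' @export
psy_config <- function(guess_rate = 0.5, lapse_rate = 0.04, slope = 2.0) {
  stopifnot(guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate < 0.5,
            slope > 0, guess_rate + lapse_rate < 1)
  structure(list(guess_rate = guess_rate, lapse_rate = lapse_rate,
                 slope = slope), class = "psy_config")
}

#' One stimulus placement
#'
#' @param sf Spatial frequency, cycles/degree.
#' @param contrast Contrast fraction in (0, 1].
#' @param polarity One of `"balanced"`, `"increment"`, `"decrement"`.
#' @param orientation One of `"horizontal"`, `"vertical"`, or `NA` before
#'   assignment.
#' @return A list of class `stimulus_point`.
#' @export
stimulus_point <- function(sf, contrast, polarity = "balanced",
                           orientation = NA_character_) {
  stopifnot(sf > 0, contrast > 0, contrast <= 1)
  polarity <- match.arg(polarity, c("balanced", "increment", "decrement"))
  structure(list(sf = sf, contrast = contrast, polarity = polarity,
                 orientation = orientation), class = "stimulus_point")
}

#' Probability of a correct 2AFC response
#'
#' @param params A [csf_params()] object (the observer's true or candidate
#'   CSF).
#' @param psy A [psy_config()].
#' @param stim A [stimulus_point()] or any list with `sf` and `contrast`.
#' @return Probability in `[guess_rate, 1 - lapse_rate)`.
#' @export
p_correct <- function(params, psy, stim) {
  s <- sensitivity(params, stim$sf)
  psy$guess_rate + (1 - psy$guess_rate - psy$lapse_rate) *
    (1 - exp(-(stim$contrast * s)^psy$slope))
}

#' Discretised parameter grid for the posterior
#'
#' Axes for gain, peak frequency and bandwidth are log-spaced; the
#' truncation axis is linear.  Each axis is given as `c(min, max, n)`.
#'
#' @param gain,peak_sf,bandwidth,truncation Axis specifications
#'   `c(min, max, n_points)`.
#' @return An object of class `param_grid` with the axis values and an
#'   `n x 4` node matrix (`nodes`), plus the node values on the scale used
#'   for posterior averaging (`nodes_scaled`: log10 for the first three
#'   axes, linear for truncation).
#' @export
param_grid <- function(gain = c(1.2, 2000, 16),
                       peak_sf = c(0.2, 20, 10),
                       bandwidth = c(1, 9, 7),
                       truncation = c(0.02, 2, 6)) {
  ax <- function(spec, log = TRUE, name = "axis") {
    stopifnot(length(spec) == 3, spec[1] > 0 || !log, spec[2] > spec[1],
              spec[3] >= 2)
    n <- as.integer(spec[3])
    if (log) 10^seq(log10(spec[1]), log10(spec[2]), length.out = n)
    else seq(spec[1], spec[2], length.out = n)
  }
  axes <- list(gain = ax(gain), peak_sf = ax(peak_sf),
               bandwidth = ax(bandwidth), truncation = ax(truncation, FALSE))
  nodes <- as.matrix(expand.grid(gain = axes$gain, peak_sf = axes$peak_sf,
                                 bandwidth = axes$bandwidth,
                                 truncation = axes$truncation,
                                 KEEP.OUT.ATTRS = FALSE))
  nodes_scaled <- cbind(log10(nodes[, 1:3, drop = FALSE]),
                        nodes[, 4, drop = FALSE])
  colnames(nodes_scaled) <- c("log_gain", "log_peak_sf", "log_bandwidth",
                              "truncation")
  structure(list(axes = axes, nodes = nodes, nodes_scaled = nodes_scaled,
                 n = nrow(nodes)), class = "param_grid")
}

# log10 sensitivity of every grid node at one frequency (vectorised over
# nodes; same algebra as log_sensitivity()).
node_log_sensitivity <- function(grid, f) {
  g <- grid$nodes
  lg <- log10(g[, "gain"])
  parab <- lg - log10(2) * (2 * log2(f / g[, "peak_sf"]) /
                              g[, "bandwidth"])^2
  low <- f < g[, "peak_sf"]
  parab[low] <- pmax(parab[low], (lg - g[, "truncation"])[low])
  parab
}

#' Candidate stimulus set for adaptive placement
#'
#' The experiment frequencies crossed with log-spaced contrasts, ordered by
#' frequency then contrast (the tie-break order of [select_stimulus()]).
#'
#' @param sf_grid An [make_sf_grid()] object.
#' @param n_contrasts Number of contrast levels.
#' @param c_min,c_max Contrast range.
#' @return Data frame with columns `sf`, `contrast`.
#' @export
make_candidates <- function(sf_grid, n_contrasts = 40, c_min = 0.001,
                            c_max = 1) {
  stopifnot(inherits(sf_grid, "sf_grid"), c_min > 0, c_max <= 1,
            c_min < c_max)
  contrasts <- 10^seq(log10(c_min), log10(c_max), length.out = n_contrasts)
  out <- expand.grid(contrast = contrasts, sf = sf_grid$values,
                     KEEP.OUT.ATTRS = FALSE)[, c("sf", "contrast")]
  rownames(out) <- NULL
  out
}

#' Precomputed likelihood tables for fast adaptive selection
#'
#' For a fixed parameter grid, psychometric function and candidate set,
#' the response likelihood of every (node, candidate) pair is fixed, so it
#' is computed once per measurement configuration.  Two matrices are
#' cached: the probability-correct matrix `L` and the combined entropy
#' kernel `L log2 L + (1-L) log2 (1-L)`, which reduce expected-entropy
#' stimulus scoring to two matrix-vector products per trial.
#'
#' @param grid A [param_grid()].
#' @param psy A [psy_config()].
#' @param candidates A candidate data frame from [make_candidates()].
#' @return An object of class `likelihood_tables`.
#' @export
likelihood_tables <- function(grid, psy, candidates) {
  sf_vals <- unique(candidates$sf)
  # node x unique-sf linear sensitivities
  S <- vapply(sf_vals, function(f) 10^node_log_sensitivity(grid, f),
              numeric(grid$n))
  sf_idx <- match(candidates$sf, sf_vals)
  span <- 1 - psy$guess_rate - psy$lapse_rate
  cs <- S[, sf_idx, drop = FALSE] *
    rep(candidates$contrast, each = grid$n)
  L <- psy$guess_rate + span * (1 - exp(-cs^psy$slope))
  structure(list(L = L, T = L * log2(L) + (1 - L) * log2(1 - L),
                 candidates = candidates, psy = psy, grid = grid),
            class = "likelihood_tables")
}

#' Initialise the posterior over the parameter grid
#'
#' @param grid A [param_grid()].
#' @param prior `"uniform"` (default) or `"lognormal"` for independent
#'   normal marginals on each axis's averaging scale.
#' @param prior_mean,prior_sd Named lists/vectors (log_gain, log_peak_sf,
#'   log_bandwidth, truncation) used when `prior = "lognormal"`.
#' @param mask Optional logical vector over nodes; `FALSE` nodes get zero
#'   prior mass.
#' @return An object of class `posterior_grid` with fields `grid` and `w`.
#' @export
init_posterior <- function(grid, prior = c("uniform", "lognormal"),
                           prior_mean = c(log_gain = 1.7, log_peak_sf = 0.3,
                                          log_bandwidth = 0.5,
                                          truncation = 0.5),
                           prior_sd = c(log_gain = 1, log_peak_sf = 0.5,
                                        log_bandwidth = 0.3,
                                        truncation = 0.5),
                           mask = NULL) {
  prior <- match.arg(prior)
  w <- rep(1, grid$n)
  if (prior == "lognormal") {
    ns <- grid$nodes_scaled
    for (k in colnames(ns))
      w <- w * stats::dnorm(ns[, k], prior_mean[[k]], prior_sd[[k]])
  }
  if (!is.null(mask)) {
    stopifnot(length(mask) == grid$n)
    w[!mask] <- 0
  }
  if (sum(w) <= 0) stop("prior has zero total mass")
  structure(list(grid = grid, w = w / sum(w)), class = "posterior_grid")
}

#' Shannon entropy of the posterior, in bits
#'
#' @param post A `posterior_grid`.
#' @return Entropy in bits.
#' @export
posterior_entropy <- function(post) {
  w <- post$w[post$w > 0]
  -sum(w * log2(w))
}

#' Bayes update of the posterior after one trial
#'
#' @param post A `posterior_grid`.
#' @param psy A [psy_config()].
#' @param stim The presented [stimulus_point()].
#' @param correct Logical response outcome.
#' @return The updated, renormalised `posterior_grid`.
#' @export
update_posterior <- function(post, psy, stim, correct) {
  S <- 10^node_log_sensitivity(post$grid, stim$sf)
  span <- 1 - psy$guess_rate - psy$lapse_rate
  p <- psy$guess_rate + span * (1 - exp(-(stim$contrast * S)^psy$slope))
  lik <- if (isTRUE(correct)) p else 1 - p
  w <- post$w * lik
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("posterior update produced zero total mass (likelihood underflow)")
  post$w <- w / tot
  post
}

#' Expected one-step-ahead posterior entropy of each candidate
#'
#' For candidate x with predictive probability correct
#' \eqn{\bar p = \sum_\theta w(\theta) \Psi(\theta, x)}, the score is
#' \eqn{\bar p H(post | correct) + (1 - \bar p) H(post | error)} in bits.
#' Computed via the identity
#' \eqn{E[H] = H(w) + \bar p \log_2 \bar p + \bar q \log_2 \bar q
#'       - w^\top (L \circ \log_2 L + (1-L) \circ \log_2 (1-L))},
#' which needs only the cached kernel of [likelihood_tables()].
#'
#' @param post A `posterior_grid`.
#' @param tables A [likelihood_tables()] built on the same grid.
#' @return Numeric vector of expected entropies, one per candidate.
#' @export
expected_entropy <- function(post, tables) {
  stopifnot(identical(dim(tables$L)[1], length(post$w)))
  w <- post$w
  pbar <- as.vector(crossprod(tables$L, w))
  b <- as.vector(crossprod(tables$T, w))
  qbar <- 1 - pbar
  xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)
  posterior_entropy(post) + xlog2x(pbar) + xlog2x(qbar) - b
}

#' Select the next stimulus by expected-entropy minimisation
#'
#' Returns the candidate minimising the expected posterior entropy after
#' the next response; ties are broken toward the lowest spatial frequency,
#' then the lowest contrast (the candidate ordering of
#' [make_candidates()]).  Orientation is not part of the criterion and is
#' assigned by the trial loop.
#'
#' @param post A `posterior_grid`.
#' @param tables A [likelihood_tables()].
#' @return A list with `index` into the candidate table, `sf`, `contrast`,
#'   and the score vector `expected_entropy`.
#' @export
select_stimulus <- function(post, tables) {
  if (nrow(tables$candidates) == 0) stop("empty candidate set")
  eh <- expected_entropy(post, tables)
  best <- min(eh)
  idx <- which(eh <= best + 1e-12 * max(1, abs(best)))[1]
  list(index = idx, sf = tables$candidates$sf[idx],
       contrast = tables$candidates$contrast[idx], expected_entropy = eh)
}

#' Posterior-mean parameter estimate
#'
#' Means are taken on each axis's natural scale — log10 for gain, peak
#' frequency and bandwidth, linear for truncation — then mapped back.
#'
#' @param post A `posterior_grid`.
#' @return A [csf_params()] object.
#' @export
estimate_from_posterior <- function(post) {
  m <- as.vector(crossprod(post$grid$nodes_scaled, post$w))
  names(m) <- colnames(post$grid$nodes_scaled)
  csf_params(gain = 10^m[["log_gain"]], peak_sf = 10^m[["log_peak_sf"]],
             bandwidth = 10^m[["log_bandwidth"]],
             truncation = m[["truncation"]])
}

# Fraction of posterior mass on the boundary planes of each axis.
edge_mass <- function(post) {
  g <- post$grid
  out <- c(gain = 0, peak_sf = 0, bandwidth = 0, truncation = 0)
  for (k in names(g$axes)) {
    v <- g$nodes[, k]
    ax <- g$axes[[k]]
    out[k] <- sum(post$w[v == ax[1] | v == ax[length(ax)]])
  }
  out
}

#' Engine configuration
#'
#' @param grid A [param_grid()].
#' @param psy A [psy_config()].
#' @param n_trials Number of adaptive trials (default 100).
#' @param n_practice Number of full-contrast practice trials preceding the
#'   adaptive run (default 5); recorded but excluded from the posterior.
#' @param n_contrasts Candidate contrast levels.
#' @param c_min,c_max Candidate contrast range.
#' @param edge_warn_frac Posterior mass on any axis boundary above which
#'   the final estimate is flagged.
#' @return A list of class `qcsf_config`.
#' @export
qcsf_config <- function(grid = param_grid(), psy = psy_config(),
                        n_trials = 100L, n_practice = 5L,
                        n_contrasts = 40L, c_min = 0.001, c_max = 1,
                        edge_warn_frac = 0.25) {
  structure(list(grid = grid, psy = psy, n_trials = as.integer(n_trials),
                 n_practice = as.integer(n_practice),
                 n_contrasts = as.integer(n_contrasts),
                 c_min = c_min, c_max = c_max,
                 edge_warn_frac = edge_warn_frac),
            class = "qcsf_config")
}

#' Run one adaptive CSF measurement
#'
#' Runs `n_practice` full-contrast practice trials (recorded, not used in
#' the posterior) followed by `n_trials` adaptive trials.  Each adaptive
#' trial selects the stimulus by [select_stimulus()], queries the
#' responder, and applies the Bayes update.  Fully deterministic given
#' `seed` and a deterministic responder.
#'
#' @param responder Function taking a [stimulus_point()] and returning a
#'   logical `correct`.
#' @param sf_grid An [make_sf_grid()] object.
#' @param config A [qcsf_config()].
#' @param polarity Stimulus polarity recorded on every trial.
#' @param seed Integer seed for the run's random stream (orientation draws
#'   and practice-frequency draws).
#' @param tables Optional precomputed [likelihood_tables()] for this
#'   (grid, psy, candidate) configuration; built on the fly if `NULL`.
#' @param seed_tag Bookkeeping string stored on every trial record.
#' @return A list of class `qcsf_run` with elements `estimate` (class
#'   `csf_estimate`) and `trials` (data frame, one row per trial).
#' @export
run_qcsf <- function(responder, sf_grid, config = qcsf_config(),
                     polarity = "balanced", seed = 1L, tables = NULL,
                     seed_tag = as.character(seed)) {
  stopifnot(is.function(responder), inherits(sf_grid, "sf_grid"))
  if (is.null(tables)) {
    candidates <- make_candidates(sf_grid, config$n_contrasts,
                                  config$c_min, config$c_max)
    tables <- likelihood_tables(config$grid, config$psy, candidates)
  }
  set.seed(as.integer(seed))
  post <- init_posterior(config$grid)
  n_tot <- config$n_practice + config$n_trials
  trials <- data.frame(
    trial_index = seq_len(n_tot), is_practice = rep(FALSE, n_tot),
    sf_cpd = NA_real_, contrast = NA_real_,
    polarity = polarity, orientation_true = NA_character_,
    orientation_resp = NA_character_, correct = NA,
    seed_tag = seed_tag, stringsAsFactors = FALSE)
  entropy_trace <- numeric(config$n_trials)
  oris <- c("horizontal", "vertical")

  do_trial <- function(i, sf, contrast, practice) {
    ori <- sample(oris, 1)
    stim <- stimulus_point(sf, contrast, polarity, ori)
    correct <- tryCatch(isTRUE(responder(stim)), error = function(e) {
      cnd <- simpleError(sprintf(
        "responder failed at trial %d (sf %.3g, contrast %.3g): %s",
        i, sf, contrast, conditionMessage(e)))
      cnd$partial_trials <- trials[seq_len(i - 1), ]
      stop(cnd)
    })
    trials$trial_index[i] <<- i
    trials$is_practice[i] <<- practice
    trials$sf_cpd[i] <<- sf
    trials$contrast[i] <<- contrast
    trials$orientation_true[i] <<- ori
    trials$orientation_resp[i] <<- if (correct) ori else setdiff(oris, ori)
    trials$correct[i] <<- correct
    stim
  }

  for (i in seq_len(config$n_practice)) {
    sf <- sample(sf_grid$values, 1)
    do_trial(i, sf, 1.0, TRUE)
  }
  for (t in seq_len(config$n_trials)) {
    sel <- select_stimulus(post, tables)
    i <- config$n_practice + t
    do_trial(i, sel$sf, sel$contrast, FALSE)
    lik_col <- tables$L[, sel$index]
    lik <- if (trials$correct[i]) lik_col else 1 - lik_col
    w <- post$w * lik
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0)
      stop("posterior update produced zero total mass at trial ", t)
    post$w <- w / tot
    entropy_trace[t] <- posterior_entropy(post)
  }

  params <- estimate_from_posterior(post)
  em <- edge_mass(post)
  cut <- cutoff_sf(params, f_max_search = max(64, 4 * sf_grid$f_max))
  estimate <- structure(list(
    params = params,
    aulcsf = aulcsf(params, sf_grid$f_min, sf_grid$f_max),
    cutoff_sf = cut$cutoff, cutoff_flag = cut$flag,
    grid_sensitivities = sensitivity(params, sf_grid$values),
    sf_values = sf_grid$values,
    posterior_entropy_trace = entropy_trace,
    n_trials = config$n_trials,
    edge_mass = em,
    edge_warning = any(em > config$edge_warn_frac),
    posterior = post), class = "csf_estimate")
  structure(list(estimate = estimate, trials = trials), class = "qcsf_run")
}

#' @export
print.csf_estimate <- function(x, ...) {
  print(x$params)
  cat(sprintf("AULCSF %.3f, cut-off %.2f c/deg (%s), %d trials%s\n",
              x$aulcsf, x$cutoff_sf, x$cutoff_flag, x$n_trials,
              if (x$edge_warning) " [edge warning]" else ""))
  invisible(x)
}
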