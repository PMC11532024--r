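# Shared fixtures: built in code, small enough for fast unit tests.

std_params <- function() csf_params(gain = 100, peak_sf = 2, bandwidth = 4,
                                    truncation = 0.5)

amblyope_grid <- function() make_sf_grid(0.31, 11.77, 12)

# Tiny posterior grid (36 nodes) for exactness-oriented engine tests.
tiny_param_grid <- function() {
  param_grid(gain = c(5, 500, 3), peak_sf = c(0.5, 8, 3),
             bandwidth = c(2, 6, 2), truncation = c(0.1, 1, 2))
}

tiny_engine_config <- function(n_trials = 10L, n_practice = 2L) {
  qcsf_config(grid = tiny_param_grid(), n_trials = n_trials,
              n_practice = n_practice, n_contrasts = 8L, c_min = 0.005)
}

# Brute-force expected posterior entropy: direct enumeration over both
# outcomes per candidate, independent of the cached-kernel identity used
# by the package.
brute_expected_entropy <- function(post, psy, candidates) {
  ent <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
  vapply(seq_len(nrow(candidates)), function(j) {
    stim <- list(sf = candidates$sf[j], contrast = candidates$contrast[j])
    p <- vapply(seq_len(post$grid$n), function(i) {
      nd <- post$grid$nodes[i, ]
      p_correct(csf_params(nd[["gain"]], nd[["peak_sf"]],
                           nd[["bandwidth"]], nd[["truncation"]]),
                psy, stim)
    }, numeric(1))
    pbar <- sum(post$w * p)
    wc <- post$w * p / pbar
    we <- post$w * (1 - p) / (1 - pbar)
    pbar * ent(wc) + (1 - pbar) * ent(we)
  }, numeric(1))
}

# Exact two-sided signed-rank p value by enumeration of all 2^n sign
# assignments (no zeros assumed; average ranks for ties).
exact_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu_w <- n * (n + 1) / 4
  mean(abs(w_all - mu_w) >= abs(w_obs - mu_w) - 1e-9)
}

# Simulated deterministic-stream responder for a known CSF.
make_responder <- function(params, psy = psy_config()) {
  function(stim) stats::runif(1) < p_correct(params, psy, stim)
}
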