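test_that("psychometric function hits its floor, threshold and ceiling", {
  p <- std_params()
  psy <- psy_config()
  # guess floor as contrast -> 0
  expect_equal(p_correct(p, psy, list(sf = 2, contrast = 1e-9)), 0.5,
               tolerance = 1e-6)
  # at threshold contrast c*S = 1: 0.5 + 0.46 (1 - e^-1)
  expect_equal(p_correct(p, psy, list(sf = 2, contrast = 0.01)),
               0.5 + 0.46 * (1 - exp(-1)), tolerance = 1e-12)
  # lapse ceiling
  expect_equal(p_correct(p, psy, list(sf = 2, contrast = 1)), 0.96,
               tolerance = 1e-3)
  # increasing in contrast (strictly until double-precision saturation
  # at the lapse ceiling)
  cs <- 10^seq(-3, 0, length.out = 30)
  ps <- vapply(cs, function(cc)
    p_correct(p, psy, list(sf = 2, contrast = cc)), numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_true(all(diff(ps[ps < 0.96 - 1e-9]) > 0))
  expect_error(psy_config(guess_rate = 0.7, lapse_rate = 0.4))
})

test_that("posterior initialisation is normalised, uniform and maskable", {
  grid <- tiny_param_grid()
  post <- init_posterior(grid)
  expect_equal(sum(post$w), 1, tolerance = 1e-12)
  expect_equal(post$w, rep(1 / grid$n, grid$n))
  expect_equal(posterior_entropy(post), log2(grid$n))
  mask <- rep(FALSE, grid$n); mask[c(3, 7, 20)] <- TRUE
  pm <- init_posterior(grid, mask = mask)
  expect_equal(sort(unique(pm$w)), c(0, 1 / 3))
  expect_equal(sum(pm$w > 0), 3)
  expect_error(init_posterior(grid, mask = rep(FALSE, grid$n)),
               "zero total mass|zero")
})

test_that("Bayes updating renormalises and reproduces the 2-node example", {
  grid <- tiny_param_grid()
  psy <- psy_config()
  post <- init_posterior(grid)
  stim <- stimulus_point(2, 0.05)
  for (k in 1:6) {
    post <- update_posterior(post, psy, stim, correct = (k %% 2 == 0))
    expect_true(all(post$w >= 0))
    expect_equal(sum(post$w), 1, tolerance = 1e-12)
  }
  # near-flat likelihood (contrast far below every node's threshold)
  # leaves the posterior essentially unchanged
  flat <- init_posterior(grid)
  flat2 <- update_posterior(flat, psy, stimulus_point(2, 1e-9), TRUE)
  expect_equal(flat2$w, flat$w, tolerance = 1e-9)
  # 2-node hand example: prior (.5, .5), likelihoods (.9, .5), correct:
  # posterior = (.45, .25)/.7 = (9/14, 5/14)
  # node A: sensitivity 2.85430... at 20 c/deg -> p = 0.9 exactly;
  # node B: negligible sensitivity at 20 c/deg -> p = 0.5 to 1e-12
  sA <- (-log(1 - 0.4 / 0.46))^(1 / 2) / 0.5   # contrast 0.5 at threshold
  g2 <- param_grid(gain = c(2, sA, 2), peak_sf = c(0.2, 20, 2),
                   bandwidth = c(1, 4, 2), truncation = c(2, 2.0001, 2))
  want <- function(gain, pk, bw) {
    abs(g2$nodes[, "gain"] - gain) < 1e-9 &
      abs(g2$nodes[, "peak_sf"] - pk) < 1e-9 &
      abs(g2$nodes[, "bandwidth"] - bw) < 1e-9 &
      abs(g2$nodes[, "truncation"] - 2) < 1e-9
  }
  mask <- want(sA, 20, 4) | want(2, 0.2, 1)
  expect_equal(sum(mask), 2)
  post2 <- init_posterior(g2, mask = mask)
  post2 <- update_posterior(post2, psy_config(), stimulus_point(20, 0.5),
                            correct = TRUE)
  got <- post2$w[mask]
  iA <- which(abs(g2$nodes[mask, "gain"] - sA) < 1e-9)
  expect_equal(got[iA], 9 / 14, tolerance = 1e-4)
  expect_equal(got[-iA], 5 / 14, tolerance = 1e-4)
})

test_that("sequential updates equal the batched product-likelihood update", {
  grid <- tiny_param_grid()
  psy <- psy_config()
  stims <- list(stimulus_point(1, 0.02), stimulus_point(4, 0.3),
                stimulus_point(0.5, 0.08))
  outcomes <- c(TRUE, FALSE, TRUE)
  seq_post <- init_posterior(grid)
  for (i in seq_along(stims))
    seq_post <- update_posterior(seq_post, psy, stims[[i]], outcomes[i])
  lik <- rep(1, grid$n)
  for (i in seq_along(stims)) {
    p <- vapply(seq_len(grid$n), function(j) {
      nd <- grid$nodes[j, ]
      p_correct(csf_params(nd[["gain"]], nd[["peak_sf"]], nd[["bandwidth"]],
                           nd[["truncation"]]), psy, stims[[i]])
    }, numeric(1))
    lik <- lik * if (outcomes[i]) p else 1 - p
  }
  expect_equal(seq_post$w, lik / sum(lik), tolerance = 1e-12)
})

test_that("stimulus selection equals brute-force entropy minimisation", {
  grid <- tiny_param_grid()
  psy <- psy_config()
  g <- make_sf_grid(0.5, 8, 4)
  cand <- make_candidates(g, n_contrasts = 5, c_min = 0.01)
  tables <- likelihood_tables(grid, psy, cand)
  set.seed(7)
  for (rep_i in 1:5) {
    post <- init_posterior(grid)
    w <- rgamma(grid$n, 1); post$w <- w / sum(w)
    eh <- expected_entropy(post, tables)
    brute <- brute_expected_entropy(post, psy, cand)
    expect_equal(eh, brute, tolerance = 1e-9)
    sel <- select_stimulus(post, tables)
    expect_equal(sel$index, which.min(brute))
  }
})

test_that("degenerate and uninformative candidates behave correctly", {
  grid <- tiny_param_grid()
  psy <- psy_config()
  g <- make_sf_grid(0.5, 8, 4)
  cand <- make_candidates(g, n_contrasts = 5, c_min = 0.01)
  tables <- likelihood_tables(grid, psy, cand)
  # point-mass posterior: all expected entropies 0; tie-break returns the
  # lowest-sf, lowest-contrast candidate
  post <- init_posterior(grid)
  post$w <- rep(0, grid$n); post$w[14] <- 1
  sel <- select_stimulus(post, tables)
  expect_equal(max(abs(sel$expected_entropy)), 0, tolerance = 1e-9)
  expect_equal(sel$index, 1L)
  expect_equal(sel$sf, min(cand$sf))
  expect_equal(sel$contrast, min(cand$contrast))
  # a fully predictable candidate is never strictly preferred over one
  # with positive expected information: 2-node posterior where candidate 1
  # has p = (0.5, 0.5) (predictable mixture-free) vs informative others
  post2 <- init_posterior(grid)
  keep <- c(1L, grid$n)
  post2$w <- rep(0, grid$n); post2$w[keep] <- 0.5
  eh2 <- expected_entropy(post2, tables)
  pc <- crossprod(tables$L, post2$w)
  predictable <- abs(pc - 0.5) < 1e-6 | pc > 1 - 1e-6
  if (any(predictable) && any(!predictable)) {
    expect_gte(min(eh2[predictable]), min(eh2[!predictable]) - 1e-9)
  }
})

test_that("posterior-mean estimate matches direct summation and symmetry", {
  grid <- tiny_param_grid()
  post <- init_posterior(grid)
  # point mass recovers the node exactly
  post$w <- rep(0, grid$n); post$w[9] <- 1
  est <- estimate_from_posterior(post)
  expect_equal(est$gain, unname(grid$nodes[9, "gain"]), tolerance = 1e-12)
  expect_equal(est$peak_sf, unname(grid$nodes[9, "peak_sf"]),
               tolerance = 1e-12)
  # symmetric mass on log-gain +/- 0.3 about 2.0
  gsym <- param_grid(gain = c(10^1.7, 10^2.3, 2), peak_sf = c(2, 2.0001, 2),
                     bandwidth = c(4, 4.0001, 2),
                     truncation = c(0.5, 0.50001, 2))
  psym <- init_posterior(gsym)
  psym$w <- rep(0, gsym$n)
  psym$w[abs(gsym$nodes[, "peak_sf"] - 2) < 1e-9 &
           abs(gsym$nodes[, "bandwidth"] - 4) < 1e-9 &
           abs(gsym$nodes[, "truncation"] - 0.5) < 1e-9] <- 0.5
  est2 <- estimate_from_posterior(psym)
  expect_equal(log10(est2$gain), 2, tolerance = 1e-9)
  # random posterior matches brute-force weighted mean
  set.seed(3)
  w <- rgamma(grid$n, 1)
  post$w <- w / sum(w)
  est3 <- estimate_from_posterior(post)
  expect_equal(log10(est3$gain),
               sum(post$w * log10(grid$nodes[, "gain"])), tolerance = 1e-12)
  expect_equal(est3$truncation,
               sum(post$w * grid$nodes[, "truncation"]), tolerance = 1e-12)
})

test_that("the trial loop runs 5 practice + 100 adaptive trials and is
           deterministic", {
  g <- amblyope_grid()
  cfg <- tiny_engine_config(n_trials = 15L, n_practice = 5L)
  responder <- make_responder(std_params())
  r1 <- run_qcsf(responder, g, cfg, seed = 11)
  expect_equal(nrow(r1$trials), 20)
  expect_equal(sum(r1$trials$is_practice), 5)
  expect_true(all(r1$trials$contrast[r1$trials$is_practice] == 1))
  expect_equal(length(r1$estimate$posterior_entropy_trace), 15)
  expect_identical(r1$trials$correct,
                   r1$trials$orientation_true == r1$trials$orientation_resp)
  r2 <- run_qcsf(make_responder(std_params()), g, cfg, seed = 11)
  expect_identical(r1$trials, r2$trials)
  r3 <- run_qcsf(make_responder(std_params()), g, cfg, seed = 12)
  expect_false(identical(r1$trials, r3$trials))
})

test_that("posterior concentrates: mean entropy declines and estimates
           sharpen from 25 to 100 trials", {
  # shared 20-seed parameter-recovery batch at the default grid; the
  # simulated observer sits away from the prior anchors so improvement
  # with trial count reflects accumulated information, not the prior
  rb <- recovery_batch()
  # gain recovery precision after 100 trials
  expect_lt(median(rb$e100[, "gain"]), 0.15)
  # all four parameters improve in median from 25 to 100 trials
  expect_true(all(apply(rb$e100, 2, median) < apply(rb$e25, 2, median)))
  # mean posterior entropy over the batch declines monotonically at
  # 10-trial block granularity (per-trial means still fluctuate when a
  # surprising response transiently raises entropy)
  m <- colMeans(rb$traces)
  blocks <- tapply(m, rep(1:10, each = 10), mean)
  expect_true(all(diff(blocks) < 0))
  expect_lt(m[100], m[10])
})

test_that("a failing responder aborts with trial context and the partial
           log preserved", {
  g <- amblyope_grid()
  cfg <- tiny_engine_config(n_trials = 10L, n_practice = 2L)
  n_ok <- 0
  responder <- function(stim) {
    if (n_ok >= 5) stop("button box unplugged")
    n_ok <<- n_ok + 1
    TRUE
  }
  err <- tryCatch(run_qcsf(responder, g, cfg, seed = 3),
                  error = function(e) e)
  expect_match(conditionMessage(err), "responder failed at trial 6")
  expect_s3_class(err$partial_trials, "data.frame")
  expect_equal(nrow(err$partial_trials), 5)
  expect_true(all(err$partial_trials$correct[1:5]))
})
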