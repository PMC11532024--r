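test_that("paired t test matches hand computation and is antisymmetric", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2, 4, 5, 6)
  r <- paired_t(x, y)
  # d = (-1, 0, -1, -1, -1): mean -0.8, sd 0.4472, t = -4, df = 4
  expect_equal(r$statistic, -4, tolerance = 1e-12)
  expect_equal(r$df1, 4)
  expect_equal(r$p, 2 * pt(-4, 4), tolerance = 1e-12)
  expect_equal(r$effect_size, -4 / sqrt(5), tolerance = 1e-12)
  expect_equal(paired_t(y, x)$statistic, 4, tolerance = 1e-12)
  # identical samples are degenerate, not an error
  rz <- paired_t(x, x)
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p, 1)
  expect_match(rz$note, "degenerate")
})

test_that("signed-rank Z agrees with exact enumeration and wilcox.test", {
  set.seed(10)
  for (n in c(6, 8, 10)) {
    for (rep_i in 1:4) {
      x <- 1 + round(rnorm(n, 0.1, 0.3), 2)
      x <- x[x != 1]
      if (length(x) < 5) next
      r <- wilcoxon_vs_const(x, 1)
      p_exact <- exact_signed_rank_p(x, 1)
      expect_equal(r$p, p_exact, tolerance = 1e-9)
    }
  }
  # above the exact-enumeration range the normal approximation is used:
  # cross-check against the reference implementation
  set.seed(11)
  x12 <- 1 + rnorm(12, 0.1, 0.3)
  wt <- suppressWarnings(stats::wilcox.test(x12, mu = 1, exact = FALSE,
                                            correct = FALSE))
  expect_equal(wilcoxon_vs_const(x12, 1)$p, wt$p.value, tolerance = 1e-9)
  # symmetric sample: W+ = W- so Z = 0 (mu = 0 keeps differences exact)
  r0 <- wilcoxon_vs_const(c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3), 0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  # maximal statistic: all 11 values above 1, no ties
  rmax <- wilcoxon_vs_const(1 + (1:11) / 100, 1)
  expect_equal(rmax$statistic, 33 / sqrt(11 * 12 * 23 / 24),
               tolerance = 1e-12)
  expect_equal(rmax$statistic, 2.934, tolerance = 1e-3)
  expect_lt(abs(rmax$p - 0.003), 5e-4)
  # zeros dropped per convention
  expect_equal(wilcoxon_vs_const(c(1, 1 + (1:11) / 100), 1)$statistic,
               rmax$statistic, tolerance = 1e-12)
  expect_error(wilcoxon_vs_const(c(1.1, 1.2, 1.3, 1.4), 1), "at least 5")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_corr(x, 2 * x + 3)$statistic, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$statistic, -1, tolerance = 1e-12)
  set.seed(4)
  y <- rnorm(5)
  r <- pearson_corr(x, y)
  # direct-formula oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$statistic, r_direct, tolerance = 1e-12)
  expect_match(pearson_corr(rep(1, 5), y)$note, "degenerate")
})

test_that("RM-ANOVA reduces to the paired t for 2-level factors", {
  set.seed(5)
  d <- expand.grid(s = factor(1:9), f = c("lo", "hi"))
  d$y <- rnorm(18) + (d$f == "hi") * 0.4
  a <- rm_anova(d, "y", "s", "f")
  tt <- paired_t(d$y[d$f == "lo"], d$y[d$f == "hi"])
  expect_equal(a$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p, tolerance = 1e-9)
  expect_match(a$note, "epsilon=1 ")   # GG epsilon exactly 1 at 2 levels
  expect_equal(a$df1, 1)
  expect_equal(a$df2, 8)
})

test_that("RM-ANOVA decomposition matches a direct sums-of-squares oracle
           on a two-factor toy design", {
  set.seed(6)
  ns <- 7
  d <- expand.grid(s = factor(1:ns), A = factor(c("a1", "a2", "a3")),
                   B = factor(c("b1", "b2", "b3")))
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) * 0.3 +
    as.numeric(d$A) * as.numeric(d$B) * 0.1
  a <- rm_anova(d, "y", "s", c("A", "B"), gg = FALSE)
  # brute-force within-subject SS from cell means
  grand <- mean(d$y)
  sm <- tapply(d$y, d$s, mean)
  am <- tapply(d$y, d$A, mean); bm <- tapply(d$y, d$B, mean)
  abm <- tapply(d$y, list(d$A, d$B), mean)
  sam <- tapply(d$y, list(d$s, d$A), mean)
  sbm <- tapply(d$y, list(d$s, d$B), mean)
  ss_a <- ns * 3 * sum((am - grand)^2)
  ss_b <- ns * 3 * sum((bm - grand)^2)
  ss_ab <- ns * sum((abm - outer(am, rep(1, 3)) -
                       outer(rep(1, 3), bm) + grand)^2)
  ss_sa <- 3 * sum((sam - outer(sm, rep(1, 3)) -
                      outer(rep(1, ns), am) + grand)^2)
  ss_sb <- 3 * sum((sbm - outer(sm, rep(1, 3)) -
                      outer(rep(1, ns), bm) + grand)^2)
  get <- function(term, what) {
    row <- a[a$term == term, ]
    ss <- as.numeric(sub(".*SS_eff=([0-9.eE+-]+) .*", "\\1", row$note))
    se <- as.numeric(sub(".*SS_err=([0-9.eE+-]+)", "\\1", row$note))
    if (what == "eff") ss else se
  }
  # the note carries 6 significant digits
  expect_equal(get("A", "eff"), ss_a, tolerance = 1e-4)
  expect_equal(get("B", "eff"), ss_b, tolerance = 1e-4)
  expect_equal(get("A:B", "eff"), ss_ab, tolerance = 1e-4)
  expect_equal(get("A", "err"), ss_sa, tolerance = 1e-4)
  expect_equal(get("B", "err"), ss_sb, tolerance = 1e-4)
  # partial eta squared definition
  rowA <- a[a$term == "A", ]
  expect_equal(rowA$effect_size, ss_a / (ss_a + ss_sa), tolerance = 1e-9)
})

test_that("Greenhouse-Geisser epsilon and corrected p match car::Anova", {
  skip_if_not_installed("car")
  set.seed(7)
  d <- expand.grid(s = factor(1:10), A = factor(c("a1", "a2")),
                   B = factor(c("b1", "b2", "b3")))
  d$y <- rnorm(60) + as.numeric(d$B) * 0.3
  a <- rm_anova(d, "y", "s", c("A", "B"))
  m <- tapply(d$y, list(d$s, d$A, d$B), mean)
  Y <- matrix(m, nrow = 10)
  idata <- expand.grid(A = factor(c("a1", "a2")),
                       B = factor(c("b1", "b2", "b3")))
  av <- car::Anova(stats::lm(Y ~ 1), idata = idata, idesign = ~ A * B,
                   type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  gg <- s$pval.adjustments
  eps <- function(term) as.numeric(sub(".*epsilon=([0-9.eE+-]+) .*", "\\1",
                                       a$note[a$term == term]))
  expect_equal(eps("B"), unname(gg["B", "GG eps"]), tolerance = 1e-6)
  expect_equal(eps("A:B"), unname(gg["A:B", "GG eps"]), tolerance = 1e-6)
  expect_equal(a$p[a$term == "B"], unname(gg["B", "Pr(>F[GG])"]),
               tolerance = 1e-6)
  expect_equal(a$p[a$term == "A:B"], unname(gg["A:B", "Pr(>F[GG])"]),
               tolerance = 1e-6)
  ut <- s$univariate.tests
  expect_equal(a$statistic[a$term == "A"], unname(ut["A", "F value"]),
               tolerance = 1e-9)
})

test_that("RM-ANOVA rejects incomplete designs", {
  d <- expand.grid(s = factor(1:4), f = c("x", "y"))
  d$y <- rnorm(8)
  expect_error(rm_anova(d[-1, ], "y", "s", "f"), "complete")
})

test_that("Bonferroni pairwise comparisons multiply p by the number of
           pairs and cap at 1", {
  set.seed(8)
  d <- expand.grid(s = factor(1:8), f = c("a", "b", "c"))
  d$y <- rnorm(24)
  pw <- pairwise_bonferroni(d, "y", "s", "f")
  expect_equal(nrow(pw), 3)
  raw_ab <- paired_t(d$y[d$f == "a"], d$y[d$f == "b"])$p
  expect_equal(pw$p[pw$term == "a vs b"], min(1, raw_ab * 3),
               tolerance = 1e-12)
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  expect_true(all(pw$correction == "bonferroni"))
})

test_that("Huynh-Feldt option matches the reference epsilon", {
  skip_if_not_installed("car")
  set.seed(9)
  d <- expand.grid(s = factor(1:12), B = factor(c("b1", "b2", "b3", "b4")))
  # per-subject random slopes violate sphericity, so HF != GG != 1
  slope <- rnorm(12)[as.integer(d$s)]
  d$y <- slope * as.numeric(d$B) + rnorm(48, 0, 0.4)
  a <- rm_anova(d, "y", "s", "B", sphericity = "huynh-feldt")
  m <- tapply(d$y, list(d$s, d$B), mean)
  av <- car::Anova(stats::lm(matrix(m, nrow = 12) ~ 1),
                   idata = data.frame(B = factor(c("b1", "b2", "b3", "b4"))),
                   idesign = ~ B, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  hf <- min(unname(s$pval.adjustments["B", "HF eps"]), 1)
  eps <- as.numeric(sub(".*epsilon=([0-9.eE+-]+) .*", "\\1", a$note))
  expect_equal(eps, hf, tolerance = 1e-5)
  expect_equal(a$p, unname(s$pval.adjustments["B", "Pr(>F[HF])"]),
               tolerance = 1e-6)
  expect_lt(eps, 1)
  expect_equal(a$correction, "huynh-feldt")
})
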