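#' Statistical test report row
#'
#' All tests in the package return a one-row data frame with a common
#' schema: `test`, `term`, `statistic`, `df1`, `df2`, `p`, `effect_size`,
#' `effect_type`, `correction`, `note`.
#'
#' @name stats_report
NULL

stats_row <- function(test, term, statistic, df1 = NA_real_,
                      df2 = NA_real_, p = NA_real_,
                      effect_size = NA_real_, effect_type = NA_character_,
                      correction = "none", note = "") {
  data.frame(test = test, term = term, statistic = statistic,
             df1 = df1, df2 = df2, p = p, effect_size = effect_size,
             effect_type = effect_type, correction = correction,
             note = note, stringsAsFactors = FALSE)
}

#' Paired-samples t test
#'
#' Two-sided paired t test with both Cohen's d conventions reported:
#' `d_z = t / sqrt(n)` (standardised mean difference of the pairs) in
#' `effect_size`, and the mean difference divided by the pooled SD of the
#' two samples in `note` (`d_pooled`).
#'
#' @param x,y Paired numeric vectors of equal length `n >= 3`.
#' @return A one-row stats report data frame.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0)
    return(stats_row("paired_t", "x - y", 0, df1 = n - 1, p = 1,
                     effect_size = 0, effect_type = "cohen_dz",
                     note = "degenerate: zero variance of differences"))
  tt <- stats::t.test(x, y, paired = TRUE)
  dz <- unname(tt$statistic) / sqrt(n)
  d_pooled <- mean(d) / sqrt((stats::var(x) + stats::var(y)) / 2)
  stats_row("paired_t", "x - y", unname(tt$statistic),
            df1 = unname(tt$parameter), p = tt$p.value,
            effect_size = dz, effect_type = "cohen_dz",
            note = sprintf("d_pooled=%.6g", d_pooled))
}

#' Wilcoxon signed-rank test against a constant
#'
#' One-sample signed-rank test of `x` against `mu`.  Zeros (exact ties
#' with `mu`) are dropped and tied absolute differences get average ranks.
#' The Z statistic always uses the normal approximation with
#' tie-corrected variance and no continuity correction.  The two-sided p
#' value is exact (full enumeration of the 2^n sign assignments of the
#' observed ranks) for `n <= exact_max`, and the normal-approximation p
#' beyond that.
#'
#' @param x Numeric vector (`n >= 5` after zero removal).
#' @param mu Null value (default 1, the unity inc/dec ratio).
#' @param exact_max Largest n for which the exact enumeration p is used.
#' @return A one-row stats report data frame; `statistic` is Z (positive
#'   when `x` tends above `mu`); `note` carries the signed-rank sum `W+`.
#' @export
wilcoxon_vs_const <- function(x, mu = 1.0, exact_max = 10L) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu_w <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(stats_row("wilcoxon_vs_const", sprintf("x vs %g", mu), 0,
                     p = 1, note = "degenerate: all values tied"))
  z <- (w_plus - mu_w) / sqrt(sigma2)
  if (n <= exact_max) {
    # exact null distribution of W+ over all sign assignments of the
    # observed (possibly tied) ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n),
                                   KEEP.OUT.ATTRS = FALSE))
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - mu_w) >= abs(w_plus - mu_w) - 1e-9)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  stats_row("wilcoxon_vs_const", sprintf("x vs %g", mu), z, p = p,
            effect_size = z / sqrt(n), effect_type = "r",
            note = sprintf("W+=%g n=%d p_method=%s", w_plus, n, method))
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return A one-row stats report data frame (`statistic` is r).
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(stats_row("pearson_corr", "x, y", NA_real_, p = NA_real_,
                     note = "degenerate: zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  stats_row("pearson_corr", "x, y", unname(ct$estimate),
            df1 = unname(ct$parameter), p = ct$p.value,
            effect_size = unname(ct$estimate), effect_type = "r")
}

# Orthonormal contrast basis for a k-level within factor (k x (k-1)).
contrast_basis <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Repeated-measures ANOVA (fully within-subject, up to three factors)
#'
#' Classical univariate within-subject decomposition: each effect is
#' tested against its own subject-by-effect interaction stratum.  For any
#' effect involving a factor with more than two levels, the
#' Greenhouse-Geisser epsilon is estimated from the covariance of the
#' subject scores on the effect's orthonormal contrasts and applied to
#' both degrees of freedom (a 2-level effect has epsilon exactly 1).
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector (1-3) of within-subject factor columns.
#' @param sphericity Sphericity correction: `"greenhouse-geisser"`
#'   (default), `"huynh-feldt"`, or `"none"`; applied to every effect
#'   with more than one numerator degree of freedom.
#' @param gg Deprecated shorthand: `gg = FALSE` is `sphericity = "none"`.
#' @return A stats report data frame, one row per effect; `df1`/`df2` are
#'   the (possibly fractional) corrected degrees of freedom.
#' @export
rm_anova <- function(data, dv, subject, within,
                     sphericity = c("greenhouse-geisser", "huynh-feldt",
                                    "none"),
                     gg = TRUE) {
  sphericity <- match.arg(sphericity)
  if (!gg) sphericity <- "none"
  stopifnot(length(within) >= 1, length(within) <= 3)
  data <- data[, c(subject, within, dv)]
  names(data) <- c(".subj", paste0(".f", seq_along(within)), ".y")
  fvars <- paste0(".f", seq_along(within))
  for (v in c(".subj", fvars)) data[[v]] <- factor(data[[v]])
  if (anyNA(data$.y)) stop("missing responses in the design")
  # completeness check
  counts <- table(data[c(".subj", fvars)])
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    stop("design not complete/balanced; first offending cell: ",
         paste(dimnames(counts)[[1]][bad[1, 1]], collapse = ","))
  }
  levs <- lapply(data[fvars], levels)
  ks <- vapply(levs, length, integer(1))
  subs <- levels(data$.subj)
  n <- length(subs)
  # subject x cell matrix, cells in expand.grid order of the factors
  cells <- do.call(expand.grid, c(levs, KEEP.OUT.ATTRS = FALSE))
  key <- do.call(paste, c(data[fvars], sep = "\r"))
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  Y <- matrix(NA_real_, n, nrow(cells))
  for (i in seq_len(nrow(data))) {
    Y[match(data$.subj[i], subs), match(key[i], cell_key)] <- data$.y[i]
  }
  out <- list()
  effects <- unlist(lapply(seq_along(within), function(ord)
    utils::combn(seq_along(within), ord, simplify = FALSE)),
    recursive = FALSE)
  for (ef in effects) {
    # Kronecker contrast matrix over cells (expand.grid varies factor 1
    # fastest, so kron runs from the last factor down)
    M <- matrix(1, 1, 1)
    for (j in rev(seq_along(within))) {
      Mj <- if (j %in% ef) contrast_basis(ks[j])
            else matrix(1 / sqrt(ks[j]), ks[j], 1)
      M <- M %x% Mj
    }
    scores <- Y %*% M                       # n x d effect scores
    d <- ncol(scores)
    mbar <- colMeans(scores)
    ss_eff <- n * sum(mbar^2)
    ss_err <- sum(sweep(scores, 2, mbar)^2)
    df1 <- d
    df2 <- d * (n - 1)
    eps <- 1
    if (sphericity != "none" && d > 1) {
      S <- stats::cov(scores)
      eps <- sum(diag(S))^2 / (d * sum(S * S))
      eps <- min(max(eps, 1 / d), 1)
      if (sphericity == "huynh-feldt") {
        eps <- (n * d * eps - 2) / (d * (n - 1 - d * eps))
        eps <- min(max(eps, 1 / d), 1)
      }
    }
    Fval <- (ss_eff / df1) / (ss_err / df2)
    p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    out[[length(out) + 1L]] <- stats_row(
      "rm_anova", paste(within[ef], collapse = ":"), Fval,
      df1 = df1 * eps, df2 = df2 * eps, p = p,
      effect_size = ss_eff / (ss_eff + ss_err),
      effect_type = "partial_eta_sq",
      correction = if (sphericity != "none" && d > 1) sphericity
                   else "none",
      note = sprintf("epsilon=%.6g SS_eff=%.6g SS_err=%.6g", eps,
                     ss_eff, ss_err))
  }
  do.call(rbind, out)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t tests between all level pairs of `factor_col`, collapsing the
#' response over remaining cells by subject mean; p values multiplied by
#' the number of comparisons (capped at 1).
#'
#' @param data Long-format data frame.
#' @param dv,subject,factor_col Column names.
#' @return Stats report data frame, one row per pair.
#' @export
pairwise_bonferroni <- function(data, dv, subject, factor_col) {
  agg <- stats::aggregate(data[[dv]],
                          list(s = data[[subject]], f = data[[factor_col]]),
                          mean)
  levs <- unique(agg$f)
  pairs <- utils::combn(as.character(levs), 2, simplify = FALSE)
  m <- length(pairs)
  out <- lapply(pairs, function(pr) {
    x <- agg$x[agg$f == pr[1]][order(agg$s[agg$f == pr[1]])]
    y <- agg$x[agg$f == pr[2]][order(agg$s[agg$f == pr[2]])]
    row <- paired_t(x, y)
    row$term <- paste(pr, collapse = " vs ")
    row$p <- min(1, row$p * m)
    row$correction <- "bonferroni"
    row
  })
  do.call(rbind, out)
}

#' Increment/decrement sensitivity ratio table
#'
#' Per subject and eye, the ratio of increment to decrement linear
#' sensitivity at each grid frequency inside the analysis window.  With
#' `window = "printed"` the per-group windows are fixed at 0.31-2.25 c/deg
#' (amblyopes) and 0.31-11.96 c/deg (controls), the ranges over which
#' thresholds stay below full contrast; `window = "auto"` keeps the
#' frequencies where both group-mean increment and decrement thresholds
#' are below 1.
#'
#' @param dataset A `study_dataset` from [generate_study()].
#' @param window `"printed"` or `"auto"`.
#' @return A long data frame of class `ratio_table` with columns
#'   `subject_id`, `group`, `eye`, `sf`, `sf_label`, `ratio`, plus the
#'   window bounds as attributes.
#' @export
inc_dec_ratio <- function(dataset, window = c("printed", "auto")) {
  window <- match.arg(window)
  est <- dataset$estimates
  out <- list()
  for (grp in unique(est$group)) {
    grid <- dataset$cohort$sf_grids[[grp]]
    sens_cols <- sprintf("log_sens_%02d", seq_len(grid$n_levels))
    ge <- est[est$group == grp, ]
    if (window == "printed") {
      upper <- if (grp == "amblyope") 2.25 else 11.96
      keep <- floor(grid$values * 100 + 1e-9) / 100 <= upper + 1e-9
    } else {
      keep <- rep(TRUE, grid$n_levels)
      for (cond in c("increment", "decrement")) {
        ml <- colMeans(as.matrix(ge[ge$condition == cond, sens_cols]))
        keep <- keep & (ml > 0)   # mean log10 sensitivity > 0: threshold < 1
      }
    }
    for (sid in unique(ge$subject_id)) for (eye in c("affected", "better")) {
      inc <- ge[ge$subject_id == sid & ge$eye == eye &
                  ge$condition == "increment", sens_cols]
      dec <- ge[ge$subject_id == sid & ge$eye == eye &
                  ge$condition == "decrement", sens_cols]
      if (nrow(inc) != 1 || nrow(dec) != 1)
        stop("missing increment/decrement estimate for ", sid, "/", eye)
      ratio <- 10^(as.numeric(inc) - as.numeric(dec))
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = grp, eye = eye,
        sf = grid$values[keep], sf_label = format_sf(grid$values[keep]),
        ratio = ratio[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("ratio_table", class(res))
  attr(res, "window") <- window
  res
}

#' Cohort-level ratio summaries (geometric means)
#'
#' Sensitivity ratios are log-symmetric: estimation noise on log
#' sensitivity makes the arithmetic mean of per-subject ratios biased
#' upward by the lognormal correction factor, so cohort-level ratio
#' curves are summarised by geometric means (unbiased on the log scale
#' and consistent with the median-based signed-rank test).
#'
#' @param ratio_table A [inc_dec_ratio()] result.
#' @return A data frame with per (group, eye, sf) geometric mean ratios,
#'   plus one row per (group, eye) with `sf = NA` giving the geometric
#'   mean over the whole window.
#' @export
ratio_geomeans <- function(ratio_table) {
  per_sf <- do.call(rbind, lapply(
    split(ratio_table, list(ratio_table$group, ratio_table$eye,
                            ratio_table$sf_label), drop = TRUE),
    function(d) data.frame(group = d$group[1], eye = d$eye[1],
                           sf = d$sf[1], sf_label = d$sf_label[1],
                           n = nrow(d),
                           geomean_ratio = 10^mean(log10(d$ratio)))))
  overall <- do.call(rbind, lapply(
    split(ratio_table, list(ratio_table$group, ratio_table$eye),
          drop = TRUE),
    function(d) data.frame(group = d$group[1], eye = d$eye[1],
                           sf = NA_real_, sf_label = "window",
                           n = nrow(d),
                           geomean_ratio = 10^mean(log10(d$ratio)))))
  out <- rbind(per_sf, overall)
  out <- out[order(out$group, out$eye, out$sf), ]
  rownames(out) <- NULL
  out
}

#' Full statistical report of a simulated study
#'
#' Emits the study's four analyses as stats report tables:
#' \describe{
#'   \item{interocular}{per group: eye x frequency RM-ANOVA on balanced
#'     log sensitivities; paired t on balanced AULCSF between eyes; the
#'     mean interocular AULCSF ratio.}
#'   \item{condition}{per group: condition x eye x frequency RM-ANOVA on
#'     increment/decrement log sensitivities; condition x eye RM-ANOVA on
#'     AULCSF; Bonferroni pairwise increment vs decrement per eye.}
#'   \item{ratio}{Wilcoxon signed-rank test of the inc/dec ratio against
#'     1 at each windowed frequency, per group and eye.}
#'   \item{correlation}{Pearson correlation of increment vs decrement
#'     AULCSF per group and eye.}
#' }
#'
#' @param dataset A `study_dataset`.
#' @param window Ratio-analysis window mode, see [inc_dec_ratio()].
#' @return A list of class `study_report` with data-frame elements
#'   `interocular`, `condition`, `ratio`, `correlation`, `ratio_table`,
#'   `aulcsf_table` and `mean_csf`.
#' @export
study_report <- function(dataset, window = "printed") {
  est <- dataset$estimates
  inter <- list(); condi <- list(); corr <- list()
  for (grp in unique(est$group)) {
    grid <- dataset$cohort$sf_grids[[grp]]
    sens_cols <- sprintf("log_sens_%02d", seq_len(grid$n_levels))
    ge <- est[est$group == grp, ]
    # --- interocular, balanced ---
    bal <- ge[ge$condition == "balanced", ]
    long <- do.call(rbind, lapply(seq_len(nrow(bal)), function(i)
      data.frame(subject = bal$subject_id[i], eye = bal$eye[i],
                 sf = format_sf(grid$values),
                 y = as.numeric(bal[i, sens_cols]))))
    a <- rm_anova(long, "y", "subject", c("eye", "sf"))
    a$test <- "rm_anova_balanced_log_sens"
    a <- cbind(group = grp, a)
    aw <- bal[bal$eye == "affected", ][order(bal$subject_id[bal$eye ==
                                                              "affected"]), ]
    bw <- bal[bal$eye == "better", ][order(bal$subject_id[bal$eye ==
                                                            "better"]), ]
    tt <- paired_t(aw$aulcsf, bw$aulcsf)
    tt$test <- "paired_t_balanced_aulcsf"
    tt <- cbind(group = grp, tt)
    ratio_row <- stats_row("mean_interocular_aulcsf_ratio",
                           "affected / better",
                           mean(aw$aulcsf / bw$aulcsf))
    inter[[grp]] <- rbind(a, tt, cbind(group = grp, ratio_row))
    # --- condition x eye (x sf) on increment/decrement ---
    ud <- ge[ge$condition != "balanced", ]
    long3 <- do.call(rbind, lapply(seq_len(nrow(ud)), function(i)
      data.frame(subject = ud$subject_id[i], eye = ud$eye[i],
                 condition = ud$condition[i], sf = format_sf(grid$values),
                 y = as.numeric(ud[i, sens_cols]))))
    a3 <- rm_anova(long3, "y", "subject", c("condition", "eye", "sf"))
    a3$test <- "rm_anova_unipolar_log_sens"
    a2 <- rm_anova(ud, "aulcsf", "subject_id", c("condition", "eye"))
    a2$test <- "rm_anova_unipolar_aulcsf"
    pw <- do.call(rbind, lapply(c("affected", "better"), function(eye) {
      r <- pairwise_bonferroni(ud[ud$eye == eye, ], "aulcsf",
                               "subject_id", "condition")
      r$term <- paste0(eye, ": ", r$term)
      r$test <- "pairwise_unipolar_aulcsf"
      r
    }))
    condi[[grp]] <- cbind(group = grp, rbind(a3, a2, pw))
    # --- correlation of inc vs dec AULCSF ---
    corr[[grp]] <- do.call(rbind, lapply(c("affected", "better"),
                                         function(eye) {
      inc <- ud[ud$eye == eye & ud$condition == "increment", ]
      dec <- ud[ud$eye == eye & ud$condition == "decrement", ]
      inc <- inc[order(inc$subject_id), ]; dec <- dec[order(dec$subject_id), ]
      r <- pearson_corr(inc$aulcsf, dec$aulcsf)
      r$term <- paste0(eye, ": inc vs dec AULCSF")
      cbind(group = grp, r)
    }))
  }
  # --- ratio vs 1, per windowed frequency ---
  rt <- inc_dec_ratio(dataset, window)
  ratio_tests <- do.call(rbind, lapply(
    split(rt, list(rt$group, rt$eye, rt$sf_label), drop = TRUE),
    function(d) {
      r <- tryCatch(wilcoxon_vs_const(d$ratio, 1),
                    error = function(e) stats_row(
                      "wilcoxon_vs_const", "ratio vs 1", NA_real_,
                      note = conditionMessage(e)))
      r$term <- sprintf("%s %s @ %s c/deg: ratio vs 1", d$group[1],
                        d$eye[1], d$sf_label[1])
      cbind(group = d$group[1], eye = d$eye[1], sf = d$sf[1],
            sf_label = d$sf_label[1], r)
    }))
  ratio_tests <- ratio_tests[order(ratio_tests$group, ratio_tests$eye,
                                   ratio_tests$sf), ]
  rownames(ratio_tests) <- NULL
  ratio_summary <- ratio_geomeans(rt)
  # group-mean CSF curves for plotting
  mean_csf <- do.call(rbind, lapply(unique(est$group), function(grp) {
    grid <- dataset$cohort$sf_grids[[grp]]
    sens_cols <- sprintf("log_sens_%02d", seq_len(grid$n_levels))
    ge <- est[est$group == grp, ]
    do.call(rbind, lapply(split(ge, list(ge$eye, ge$condition)),
                          function(d) data.frame(
      group = grp, eye = d$eye[1], condition = d$condition[1],
      sf = grid$values,
      mean_log_sens = colMeans(as.matrix(d[, sens_cols])),
      se_log_sens = apply(as.matrix(d[, sens_cols]), 2, stats::sd) /
        sqrt(nrow(d)))))
  }))
  rownames(mean_csf) <- NULL
  aulcsf_table <- est[, c("subject_id", "group", "eye", "condition",
                          "aulcsf", "true_aulcsf")]
  structure(list(interocular = do.call(rbind, inter),
                 condition = do.call(rbind, condi),
                 ratio = ratio_tests,
                 correlation = do.call(rbind, corr),
                 ratio_table = rt, ratio_summary = ratio_summary,
                 aulcsf_table = aulcsf_table,
                 mean_csf = mean_csf),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n== Interocular (balanced) ==\n")
  print(x$interocular[, c("group", "test", "term", "statistic", "df1",
                          "df2", "p")], digits = 4)
  cat("== Increment vs decrement ==\n")
  print(x$condition[, c("group", "test", "term", "statistic", "p")],
        digits = 4)
  cat("== Inc/dec ratio vs 1 ==\n")
  print(x$ratio[, c("term", "statistic", "p")], digits = 4)
  cat("== Inc-dec AULCSF correlation ==\n")
  print(x$correlation[, c("group", "term", "statistic", "p")], digits = 4)
  invisible(x)
}
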