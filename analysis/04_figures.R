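#!/usr/bin/env Rscript
# Figures from the simulated study (clearly synthetic data): group-mean
# CSF curves per condition and eye, the interocular AULCSF scatter, and
# the inc/dec ratio as a function of spatial frequency.  PDFs under
# results/figures/.

suppressMessages({
  library(onoffcsf)
  library(ggplot2)
})

dataset <- load_study("results/study")
rep <- study_report(dataset, window = "printed")
out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mc <- rep$mean_csf
p1 <- ggplot(mc, aes(sf, mean_log_sens, colour = condition,
                     linetype = eye)) +
  geom_line() +
  geom_ribbon(aes(ymin = mean_log_sens - se_log_sens,
                  ymax = mean_log_sens + se_log_sens, fill = condition),
              alpha = 0.15, colour = NA) +
  scale_x_log10() +
  facet_wrap(~ group, scales = "free_x") +
  labs(x = "Spatial frequency (c/deg)", y = "log10 contrast sensitivity",
       title = "Group-mean CSFs (simulated cohort)") +
  theme_minimal()
ggsave(file.path(out, "mean_csf.pdf"), p1, width = 8, height = 4)

au <- rep$aulcsf_table
bal <- au[au$condition == "balanced", ]
wide <- merge(bal[bal$eye == "affected", c("subject_id", "group", "aulcsf")],
              bal[bal$eye == "better", c("subject_id", "aulcsf")],
              by = "subject_id", suffixes = c("_affected", "_better"))
p2 <- ggplot(wide, aes(aulcsf_better, aulcsf_affected, shape = group)) +
  geom_abline(linetype = 2, colour = "grey50") +
  geom_point(size = 2) +
  coord_equal() +
  labs(x = "Fellow / dominant eye AULCSF",
       y = "Amblyopic / non-dominant eye AULCSF",
       title = "Interocular AULCSF (balanced, simulated)") +
  theme_minimal()
ggsave(file.path(out, "aulcsf_scatter.pdf"), p2, width = 5, height = 5)

rs <- rep$ratio_summary
rs <- rs[rs$sf_label != "window", ]
p3 <- ggplot(rs, aes(sf, geomean_ratio, colour = eye)) +
  geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
  geom_line() + geom_point() +
  scale_x_log10() +
  facet_wrap(~ group, scales = "free_x") +
  labs(x = "Spatial frequency (c/deg)",
       y = "Increment / decrement sensitivity ratio (geometric mean)",
       title = "ON/OFF sensitivity ratio vs frequency (simulated)") +
  theme_minimal()
ggsave(file.path(out, "inc_dec_ratio.pdf"), p3, width = 8, height = 4)

cat("Figures written to", out, "\n")
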