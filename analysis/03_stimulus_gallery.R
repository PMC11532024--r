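#!/usr/bin/env Rscript
# Renders the three stimulus classes (balanced, increment, decrement) as
# PNGs with JSON sidecars for a few frequencies of the amblyope test
# grid, plus a band-pass spectral check, under results/stimuli/.

suppressMessages(library(onoffcsf))

out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- make_sf_grid(0.31, 11.77, 12)
for (sf in g$values[c(5, 8, 11)]) {
  side <- export_stimuli(sf, out, seed = 7, contrast = 0.5, sigma_deg = 2)
  cat(sprintf("sf %5.2f c/deg: inc min %.3g, dec max %.3g, peak contrast %.3f\n",
              sf, side$increment$min_pixel, side$decrement$max_pixel,
              side$balanced$peak_weber))
  img <- make_bandpass_noise(sf, seed = 7)
  sp <- radial_spectrum(img)
  peak <- sp$f_cpd[which.max(sp$amplitude)]
  cat(sprintf("            spectral peak %.2f c/deg (%+.2f octaves)\n",
              peak, log2(peak / sf)))
}
cat("Stimuli written to", out, "\n")
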