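#!/usr/bin/env Rscript
# Simulate the viability screens the fits will consume: one MYC-high cell
# line whose ground truth carries a synthetic-lethal (negative bilinear)
# interaction between ssCHK1 and ssBRD4, and one MYC-low line identical in
# every other effect. Three replicates per run, sd 0.05 measurement noise.

library(qpopr)
dir.create("results", showWarnings = FALSE)

panel <- default_modulator_panel()
design <- read_design_tsv("results/design_coded.tsv", modulators = panel)

truths <- list(myc_high = make_truth("myc_high", seed = 101L),
               myc_low = make_truth("myc_low", seed = 202L))
for (line in names(truths)) {
  tr <- truths[[line]]
  print(tr)
  rec <- simulate_screen(tr, design)
  write_viability_csv(rec, sprintf("results/screen_%s.csv", line))
  cat(sprintf("%s: %d measurements, viability %0.3f..%0.3f (mean %0.3f)\n",
              line, nrow(rec), min(rec$viability), max(rec$viability),
              mean(rec$viability)))
}
cat("the two truths differ only in the ssCHK1 x ssBRD4 interaction term\n")
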