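#!/usr/bin/env Rscript
# Generate the synthetic datasets every downstream analysis runs on:
# the macaw-like nine-sample panel, a no-introgression null, and a
# dataset carrying a P3 -> P2 introgression pulse (f = 0.2).
suppressMessages(library(macawpop))

fix_dir <- "results/fixtures"
seed <- 20260923L

presets <- c(macaw_like = 0L, null_ils = 1L, introgression = 2L)
for (i in seq_along(presets)) {
  preset <- names(presets)[i]
  paths <- make_fixture(preset, seed = seed + presets[[i]], dir = fix_dir,
                        n_sites = 20000L)
  vt <- read_vcf(paths$vcf)
  cat(sprintf("%-13s %6d sites x %d samples -> %s\n",
              preset, n_sites(vt), length(sample_ids(vt)), paths$vcf))
}
cat("fixtures written to ", fix_dir, "\n", sep = "")
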