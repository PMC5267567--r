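#!/usr/bin/env Rscript
# Stage 3: traditional (non-phylogenetic) Rensch's-rule analysis. SMA
# regression of log10 male size on log10 female size for the whole
# dataset, each suborder, and each family with at least seven species;
# the verdict reads the 95% CI against slope 1.

library(ssdallometry)

seed <- 1
ds <- read_dataset("results/data/study_dataset.csv", verbose = FALSE)

for (metric in c("mass", "scl")) {
  one <- select_one_population_per_species(ds, metric, seed = seed,
                                           verbose = FALSE)
  sub <- run_traditional(one, analysis_config(metric, "suborder",
                                              seed = seed))
  fam <- run_traditional(one, analysis_config(metric, "family",
                                              seed = seed))
  tab <- rbind(sub, fam[fam$clade != "All", ])
  write.csv(tab, sprintf("results/sma_traditional_%s.csv", metric),
            row.names = FALSE)

  cat("==", metric, "==\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s n=%3d  b=%.3f  CI [%.3f, %.3f]  %s\n",
                tab$clade[i], tab$n[i], tab$slope[i], tab$ci_low[i],
                tab$ci_high[i], tab$verdict[i]))
  skipped <- attr(fam, "skipped")
  if (length(skipped))
    cat("  families below the 7-species threshold:",
        paste(skipped, collapse = ", "), "\n")
}
cat("Wrote sma_traditional_*.csv under results/\n")
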