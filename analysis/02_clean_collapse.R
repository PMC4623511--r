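#!/usr/bin/env Rscript
# Stage 2: apply the six elimination rules to both libraries, collapse the
# surviving adapter-trimmed inserts to unique counted tags, and summarize
# the clean-read length distribution (expected modes: 24 nt, then 21 nt).
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L, stages = "clean")

stats <- read_tsv(file.path(outdir, "cleaning_stats.tsv"))
print(stats)
ld <- read_tsv(file.path(outdir, "length_dist.tsv"))
top <- ld[order(-ld$count), ][1:3, c("length", "count")]
cat("dominant clean-read lengths:\n")
print(top, row.names = FALSE)
stopifnot(stats$raw_reads == stats$clean_reads + rowSums(
  stats[, c("low_quality", "adapter5_contaminant", "no_adapter3",
            "no_insert", "polyA", "length_out_of_range")]))
cat("read accounting conserved for both libraries\n")
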