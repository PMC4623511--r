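#!/usr/bin/env Rscript
# Stage 1: build the synthetic study -- a 12 x 50 kb genome with planted
# known/novel miRNA hairpins, decoy ncRNAs, repeats and gene models, and
# simulate the two small-RNA libraries (control vs salt) with a complete
# ground-truth manifest.
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L, stages = "simulate")

man <- read_tsv(file.path(outdir, "manifest_cleaning.tsv"))
known <- read_tsv(file.path(outdir, "manifest_known.tsv"))
novel <- read_tsv(file.path(outdir, "manifest_novel.tsv"))
cat(sprintf("simulated %d + %d raw reads (control + salt)\n",
            man$raw_reads[1], man$raw_reads[2]))
cat(sprintf("planted %d known miRNAs (%d families), %d novel hairpins\n",
            nrow(known), length(unique(known$family)), nrow(novel)))
cat("novel contexts:", paste(sort(table(novel$context), decreasing = TRUE) |>
                               (\(x) paste0(names(x), "=", x))(),
                             collapse = ", "), "\n")
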