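#!/usr/bin/env Rscript
# Stage 4: Mireap-style novel miRNA discovery -- excise candidate windows
# around unannotated 18-26 nt tag alignments, fold them, apply the full
# duplex/energy/composition criteria, classify genomic context and assign
# oco-miRNNN-5p/3p names. Recovery is checked against the planted truth.
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L, stages = "discover")

novel <- read_tsv(file.path(outdir, "novel_mirnas.tsv"))
man <- read_tsv(file.path(outdir, "manifest_novel.tsv"))
cat(sprintf("accepted novel miRNAs: %d (MFE %.1f .. %.1f kcal/mol)\n",
            nrow(novel), min(novel$mfe), max(novel$mfe)))
cat("contexts:", paste(names(table(novel$context)), table(novel$context),
                       sep = "=", collapse = ", "), "\n")
rec <- mean(man$mature_seq %in% novel$mature_seq)
cat(sprintf("planted mature recovery: %.0f%%\n", 100 * rec))
rej <- read_tsv(file.path(outdir, "rejections.tsv"))
reasons <- sort(table(unlist(strsplit(rej$reasons, ","))), decreasing = TRUE)
cat("top rejection reasons:",
    paste(names(reasons)[1:min(4, length(reasons))], collapse = ", "), "\n")
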