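#!/usr/bin/env Rscript
# Stage 7: target prediction for the differentially expressed miRNAs
# (complementarity scoring with seed-weighted penalties, cleavage-site
# mapping between miRNA positions 10/11) and GO-term enrichment of the
# target gene set (hypergeometric SEA, Benjamini-Hochberg FDR < 0.05).
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L,
             stages = c("targets", "enrich", "report"))

hits <- read_tsv(file.path(outdir, "targets.tsv"))
cat(sprintf("target hits: %d (%d cleavage, %d translation) across %d transcripts\n",
            nrow(hits), sum(hits$inhibition == "cleavage"),
            sum(hits$inhibition == "translation"),
            length(unique(hits$transcript))))
enr <- read_tsv(file.path(outdir, "enrichment.tsv"))
cat("GO enrichment:\n")
print(enr[, c("term", "k", "n", "K", "N", "pvalue", "fdr", "significant")],
      row.names = FALSE)
summ <- read_tsv(file.path(outdir, "summary.tsv"))
cat("study summary table:\n")
print(summ, row.names = FALSE)
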