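#!/usr/bin/env Rscript
# Stage 3: map the unique tags to the genome (ungapped, <= 2 mismatches,
# copy cap 20) and push every mapped tag through the annotation hierarchy:
# rRNA-type ncRNAs (GenBank-like > Rfam-like) > known miRNAs > repeats >
# exons > introns > unannotated.
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L, stages = c("map", "annotate"))

status <- read_tsv(file.path(outdir, "tag_status.tsv"))
cat("tag mapping status:\n")
print(table(status$status))
ann <- read_tsv(file.path(outdir, "annotation.tsv"))
cat("annotation classes:\n")
print(table(ann$category))
known <- read_tsv(file.path(outdir, "known_mirnas.tsv"))
cat(sprintf("known miRNAs: %d tags, %d distinct names, %d families, %d star species\n",
            nrow(known), length(unique(known$name)),
            length(unique(known$family)), sum(known$is_star)))
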