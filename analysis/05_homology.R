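#!/usr/bin/env Rscript
# Stage 5: in-silico conserved miRNA discovery -- search the reference
# precursors against the transcriptome with the local seed-and-extend
# aligner and validate hits as hairpins.
library(halomiR)

outdir <- file.path("results", "pipeline")
run_pipeline(default_config(), outdir, seed = 1L, stages = "homology")

hits <- read_tsv(file.path(outdir, "homology_hits.tsv"))
cat(sprintf("homology hits: %d (%d validated hairpins)\n",
            nrow(hits), sum(hits$validated)))
if (nrow(hits) > 0) {
  print(hits[hits$validated, c("query", "transcript", "identity", "coverage")],
        row.names = FALSE)
}
man <- read_tsv(file.path(outdir, "manifest_homologs.tsv"))
found <- vapply(man$query, function(q)
  any(hits$query == q & hits$validated & hits$identity == 1), TRUE)
cat(sprintf("planted transcriptome homologs recovered: %d/%d\n",
            sum(found), length(found)))
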