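---
title: "Methods: miRNA discovery and salt-stress expression analysis in halomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and salt-stress expression analysis in halomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

halomiR re-implements, as a tested end-to-end workflow, the computational
analysis used in plant small RNA-seq studies that compare a control and a
stress-treated library: read cleaning, tag collapsing, ungapped genome
mapping, hierarchical ncRNA annotation, Mireap-style novel miRNA hairpin
discovery, homology-based conserved miRNA recovery, count-based
differential expression, target prediction with cleavage-site mapping, and
GO-term enrichment. The package is organized so that every stage's
computation lives in an exported function, the numbered scripts under
`analysis/` are thin narrative drivers over `run_pipeline()`, and the whole
workflow is exercised on synthetic libraries with planted ground truth.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic study does and does not demonstrate.

## The study design being emulated

The workflow models a two-library design: small RNAs of 16-36 nt from
control and salt-treated leaf tissue, sequenced with a 3' adapter, cleaned,
and collapsed to unique tags carrying one count per library. All abundance
statements downstream (TPM, fold-change, the count test) are per-tag or
per-miRNA totals against the library clean-read totals; the design has no
biological replicates, which is why the differential test is an exact
two-library count test rather than a dispersion-based model.

## Read cleaning

Reads are eliminated by the first rule they violate, in a fixed order:
(i) low quality, (ii) 5' primer contaminant, (iii) no 3' primer, (iv) no
insert, (v) poly-A, (vi) insert length outside 16-36 nt. The rule *order*
and the length window are fixed by the emulated protocol; the rules' numeric
definitions are not published anywhere we could adopt them from, so the
package declares its own and exposes every one in the configuration:

* low quality: mean Phred < 20, or more than 10% of bases under Phred 10;
* 5' contaminant: the read starts with the first 8 nt of the 5' adapter at
  most 1 mismatch away;
* 3' adapter search: exact prefix match of decreasing length 12 down to 6,
  leftmost occurrence wins (deterministic, so trimming is testable);
* no insert: trimmed insert empty; poly-A: insert at least 80% A.

The cleaning statistics satisfy an exact conservation law (raw = clean +
sum of per-rule removals), which the test suite checks against the
generator's per-rule manifest counts with zero tolerance.

## Mapping

Tags are aligned ungapped to the genome on both strands with at most 2
mismatches, all placements reported. The implementation seeds candidate
positions with exact 5-mer index lookups: a tag split into three disjoint
seeds cannot carry 2 mismatches in all three, so the union of exact-seed
hits is a superset of all valid placements, each then verified directly.
The test suite proves exact equivalence against a quadratic brute-force
Hamming scan. `N` never matches: not in the genome, not in a tag. A tag
with more than 20 placements (the copy-number cap of the discovery
parameter set) is flagged `over_copy_cap` and excluded from hairpin
discovery; the cap is applied at mapping time because every consumer of
multi-locus placements downstream respects it, and reporting capped tags
with a distinct status preserves the information.

## Annotation hierarchy

Every mapped tag receives exactly one class by priority: rRNA-type ncRNAs
(with the GenBank-like set taking precedence over the Rfam-like set) >
known miRNAs > repeats > exons > introns > unannotated. Classes are
assigned by sequence matching against user-supplied reference sets with the
same ungapped 2-mismatch matcher as the mapper — including exons and
introns, which are matched against mRNA/intron reference *sequences* rather
than genome coordinates. That choice mirrors the real situation this
workflow comes from: the transcript database is heterologous and
incomplete, so a miRNA residing in an unannotated host gene's exon stays
"unannotated" and reaches discovery. This is also how the synthetic
generator can plant exonic and UTR novel miRNAs that are genuinely
discoverable: its annotation reference deliberately covers only the genes
that do not host planted hairpins.

Known miRNAs are matched against mature references with at most 2
mismatches and 2-nt end shifts (a declared tolerance — the emulated
protocol states a mismatch policy only for genome mapping). Each reference
precursor is folded once to derive its star sequence; star-matching tags
are reported as miRNA* species with their own counts, unconstrained by the
mature's (star counts exceeding mature counts are reported as-is).

## Folding engine

The bundled backend is a Zuker-style dynamic program over a documented
nearest-neighbor model: stacking energies on adjacent canonical pairs
(Watson-Crick and G:U), tabulated hairpin/bulge/internal-loop penalties
with logarithmic extrapolation above the table, a 0.5 kcal/mol/nt
internal-loop asymmetry term capped at 3, a linear multiloop model
(a = 3.4, b = 0.4/branch, c = 0.1/nt), minimum hairpin loop 3, interior
loops capped at 30 nt. It is guaranteed optimal *under this table*: the
test suite enumerates every non-crossing structure of test sequences up to
24 nt, scores them with an independent loop-decomposition scorer, and
demands exact agreement; the scorer also re-scores every structure the DP
returns. Absolute energies approximate full thermodynamic folders, and the
-18 kcal/mol precursor ceiling applies to whichever backend is configured —
`fold()` accepts any function with the same contract, and candidate
evaluation passes a backend through, which is also how the acceptance
machinery probes the energy boundary with stipulated MFE values.

## Novel miRNA discovery

Unannotated, mapped tags of 18-26 nt seed candidate windows: per alignment,
one window extending 3' and one extending 5', each bounded by the tag plus
the 300-nt maximum mature-star distance plus the 20-nt precursor flank,
clipped at chromosome edges, taken from the alignment strand. Each window
is folded; the mature must sit entirely on one arm; the star is the
pairing footprint shifted 2 nt 3'-ward (the canonical Dicer 2-nt 3'
overhang, one formula for both arms); the precursor is then trimmed to the
mature-star span plus the 20-nt flank and refolded, because the criteria —
in particular MFEI and A+U content — are properties of the precursor, not
of an excision window three times its size.

A candidate is accepted only if *all* criteria hold: mature on one arm;
star without loop or break; duplex mismatches <= 2; >= 19 paired bases;
largest bulge <= 8; duplex asymmetry <= 4; mature-star distance <= 300 nt;
MFE <= -18 kcal/mol; A+U fraction within 30-70%; |MFEI| >= 0.85. The MFEI
floor deserves a note: the emulated criteria require only "higher MFEIs"
with no number, so the default 0.85 follows standard plant-miRNA practice,
is configurable, can be disabled (set it to 0), and MFEI is always
reported. The duplex-mismatch criterion is printed once as "less than 2"
and the mapping policy as "no more than 2"; the default takes the
inclusive reading (<= 2), configurable. All criteria are always evaluated —
a rejection carries the complete list of distinct reasons, not just the
first — which makes `rejections.tsv` a per-window diagnosis table.

Duplex statistics are defined on the duplex region (the mature minus its
2-nt 3' overhang, and the star's counterpart): mismatches are unpaired
mature positions there, the bulge is the longest unpaired run on either
strand, asymmetry is the absolute difference of unpaired counts between the
two strands, and `paired_bp` counts paired mature positions.

Accepted candidates with identical mature sequence merge; within one
precursor locus and arm, matures within 2 mismatches / 2-nt shifts of the
most abundant mature are absorbed as sequencing-error and end-trimming
isomiRs. Names are sequential by locus (`oco-miR001-5p`, ...), and two
matures from one precursor share a number and differ in the -5p/-3p
suffix. The reported mature is spelled as the precursor spells it, so a
tag that aligned with mismatches still names the genomic species.
Genomic context is the majority-overlap class of the precursor locus
(5'UTR > 3'UTR > exon > intron on ties, intergenic when no gene overlaps).

## Homology search

Conserved-miRNA recovery against a transcriptome FASTA replaces a remote
BLASTN stage with a local seed-and-extend aligner: exact 11-mer word
seeds, ungapped X-drop extension on the seed diagonal, both strands,
identity >= 0.9 over >= 0.9 of the query (declared stand-ins for a web
server's unstated defaults, all configurable). Gapped extension is omitted
— the queries are short, highly conserved precursors — and documented as a
limitation. Precursor hits are refolded and validated with the full
candidate criteria (context checks do not apply on transcripts);
mature-only queries are reported but never validated.

## Differential expression

Normalized expression is tags-per-million: count / library clean-read total
x 10^6. Fold-change is log2(treated/control) on TPM, with values below
0.01 TPM floored *only* inside the fold-change so library-exclusive miRNAs
get finite values; reports always show the true TPM. The p-value is the
Audic-Claverie exact count test — the emulated study's p-value formula is
unreadable in the source material, and this test is the standard for
two-library tag counts; the choice is prominently documented and the test
is computed in log-space with tails summed to machine precision
(normalization of the conditional distribution is checked to 1e-12, tails
against brute-force summation to 1e-9, and the negative-binomial identity
of the conditional law provides an independent oracle in the tests).
Calls use the printed thresholds with inclusive boundaries: up when
log2FC >= 1 at P <= 0.05, down when log2FC <= -1 at P <= 0.05. Raw p
drives the calls, as in the emulated analysis; Benjamini-Hochberg q-values
are reported alongside. The comparative-Ct utility (RQ = 2^-ddCt against a
U6-type reference, replicates averaged on the Ct scale) supports the
qRT-PCR cross-check table.

## Target prediction and enrichment

Targets are scored psRNATarget-style: the miRNA is aligned antiparallel
against each transcript window (window sizes miRNA length +/- 2 admit
small bulges), with penalties match 0, G:U wobble 0.5, mismatch 1.0, gap
2.0, all doubled across miRNA positions 2-13; hits at expectation <= 3.0
are reported, overlapping window reports deduplicated to the best-scoring
representative. The schema constants follow the published server
description and are configurable; target-site accessibility (UPE) is
omitted, a documented deviation, as it requires partition-function folding
of long mRNAs. Inhibition is `translation` when a mismatch or gap faces
miRNA positions 9-11 (G:U wobbles there do not block slicing under this
schema), otherwise `cleavage`, with the slice coordinate mapped gap-aware
to the transcript boundary between the bases paired to miRNA positions 10
and 11. Enrichment of target gene sets is a local singular enrichment
analysis: per-term hypergeometric upper-tail p against the background
universe, Benjamini-Hochberg FDR, significance at FDR < 0.05.

## The synthetic study and what it shows

`build_genome()` assembles 12 chromosomes of 50 kb (mirroring rice's 12
chromosomes at desk scale) and plants, at recorded non-overlapping loci:
30 gene models; 14 known miRNA hairpins matching a miRBase-like reference;
10 novel hairpins, each accepted by the candidate criteria at design time
via rejection sampling, with at least one each in intergenic, intronic,
exonic, 5'UTR and 3'UTR context; decoy rRNA/tRNA/snoRNA/snRNA/scRNA loci;
two repeat families at 4 copies; perfect target sites for four known
miRNAs and 3-mismatch (non-seed) sites for two novel miRNAs inside 3'
coding exons; and three known precursors copied verbatim into coding exons
as homology-search truth. Hairpins are designed with flanks exactly as
long as the evaluator's trimming flank, so the precursor judged at design
time is the precursor judged in situ.

`simulate_libraries()` draws per-tag counts as Poisson around expected
abundances — the simplest generative model consistent with the downstream
count test — and emits insert + adapter + random fill reads of 50 nt with
uniform substitution errors at 0.1% (no indels; mapping is ungapped).
Planted expression: blocks of up- (x4) and down- (/4) regulated miRNAs
whose larger expected count is 200 reads, neutral miRNAs at 30, one
exemplar with a rare mature (2 reads) under an abundant star (800), and a
background of decoy/exon/intron/repeat/intergenic fragments whose length
mix is calibrated at generation time so the clean-read length mode is
24 nt with the 21-nt class second — the hallmark size profile of plant
small RNA libraries. Per-rule contaminant reads are drawn (2%/1%/2%/1%/1%/2%
of the clean count for rules i-vi) and each emitted read is verified
against the rule it must trigger or survive, so the manifest counts are
exact by construction, not approximately recovered.

Passing the recovery tests on this generator shows that the pipeline's
stages invert the generator's constructions under realistic noise — exact
per-rule accounting, >= 90% exact recovery of planted matures, correct
up/down calls for all strongly regulated miRNAs with adequate counts, a
calibrated type-I rate on null counts. It does not show robustness to
real-library phenomena the generator leaves out: heteroskedastic
sequencing-error profiles, adapter dimers and chimeras, RNA editing,
isomiR biology beyond substitution errors, heterochromatic siRNA clusters
that mimic hairpin loci, or genome mis-assembly. Those caveats bound any
claim the synthetic run supports.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 and human-readable
  reports are 1-based inclusive; the conversion happens at exactly one
  boundary (`read_gff3()`/`write_gff3()`).
* DNA is the storage alphabet everywhere; folding converts T to U at its
  boundary, explicitly, never silently.
* Phred+33 only; the offset is a parameter, never auto-detected.
* Energy comparisons inside the fold DP and its traceback use an absolute
  tolerance of 1e-6 kcal/mol; ties in the traceback prefer the unpaired
  option, so a sequence with no stabilizing structure reports the open
  chain at exactly 0.
* The mapper's over-cap status, the lexicographic tag ordering, the
  locus-ordered novel naming, and the (miRNA, transcript, position) target
  ordering make every output table deterministic; the whole pipeline is
  byte-identical under a fixed seed and resumable per stage from its
  serialized text intermediates.
* Problem sizes in the default synthetic study (600 kb genome, ~17k reads
  per library, ~800 unique tags) were chosen so the complete pipeline runs
  in about a minute on one CPU — large enough that every annotation class,
  context class and DE block is populated with margin, small enough to
  iterate on.
* The `cli` module surface of the workflow is `run_pipeline()` plus the
  numbered `analysis/` drivers; the pipeline is a single-process streaming
  design whose only contract is stage order and restartability.

## Known limitations

The energy table is a simplified nearest-neighbor set: no dangling ends,
no terminal-AU penalties, no special tetraloops, bulges do not preserve
stacking. MFEI and MFE values are therefore comparable within this
package, approximate against ViennaRNA/mfold. The homology aligner is
ungapped. Target scoring omits accessibility. The count test conditions on
one library's count and has no dispersion parameter — with pooled
single-library designs that is the appropriate (and emulated) choice, but
it will understate biological variance whenever true replicates exist.
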