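test_that("star derivation follows canonical Dicer duplex geometry", {
  # ideal hairpin: mature [0,21) fully paired to the complement arm; the
  # star is the pairing footprint shifted +2 (2-nt 3' overhangs both sides)
  m <- "GCACGTACGGATCCGATCGTA"
  hp <- construct_hairpin(m, loop_seq = "TATATTTATA", flank5 = "", flank3 = "ACGT")
  fr <- fold(dna_to_rna(hp$sequence))
  st <- detect_star(hp$mature, fr$structure)
  expect_true(st$ok)
  expect_equal(st$arm, "5p")
  # full 21-bp stem, loop 10: partners of mature 1..21 are 52..32 (1-based),
  # so the star footprint [31, 52) shifts to [33, 54)
  expect_equal(st$star, c(33L, 54L))
})

test_that("a mature spanning the terminal loop has no defined star", {
  m <- "GCACGTACGGATCCGATCGTA"
  hp <- construct_hairpin(m, loop_seq = "TATATTTATA", flank5 = "", flank3 = "ACGT")
  fr <- fold(dna_to_rna(hp$sequence))
  st <- detect_star(c(15L, 36L), fr$structure) # straddles arm and loop
  expect_false(st$ok)
  expect_equal(st$reason, "mature_spans_loop")
})

test_that("candidate evaluation enforces each criterion with its own reason", {
  set.seed(51)
  d <- design_hairpin(21, 0)
  cfg <- default_config()$discovery
  base <- evaluate_candidate(d$sequence, d$mature[1], 21, cfg)
  expect_equal(base$verdict, "ACCEPT")
  expect_length(base$rejection_reasons, 0)

  # energy ceiling, tested through the pluggable backend
  inject <- function(mfe) function(seq) {
    r <- fold(seq)
    list(structure = r$structure, mfe = mfe)
  }
  noMfei <- cfg; noMfei$mfei_min <- 0
  r1 <- evaluate_candidate(d$sequence, d$mature[1], 21, noMfei,
                           fold_backend = inject(-17.5))
  expect_equal(r1$verdict, "REJECT")
  expect_true("mfe_above_threshold" %in% r1$rejection_reasons)
  r2 <- evaluate_candidate(d$sequence, d$mature[1], 21, noMfei,
                           fold_backend = inject(-18.0))
  expect_equal(r2$verdict, "ACCEPT")

  # A+U composition window
  tight <- cfg; tight$au_min <- 0.60
  r3 <- evaluate_candidate(d$sequence, d$mature[1], 21, tight)
  expect_true("au_out_of_range" %in% r3$rejection_reasons)

  # all tests run: an energy failure does not suppress other diagnoses
  r4 <- evaluate_candidate(d$sequence, d$mature[1], 21, tight,
                           fold_backend = inject(-10))
  expect_true(all(c("au_out_of_range", "mfe_above_threshold") %in%
                    r4$rejection_reasons))
})

test_that("duplex statistics count designed mismatches", {
  set.seed(52)
  for (mm in 0:2) {
    d <- design_hairpin(21, mm)
    expect_equal(d$candidate$duplex_mismatches, mm)
    expect_equal(d$candidate$paired_bp, 21L - mm)
  }
})

test_that("hairpin design rejects unattainable parameter combinations", {
  cfg <- default_config()$discovery
  expect_error(design_hairpin(21, 3, config = cfg), "exceeds the configured maximum")
  expect_error(design_hairpin(19, 2, config = cfg), "unattainable")
  set.seed(53); a <- design_hairpin(21, 1)
  set.seed(53); b <- design_hairpin(21, 1)
  expect_identical(a, b)
})

test_that("candidate windows are excised on both sides and clipped", {
  g <- list(chr1 = rand_dna(2000))
  aln <- data.frame(tag_id = "t1", chrom = "chr1", start = 1000L, end = 1021L,
                    strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  w <- excise_candidates(aln, g, flank = 20L, max_distance = 300L)
  expect_equal(nrow(w), 2L)
  expect_equal(w$win_start[w$side == "5p_extend"], 980L)
  expect_equal(w$win_end[w$side == "5p_extend"], 1021L + 300L + 20L)
  expect_equal(w$win_start[w$side == "3p_extend"], 1000L - 300L - 20L)
  expect_equal(w$mature_offset[w$side == "5p_extend"], 20L)
  # near the chromosome start the 5'-extended window clips but is emitted
  aln2 <- data.frame(tag_id = "t2", chrom = "chr1", start = 10L, end = 31L,
                     strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  w2 <- excise_candidates(aln2, g, 20L, 300L)
  expect_equal(nrow(w2), 2L)
  expect_equal(min(w2$win_start), 0L)
  # minus-strand windows carry the reverse complement and a mapped offset
  aln3 <- data.frame(tag_id = "t3", chrom = "chr1", start = 1000L, end = 1021L,
                     strand = "-", mismatches = 0L, stringsAsFactors = FALSE)
  w3 <- excise_candidates(aln3, g, 20L, 300L)
  tag_rc <- revcomp(substr(g$chr1, 1001, 1021))
  for (k in 1:2) {
    expect_equal(substr(w3$sequence[k], w3$mature_offset[k] + 1L,
                        w3$mature_offset[k] + 21L), tag_rc)
  }
})

test_that("genomic context uses majority overlap with fixed precedence", {
  models <- list(list(
    gene_id = "G1", mrna_id = "G1.1", chrom = "chr1", strand = "+",
    exons = cbind(start = c(100L, 300L), end = c(200L, 400L)),
    cds = cbind(start = c(150L, 300L), end = c(200L, 350L)),
    utr5 = cbind(start = 100L, end = 150L),
    utr3 = cbind(start = 350L, end = 400L),
    introns = cbind(start = 200L, end = 300L)))
  expect_equal(classify_context("chr1", 500, 560, models), "intergenic")
  expect_equal(classify_context("chr2", 150, 200, models), "intergenic")
  expect_equal(classify_context("chr1", 210, 260, models), "intronic")
  expect_equal(classify_context("chr1", 110, 140, models), "5'UTR")
  expect_equal(classify_context("chr1", 360, 390, models), "3'UTR")
  # 60% in CDS, 40% in intron: exonic by majority
  expect_equal(classify_context("chr1", 170, 220, models), "exonic")
})

test_that("tightening any threshold never enlarges the accepted set", {
  set.seed(54)
  cfg <- default_config()$discovery
  cands <- lapply(1:8, function(i)
    design_hairpin(21, sample(0:2, 1), config = cfg))
  verdicts <- function(cc) vapply(cands, function(d)
    evaluate_candidate(d$sequence, d$mature[1], 21, cc)$verdict == "ACCEPT",
    TRUE)
  base <- verdicts(cfg)
  for (tweak in list(c("mfe_max", -25), c("min_paired", 21),
                     c("max_duplex_mismatch", 0), c("au_min", 0.45),
                     c("au_max", 0.55), c("mfei_min", 1.2))) {
    cc <- cfg
    cc[[tweak[1]]] <- as.numeric(tweak[2])
    expect_true(all(base | !verdicts(cc)), label = tweak[1])
  }
})

test_that("naming groups arms of one precursor and orders by locus", {
  acc <- data.frame(
    tag_id = c("t1", "t2", "t3"),
    chrom = c("chr2", "chr2", "chr1"),
    start = c(5000L, 5010L, 100L), end = c(5090L, 5100L, 190L),
    strand = c("+", "+", "+"), arm = c("5p", "3p", "5p"),
    mature_seq = c("ACGGATCCGATCGTAGCACGT", "GGCTAACGGTTCCGAGGTCAA",
                   "TTGGCCAACCGGTTAACCGGA"),
    star_seq = "x", precursor_seq = "x", mfe = -30, mfei = -1,
    au_fraction = 0.5, context = "intergenic",
    count_control = c(10L, 3L, 7L), count_treated = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  out <- name_and_deduplicate(acc)
  expect_equal(out$name, c("oco-miR001-5p", "oco-miR002-5p", "oco-miR002-3p"))
  # identical matures from different windows merge into one record
  acc2 <- rbind(acc, acc[1, ])
  acc2$tag_id[4] <- "t4"
  out2 <- name_and_deduplicate(acc2)
  expect_equal(nrow(out2), 3L)
  expect_equal(out2$count_control[out2$name == "oco-miR002-5p"], 20L)
})
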