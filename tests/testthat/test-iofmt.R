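test_that("FASTA reading splits headers and concatenates sequence lines", {
  f <- withr::local_tempfile(lines = c(">a x", "ACGT", "ACGT", ">b", "GG"))
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$description, c("x", ""))
  expect_equal(rec$sequence, c("ACGTACGT", "GG"))
})

test_that("malformed FASTA is rejected with a format error", {
  f1 <- withr::local_tempfile(lines = c(">a", "", ">b", "AC"))
  expect_error(read_fasta(f1), "empty sequence")
  f2 <- withr::local_tempfile(lines = c("ACGT", ">a", "ACGT"))
  expect_error(read_fasta(f2), "before any header")
  f3 <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_fasta(f3)), 0L)
})

test_that("FASTA write/read round-trips arbitrary record sets", {
  set.seed(11)
  for (rep in 1:5) {
    recs <- random_fasta_records(sample(1:20, 1))
    f <- withr::local_tempfile()
    write_fasta(recs, f, width = 17L)
    expect_equal(read_fasta(f), recs)
  }
})

test_that("FASTQ parsing decodes Phred+33 and validates structure", {
  f <- withr::local_tempfile(lines = c("@r1", "ACGT", "+", "IIII"))
  rd <- read_fastq(f)
  expect_equal(rd$sequence, "ACGT")
  expect_equal(phred_scores(rd$quality)[[1]], c(40L, 40L, 40L, 40L))

  bad <- withr::local_tempfile(lines = c("@r1", "ACGT", "+", "II"))
  expect_error(read_fastq(bad), "length mismatch at line 4")
  trunc <- withr::local_tempfile(lines = c("@r1", "ACGT", "+", "IIII", "@r2", "AC"))
  expect_error(read_fastq(trunc), "truncated record at line 5")
})

test_that("FASTQ write/read round-trips simulated reads losslessly", {
  set.seed(12)
  n <- 1000L
  reads <- data.frame(
    id = sprintf("r%04d", 1:n),
    sequence = vapply(1:n, function(i) rand_dna(sample(16:50, 1)), ""),
    stringsAsFactors = FALSE)
  reads$quality <- vapply(nchar(reads$sequence), function(L)
    rawToChar(as.raw(sample(33:73, L, replace = TRUE))), "")
  f <- withr::local_tempfile()
  write_fastq(reads, f)
  expect_equal(read_fastq(f), reads)
})

test_that("GFF3 round-trips with exact 1-based/0-based coordinate conversion", {
  models <- list(list(
    gene_id = "G1", mrna_id = "G1.1", chrom = "chr1", strand = "+",
    exons = cbind(start = c(10L, 30L), end = c(20L, 40L)),
    cds = cbind(start = 15L, end = 20L),
    utr5 = cbind(start = 10L, end = 15L),
    utr3 = cbind(start = 35L, end = 40L),
    introns = cbind(start = 20L, end = 30L)))
  f <- withr::local_tempfile()
  write_gff3(models, f, c(chr1 = 100L))
  # the emitted GFF row for the first exon must be 1-based inclusive 11..20
  raw <- readLines(f)
  expect_true(any(grepl("\texon\t11\t20\t", raw)))
  back <- read_gff3(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$exons, models[[1]]$exons)
  expect_equal(back[[1]]$introns, models[[1]]$introns)
  expect_equal(back[[1]]$utr5, models[[1]]$utr5)
})

test_that("synthetic gene models survive a GFF3 write/read cycle", {
  set.seed(13)
  cfg <- small_config()
  b <- build_genome(cfg, seed = 13)
  f <- withr::local_tempfile()
  write_gff3(b$models, f, stats::setNames(nchar(b$genome), names(b$genome)))
  back <- read_gff3(f)
  expect_length(back, length(b$models))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$exons, b$models[[k]]$exons, ignore_attr = TRUE)
    expect_equal(back[[k]]$introns, b$models[[k]]$introns, ignore_attr = TRUE)
    expect_equal(back[[k]]$chrom, b$models[[k]]$chrom)
  }
})

test_that("configuration files overlay onto the defaults", {
  f <- withr::local_tempfile()
  writeLines("discovery:\n  mfe_max: -25.0\nmapping:\n  max_hits: 10", f)
  cfg <- read_config(f)
  expect_equal(cfg$discovery$mfe_max, -25.0)
  expect_equal(cfg$mapping$max_hits, 10L)
  expect_equal(cfg$discovery$max_distance, default_config()$discovery$max_distance)
  f2 <- withr::local_tempfile()
  write_config(cfg, f2)
  expect_equal(read_config(f2)$discovery$mfe_max, -25.0)
})
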