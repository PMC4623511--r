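mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}
cl <- default_config()$cleaning
AD <- cl$adapter3

test_that("each cleaning rule catches its read class, in printed order", {
  set.seed(31)
  pad <- function(x, n = 50L) {
    paste0(x, substr(strrep("GTCA", 20), 1, max(0, n - nchar(x))))
  }
  reads <- mk_reads(
    c(pad(paste0(rand_dna(24), AD)),                 # clean
      pad(paste0(rand_dna(24), AD)),                 # low quality (by qual below)
      pad(paste0(substr(cl$adapter5, 1, 12), rand_dna(20))), # 5' contaminant
      strrep("GTCA", 13),                            # wait, pads below
      pad(AD),                                       # no insert
      pad(paste0(strrep("A", 25), AD)),              # poly-A
      pad(paste0(rand_dna(15), AD)),                 # 15-nt insert: too short
      pad(paste0(rand_dna(40), AD))))                # 40-nt insert: too long
  reads$sequence[4] <- paste(rep("CTAG", 13), collapse = "") # no 3' adapter
  reads$sequence <- substr(reads$sequence, 1, 50)
  reads$quality <- strrep("I", nchar(reads$sequence))
  reads$quality[2] <- strrep("$", nchar(reads$sequence[2])) # Phred 3
  got <- classify_reads(reads, cl)$class
  expect_equal(got, c("clean", "low_quality", "adapter5_contaminant",
                      "no_adapter3", "no_insert", "polyA",
                      "length_out_of_range", "length_out_of_range"))
})

test_that("cleaning is conservative and exact against the planted manifest", {
  set.seed(32)
  cfg <- small_config()
  b <- build_genome(cfg, seed = 32)
  sim <- simulate_libraries(b, cfg, seed = 32)
  truth <- sim$manifest$cleaning_truth
  for (lib in c("control", "treated")) {
    res <- clean_reads(sim[[if (lib == "control") "control" else "treated"]],
                       cfg$cleaning)
    s <- res$stats
    tr <- truth[truth$library == lib, ]
    expect_equal(s$raw_reads, tr$raw_reads)
    expect_equal(s$clean_reads, tr$clean_reads)
    for (rule in c("low_quality", "adapter5_contaminant", "no_adapter3",
                   "no_insert", "polyA", "length_out_of_range")) {
      expect_equal(s[[rule]], tr[[rule]], label = paste(lib, rule))
    }
    # conservation: every raw read accounted for exactly once
    expect_equal(s$raw_reads, s$clean_reads + s$low_quality +
                   s$adapter5_contaminant + s$no_adapter3 + s$no_insert +
                   s$polyA + s$length_out_of_range)
    expect_equal(length(unique(res$clean$insert)), tr$unique_tags)
  }
})

test_that("re-cleaning cleaned inserts removes nothing (idempotence)", {
  set.seed(33)
  inserts <- vapply(1:50, function(i) {
    s <- rand_dna(sample(16:36, 1))
    while (grepl(substr(AD, 1, 6), s, fixed = TRUE)) s <- rand_dna(nchar(s))
    s
  }, "")
  again <- mk_reads(paste0(inserts, AD))
  res <- clean_reads(again, cl)
  expect_equal(res$stats$clean_reads, 50L)
  expect_equal(res$clean$insert, inserts)
})

test_that("empty input produces all-zero statistics", {
  res <- clean_reads(mk_reads(character(0)), cl)
  expect_equal(res$stats$raw_reads, 0L)
  expect_equal(res$stats$clean_reads, 0L)
})

test_that("tag collapsing preserves totals and orders deterministically", {
  tags <- collapse_tags(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAAT"),
                        c("ACGTACGTACGTACGTA"))
  expect_equal(nrow(tags), 2L)
  i <- which(tags$sequence == "ACGTACGTACGTACGTA")
  expect_equal(tags$count_control[i], 2L)
  expect_equal(tags$count_treated[i], 1L)
  expect_equal(tags$sequence, sort(tags$sequence))
  # disjoint inputs: as many tags as reads
  dj <- collapse_tags(c("AAAACCCCGGGGTTTTA"), c("CCCCGGGGTTTTAAAAC"))
  expect_equal(nrow(dj), 2L)
})

test_that("length histogram is count-weighted and conserves totals", {
  tags <- data.frame(tag_id = c("t1", "t2"),
                     sequence = c(strrep("ACGT", 5), strrep("AC", 12)),
                     count_control = c(5L, 2L), count_treated = c(0L, 3L))
  h <- length_distribution(tags)
  expect_equal(h$count[h$length == 20], 5L)
  expect_equal(h$count[h$length == 24], 5L)
  expect_equal(sum(h$count_control), sum(tags$count_control))
  expect_equal(sum(h$count_treated), sum(tags$count_treated))
})
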