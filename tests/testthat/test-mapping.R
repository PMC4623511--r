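test_that("planted tags map to their loci with the stated mismatch policy", {
  set.seed(41)
  g <- c(chrA = rand_dna(5000), chrB = rand_dna(4000))
  tag <- substr(g[["chrB"]], 1001, 1021) # 21-mer planted at [1000, 1021)
  mut3 <- tag
  for (p in c(3, 9, 15)) substr(mut3, p, p) <- chartr("ACGT", "GTAC", substr(mut3, p, p))
  tags <- data.frame(tag_id = c("t1", "t2"), sequence = c(tag, mut3),
                     stringsAsFactors = FALSE)
  res <- map_tags(tags, build_index(g))
  a1 <- res$alignments[res$alignments$tag_id == "t1", ]
  expect_true(any(a1$chrom == "chrB" & a1$start == 1000 & a1$strand == "+" &
                    a1$mismatches == 0))
  expect_equal(res$status$status, c("mapped", "unmapped"))
})

test_that("a tag at more loci than the copy cap is flagged over_copy_cap", {
  set.seed(42)
  unit <- rand_dna(21)
  g <- c(chr1 = paste(c(rbind(replicate(21, unit), replicate(21, rand_dna(30)))),
                      collapse = ""))
  tags <- data.frame(tag_id = "t1", sequence = unit, stringsAsFactors = FALSE)
  res <- map_tags(tags, build_index(g), max_hits = 20L)
  expect_equal(res$status$status, "over_copy_cap")
  expect_equal(nrow(res$alignments), 0L)
  expect_gte(res$status$n_hits, 21L)
  # the same tag passes under a raised cap
  res2 <- map_tags(tags, build_index(g), max_hits = 50L)
  expect_equal(res2$status$status, "mapped")
})

test_that("the seeded mapper equals a brute-force Hamming scan", {
  set.seed(43)
  g <- c(c1 = rand_dna(15000), c2 = rand_dna(8000))
  mk_tag <- function(i) {
    src <- g[[1 + i %% 2]]
    s <- sample(nchar(src) - 30, 1)
    tg <- substr(src, s, s + sample(16:24, 1))
    nmut <- sample(0:3, 1)
    for (p in sample(nchar(tg), nmut)) {
      substr(tg, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(tg, p, p)), 1)
    }
    tg
  }
  tags <- data.frame(tag_id = sprintf("t%02d", 1:25),
                     sequence = c(vapply(1:20, mk_tag, ""),
                                  vapply(1:5, function(i) rand_dna(20), "")),
                     stringsAsFactors = FALSE)
  tags <- tags[!duplicated(tags$sequence), ]
  bf <- map_tags_bruteforce(tags, g, 2L)
  fast <- map_tags(tags, build_index(g), 2L, max_hits = 10000L)$alignments
  expect_equal(fast, bf, ignore_attr = TRUE)
})

test_that("mapping is strand-symmetric", {
  set.seed(44)
  g <- c(chr = rand_dna(6000))
  grc <- c(chr = revcomp(g[["chr"]]))
  tags <- data.frame(tag_id = sprintf("t%d", 1:6),
                     sequence = vapply(1:6, function(i) {
                       s <- sample(5000, 1)
                       substr(g[["chr"]], s, s + 20)
                     }, ""), stringsAsFactors = FALSE)
  fwd <- map_tags(tags, build_index(g))$alignments
  tags_rc <- tags
  tags_rc$sequence <- revcomp(tags$sequence)
  rev <- map_tags(tags_rc, build_index(grc))$alignments
  L <- nchar(g[["chr"]])
  # an alignment of t at [s, e) on strand x corresponds to revcomp(t) on
  # revcomp(G) at [L - e, L - s) with the SAME strand label (reversing both
  # the tag and the genome cancels the orientation flip)
  rev_mapped_back <- data.frame(
    tag_id = rev$tag_id, chrom = rev$chrom,
    start = L - rev$end, end = L - rev$start,
    strand = rev$strand,
    mismatches = rev$mismatches, stringsAsFactors = FALSE)
  o <- function(d) d[order(d$tag_id, d$start, d$strand), c("tag_id", "start",
                                                           "end", "strand",
                                                           "mismatches")]
  expect_equal(o(rev_mapped_back), o(fwd), ignore_attr = TRUE)
})

test_that("index lookups return exactly the true seed positions", {
  set.seed(45)
  g <- c(chr = rand_dna(3000))
  idx <- build_index(g, seed_len = 12L)
  for (i in 1:5) {
    s <- sample(2900, 1)
    kmer <- substr(g[["chr"]], s, s + 11)
    hits <- index_lookup(idx, kmer)
    # brute-force positions of the 12-mer on both strands
    truth_f <- which(vapply(1:(3000 - 11), function(p)
      substr(g[["chr"]], p, p + 11) == kmer, TRUE)) - 1L
    truth_r <- which(vapply(1:(3000 - 11), function(p)
      substr(g[["chr"]], p, p + 11) == revcomp(kmer), TRUE)) - 1L
    expect_setequal(hits$start[hits$strand == "+"], truth_f)
    expect_setequal(hits$start[hits$strand == "-"], truth_r)
  }
  expect_error(build_index(g, seed_len = 17L), "<= 16")
})
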