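test_that("a verbatim precursor copy is found and validates as a hairpin", {
  set.seed(81)
  d <- design_hairpin(21, 0)
  tx <- data.frame(id = "tx1",
                   sequence = paste0(rand_dna(150), d$sequence, rand_dna(150)),
                   stringsAsFactors = FALSE)
  q <- data.frame(id = "q1-MI", sequence = d$sequence, stringsAsFactors = FALSE)
  hits <- search_homologs(q, tx, mature_of = c("q1-MI" = d$mature_seq))
  expect_gte(nrow(hits), 1L)
  top <- hits[which.max(hits$identity), ]
  expect_equal(top$identity, 1.0)
  expect_gte(top$coverage, 1.0)
  expect_equal(top$strand, "+")
  expect_true(top$validated)
  expect_equal(top$t_start, 150L)
})

test_that("absent queries yield no hits; empty transcriptomes are fine", {
  set.seed(82)
  q <- data.frame(id = "q", sequence = rand_dna(100), stringsAsFactors = FALSE)
  tx <- data.frame(id = "t", sequence = rand_dna(2000), stringsAsFactors = FALSE)
  expect_equal(nrow(search_homologs(q, tx)), 0L)
  expect_equal(nrow(search_homologs(
    q, data.frame(id = character(0), sequence = character(0)))), 0L)
})

test_that("mature-only queries are reported without hairpin validation", {
  set.seed(83)
  mat <- rand_dna(21)
  tx <- data.frame(id = "tx",
                   sequence = paste0(rand_dna(80), mat, rand_dna(80)),
                   stringsAsFactors = FALSE)
  q <- data.frame(id = "mat1", sequence = mat, stringsAsFactors = FALSE)
  hits <- search_homologs(q, tx)
  expect_gte(nrow(hits), 1L)
  expect_equal(unique(hits$query_kind), "mature_only")
  expect_false(any(hits$validated))
})

test_that("minus-strand homologs are found", {
  set.seed(84)
  d <- design_hairpin(21, 0)
  tx <- data.frame(id = "tx",
                   sequence = paste0(rand_dna(100), revcomp(d$sequence),
                                     rand_dna(100)), stringsAsFactors = FALSE)
  q <- data.frame(id = "q-MI", sequence = d$sequence, stringsAsFactors = FALSE)
  hits <- search_homologs(q, tx)
  expect_true(any(hits$strand == "-" & hits$identity == 1.0))
})

test_that("diverged copies above the identity floor are still recovered", {
  # oracle: any placement at >= 90% identity over >= 90% of the query must
  # be reported by the seeded search
  set.seed(85)
  q <- rand_dna(100)
  mut <- q
  for (p in sample(100, 8)) { # 92% identity
    substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(mut, p, p)), 1)
  }
  tx <- data.frame(id = "tx", sequence = paste0(rand_dna(60), mut, rand_dna(60)),
                   stringsAsFactors = FALSE)
  hits <- search_homologs(data.frame(id = "q", sequence = q),
                          tx)
  expect_gte(nrow(hits), 1L)
  expect_gte(max(hits$identity), 0.90)
  # far below the floor: not reported
  mut2 <- q
  for (p in sample(100, 30)) {
    substr(mut2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(mut2, p, p)), 1)
  }
  tx2 <- data.frame(id = "tx", sequence = paste0(rand_dna(60), mut2, rand_dna(60)),
                    stringsAsFactors = FALSE)
  hits2 <- search_homologs(data.frame(id = "q", sequence = q), tx2)
  expect_true(nrow(hits2) == 0L || all(hits2$coverage < 0.9 | hits2$identity >= 0.9))
})

test_that("the pipeline recovers the planted transcriptome homologs", {
  run <- get_default_run()
  hits <- read_run(run, "homology_hits.tsv")
  man <- read_run(run, "manifest_homologs.tsv")
  for (q in man$query) {
    h <- hits[hits$query == q & hits$identity == 1.0 & hits$validated, ]
    expect_gte(nrow(h), 1L, label = q)
  }
})
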