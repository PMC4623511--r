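perfect_site <- function(mirna) revcomp(mirna)

test_that("duplex scoring applies the penalty schema with seed weighting", {
  set.seed(101)
  mir <- "TGACAGAAGAGAGTGAGCACA" # 21 nt
  win <- perfect_site(mir)
  sd0 <- score_duplex(mir, win)
  expect_equal(sd0$expectation, 0.0)
  expect_equal(sd0$inhibition, "cleavage")

  # G:U wobble at miRNA position 15 (outside the seed): 0.5
  # pairing partner of position p sits at window index len - p (0-based)
  w1 <- win
  p <- 15
  mb <- substr(mir, p, p)
  wobbly <- c(A = NA, C = NA, G = "T", T = "G")[[mb]] # target base making G:U
  substr(w1, 21 - p + 1, 21 - p + 1) <- wobbly
  expect_equal(score_duplex(mir, w1)$expectation, 0.5)

  # mismatch at position 5 (seed): 1.0 x 2
  w2 <- win
  p <- 5
  mb <- substr(mir, p, p)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", mb), if (mb == "G") "T", if (mb == "T") "G"))[1]
  substr(w2, 21 - p + 1, 21 - p + 1) <- bad
  expect_equal(score_duplex(mir, w2)$expectation, 2.0)
})

test_that("expectation grows monotonically with accumulated edits", {
  set.seed(102)
  mir <- rand_dna(21)
  win <- perfect_site(mir)
  prev <- -1
  for (nmut in 0:4) {
    w <- win
    for (p in utils::head(c(3, 8, 12, 17), nmut)) {
      substr(w, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(w, p, p)), 1)
    }
    e <- score_duplex(mir, w)$expectation
    expect_gte(e, prev)
    prev <- e
  }
})

test_that("cleavage is predicted between the bases facing positions 10/11", {
  set.seed(103)
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tx <- data.frame(id = "tx", sequence = paste0(rand_dna(100), perfect_site(mir),
                                                rand_dna(100)))
  hits <- scan_transcriptome(data.frame(id = "miR", sequence = mir), tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$t_start, 100L)
  expect_equal(hits$expectation, 0)
  # site [100, 121): slice between transcript bases 110 and 111 (0-based),
  # i.e. inter-base coordinate 111
  expect_equal(hits$cleavage_site, 111L)
  expect_equal(predict_cleavage(hits[1, ]), 111L)

  # a 1-nt target bulge 5' of the slice site shifts the coordinate by 1
  site_bulged <- paste0(substr(perfect_site(mir), 1, 5), "A",
                        substr(perfect_site(mir), 6, 21))
  tx2 <- data.frame(id = "tx", sequence = paste0(rand_dna(100), site_bulged,
                                                 rand_dna(100)))
  hits2 <- scan_transcriptome(data.frame(id = "miR", sequence = mir), tx2)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$cleavage_site, 112L)

  # translation-mode hits have no cleavage coordinate
  wmid <- perfect_site(mir)
  p <- 10
  mb <- substr(mir, p, p)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", mb), if (mb == "G") "T", if (mb == "T") "G"))[1]
  substr(wmid, 21 - p + 1, 21 - p + 1) <- bad
  sd <- score_duplex(mir, wmid)
  expect_equal(sd$inhibition, "translation")
  expect_error(predict_cleavage(list(inhibition = "translation",
                                     cleavage_site = NA)), "undefined")
})

test_that("transcriptome scanning reports every window at or under cutoff", {
  set.seed(104)
  mirs <- data.frame(id = c("mA", "mB"),
                     sequence = c(rand_dna(21), rand_dna(22)))
  # two planted sites for different miRNAs on one transcript
  tx <- data.frame(id = "tx", sequence = paste0(
    rand_dna(60), perfect_site(mirs$sequence[1]), rand_dna(40),
    perfect_site(mirs$sequence[2]), rand_dna(60)))
  hits <- scan_transcriptome(mirs, tx)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$mirna, c("mA", "mB"))
  expect_true(all(hits$expectation == 0))
  # a random transcript with no complementary site yields nothing
  tx0 <- data.frame(id = "bg", sequence = rand_dna(600))
  expect_equal(nrow(scan_transcriptome(mirs, tx0)), 0L)
})

test_that("scanning equals an all-window brute-force scorer", {
  set.seed(105)
  cfg <- default_config()$targets
  mir <- rand_dna(20)
  site2 <- perfect_site(mir)
  substr(site2, 3, 3) <- "A"
  tx <- data.frame(id = "tx", sequence = paste0(
    rand_dna(40), perfect_site(mir), rand_dna(30), site2, rand_dna(40)))
  hits <- scan_transcriptome(data.frame(id = "m", sequence = mir), tx)
  # brute force: score every window of every admissible length
  L <- nchar(tx$sequence)
  best <- list()
  for (wl in (20 - cfg$len_delta):(20 + cfg$len_delta)) {
    for (s in 0:(L - wl)) {
      e <- score_duplex(mir, substr(tx$sequence, s + 1, s + wl), cfg)$expectation
      if (e <= cfg$expectation_cutoff) best[[length(best) + 1L]] <- c(s, s + wl, e)
    }
  }
  # every brute-force site must be covered by a reported hit with an
  # expectation at least as good
  for (b in best) {
    cover <- hits$t_start < b[2] & b[1] < hits$t_end
    expect_true(any(cover) && min(hits$expectation[cover]) <= b[3] + 1e-9)
  }
})

test_that("hypergeometric enrichment matches exact combinatorics and BH", {
  # closed-form: all 5 drawn genes carry the term
  go <- data.frame(gene = sprintf("g%02d", 1:5), term = "T1")
  res <- sea_enrichment(sprintf("g%02d", 1:5), sprintf("g%02d", 1:20), go)
  expect_equal(res$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  # universal term: p = 1
  go2 <- data.frame(gene = sprintf("g%02d", 1:20), term = "T1")
  res2 <- sea_enrichment(sprintf("g%02d", 1:5), sprintf("g%02d", 1:20), go2)
  expect_equal(res2$pvalue, 1.0)
  # random instances against the exact combinatorial sum
  set.seed(106)
  for (i in 1:20) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    bg <- sprintf("g%03d", 1:N)
    tg <- sample(bg, n)
    go3 <- data.frame(gene = sample(bg, K), term = "T")
    res3 <- sea_enrichment(tg, bg, go3)
    k <- length(intersect(go3$gene, tg))
    expect_equal(res3$pvalue, hyper_pvalue_exact(k, K, N, n), tolerance = 1e-10)
  }
  expect_error(sea_enrichment(c("g1", "zz"), c("g1", "g2"),
                              data.frame(gene = "g1", term = "T")),
               "absent from background")
})

test_that("Benjamini-Hochberg adjustment follows its definition", {
  # fdr_i = min over j >= i of p_(j) * m / j
  p <- c(0.01, 0.02, 0.9)
  expect_equal(stats::p.adjust(p, "BH"), c(0.03, 0.03, 0.9))
  go <- rbind(data.frame(gene = c("g1", "g2", "g3"), term = "A"),
              data.frame(gene = c("g1", "g2"), term = "B"),
              data.frame(gene = "g9", term = "C"))
  res <- sea_enrichment(c("g1", "g2", "g3"), sprintf("g%d", 1:9), go)
  expect_equal(res$fdr, stats::p.adjust(res$pvalue, "BH"), tolerance = 1e-12)
})
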