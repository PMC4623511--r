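mk_tagset <- function(seqs) {
  data.frame(tag_id = sprintf("t%03d", seq_along(seqs)), sequence = seqs,
             count_control = 1L, count_treated = 1L, stringsAsFactors = FALSE)
}

test_that("the priority rule assigns exactly one class per tag", {
  set.seed(71)
  rrna <- rand_dna(120)
  mrna <- rand_dna(400)
  intr <- rand_dna(200)
  reptc <- rand_dna(200)
  mature <- rand_dna(21)
  # a tag present in both the rRNA decoy and the intron reference
  both <- substr(rrna, 10, 33)
  intr2 <- paste0(substr(intr, 1, 50), both, substr(intr, 51, 200))
  refs <- list(
    genbank = data.frame(id = "rRNA_01", sequence = rrna),
    rfam = data.frame(id = "snoRNA_01", sequence = rand_dna(120)),
    repeats = data.frame(id = "repeat_1", sequence = reptc),
    exon = data.frame(id = "mRNA_1", sequence = paste0(mrna, mature)),
    intron = data.frame(id = "G1.introns", sequence = intr2))
  tags <- mk_tagset(c(both,              # rRNA + intron -> rRNA_etc
                      mature,            # known mature inside an exon -> known
                      substr(reptc, 5, 28),  # repeat
                      substr(mrna, 100, 123), # exon
                      substr(intr, 100, 123), # intron
                      rand_dna(24)))     # nothing -> unannotated
  ann <- classify_tags(tags, known_tag_ids = "t002", refs)
  expect_equal(ann$category, c("rRNA_etc", "known_miRNA", "repeat", "exon",
                               "intron", "unannotated"))
  expect_equal(ann$subcategory[1], "rRNA")
  expect_equal(ann$evidence[1], "genbank_like")
  # partition: every tag in exactly one class
  expect_equal(nrow(ann), nrow(tags))
  expect_false(any(is.na(ann$category)))
})

test_that("adding a lower-priority reference never reclassifies a tag", {
  set.seed(72)
  rrna <- rand_dna(120)
  tags <- mk_tagset(substr(rrna, 20, 42))
  refs0 <- list(genbank = data.frame(id = "rRNA_01", sequence = rrna),
                rfam = data.frame(id = character(0), sequence = character(0)),
                repeats = data.frame(id = character(0), sequence = character(0)),
                exon = data.frame(id = character(0), sequence = character(0)),
                intron = data.frame(id = character(0), sequence = character(0)))
  a0 <- classify_tags(tags, character(0), refs0)
  refs1 <- refs0
  refs1$exon <- data.frame(id = "mRNA_X", sequence = paste0(rand_dna(50), rrna))
  a1 <- classify_tags(tags, character(0), refs1)
  expect_equal(a0$category, a1$category)
})

test_that("known-miRNA matching tolerates 2 mismatches and 2-nt shifts only", {
  set.seed(73)
  d <- design_hairpin(21, 0)
  refs_m <- data.frame(id = "osa-miR999a", sequence = d$mature_seq)
  refs_p <- data.frame(id = "osa-miR999a-MI", sequence = d$sequence)
  mut <- function(s, n) {
    for (p in sample(5:15, n)) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }
  tags <- mk_tagset(c(d$mature_seq, mut(d$mature_seq, 2), mut(d$mature_seq, 3),
                      substr(d$mature_seq, 3, 23))) # 2-nt shifted variant
  got <- identify_known(tags, refs_m, refs_p)
  expect_true(all(c("t001", "t002") %in% got$tag_id))
  expect_false("t003" %in% got$tag_id)   # 3 mismatches: not a known miRNA
  expect_equal(unique(got$name), "oco-miR999a")
  expect_equal(unique(got$family), "miR999")
})

test_that("star species are detected and may exceed the mature in reads", {
  set.seed(74)
  d <- design_hairpin(21, 0)
  refs_m <- data.frame(id = "osa-miR166c", sequence = d$mature_seq)
  refs_p <- data.frame(id = "osa-miR166c-MI", sequence = d$sequence)
  tags <- data.frame(tag_id = c("t001", "t002"),
                     sequence = c(d$mature_seq, d$star_seq),
                     count_control = c(2L, 17092L), count_treated = c(1L, 900L),
                     stringsAsFactors = FALSE)
  got <- identify_known(tags, refs_m, refs_p)
  expect_equal(nrow(got), 2L)
  star <- got[got$is_star, ]
  expect_equal(star$count_control, 17092L) # reported as-is, no constraint
  expect_equal(got$arm[!got$is_star], d$arm)
  expect_true(star$arm != d$arm)
})

test_that("family names strip member letters and arm suffixes", {
  expect_equal(mirna_family(c("oco-miR169a", "oco-miR169g")),
               c("miR169", "miR169"))
  expect_equal(mirna_family("oco-miR166c-3p"), "miR166")
  expect_equal(mirna_family("osa-miR1432"), "miR1432")
  fams <- mirna_family(c("oco-miR169a", "oco-miR169g"))
  expect_equal(unname(table(fams)["miR169"]), 2L)
})
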