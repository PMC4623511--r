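#' Random DNA of a given length and GC content
#'
#' @param n sequence length.
#' @param gc expected G+C fraction.
#' @return A DNA string.
#' @export
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Design a hairpin precursor guaranteed to pass candidate evaluation
#'
#' Rejection-samples mature/loop/flank sequences through
#' [construct_hairpin()] until [evaluate_candidate()] accepts the folded
#' precursor with the intended mature interval and duplex-mismatch count.
#' The designed star carries the canonical 2-nt 3' overhang. With the same
#' RNG state the result is reproducible.
#'
#' @param mature_len mature length (within the 18-26 nt candidate range;
#'   references are typically 20-24).
#' @param duplex_mismatches designed mature/star mismatches; must not exceed
#'   the configured maximum.
#' @param loop_len terminal loop length.
#' @param arm arm carrying the mature.
#' @param config discovery thresholds (see [default_config()]).
#' @param forbidden character vector of motifs that must not occur in the
#'   precursor (e.g. adapter prefixes, so simulated reads trim cleanly).
#' @param max_attempts rejection-sampling bound; a parameter combination
#'   that keeps failing raises an error.
#' @return list `sequence` (DNA precursor), `mature`, `star` (0-based
#'   half-open), `arm`, `mature_seq`, `star_seq`, `candidate` (the
#'   accepting evaluation).
#' @export
design_hairpin <- function(mature_len = 21L, duplex_mismatches = 0L,
                           loop_len = 10L, arm = c("5p", "3p"),
                           config = default_config()$discovery,
                           forbidden = character(0), max_attempts = 60L) {
  arm <- match.arg(arm)
  if (duplex_mismatches > config$max_duplex_mismatch) {
    stop("duplex_mismatches (", duplex_mismatches,
         ") exceeds the configured maximum (", config$max_duplex_mismatch, ")")
  }
  if (mature_len < config$min_tag_len || mature_len > config$max_tag_len) {
    stop("mature_len outside the candidate length range")
  }
  if (mature_len - duplex_mismatches < config$min_paired) {
    stop("unattainable: ", mature_len, " nt mature with ", duplex_mismatches,
         " duplex mismatches cannot reach ", config$min_paired, " paired bases")
  }
  for (attempt in seq_len(max_attempts)) {
    mature <- rand_dna(mature_len, gc = 0.55)
    if (grepl("AAAA|TTTT", mature)) next # avoid near-homopolymer matures
    mm_pos <- if (duplex_mismatches > 0L) {
      pool <- seq(4L, mature_len - 5L)
      p <- sort(sample(pool, duplex_mismatches))
      if (duplex_mismatches > 1L && min(diff(p)) < 2L) next
      p
    } else integer(0)
    # flanks the same length the evaluator trims to, so the precursor judged
    # here is the precursor judged in situ
    hp <- construct_hairpin(mature, mm_pos,
                            loop_seq = rand_dna(loop_len, gc = 0.25),
                            flank5 = rand_dna(config$flank, gc = 0.3),
                            flank3 = rand_dna(config$flank, gc = 0.3),
                            arm = arm)
    if (length(forbidden) > 0L &&
        any(vapply(forbidden, function(f) grepl(f, hp$sequence, fixed = TRUE), TRUE))) next
    cand <- evaluate_candidate(hp$sequence, hp$mature[1],
                               mature_len, config)
    if (cand$verdict != "ACCEPT") next
    if (cand$duplex_mismatches != duplex_mismatches) next
    if (is.null(cand$star)) next
    star_abs <- cand$star + cand$prec_offset
    star_seq <- substr(hp$sequence, star_abs[1] + 1L, star_abs[2])
    if (nchar(gsub("[^A]", "", star_seq)) / nchar(star_seq) >= 0.8) next
    if (length(forbidden) > 0L &&
        any(vapply(forbidden, function(f) grepl(f, star_seq, fixed = TRUE), TRUE))) next
    return(list(sequence = hp$sequence, mature = hp$mature, star = star_abs,
                arm = arm, mature_seq = mature, star_seq = star_seq,
                candidate = cand))
  }
  stop("design_hairpin: no accepted precursor after ", max_attempts,
       " attempts (parameter combination may be unattainable)")
}

#' Design a hairpin precursor with an exact A+U fraction
#'
#' Builds a 100-nt precursor (20-nt flanks, 21-nt mature, 16-nt loop) whose
#' base composition hits the requested A+U fraction exactly, and
#' rejection-samples until every candidate criterion other than the
#' composition window itself is satisfied. Used to probe the 30-70% A+U
#' acceptance boundary in isolation; the MFEI floor is disabled in the
#' supplied config for the same reason.
#'
#' @param au_fraction target A+U fraction; `au_fraction * 100` must be an
#'   integer.
#' @param config discovery thresholds; evaluation runs against these.
#' @param max_attempts rejection-sampling bound.
#' @return The accepting-or-composition-rejected `PrecursorCandidate`.
#' @export
make_au_candidate <- function(au_fraction, config = default_config()$discovery,
                              max_attempts = 300L) {
  target <- au_fraction * 100
  stopifnot(abs(target - round(target)) < 1e-9)
  target <- as.integer(round(target))
  exact_seq <- function(len, n_au) {
    stopifnot(n_au >= 0L, n_au <= len)
    b <- c(sample(c("A", "T"), n_au, replace = TRUE),
           sample(c("G", "C"), len - n_au, replace = TRUE))
    paste(sample(b), collapse = "")
  }
  au_m <- max(5L, min(15L, round(au_fraction * 21)))
  rem <- target - 2L * au_m - 1L # complement arm mirrors the mature; CA has one A
  au_l <- max(0L, min(16L, rem - 24L))
  au_f <- rem - au_l
  stopifnot(au_f >= 0L, au_f <= 40L)
  for (k in seq_len(max_attempts)) {
    mature <- exact_seq(21L, au_m)
    au_f5 <- sample(max(0L, au_f - 20L):min(20L, au_f), 1L)
    hp <- construct_hairpin(mature, loop_seq = exact_seq(16L, au_l),
                            flank5 = exact_seq(20L, au_f5),
                            flank3 = exact_seq(20L, au_f - au_f5))
    cand <- evaluate_candidate(hp$sequence, hp$mature[1], 21L, config)
    if (nchar(cand$precursor) == nchar(hp$sequence) &&
        length(setdiff(cand$rejection_reasons, "au_out_of_range")) == 0L) {
      return(cand)
    }
  }
  stop("make_au_candidate: no candidate met the non-composition criteria")
}

.known_family_defs <- c(
  "miR166c", "miR169a", "miR169g", "miR156a", "miR160b", "miR164e",
  "miR168b", "miR171f", "miR172d", "miR319a", "miR393a", "miR396c",
  "miR408", "miR528", "miR820a", "miR1432", "miR2118a", "miR444d")

#' Build a synthetic genome bundle with planted ground truth
#'
#' Generates random chromosomes and embeds, at recorded non-overlapping
#' loci: gene models (with UTRs, exons, introns), known miRNA hairpins
#' matching a miRBase-like reference set, novel hairpins that pass all
#' candidate criteria (at least one each in intergenic, intronic, exonic,
#' 5'UTR and 3'UTR context), decoy ncRNA loci for each cleaning/annotation
#' class, multi-copy repeats, and perfect/near-perfect target sites for a
#' subset of the known miRNAs inside transcript 3' exons. Per-miRNA expected
#' abundances and true log2 fold-changes (salt vs control) are assigned
#' here and recorded, together with everything else, in the ground-truth
#' manifest that downstream recovery tests treat as the oracle.
#'
#' The mRNA/intron annotation reference is deliberately restricted to a
#' subset of the genes (the ones not hosting novel hairpins), emulating the
#' incomplete heterologous transcript databases such studies annotate
#' against -- this is what lets exonic/UTR novel miRNAs survive annotation
#' and reach discovery, as they do in real data.
#'
#' @param config full configuration (the `synthetic` section drives sizes).
#' @param seed RNG seed.
#' @return list with `genome` (named chromosome vector), `models` (gene
#'   models), `refs` (reference sets: `mature`, `precursor`, `genbank`,
#'   `rfam`, `repeats`, `exon`, `intron`), `transcripts`, `go_map`, `ct`,
#'   and `manifest` (a `GroundTruthManifest`).
#' @export
build_genome <- function(config = default_config(), seed = config$seed) {
  set.seed(seed)
  syn <- config$synthetic
  if (syn$repeat_copies > config$mapping$max_hits) {
    stop("capacity error: repeat copy number (", syn$repeat_copies,
         ") exceeds the maximum copy number (", config$mapping$max_hits, ")")
  }
  forbidden <- c(substr(config$cleaning$adapter3, 1L, config$cleaning$adapter3_min_prefix),
                 substr(config$cleaning$adapter5, 1L, config$cleaning$adapter5_min_prefix))
  # an insert whose first bases near-match the 5' adapter head would be
  # eliminated as a 5'-primer contaminant; keep such sequences out of the
  # clean pool so the manifest's per-rule counts stay exact
  a5 <- strsplit(substr(config$cleaning$adapter5, 1L,
                        config$cleaning$adapter5_min_prefix), "")[[1]]
  insert_ok <- function(s) {
    h <- strsplit(substr(s, 1L, length(a5)), "")[[1]]
    length(h) < length(a5) ||
      sum(h != a5) > config$cleaning$adapter5_max_mm
  }

  chroms <- sprintf("chr%02d", seq_len(syn$n_chrom))
  genome <- stats::setNames(
    vapply(seq_len(syn$n_chrom), function(i) rand_dna(syn$chrom_len), ""),
    chroms)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)

  overlaps <- function(chrom, s, e, margin = 30L) {
    occ <- occupied[[chrom]]
    if (is.null(occ) || length(occ) == 0L) return(FALSE)
    any(vapply(occ, function(iv) s < iv[2] + margin && iv[1] - margin < e, TRUE))
  }
  claim <- function(chrom, s, e) {
    occupied[[chrom]][[length(occupied[[chrom]]) + 1L]] <<- c(s, e)
  }
  place <- function(len, max_attempts = 200L) {
    for (k in seq_len(max_attempts)) {
      chrom <- sample(chroms, 1L)
      s <- sample.int(syn$chrom_len - len - 1L, 1L) - 1L
      if (!overlaps(chrom, s, s + len)) {
        claim(chrom, s, s + len)
        return(list(chrom = chrom, start = s, end = s + len))
      }
    }
    stop("capacity error: genome too small to place all elements without overlap")
  }
  paint <- function(chrom, start, seq, strand = "+") {
    if (strand == "-") seq <- revcomp(seq)
    substring(genome[[chrom]], start + 1L, start + nchar(seq)) <<- seq
    invisible(NULL)
  }

  # ---- gene models (all plus-strand; layout utr5|cds1 . cds2 . cds3|utr3)
  utr_len <- 100L; cds1 <- 150L; cds2 <- 250L; cds3 <- 150L; intr <- 150L
  gene_len <- utr_len + cds1 + intr + cds2 + intr + cds3 + utr_len
  models <- list()
  for (g in seq_len(syn$n_genes)) {
    loc <- place(gene_len)
    s <- loc$start
    e1 <- c(s, s + utr_len + cds1)
    e2 <- c(e1[2] + intr, e1[2] + intr + cds2)
    e3 <- c(e2[2] + intr, e2[2] + intr + cds3 + utr_len)
    gid <- sprintf("G%03d", g)
    models[[g]] <- list(
      gene_id = gid, mrna_id = paste0(gid, ".1"), chrom = loc$chrom,
      strand = "+",
      exons = cbind(start = c(e1[1], e2[1], e3[1]), end = c(e1[2], e2[2], e3[2])),
      cds = cbind(start = c(e1[1] + utr_len, e2[1], e3[1]),
                  end = c(e1[2], e2[2], e3[1] + cds3)),
      utr5 = cbind(start = e1[1], end = e1[1] + utr_len),
      utr3 = cbind(start = e3[2] - utr_len, end = e3[2]),
      introns = cbind(start = c(e1[2], e2[2]), end = c(e2[1], e3[1])))
  }

  place_inside <- function(iv, chrom, len) {
    # place within a host feature interval (host gene already claimed)
    stopifnot(iv[2] - iv[1] >= len + 4L)
    s <- iv[1] + sample.int(iv[2] - iv[1] - len - 3L, 1L) + 1L
    list(chrom = chrom, start = s, end = s + len)
  }

  # ---- known miRNA hairpins + miRBase-like reference sets
  n_known <- syn$n_known
  fams <- .known_family_defs[seq_len(n_known)]
  known_len <- rep(c(21L, 24L, 24L, 21L, 22L, 24L, 20L, 23L), length.out = n_known)
  if (n_known > 0L) known_len[1] <- 21L # the high-star exemplar
  known <- list()
  design_clean <- function(...) {
    for (k in 1:40) {
      hp <- design_hairpin(..., config = config$discovery,
                           forbidden = forbidden, max_attempts = 150L)
      if (insert_ok(hp$mature_seq) && insert_ok(hp$star_seq)) return(hp)
    }
    stop("could not design a hairpin with clean-trimming mature/star")
  }
  for (i in seq_len(n_known)) {
    hp <- design_clean(known_len[i], duplex_mismatches = sample(0:1, 1L),
                       arm = sample(c("5p", "3p"), 1L))
    loc <- place(nchar(hp$sequence))
    strand <- sample(c("+", "-"), 1L)
    paint(loc$chrom, loc$start, hp$sequence, strand)
    known[[i]] <- data.frame(
      ref_name = paste0("osa-", fams[i]),
      family = sub("[a-z]$", "", fams[i]),
      mature_seq = hp$mature_seq, star_seq = hp$star_seq,
      precursor_seq = hp$sequence,
      chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
      arm = hp$arm, stringsAsFactors = FALSE)
  }
  empty_known <- data.frame(
    ref_name = character(0), family = character(0), mature_seq = character(0),
    star_seq = character(0), precursor_seq = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    arm = character(0), stringsAsFactors = FALSE)
  known <- if (length(known) > 0L) do.call(rbind, known) else empty_known

  # ---- novel hairpins with all genomic contexts represented
  n_novel <- syn$n_novel
  novel_len <- rep(c(21L, 24L, 22L, 21L, 24L, 21L, 23L, 20L, 21L, 24L),
                   length.out = n_novel)
  host_genes <- sample(seq_len(syn$n_genes), min(4L, n_novel))
  contexts <- if (n_novel >= 4L) {
    c("intronic", "exonic", "5'UTR", "3'UTR", rep("intergenic", n_novel - 4L))
  } else {
    utils::head(c("intronic", "exonic", "5'UTR", "3'UTR"), n_novel)
  }
  novel <- list()
  for (i in seq_len(n_novel)) {
    mm_max <- min(config$discovery$max_duplex_mismatch,
                  novel_len[i] - config$discovery$min_paired)
    hp <- design_clean(novel_len[i], duplex_mismatches = sample(0:mm_max, 1L),
                       arm = sample(c("5p", "3p"), 1L))
    plen <- nchar(hp$sequence)
    ctx <- contexts[i]
    if (ctx == "intergenic") {
      loc <- place(plen)
      strand <- sample(c("+", "-"), 1L)
    } else {
      m <- models[[host_genes[match(ctx, c("intronic", "exonic", "5'UTR", "3'UTR"))]]]
      iv <- switch(ctx,
                   "intronic" = m$introns[1, ],
                   "exonic" = m$cds[2, ],
                   "5'UTR" = m$utr5[1, ],
                   "3'UTR" = m$utr3[1, ])
      loc <- place_inside(c(iv[1], iv[2]), m$chrom, plen)
      strand <- "+"
    }
    paint(loc$chrom, loc$start, hp$sequence, strand)
    novel[[i]] <- data.frame(
      true_name = sprintf("novel%02d", i),
      mature_seq = hp$mature_seq, star_seq = hp$star_seq,
      precursor_seq = hp$sequence,
      chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
      arm = hp$arm, context = ctx, stringsAsFactors = FALSE)
  }
  novel <- if (length(novel) > 0L) do.call(rbind, novel) else data.frame(
    true_name = character(0), mature_seq = character(0),
    star_seq = character(0), precursor_seq = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), arm = character(0), context = character(0),
    stringsAsFactors = FALSE)

  # ---- decoy ncRNA loci
  decoy_classes_gb <- rep(c("rRNA", "tRNA"), length.out = syn$n_decoys_genbank)
  decoy_classes_rf <- rep(c("snoRNA", "snRNA", "scRNA"), length.out = syn$n_decoys_rfam)
  make_decoys <- function(classes, source) {
    out <- list()
    for (i in seq_along(classes)) {
      len <- if (classes[i] == "tRNA") 75L else 120L
      seq <- rand_dna(len)
      while (any(vapply(forbidden, function(f) grepl(f, seq, fixed = TRUE), TRUE))) {
        seq <- rand_dna(len)
      }
      loc <- place(len)
      strand <- sample(c("+", "-"), 1L)
      paint(loc$chrom, loc$start, seq, strand)
      out[[i]] <- data.frame(
        ref_id = sprintf("%s_%02d", classes[i], i), class = classes[i],
        source = source, sequence = seq, chrom = loc$chrom,
        start = loc$start, end = loc$end, strand = strand,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  decoys <- rbind(make_decoys(decoy_classes_gb, "genbank_like"),
                  make_decoys(decoy_classes_rf, "rfam_like"))

  # ---- repeats (one consensus, several copies; >1 and <= copy cap)
  repeats <- list()
  for (r in seq_len(syn$n_repeats)) {
    cons <- rand_dna(200L)
    while (any(vapply(forbidden, function(f) grepl(f, cons, fixed = TRUE), TRUE))) {
      cons <- rand_dna(200L)
    }
    for (cp in seq_len(syn$repeat_copies)) {
      loc <- place(200L)
      strand <- sample(c("+", "-"), 1L)
      paint(loc$chrom, loc$start, cons, strand)
      repeats[[length(repeats) + 1L]] <- data.frame(
        family = sprintf("repeat_%d", r), copy = cp, sequence = cons,
        chrom = loc$chrom, start = loc$start, end = loc$end,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  repeats <- do.call(rbind, repeats)

  # ---- target sites inside 3'-most exons: perfect for known miRNAs,
  #      3 non-seed mismatches for two novel miRNAs (so the site itself
  #      is invisible to the <=2-mismatch genome mapper)
  target_hosts <- setdiff(seq_len(syn$n_genes), host_genes)
  target_defs <- list()
  tg_known <- if (n_known >= 2L) {
    seq_len(min(4L, n_known - 1L)) + 1L # skip the low-count exemplar
  } else integer(0)
  for (j in seq_along(tg_known)) {
    g <- target_hosts[j]
    mat <- known$mature_seq[tg_known[j]]
    site <- revcomp(mat)
    m <- models[[g]]
    iv <- c(m$cds[3, 1] + 10L, m$cds[3, 1] + 10L + nchar(site))
    paint(m$chrom, iv[1], site, "+")
    target_defs[[length(target_defs) + 1L]] <- data.frame(
      mirna_ref = known$ref_name[tg_known[j]], kind = "known",
      gene_id = m$gene_id, chrom = m$chrom, start = iv[1], end = iv[2],
      mismatches = 0L, stringsAsFactors = FALSE)
  }
  for (j in seq_len(if (n_novel >= 6L) 2L else 0L)) {
    g <- target_hosts[length(tg_known) + j]
    mat <- novel$mature_seq[4L + j]
    site <- strsplit(revcomp(mat), "")[[1]]
    # mutate the target bases opposite miRNA positions 15/17/19 (non-seed)
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    for (p in c(15L, 17L, 19L)) {
      idx <- nchar(mat) - p + 1L
      site[idx] <- flip[[site[idx]]]
    }
    site <- paste(site, collapse = "")
    m <- models[[g]]
    iv <- c(m$cds[3, 1] + 10L, m$cds[3, 1] + 10L + nchar(site))
    paint(m$chrom, iv[1], site, "+")
    target_defs[[length(target_defs) + 1L]] <- data.frame(
      mirna_ref = novel$true_name[4L + j], kind = "novel",
      gene_id = m$gene_id, chrom = m$chrom, start = iv[1], end = iv[2],
      mismatches = 3L, stringsAsFactors = FALSE)
  }
  target_defs <- if (length(target_defs) > 0L) do.call(rbind, target_defs) else
    data.frame(mirna_ref = character(0), kind = character(0),
               gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), mismatches = integer(0),
               stringsAsFactors = FALSE)

  # ---- homolog copies: a few known precursors embedded verbatim in coding
  #      exons, so transcriptome homology search has true positives
  homolog_defs <- list()
  hom_known <- if (n_known >= 3L) seq(max(1L, n_known - 4L), n_known - 2L) else integer(0)
  for (j in seq_along(hom_known)) {
    g <- target_hosts[length(tg_known) + 2L + j]
    if (is.na(g)) break
    prec <- known$precursor_seq[hom_known[j]]
    m <- models[[g]]
    iv <- c(m$cds[2, 1] + 10L, m$cds[2, 1] + 10L + nchar(prec))
    paint(m$chrom, iv[1], prec, "+")
    homolog_defs[[length(homolog_defs) + 1L]] <- data.frame(
      query = paste0(known$ref_name[hom_known[j]], "-MI"),
      gene_id = m$gene_id, chrom = m$chrom, start = iv[1], end = iv[2],
      stringsAsFactors = FALSE)
  }
  homolog_defs <- if (length(homolog_defs) > 0L) do.call(rbind, homolog_defs) else
    data.frame(query = character(0), gene_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)

  # ---- transcripts (spliced exons, after painting)
  transcripts <- do.call(rbind, lapply(models, function(m) {
    seq <- paste(vapply(seq_len(nrow(m$exons)), function(k) {
      substr(genome[[m$chrom]], m$exons[k, 1] + 1L, m$exons[k, 2])
    }, ""), collapse = "")
    data.frame(id = m$mrna_id, gene_id = m$gene_id, sequence = seq,
               stringsAsFactors = FALSE)
  }))
  # transcript coordinates of the planted sites (all sit in the last exon)
  if (nrow(target_defs) > 0L) target_defs$tstart <- NA_integer_
  for (k in seq_len(nrow(target_defs))) {
    m <- models[[match(target_defs$gene_id[k], vapply(models, `[[`, "", "gene_id"))]]
    before <- sum(pmin(m$exons[, 2], target_defs$start[k]) -
                    pmin(m$exons[, 1], target_defs$start[k]))
    target_defs$tstart[k] <- before
    target_defs$tend[k] <- before + (target_defs$end[k] - target_defs$start[k])
  }
  target_defs$transcript <- transcripts$id[match(target_defs$gene_id, transcripts$gene_id)]

  # ---- abundance profile and true fold-changes: after the low-count
  #      exemplar, blocks of up- (x4) and down- (/4) regulated miRNAs with
  #      the larger expected count at 200 reads, the rest neutral
  lam_profile <- function(n, lead = 0L) {
    n_up <- min(4L, max(0L, n - lead))
    n_dn <- min(4L, max(0L, n - lead - n_up))
    n_rest <- n - lead - n_up - n_dn
    list(control = c(rep(2, lead), rep(50, n_up), rep(200, n_dn), rep(30, n_rest)),
         treated = c(rep(2, lead), rep(200, n_up), rep(50, n_dn), rep(30, n_rest)))
  }
  kp <- lam_profile(n_known, lead = min(1L, n_known))
  known$lambda_control <- kp$control
  known$lambda_treated <- kp$treated
  known$star_lambda <- pmax(1, round(0.08 * known$lambda_control))
  if (n_known > 0L) known$star_lambda[1] <- 800 # star far above its mature
  known$log2fc <- log2(known$lambda_treated / known$lambda_control)
  np <- lam_profile(n_novel)
  novel$lambda_control <- np$control
  novel$lambda_treated <- np$treated
  novel$star_lambda <- pmax(1, round(0.08 * novel$lambda_control))
  novel$log2fc <- log2(novel$lambda_treated / novel$lambda_control)

  # ---- background tags: mostly 24-mers, then 21-mers, drawn from decoy,
  #      repeat, annotated-gene and intergenic loci
  annotated_genes <- setdiff(seq_len(syn$n_genes), host_genes)
  sample_frag <- function(src, len) {
    for (k in 1:60) {
      if (nchar(src) < len + 1L) return(NA_character_)
      s <- sample.int(nchar(src) - len, 1L)
      fr <- substr(src, s, s + len - 1L)
      if (any(vapply(forbidden, function(f) grepl(f, fr, fixed = TRUE), TRUE))) next
      if (nchar(gsub("[^A]", "", fr)) / len >= 0.8) next
      if (grepl("N", fr)) next
      if (!insert_ok(fr)) next
      return(fr)
    }
    NA_character_
  }
  bg_len_pool <- function(n) {
    sample(c(rep(24L, 55), rep(21L, 20), rep(22L, 5), rep(23L, 5),
             16:20, 25:30), n, replace = TRUE)
  }
  exon_seq_of <- function(g) transcripts$sequence[g]
  intron_seq_of <- function(g) {
    m <- models[[g]]
    paste(vapply(seq_len(nrow(m$introns)), function(k) {
      substr(genome[[m$chrom]], m$introns[k, 1] + 1L, m$introns[k, 2])
    }, ""), collapse = "")
  }
  n_bg <- syn$n_background
  alloc <- c(decoy = round(0.45 * n_bg), exon = round(0.15 * n_bg),
             intron = round(0.15 * n_bg), repeat_ = round(0.10 * n_bg))
  alloc <- c(alloc, unannotated = max(0L, min(syn$n_unannotated_bg,
                                              n_bg - sum(alloc))))
  bg <- list()
  add_bg <- function(class, src_fun, n) {
    lens <- bg_len_pool(n)
    for (k in seq_len(n)) {
      fr <- sample_frag(src_fun(), lens[k])
      if (is.na(fr)) next
      bg[[length(bg) + 1L]] <<- data.frame(
        sequence = fr, source = class, stringsAsFactors = FALSE)
    }
  }
  add_bg("rRNA_etc", function() sample(decoys$sequence, 1L), alloc["decoy"])
  pick_gene <- function() annotated_genes[sample.int(length(annotated_genes), 1L)]
  add_bg("exon", function() exon_seq_of(pick_gene()), alloc["exon"])
  add_bg("intron", function() intron_seq_of(pick_gene()), alloc["intron"])
  add_bg("repeat", function() sample(unique(repeats$sequence), 1L), alloc["repeat_"])
  add_bg("unannotated", function() {
    ch <- sample(chroms, 1L)
    # an unclaimed intergenic stretch
    for (k in 1:40) {
      s <- sample.int(syn$chrom_len - 60L, 1L)
      if (!overlaps(ch, s, s + 40L, margin = 5L)) {
        return(substr(genome[[ch]], s, s + 39L))
      }
    }
    substr(genome[[ch]], 1L, 40L)
  }, alloc["unannotated"])
  bg <- do.call(rbind, bg)
  bg <- bg[!duplicated(bg$sequence), , drop = FALSE]
  bg <- bg[!(bg$sequence %in% c(known$mature_seq, known$star_seq,
                                novel$mature_seq, novel$star_seq)), , drop = FALSE]
  bg$lambda_control <- pmax(1, stats::rpois(nrow(bg), 12))
  bg$lambda_treated <- pmax(1, stats::rpois(nrow(bg), 12))

  # calibrate background 24-mers so the clean-read length mode is 24 nt
  # with the 21 nt class second (a stated property of the libraries)
  lens_all <- c(nchar(known$mature_seq), nchar(known$star_seq),
                nchar(novel$mature_seq), nchar(novel$star_seq), nchar(bg$sequence))
  lam_all <- c(known$lambda_control + known$lambda_treated,
               2 * known$star_lambda,
               novel$lambda_control + novel$lambda_treated,
               2 * novel$star_lambda,
               bg$lambda_control + bg$lambda_treated)
  mass <- function(L) sum(lam_all[lens_all == L])
  is24 <- nchar(bg$sequence) == 24L
  other_max <- max(vapply(setdiff(16:36, c(21L, 24L)), mass, 0))
  need21 <- max(0, 1.4 * other_max - mass(21L))
  if (need21 > 0) {
    is21 <- nchar(bg$sequence) == 21L
    bump <- ceiling(need21 / max(1L, sum(is21)) / 2)
    bg$lambda_control[is21] <- bg$lambda_control[is21] + bump
    bg$lambda_treated[is21] <- bg$lambda_treated[is21] + bump
    lam_all <- c(known$lambda_control + known$lambda_treated, 2 * known$star_lambda,
                 novel$lambda_control + novel$lambda_treated, 2 * novel$star_lambda,
                 bg$lambda_control + bg$lambda_treated)
  }
  need24 <- max(0, 1.3 * mass(21L) - mass(24L))
  bump <- ceiling(need24 / max(1L, sum(is24)) / 2)
  bg$lambda_control[is24] <- bg$lambda_control[is24] + bump
  bg$lambda_treated[is24] <- bg$lambda_treated[is24] + bump

  # ---- GO term map and qPCR Ct table
  go_terms <- data.frame(
    term = c("GO:0050896", "GO:0008152", "GO:0003677", "GO:0016301"),
    name = c("response to stimulus", "metabolic process", "DNA binding",
             "kinase activity"),
    ontology = c("BP", "BP", "MF", "MF"), stringsAsFactors = FALSE)
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  stress_genes <- unique(c(target_defs$gene_id, gene_ids[1]))
  go_map <- rbind(
    data.frame(gene = stress_genes, term = "GO:0050896", stringsAsFactors = FALSE),
    data.frame(gene = gene_ids[seq_len(ceiling(length(gene_ids) / 2))],
               term = "GO:0008152", stringsAsFactors = FALSE),
    data.frame(gene = gene_ids[c(2, 5, 8)], term = "GO:0003677",
               stringsAsFactors = FALSE),
    data.frame(gene = gene_ids[c(3, 6)], term = "GO:0016301",
               stringsAsFactors = FALSE))
  go_map <- merge(go_map, go_terms, by = "term")[, c("gene", "term", "name", "ontology")]
  go_map <- go_map[order(go_map$gene, go_map$term), ]

  ct_idx <- intersect(c(2L, 3L, 6L, 10L), seq_len(n_known))
  ct_mirnas <- known$ref_name[ct_idx]
  ct_fc <- known$log2fc[ct_idx]
  ct <- do.call(rbind, lapply(seq_along(ct_mirnas), function(i) {
    do.call(rbind, lapply(1:3, function(rep) {
      data.frame(
        target = rep(sub("osa", "oco", ct_mirnas[i]), 2),
        sample = c("control", "treated"),
        ct_target = c(25, 25 - ct_fc[i]) + stats::rnorm(2, 0, 0.05),
        ct_reference = c(15, 15) + stats::rnorm(2, 0, 0.05),
        replicate = rep, stringsAsFactors = FALSE)
    }))
  }))

  refs <- list(
    mature = data.frame(id = known$ref_name,
                        description = rep("mature", nrow(known)),
                        sequence = known$mature_seq, stringsAsFactors = FALSE),
    precursor = data.frame(id = if (nrow(known) > 0L)
                             paste0(known$ref_name, "-MI") else character(0),
                           description = rep("precursor", nrow(known)),
                           sequence = known$precursor_seq, stringsAsFactors = FALSE),
    genbank = data.frame(id = decoys$ref_id[decoys$source == "genbank_like"],
                         description = "",
                         sequence = decoys$sequence[decoys$source == "genbank_like"],
                         stringsAsFactors = FALSE),
    rfam = data.frame(id = decoys$ref_id[decoys$source == "rfam_like"],
                      description = "",
                      sequence = decoys$sequence[decoys$source == "rfam_like"],
                      stringsAsFactors = FALSE),
    repeats = data.frame(id = unique(repeats$family), description = "",
                         sequence = unique(repeats$sequence),
                         stringsAsFactors = FALSE),
    exon = data.frame(id = transcripts$id[annotated_genes],
                      description = "annotated mRNA",
                      sequence = transcripts$sequence[annotated_genes],
                      stringsAsFactors = FALSE),
    intron = data.frame(id = paste0(gene_ids[annotated_genes], ".introns"),
                        description = "annotated introns",
                        sequence = vapply(annotated_genes, intron_seq_of, ""),
                        stringsAsFactors = FALSE))

  manifest <- structure(list(
    seed = seed, known = known, novel = novel, decoys = decoys,
    repeats = repeats, background = bg, targets = target_defs,
    homologs = homolog_defs,
    go_terms = go_terms, ct_truth = data.frame(
      target = sub("osa", "oco", ct_mirnas), expected_rq = 2^ct_fc,
      stringsAsFactors = FALSE),
    contexts = contexts), class = "GroundTruthManifest")

  list(genome = genome, models = models, refs = refs,
       transcripts = transcripts, go_map = go_map, ct = ct,
       manifest = manifest)
}

.classify_one_read <- function(seq, qual, params) {
  classify_reads(data.frame(id = "r", sequence = seq, quality = qual,
                            stringsAsFactors = FALSE), params)
}

#' Simulate the two small-RNA libraries
#'
#' Emits reads as insert + 3' adapter + random fill, truncated to the read
#' length, with Poisson-distributed copy numbers around each planted tag's
#' expected abundance, uniform substitution sequencing errors at the
#' configured rate, and per-rule contaminant reads whose exact counts are
#' recorded in the manifest. Every emitted read is verified against the
#' cleaning rules it is meant to trigger (or survive), so the manifest
#' counts are exact by construction. Deterministic under a fixed seed.
#'
#' @param bundle output of [build_genome()].
#' @param config full configuration.
#' @param seed RNG seed.
#' @return list `control`, `treated` (FASTQ data.frames for [write_fastq()])
#'   and `manifest` (the input manifest extended with `cleaning_truth`,
#'   `library_truth` and per-miRNA realized counts).
#' @export
simulate_libraries <- function(bundle, config = default_config(),
                               seed = config$seed) {
  set.seed(seed + 1L)
  syn <- config$synthetic
  cl <- config$cleaning
  if (nchar(cl$adapter3) < 6L) stop("3' adapter shorter than 6 nt is untrimmable")
  man <- bundle$manifest
  read_len <- syn$read_len

  qual_hi <- function(n) {
    vapply(seq_len(n), function(i)
      rawToChar(as.raw(33L + sample(32:40, read_len, replace = TRUE))), "")
  }
  qual_lo <- function(n) {
    vapply(seq_len(n), function(i)
      rawToChar(as.raw(33L + sample(5:14, read_len, replace = TRUE))), "")
  }
  fill_to <- function(x) {
    pad <- read_len - nchar(x)
    vapply(seq_along(x), function(i) {
      if (pad[i] <= 0L) return(substr(x[i], 1L, read_len))
      paste0(x[i], rand_dna(pad[i]))
    }, "")
  }

  pool_block <- function(sequence, who, kind, lc, lt) {
    data.frame(sequence = sequence, who = rep_len(who, length(sequence)),
               kind = rep_len(kind, length(sequence)), lc = lc, lt = lt,
               stringsAsFactors = FALSE)
  }
  pool <- rbind(
    pool_block(man$known$mature_seq, man$known$ref_name, "known_mature",
               man$known$lambda_control, man$known$lambda_treated),
    pool_block(man$known$star_seq, paste0(man$known$ref_name, "*"),
               "known_star", man$known$star_lambda, man$known$star_lambda),
    pool_block(man$novel$mature_seq, man$novel$true_name, "novel_mature",
               man$novel$lambda_control, man$novel$lambda_treated),
    pool_block(man$novel$star_seq, paste0(man$novel$true_name, "*"),
               "novel_star", man$novel$star_lambda, man$novel$star_lambda),
    pool_block(man$background$sequence, NA_character_,
               paste0("bg_", man$background$source),
               man$background$lambda_control, man$background$lambda_treated))
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]

  make_library <- function(lambda) {
    counts <- stats::rpois(nrow(pool), lambda)
    inserts <- rep(pool$sequence, counts)
    reads <- fill_to(paste0(inserts, cl$adapter3))
    quals <- qual_hi(length(reads))
    # sequencing errors: uniform substitutions; a mutation that would change
    # the read's cleaning class is discarded (adapter read-through is clean)
    nerr <- stats::rbinom(length(reads), read_len, syn$error_rate)
    final_insert <- inserts
    for (i in which(nerr > 0L)) {
      r <- strsplit(reads[i], "")[[1]]
      posns <- sample.int(read_len, nerr[i])
      for (p in posns) r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1L)
      mutated <- paste(r, collapse = "")
      chk <- .classify_one_read(mutated, quals[i], cl)
      if (chk$class == "clean") {
        reads[i] <- mutated
        final_insert[i] <- chk$insert
      }
    }
    list(reads = reads, quals = quals, inserts = final_insert,
         planted = rep(pool$sequence, counts), counts = counts)
  }

  make_contaminants <- function(n_clean) {
    fr <- syn$contaminant_fracs
    ns <- stats::setNames(stats::rpois(length(fr), fr * n_clean), names(fr))
    gen <- list(
      low_quality = function() list(seq = fill_to(paste0(rand_dna(24L), cl$adapter3)),
                                    qual = qual_lo(1L)),
      adapter5_contaminant = function() list(
        seq = fill_to(paste0(substr(cl$adapter5, 1L, 26L), rand_dna(10L))),
        qual = qual_hi(1L)),
      no_adapter3 = function() list(seq = rand_dna(read_len), qual = qual_hi(1L)),
      no_insert = function() list(seq = fill_to(cl$adapter3), qual = qual_hi(1L)),
      polyA = function() list(seq = fill_to(paste0(strrep("A", 25L), cl$adapter3)),
                              qual = qual_hi(1L)),
      length_out_of_range = function() {
        len <- sample(c(10L, 40L), 1L)
        list(seq = fill_to(paste0(rand_dna(len), cl$adapter3)), qual = qual_hi(1L))
      })
    seqs <- character(0); quals <- character(0)
    for (rule in names(ns)) {
      made <- 0L
      guard <- 0L
      while (made < ns[[rule]]) {
        guard <- guard + 1L
        if (guard > 50L * (ns[[rule]] + 1L)) {
          stop("could not synthesize a read for cleaning rule ", rule)
        }
        g <- gen[[rule]]()
        if (.classify_one_read(g$seq, g$qual, cl)$class == rule) {
          seqs <- c(seqs, g$seq); quals <- c(quals, g$qual)
          made <- made + 1L
        }
      }
    }
    list(seqs = seqs, quals = quals, counts = ns)
  }

  build <- function(lambda, lib) {
    good <- make_library(lambda)
    bad <- make_contaminants(length(good$reads))
    seqs <- c(good$reads, bad$seqs)
    quals <- c(good$quals, bad$quals)
    ord <- sample.int(length(seqs))
    fq <- data.frame(
      id = sprintf("%s_r%06d", lib, seq_along(seqs)),
      sequence = seqs[ord], quality = quals[ord], stringsAsFactors = FALSE)
    list(fq = fq, clean_total = length(good$reads),
         unique_tags = length(unique(good$inserts)),
         contaminants = bad$counts, planted_counts = good$counts,
         inserts = good$inserts)
  }

  ctrl <- build(pool$lc, "ctl")
  trt <- build(pool$lt, "trt")

  man$cleaning_truth <- data.frame(
    library = c("control", "treated"),
    raw_reads = c(nrow(ctrl$fq), nrow(trt$fq)),
    rbind(ctrl$contaminants, trt$contaminants),
    clean_reads = c(ctrl$clean_total, trt$clean_total),
    unique_tags = c(length(unique(ctrl$inserts)), length(unique(trt$inserts))),
    stringsAsFactors = FALSE)
  man$library_truth <- data.frame(
    sequence = pool$sequence, who = pool$who, kind = pool$kind,
    lambda_control = pool$lc, lambda_treated = pool$lt,
    count_control = ctrl$planted_counts, count_treated = trt$planted_counts,
    stringsAsFactors = FALSE)

  list(control = ctrl$fq, treated = trt$fq, manifest = man)
}
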