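#' Derive the miRNA* interval from a precursor structure
#'
#' Given the mature interval on a folded precursor, the star is the set of
#' positions pairing with the mature, shifted 2 nt toward its own 3' end so
#' that both duplex strands carry the canonical 2-nt 3' overhang left by
#' Dicer. Works for matures on either arm; the mature must lie entirely on
#' one arm (no overlap with the terminal loop), otherwise the star is
#' undefined.
#'
#' @param mature integer c(start, end), 0-based half-open, in precursor
#'   coordinates.
#' @param db dot-bracket structure of the precursor.
#' @return list with `ok` (logical), `star` (0-based half-open interval or
#'   NULL), `arm` ("5p"/"3p"/NA) and `reason` (why the star is undefined).
#' @export
detect_star <- function(mature, db) {
  pt <- pair_table(db)
  n <- length(pt)
  a <- mature[1] + 1L; b <- mature[2] # 1-based inclusive a..b
  if (a < 1L || b > n || a > b) stop("mature interval outside precursor")
  partners <- pt[a:b]
  partners <- partners[partners > 0L]
  if (length(partners) == 0L) {
    return(list(ok = FALSE, star = NULL, arm = NA_character_,
                reason = "mature_unpaired"))
  }
  if (all(partners > b)) {
    arm <- "5p"
  } else if (all(partners < a)) {
    arm <- "3p"
  } else {
    return(list(ok = FALSE, star = NULL, arm = NA_character_,
                reason = "mature_spans_loop"))
  }
  # raw pairing footprint, then +2 shift = 3'-ward on the star strand for
  # either arm (both arms read 5'->3' in increasing precursor coordinates)
  star <- c(min(partners) - 1L + 2L, max(partners) + 2L)
  star[1] <- max(0L, star[1])
  star[2] <- min(n, star[2])
  if (star[2] - star[1] < 2L) {
    return(list(ok = FALSE, star = NULL, arm = arm, reason = "star_degenerate"))
  }
  list(ok = TRUE, star = star, arm = arm, reason = NA_character_)
}

#' Excise precursor candidate windows around unannotated tag alignments
#'
#' For every alignment two windows are excised: one with the tag at the 5'
#' end extending 3', one with the tag at the 3' end extending 5'. Each is
#' bounded by the tag plus the maximum mature-star distance plus the
#' precursor flank, and clipped at the chromosome edges. Windows are taken
#' from the alignment strand (minus-strand windows are reverse-complemented
#' and the tag offset mapped accordingly).
#'
#' @param alignments alignment rows (as from [map_tags()]) for the tags to
#'   consider; the caller restricts these to mapped, unannotated tags of
#'   18-26 nt.
#' @param genome named character vector of chromosome sequences.
#' @param flank precursor flank length (20 nt).
#' @param max_distance maximum mature-star distance (300 nt).
#' @return data.frame with `tag_id`, `chrom`, `win_start`, `win_end`,
#'   `strand`, `side` ("5p_extend"/"3p_extend"), `sequence` (window, DNA, on
#'   the alignment strand) and `mature_offset` (0-based tag start within the
#'   window sequence).
#' @export
excise_candidates <- function(alignments, genome, flank = 20L,
                              max_distance = 300L) {
  rows <- list()
  for (k in seq_len(nrow(alignments))) {
    al <- alignments[k, ]
    clen <- nchar(genome[[al$chrom]])
    wins <- list(
      c(max(0L, al$start - flank), min(clen, al$end + max_distance + flank), "5p_extend"),
      c(max(0L, al$start - max_distance - flank), min(clen, al$end + flank), "3p_extend")
    )
    for (w in wins) {
      ws <- as.integer(w[1]); we <- as.integer(w[2])
      seq <- substr(genome[[al$chrom]], ws + 1L, we)
      if (al$strand == "+") {
        off <- al$start - ws
      } else {
        seq <- revcomp(seq)
        off <- we - al$end
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = al$tag_id, chrom = al$chrom, win_start = ws, win_end = we,
        strand = al$strand, side = w[3], sequence = seq,
        mature_offset = off, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tag_id = character(0), chrom = character(0),
                      win_start = integer(0), win_end = integer(0),
                      strand = character(0), side = character(0),
                      sequence = character(0), mature_offset = integer(0)))
  }
  do.call(rbind, rows)
}

.rejection_reasons <- c(
  "tag_length_out_of_range", "no_hairpin", "mature_spans_loop",
  "star_undefined", "star_spans_loop", "star_broken",
  "duplex_mismatch_excess", "paired_below_min", "bulge_too_large",
  "asymmetry_too_large", "distance_too_large", "mfe_above_threshold",
  "au_out_of_range", "mfei_below_min")

.longest_run <- function(x) { # longest run of TRUE
  if (length(x) == 0L || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Evaluate a precursor candidate against the full criteria set
#'
#' Folds the window, locates the mature tag on one arm, derives the star,
#' trims the precursor to the mature-star span plus the configured flank,
#' refolds, and tests every acceptance criterion: stem-loop with the mature
#' on one arm; star without loop or break; duplex mismatches, paired bases,
#' largest bulge, asymmetry and mature-star distance within bounds; MFE at
#' or below the energy ceiling; A+U content within range; |MFEI| at or above
#' the floor. All tests run (no short-circuit); each failure appends its
#' distinct rejection reason, and the verdict is ACCEPT only when none fail.
#'
#' @param window window sequence (DNA, alignment strand).
#' @param mature_offset 0-based start of the mature tag within `window`.
#' @param mature_len mature tag length.
#' @param config the `discovery` section of [default_config()].
#' @param fold_backend optional folding backend passed through to [fold()]
#'   (the pluggable-backend hook).
#' @return A `PrecursorCandidate`: list with the trimmed precursor sequence
#'   and offset, fold result, mature/star intervals (precursor coordinates),
#'   arm, duplex statistics, `mfe`, `mfei`, `au_fraction`, `verdict`
#'   ("ACCEPT"/"REJECT") and `rejection_reasons`.
#' @export
evaluate_candidate <- function(window, mature_offset, mature_len,
                               config = default_config()$discovery,
                               fold_backend = NULL) {
  reasons <- character(0)
  if (mature_len < config$min_tag_len || mature_len > config$max_tag_len) {
    reasons <- c(reasons, "tag_length_out_of_range")
  }
  precursor <- toupper(window)
  m_iv <- c(mature_offset, mature_offset + mature_len)
  prec_offset <- 0L
  fr <- fold(dna_to_rna(precursor), backend = fold_backend)
  st <- detect_star(m_iv, fr$structure)

  # trim to the mature-star span plus flank and refold: the precursor is the
  # extended hairpin, not the whole excision window
  if (st$ok) {
    lo <- max(0L, min(m_iv[1], st$star[1]) - config$flank)
    hi <- min(nchar(precursor), max(m_iv[2], st$star[2]) + config$flank)
    if (lo > 0L || hi < nchar(precursor)) {
      precursor <- substr(precursor, lo + 1L, hi)
      prec_offset <- lo
      m_iv <- m_iv - lo
      fr <- fold(dna_to_rna(precursor), backend = fold_backend)
      st <- detect_star(m_iv, fr$structure)
    }
  }

  n <- nchar(precursor)
  pt <- pair_table(fr$structure)
  a <- m_iv[1] + 1L; b <- m_iv[2]

  paired_bp <- sum(pt[a:b] > 0L)
  mm_duplex <- NA_integer_; bulge <- NA_integer_; asym <- NA_integer_
  distance <- NA_integer_
  if (!st$ok) {
    reasons <- c(reasons,
                 if (identical(st$reason, "mature_spans_loop")) "mature_spans_loop"
                 else "no_hairpin",
                 "star_undefined")
  } else {
    s_lo <- st$star[1] + 1L; s_hi <- st$star[2] # 1-based inclusive
    # criterion: star entirely on the opposite arm, no loop in between shared
    if (st$arm == "5p" && st$star[1] < m_iv[2]) reasons <- c(reasons, "star_spans_loop")
    if (st$arm == "3p" && st$star[2] > m_iv[1]) reasons <- c(reasons, "star_spans_loop")
    # star "break": a paired star-duplex position pairing outside the mature
    # star minus its 2-nt 3' overhang
    sd <- if (s_hi - 2L >= s_lo) s_lo:(s_hi - 2L) else integer(0)
    sd <- sd[sd >= 1L & sd <= n]
    sp <- pt[sd]
    if (any(sp > 0L & (sp < a - 2L | sp > b + 2L))) {
      reasons <- c(reasons, "star_broken")
    }
    # duplex statistics; the mature's 2-nt 3' overhang is outside the duplex
    md <- a:(b - 2L)
    mm_duplex <- sum(pt[md] == 0L)
    unpaired_star <- sum(pt[sd] == 0L)
    bulge <- max(.longest_run(pt[md] == 0L), .longest_run(pt[sd] == 0L))
    asym <- abs(mm_duplex - unpaired_star)
    distance <- if (st$arm == "5p") st$star[1] - m_iv[2] else m_iv[1] - st$star[2]
    distance <- max(0L, distance)
    if (mm_duplex > config$max_duplex_mismatch) reasons <- c(reasons, "duplex_mismatch_excess")
    if (paired_bp < config$min_paired) reasons <- c(reasons, "paired_below_min")
    if (bulge > config$max_bulge) reasons <- c(reasons, "bulge_too_large")
    if (asym > config$max_asymmetry) reasons <- c(reasons, "asymmetry_too_large")
    if (distance > config$max_distance) reasons <- c(reasons, "distance_too_large")
  }

  bases <- strsplit(precursor, "")[[1]]
  au <- mean(bases %in% c("A", "T", "U"))
  gc_pct <- 100 * mean(bases %in% c("G", "C"))
  mfei <- if (gc_pct > 0) (fr$mfe / n * 100) / gc_pct else 0
  if (fr$mfe > config$mfe_max) reasons <- c(reasons, "mfe_above_threshold")
  if (au < config$au_min || au > config$au_max) reasons <- c(reasons, "au_out_of_range")
  if (abs(mfei) < config$mfei_min) reasons <- c(reasons, "mfei_below_min")

  reasons <- unique(reasons)
  structure(list(
    precursor = precursor, prec_offset = prec_offset, fold = fr,
    mature = m_iv, star = if (st$ok) st$star else NULL, arm = st$arm,
    paired_bp = paired_bp, duplex_mismatches = mm_duplex,
    largest_bulge = bulge, asymmetry = asym, distance = distance,
    mfe = fr$mfe, mfei = mfei, au_fraction = au, gc_pct = gc_pct,
    verdict = if (length(reasons) == 0L) "ACCEPT" else "REJECT",
    rejection_reasons = reasons), class = "PrecursorCandidate")
}

#' Genomic context of an accepted precursor
#'
#' Classifies the precursor locus by majority overlap against the gene
#' models: 5'UTR, 3'UTR, exonic (CDS), intronic, with ties broken in that
#' order of precedence; no gene overlap at all means intergenic.
#'
#' @param chrom,start,end precursor locus (0-based half-open).
#' @param gene_models list of gene models from [read_gff3()].
#' @return One of "intergenic", "intronic", "exonic", "5'UTR", "3'UTR".
#' @export
classify_context <- function(chrom, start, end, gene_models) {
  q <- IRanges::IRanges(start + 1L, end)
  widths <- c(`5'UTR` = 0L, `3'UTR` = 0L, exonic = 0L, intronic = 0L)
  grab <- function(m, field) {
    mat <- m[[field]]
    if (nrow(mat) == 0L) return(0L)
    iv <- IRanges::IRanges(mat[, 1] + 1L, mat[, 2])
    sum(IRanges::width(IRanges::intersect(iv, q)))
  }
  for (m in gene_models) {
    if (m$chrom != chrom) next
    widths["5'UTR"] <- widths["5'UTR"] + grab(m, "utr5")
    widths["3'UTR"] <- widths["3'UTR"] + grab(m, "utr3")
    widths["exonic"] <- widths["exonic"] +
      grab(m, if (nrow(m$cds) > 0L) "cds" else "exons")
    widths["intronic"] <- widths["intronic"] + grab(m, "introns")
  }
  if (all(widths == 0L)) return("intergenic")
  # which.max takes the first maximum; the vector is already in precedence order
  names(widths)[which.max(widths)]
}

#' Name accepted novel miRNAs and merge duplicates
#'
#' Candidates with an identical mature sequence are merged (their per-library
#' counts summed over distinct tags). Precursor loci that overlap on the
#' same strand share one sequential number; two matures from the same
#' precursor are distinguished only by their -5p/-3p arm suffix. Ordering --
#' and therefore naming -- is deterministic by locus.
#'
#' @param accepted data.frame of accepted candidates with columns `tag_id`,
#'   `chrom`, `start`, `end`, `strand`, `arm`, `mature_seq`, `star_seq`,
#'   `precursor_seq`, `mfe`, `mfei`, `au_fraction`, `context`,
#'   `count_control`, `count_treated`.
#' @param prefix species-style name prefix.
#' @return data.frame with a `name` column (e.g. oco-miR001-5p), one row per
#'   distinct mature sequence.
#' @export
name_and_deduplicate <- function(accepted, prefix = "oco-miR") {
  if (nrow(accepted) == 0L) {
    accepted$name <- character(0)
    return(accepted)
  }
  # one row per mature sequence: first locus in (chrom, start) order wins
  accepted <- accepted[order(accepted$chrom, accepted$start, accepted$end), , drop = FALSE]
  merged <- do.call(rbind, lapply(split(accepted, accepted$mature_seq), function(g) {
    first <- g[1, , drop = FALSE]
    dd <- g[!duplicated(g$tag_id), , drop = FALSE]
    first$count_control <- sum(dd$count_control)
    first$count_treated <- sum(dd$count_treated)
    first
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$end), , drop = FALSE]
  # group overlapping same-strand precursor loci under one number
  group <- integer(nrow(merged))
  gid <- 0L
  for (i in seq_len(nrow(merged))) {
    assigned <- FALSE
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (merged$chrom[j] == merged$chrom[i] &&
            merged$strand[j] == merged$strand[i] &&
            merged$start[i] < merged$end[j] && merged$start[j] < merged$end[i]) {
          group[i] <- group[j]
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      gid <- gid + 1L
      group[i] <- gid
    }
  }
  merged$group <- group
  # collapse sequence variants: within one precursor group and arm, matures
  # within 2 mismatches / 2-nt end shifts of the most abundant mature are
  # the same species (sequencing-error and end-trimming isomiRs) and their
  # counts are absorbed by it
  collapsed <- do.call(rbind, lapply(
    split(merged, list(merged$group, merged$arm), drop = TRUE), function(g) {
      g <- g[order(-(g$count_control + g$count_treated), g$mature_seq), , drop = FALSE]
      reps <- list()
      for (i in seq_len(nrow(g))) {
        absorbed <- FALSE
        for (r in seq_along(reps)) {
          hit <- match_mature_cpp(g$mature_seq[i], reps[[r]]$mature_seq, 2L, 2L)
          if (hit$ref[1] > 0L) {
            reps[[r]]$count_control <- reps[[r]]$count_control + g$count_control[i]
            reps[[r]]$count_treated <- reps[[r]]$count_treated + g$count_treated[i]
            absorbed <- TRUE
            break
          }
        }
        if (!absorbed) reps[[length(reps) + 1L]] <- g[i, , drop = FALSE]
      }
      do.call(rbind, reps)
    }))
  collapsed <- collapsed[order(collapsed$group, collapsed$arm,
                               collapsed$start), , drop = FALSE]
  # renumber groups densely in locus order
  collapsed <- collapsed[order(collapsed$chrom, collapsed$start, collapsed$end), ,
                         drop = FALSE]
  collapsed$group <- match(collapsed$group, unique(collapsed$group))
  collapsed$name <- sprintf("%s%03d-%s", prefix, collapsed$group, collapsed$arm)
  dup <- duplicated(collapsed$name)
  if (any(dup)) { # genuinely distinct same-arm matures from one precursor
    collapsed$name[dup] <- paste0(collapsed$name[dup], ".",
                                  seq_len(sum(dup)) + 1L)
  }
  collapsed$group <- NULL
  rownames(collapsed) <- NULL
  collapsed
}

#' Construct a synthetic hairpin precursor around a given mature sequence
#'
#' Builds flank5 + mature + loop + complement-arm + flank3 (5p arm) or the
#' mirrored layout (3p arm), with the complement arm carrying designed
#' non-pairing substitutions at the requested mature positions and a 2-nt
#' extension so the star keeps its 3' overhang inside the precursor. This is
#' the deterministic construction layer under [design_hairpin()], exposed so
#' duplex geometry can be stipulated directly.
#'
#' @param mature mature sequence (DNA).
#' @param mismatch_pos 1-based mature positions whose star partner is
#'   mutated to a non-pairing base.
#' @param loop_seq terminal loop sequence.
#' @param flank5,flank3 flanking sequences.
#' @param arm which arm carries the mature.
#' @return list with `sequence` (DNA precursor) and `mature` (0-based
#'   half-open interval of the mature within it).
#' @export
construct_hairpin <- function(mature, mismatch_pos = integer(0),
                              loop_seq = "TTCTTTGGTC", flank5 = "ACGTAC",
                              flank3 = "GTACGT", arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  mature <- toupper(mature)
  m <- nchar(mature)
  comp <- strsplit(revcomp(mature), "")[[1]]
  # revcomp index pairing mature position i is m - i + 1
  nonpairing <- list(A = "C", C = "A", G = "A", T = "C")
  for (i in mismatch_pos) {
    stopifnot(i >= 1L, i <= m)
    mb <- substr(mature, i, i)
    comp[m - i + 1L] <- nonpairing[[mb]]
  }
  comp <- paste(comp, collapse = "")
  if (arm == "5p") {
    # 2-nt tail after the complement arm hosts the star 3' overhang
    seq <- paste0(flank5, mature, loop_seq, comp, "CA", flank3)
    mat <- c(nchar(flank5), nchar(flank5) + m)
  } else {
    seq <- paste0(flank5, "CA", comp, loop_seq, mature, flank3)
    mat <- c(nchar(flank5) + 2L + m + nchar(loop_seq),
             nchar(flank5) + 2L + m + nchar(loop_seq) + m)
  }
  list(sequence = seq, mature = mat)
}
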