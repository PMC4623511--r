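#' Match tags against a reference sequence set
#'
#' A tag "matches" a reference class when it aligns within a member sequence
#' with at most `max_mm` mismatches on either strand -- the same ungapped
#' matcher the genome mapper uses.
#'
#' @param tags character vector of tag sequences.
#' @param refs reference set (data.frame with `id`, `sequence`).
#' @param max_mm mismatch tolerance.
#' @return Character vector, per tag: the id of the first matching reference
#'   (in reference order) or NA.
#' @export
match_reference <- function(tags, refs, max_mm = 2L) {
  out <- rep(NA_character_, length(tags))
  if (length(tags) == 0L || nrow(refs) == 0L) return(out)
  hits <- map_scan_cpp(refs$sequence, tags, as.integer(max_mm))
  if (nrow(hits) == 0L) return(out)
  first <- tapply(hits$chrom, hits$tag, min)
  idx <- as.integer(names(first))
  out[idx] <- refs$id[first]
  out
}

#' Identify known miRNAs (and their stars) among the tags
#'
#' A tag is a known mature miRNA if it matches a reference mature sequence
#' with at most `max_mm` mismatches and end shifts of at most `max_shift`
#' nt. Reference precursors are folded once to derive each reference star
#' (canonical 2-nt 3' overhang); tags matching a star the same way are
#' reported as miRNA* species. Mature matches take precedence over star
#' matches. Star counts may exceed mature counts; both are reported as-is.
#'
#' @param tags tag set from [collapse_tags()].
#' @param mature_refs,precursor_refs reference data.frames (`id`,
#'   `sequence`); precursor ids are expected to be the mature id plus a
#'   suffix. A precursor whose mature cannot be located is skipped with a
#'   warning.
#' @param config the `annotation` section of [default_config()].
#' @param rename_prefix optional c(from, to) species-prefix substitution for
#'   reported names (reference rice names become this species' names).
#' @return data.frame `tag_id`, `sequence`, `name`, `family`, `arm`,
#'   `is_star`, `count_control`, `count_treated`.
#' @export
identify_known <- function(tags, mature_refs, precursor_refs = NULL,
                           config = default_config()$annotation,
                           rename_prefix = c("osa-", "oco-")) {
  empty <- data.frame(tag_id = character(0), sequence = character(0),
                      name = character(0), family = character(0),
                      arm = character(0), is_star = logical(0),
                      count_control = integer(0), count_treated = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(tags) == 0L || nrow(mature_refs) == 0L) return(empty)

  # arm and star of each reference, from its folded precursor
  ref_arm <- rep(NA_character_, nrow(mature_refs))
  star_seq <- rep(NA_character_, nrow(mature_refs))
  if (!is.null(precursor_refs)) {
    for (i in seq_len(nrow(mature_refs))) {
      pid <- grep(paste0("^", mature_refs$id[i]), precursor_refs$id)
      if (length(pid) == 0L) next
      prec <- precursor_refs$sequence[pid[1]]
      pos <- regexpr(mature_refs$sequence[i], prec, fixed = TRUE)
      if (pos < 0L) {
        warning("precursor ", precursor_refs$id[pid[1]],
                " does not contain its annotated mature; skipped")
        next
      }
      fr <- fold(dna_to_rna(prec))
      st <- detect_star(c(pos - 1L, pos - 1L + nchar(mature_refs$sequence[i])),
                        fr$structure)
      if (st$ok) {
        ref_arm[i] <- st$arm
        star_seq[i] <- substr(prec, st$star[1] + 1L, st$star[2])
      }
    }
  }

  mm <- match_mature_cpp(tags$sequence, mature_refs$sequence,
                         as.integer(config$max_mismatch),
                         as.integer(config$max_shift))
  has_star <- !is.na(star_seq)
  sm <- if (any(has_star)) {
    match_mature_cpp(tags$sequence, star_seq[has_star],
                     as.integer(config$max_mismatch),
                     as.integer(config$max_shift))
  } else NULL

  rows <- list()
  other_arm <- function(a) if (is.na(a)) NA_character_ else if (a == "5p") "3p" else "5p"
  for (t in seq_len(nrow(tags))) {
    if (mm$ref[t] > 0L) {
      i <- mm$ref[t]
      nm <- sub(rename_prefix[1], rename_prefix[2], mature_refs$id[i], fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tags$tag_id[t], sequence = tags$sequence[t], name = nm,
        family = mirna_family(nm), arm = ref_arm[i], is_star = FALSE,
        count_control = tags$count_control[t],
        count_treated = tags$count_treated[t], stringsAsFactors = FALSE)
    } else if (!is.null(sm) && sm$ref[t] > 0L) {
      i <- which(has_star)[sm$ref[t]]
      nm <- sub(rename_prefix[1], rename_prefix[2], mature_refs$id[i], fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tags$tag_id[t], sequence = tags$sequence[t],
        name = paste0(nm, "-", other_arm(ref_arm[i]), "*"),
        family = mirna_family(nm), arm = other_arm(ref_arm[i]), is_star = TRUE,
        count_control = tags$count_control[t],
        count_treated = tags$count_treated[t], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' miRNA family from a miRNA name
#'
#' Strips the species prefix, the member letter and any arm suffix:
#' oco-miR169a-5p -> miR169.
#'
#' @param name character vector of miRNA names.
#' @return Character vector of family names.
#' @export
mirna_family <- function(name) {
  x <- sub("^[a-z]{3}-", "", name)
  x <- sub("(-[35]p)?\\*?$", "", x)
  sub("([0-9])[a-z]+$", "\\1", x)
}

.annotation_priority <- c("rRNA_etc", "known_miRNA", "repeat", "exon",
                          "intron", "unannotated")

#' Assign every mapped tag to exactly one annotation class
#'
#' Applies the hierarchical priority rule: rRNA-type ncRNAs (the
#' GenBank-like set taking precedence over the Rfam-like set) > known
#' miRNAs > repeats > exons > introns; anything left is unannotated. The
#' partition is exhaustive and exclusive over the supplied tags.
#'
#' @param tags tag set (typically the mapped subset).
#' @param known_tag_ids tag ids identified by [identify_known()] (matures
#'   and stars).
#' @param refs list of reference sets: `genbank`, `rfam`, `repeats`, `exon`,
#'   `intron` (each a data.frame `id`, `sequence`).
#' @param config the `annotation` section of [default_config()].
#' @return data.frame `tag_id`, `category`, `subcategory`, `evidence`.
#' @export
classify_tags <- function(tags, known_tag_ids, refs,
                          config = default_config()$annotation) {
  n <- nrow(tags)
  category <- rep(NA_character_, n)
  subcat <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)
  mm <- config$max_mismatch

  assign_class <- function(ids, cat, subval, ev) {
    open <- is.na(category) & !is.na(ids)
    category[open] <<- cat
    subcat[open] <<- if (is.null(subval)) sub("_.*$", "", ids[open]) else subval
    evidence[open] <<- ev
  }
  assign_class(match_reference(tags$sequence, refs$genbank, mm),
               "rRNA_etc", NULL, "genbank_like")
  assign_class(match_reference(tags$sequence, refs$rfam, mm),
               "rRNA_etc", NULL, "rfam_like")
  open <- is.na(category) & tags$tag_id %in% known_tag_ids
  category[open] <- "known_miRNA"; subcat[open] <- "miRNA"
  evidence[open] <- "mirbase_like"
  assign_class(match_reference(tags$sequence, refs$repeats, mm),
               "repeat", "repeat", "repeat_set")
  assign_class(match_reference(tags$sequence, refs$exon, mm),
               "exon", "mRNA", "genbank_like")
  assign_class(match_reference(tags$sequence, refs$intron, mm),
               "intron", "mRNA", "genbank_like")
  category[is.na(category)] <- "unannotated"
  subcat[is.na(subcat)] <- ""
  evidence[is.na(evidence)] <- ""
  data.frame(tag_id = tags$tag_id, category = category,
             subcategory = subcat, evidence = evidence,
             stringsAsFactors = FALSE)
}
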