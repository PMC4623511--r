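#' Build a genome index for ungapped tag mapping
#'
#' Holds the chromosome sequences together with the seed length used by the
#' mapper's pigeonhole filter. Rebuilding from the same FASTA is
#' deterministic, and the index round-trips through [write_fasta()].
#'
#' @param genome data.frame from [read_fasta()] or a named character vector
#'   of chromosome sequences.
#' @param seed_len k-mer seed length (must not exceed the shortest mappable
#'   tag, 16 nt).
#' @return A `GenomeIndex` object.
#' @export
build_index <- function(genome, seed_len = 12L) {
  if (is.data.frame(genome)) {
    seqs <- stats::setNames(genome$sequence, genome$id)
  } else {
    seqs <- genome
  }
  if (length(seqs) == 0L || any(!nzchar(seqs))) stop("genome is empty")
  if (seed_len > 16L) stop("seed_len must be <= 16 (the shortest tag)")
  structure(list(chrom = names(seqs), length = nchar(seqs),
                 sequence = unname(toupper(seqs)), seed_len = as.integer(seed_len)),
            class = "GenomeIndex")
}

#' Look up exact occurrences of a seed k-mer in an indexed genome
#'
#' @param index a `GenomeIndex`.
#' @param kmer seed sequence (DNA).
#' @return data.frame `chrom`, `start` (0-based), `strand`.
#' @export
index_lookup <- function(index, kmer) {
  hits <- map_scan_cpp(index$sequence, toupper(kmer), 0L)
  data.frame(chrom = index$chrom[hits$chrom], start = hits$start,
             strand = hits$strand, stringsAsFactors = FALSE)
}

#' Map tags to the genome, ungapped, with at most `max_mismatch` mismatches
#'
#' Reports ALL placements on both strands (minus-strand alignments store the
#' genomic locus whose reverse complement equals the tag). A tag with more
#' placements than the copy-number cap is flagged `over_copy_cap` and its
#' alignments are suppressed so it cannot seed hairpin discovery; a tag with
#' no placement is `unmapped`. N in the genome never matches; N in a tag
#' counts as a mismatch.
#'
#' @param tags tag set from [collapse_tags()] (or any data.frame with
#'   `tag_id` and `sequence`).
#' @param index a `GenomeIndex` from [build_index()].
#' @param max_mismatch mismatch ceiling (2).
#' @param max_hits copy-number cap (20).
#' @return list with `alignments` (data.frame `tag_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `mismatches`, ordered by tag, chrom,
#'   start, strand) and `status` (data.frame `tag_id`, `status`, `n_hits`).
#' @export
map_tags <- function(tags, index, max_mismatch = 2L, max_hits = 20L) {
  stopifnot(inherits(index, "GenomeIndex"))
  hits <- map_scan_cpp(index$sequence, tags$sequence, as.integer(max_mismatch))
  n_hits <- tabulate(hits$tag, nbins = nrow(tags))
  status <- ifelse(n_hits == 0L, "unmapped",
                   ifelse(n_hits > max_hits, "over_copy_cap", "mapped"))
  keep <- n_hits[hits$tag] <= max_hits
  hits <- hits[keep, , drop = FALSE]
  aln <- data.frame(
    tag_id = tags$tag_id[hits$tag],
    chrom = index$chrom[hits$chrom],
    start = hits$start,
    end = hits$start + nchar(tags$sequence[hits$tag]),
    strand = hits$strand,
    mismatches = hits$mismatches,
    stringsAsFactors = FALSE
  )
  aln <- aln[order(aln$tag_id, aln$chrom, aln$start, aln$strand), , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       status = data.frame(tag_id = tags$tag_id, status = status,
                           n_hits = n_hits, stringsAsFactors = FALSE))
}

#' Brute-force reference mapper (test oracle)
#'
#' Sliding-window Hamming scan over both strands in plain R. Quadratic and
#' meant for small genomes; the production mapper must produce exactly the
#' same alignment set.
#'
#' @inheritParams map_tags
#' @param genome named character vector of chromosome sequences.
#' @return data.frame like the `alignments` component of [map_tags()].
#' @export
map_tags_bruteforce <- function(tags, genome, max_mismatch = 2L) {
  out <- list()
  for (t in seq_len(nrow(tags))) {
    tg <- strsplit(tags$sequence[t], "")[[1]]
    rc <- strsplit(revcomp(tags$sequence[t]), "")[[1]]
    lt <- length(tg)
    for (c in seq_along(genome)) {
      g <- strsplit(genome[[c]], "")[[1]]
      if (length(g) < lt) next
      for (pos in 0:(length(g) - lt)) {
        win <- g[(pos + 1):(pos + lt)]
        ok <- win %in% c("A", "C", "G", "T")
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") tg else rc
          mm <- sum(!(win == pat & ok))
          if (mm <= max_mismatch) {
            out[[length(out) + 1L]] <- data.frame(
              tag_id = tags$tag_id[t], chrom = names(genome)[c],
              start = pos, end = pos + lt, strand = strand,
              mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tag_id, res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
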