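#' Search reference miRNA sequences against a transcriptome
#'
#' Localized conserved-miRNA discovery: a seed-and-extend ungapped local
#' aligner (exact word seeds, X-drop extension on the seed diagonal, both
#' strands) stands in for the remote BLASTN search such studies run against
#' assembled transcript libraries. Precursor hits are re-folded and
#' validated with the full candidate criteria (genomic-context checks do
#' not apply on transcripts); mature-only queries are reported without
#' hairpin validation and flagged accordingly.
#'
#' @param queries data.frame (`id`, `sequence`) of precursor and/or mature
#'   query sequences; `kind` column ("precursor"/"mature_only") is inferred
#'   from length (< 40 nt means mature_only) when absent.
#' @param transcriptome data.frame (`id`, `sequence`) of transcripts.
#' @param config the `homology` section of [default_config()].
#' @param discovery_config candidate thresholds for hairpin validation.
#' @param mature_of optional named character vector: mature sequence per
#'   precursor query id, used to locate the mature within a validated hit.
#' @return data.frame `query`, `transcript`, `t_start`, `t_end` (0-based
#'   half-open on the transcript), `strand`, `identity`, `coverage`,
#'   `query_kind`, `validated`.
#' @export
search_homologs <- function(queries, transcriptome,
                            config = default_config()$homology,
                            discovery_config = default_config()$discovery,
                            mature_of = NULL) {
  empty <- data.frame(query = character(0), transcript = character(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), query_kind = character(0),
                      validated = logical(0), stringsAsFactors = FALSE)
  if (nrow(queries) == 0L || nrow(transcriptome) == 0L) return(empty)
  if (is.null(queries$kind)) {
    queries$kind <- ifelse(nchar(queries$sequence) < 40L, "mature_only", "precursor")
  }
  w <- config$word_size
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    qseq <- toupper(queries$sequence[qi])
    qlen <- nchar(qseq)
    if (qlen < w) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qseq else revcomp(qseq)
      for (ti in seq_len(nrow(transcriptome))) {
        tseq <- toupper(transcriptome$sequence[ti])
        tlen <- nchar(tseq)
        if (tlen < w) next
        # seed diagonals: exact w-mers of the query found in the transcript
        diags <- integer(0)
        for (off in seq_len(qlen - w + 1L)) {
          word <- substr(q, off, off + w - 1L)
          hit <- gregexpr(word, tseq, fixed = TRUE)[[1]]
          if (hit[1] > 0L) diags <- c(diags, hit - off) # t_start - q_start
        }
        for (d in unique(diags)) {
          # ungapped overlap of query [1..qlen] with the transcript on diagonal d
          q_lo <- max(1L, 1L - d)
          q_hi <- min(qlen, tlen - d)
          if (q_hi - q_lo + 1L < ceiling(config$min_coverage * qlen)) next
          qa <- strsplit(substr(q, q_lo, q_hi), "")[[1]]
          ta <- strsplit(substr(tseq, q_lo + d, q_hi + d), "")[[1]]
          match <- qa == ta
          # best X-drop-bounded segment containing at least one seed
          sc <- ifelse(match, 1, -2)
          best <- best_segment(sc, config$xdrop)
          if (is.null(best)) next
          seg_len <- best[2] - best[1] + 1L
          ident <- mean(match[best[1]:best[2]])
          cover <- seg_len / qlen
          if (ident < config$min_identity || cover < config$min_coverage) next
          t_start <- (q_lo + best[1] - 1L) + d - 1L # 0-based on transcript
          rows[[length(rows) + 1L]] <- data.frame(
            query = queries$id[qi], transcript = transcriptome$id[ti],
            t_start = t_start, t_end = t_start + seg_len,
            strand = strand, identity = ident, coverage = cover,
            query_kind = queries$kind[qi], validated = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[, c("query", "transcript", "t_start", "strand")]), ]
  hits <- hits[order(hits$query, hits$transcript, hits$t_start, hits$strand), ]
  rownames(hits) <- NULL

  # hairpin validation of precursor hits
  for (k in which(hits$query_kind == "precursor")) {
    ti <- match(hits$transcript[k], transcriptome$id)
    region <- substr(transcriptome$sequence[ti],
                     max(1L, hits$t_start[k] + 1L - 10L),
                     min(nchar(transcriptome$sequence[ti]), hits$t_end[k] + 10L))
    if (hits$strand[k] == "-") region <- revcomp(region)
    mat <- if (!is.null(mature_of)) mature_of[[hits$query[k]]] else NULL
    if (is.null(mat) || is.na(mat)) next
    pos <- regexpr(mat, region, fixed = TRUE)
    if (pos < 0L) next
    cand <- evaluate_candidate(region, pos - 1L, nchar(mat), discovery_config)
    hits$validated[k] <- cand$verdict == "ACCEPT"
  }
  hits
}

#' Best-scoring contiguous segment under an X-drop rule
#'
#' Kadane-style maximal segment of per-position scores, abandoning a
#' candidate when its running score drops more than `xdrop` below the
#' running maximum (the classic ungapped-extension bound).
#'
#' @param scores numeric vector of per-position scores.
#' @param xdrop drop-off bound.
#' @return c(start, end) indices (1-based, inclusive) of the best positive
#'   segment, or NULL when no positive segment exists.
#' @keywords internal
best_segment <- function(scores, xdrop) {
  best <- 0; best_iv <- NULL
  run <- 0; run_start <- 1L; run_max <- 0; run_best_end <- 0L
  for (i in seq_along(scores)) {
    run <- run + scores[i]
    if (run > run_max) { run_max <- run; run_best_end <- i }
    if (run < run_max - xdrop || run < 0) {
      if (run_max > best && run_best_end >= run_start) {
        best <- run_max; best_iv <- c(run_start, run_best_end)
      }
      run <- 0; run_max <- 0; run_start <- i + 1L; run_best_end <- i
    }
  }
  if (run_max > best && run_best_end >= run_start) {
    best <- run_max; best_iv <- c(run_start, run_best_end)
  }
  best_iv
}
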