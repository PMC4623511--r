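#' Classify raw reads by the seven-step cleaning procedure
#'
#' Applies the elimination rules in their printed order -- (i) low quality,
#' (ii) 5' primer contaminant, (iii) no 3' primer, (iv) no insert,
#' (v) poly-A, (vi) insert length outside 16-36 nt -- and assigns each read
#' to the FIRST rule it violates, or to `clean`. The 3' adapter is located
#' by exact prefix match of decreasing length (12 down to 6 by default),
#' leftmost occurrence winning, and the insert is everything 5' of it.
#'
#' @param reads data.frame from [read_fastq()] (`id`, `sequence`, `quality`).
#' @param params the `cleaning` section of [default_config()].
#' @return data.frame `id`, `sequence`, `quality`, `class`, `insert` where
#'   `class` is one of clean, low_quality, adapter5_contaminant, no_adapter3,
#'   no_insert, polyA, length_out_of_range.
#' @export
classify_reads <- function(reads, params = default_config()$cleaning) {
  n <- nrow(reads)
  cls <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  if (n == 0L) {
    return(cbind(reads, class = character(0), insert = character(0)))
  }
  if (nchar(params$adapter3) < 6L) {
    stop("3' adapter must be at least 6 nt to be trimmable")
  }

  # rule (i): low quality
  qstats <- vapply(reads$quality, function(q) {
    s <- as.integer(charToRaw(q)) - 33L
    c(mean(s), mean(s < 10L))
  }, numeric(2), USE.NAMES = FALSE)
  low <- qstats[1, ] < params$min_mean_phred | qstats[2, ] > params$max_frac_below10
  cls[low] <- "low_quality"

  # rule (ii): 5' primer contaminant -- read begins with a long prefix of the
  # 5' adapter, up to adapter5_max_mm mismatches
  open <- is.na(cls)
  p5 <- substr(params$adapter5, 1L, params$adapter5_min_prefix)
  pre <- substr(reads$sequence, 1L, nchar(p5))
  mm5 <- vapply(pre, function(x) {
    a <- strsplit(x, "")[[1]]
    b <- strsplit(p5, "")[[1]]
    if (length(a) < length(b)) return(Inf)
    sum(a != b)
  }, numeric(1), USE.NAMES = FALSE)
  cls[open & mm5 <= params$adapter5_max_mm] <- "adapter5_contaminant"

  # rule (iii): locate the 3' adapter; exact prefix 12 -> 6, leftmost wins
  pos <- rep(-1L, n)
  for (L in seq(params$adapter3_max_prefix, params$adapter3_min_prefix)) {
    idx <- which(pos < 0L)
    if (length(idx) == 0L) break
    hit <- regexpr(substr(params$adapter3, 1L, L), reads$sequence[idx],
                   fixed = TRUE)
    pos[idx[hit > 0L]] <- hit[hit > 0L]
  }
  open <- is.na(cls)
  cls[open & pos < 0L] <- "no_adapter3"

  ins <- ifelse(pos > 0L, substr(reads$sequence, 1L, pos - 1L), "")

  # rule (iv): empty insert
  open <- is.na(cls)
  cls[open & nchar(ins) == 0L] <- "no_insert"

  # rule (v): poly-A insert
  open <- is.na(cls)
  fracA <- ifelse(nchar(ins) > 0L,
                  nchar(gsub("[^A]", "", ins)) / nchar(ins), 0)
  cls[open & fracA >= params$polya_frac] <- "polyA"

  # rule (vi): insert length out of range
  open <- is.na(cls)
  cls[open & (nchar(ins) < params$min_len | nchar(ins) > params$max_len)] <-
    "length_out_of_range"

  cls[is.na(cls)] <- "clean"
  insert <- ifelse(cls == "clean", ins, NA_character_)
  out <- reads
  out$class <- cls
  out$insert <- insert
  out
}

.removal_rules <- c("low_quality", "adapter5_contaminant", "no_adapter3",
                    "no_insert", "polyA", "length_out_of_range")

#' Clean a raw read library
#'
#' Runs [classify_reads()] and splits the library into surviving
#' adapter-trimmed inserts and per-rule removal statistics. The statistics
#' satisfy the conservation invariant
#' `raw_reads == clean_reads + sum(removed)` exactly.
#'
#' @inheritParams classify_reads
#' @return list with `clean` (data.frame `id`, `insert`) and `stats` (a
#'   one-row data.frame: `raw_reads`, one column per removal rule,
#'   `clean_reads`).
#' @export
clean_reads <- function(reads, params = default_config()$cleaning) {
  cl <- classify_reads(reads, params)
  removed <- vapply(.removal_rules, function(r) sum(cl$class == r), 0L)
  keep <- cl$class == "clean"
  stats <- as.data.frame(c(list(raw_reads = nrow(cl)), as.list(removed),
                           list(clean_reads = sum(keep))))
  stopifnot(stats$raw_reads == stats$clean_reads + sum(removed))
  list(clean = data.frame(id = cl$id[keep], insert = cl$insert[keep],
                          stringsAsFactors = FALSE),
       stats = stats)
}

#' Collapse cleaned inserts from the two libraries into counted unique tags
#'
#' @param control_inserts,treated_inserts character vectors of cleaned insert
#'   sequences (one entry per read).
#' @return data.frame `tag_id`, `sequence`, `count_control`, `count_treated`,
#'   ordered lexicographically by sequence; tag ids are assigned in that
#'   order, so collapsing is deterministic.
#' @export
collapse_tags <- function(control_inserts, treated_inserts) {
  seqs <- sort(unique(c(control_inserts, treated_inserts)))
  cc <- table(factor(control_inserts, levels = seqs))
  ct <- table(factor(treated_inserts, levels = seqs))
  out <- data.frame(
    tag_id = sprintf("tag%06d", seq_along(seqs)),
    sequence = seqs,
    count_control = as.integer(cc),
    count_treated = as.integer(ct),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(out$count_control) == length(control_inserts),
            sum(out$count_treated) == length(treated_inserts),
            all(out$count_control + out$count_treated >= 1L))
  out
}

#' Length distribution of clean reads
#'
#' Histogram of read counts (not unique tags) by insert length over the
#' retained 16-36 nt range; the column sums equal the library clean-read
#' totals.
#'
#' @param tags tag set from [collapse_tags()].
#' @param min_len,max_len length range of the histogram.
#' @return data.frame `length`, `count_control`, `count_treated`, `count`.
#' @export
length_distribution <- function(tags, min_len = 16L, max_len = 36L) {
  len <- nchar(tags$sequence)
  lv <- seq(min_len, max_len)
  cc <- vapply(lv, function(L) sum(tags$count_control[len == L]), 0L)
  ct <- vapply(lv, function(L) sum(tags$count_treated[len == L]), 0L)
  data.frame(length = lv, count_control = cc, count_treated = ct,
             count = cc + ct)
}
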