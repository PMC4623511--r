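#' Score a miRNA against one candidate target window
#'
#' Plant-style complementarity scoring: the miRNA (5'->3') is aligned
#' antiparallel against the target window and penalized per position --
#' match 0, G:U wobble 0.5, mismatch 1.0, gap 2.0 -- with every penalty
#' doubled across the seed region (miRNA positions 2-13 by default). The
#' expectation is the penalty total. Inhibition is `translation` when any
#' mismatch or gap faces the central positions (9-11), `cleavage` otherwise;
#' for cleavage hits the slice site is the boundary between the target
#' bases paired to miRNA positions 10 and 11.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA).
#' @param window target window sequence in transcript orientation (5'->3').
#' @param config the `targets` section of [default_config()].
#' @return list with `expectation`, `inhibition`, `alignment` (three-row
#'   character rendering), `pair_of` (window position, 1-based 5'->3',
#'   paired to each miRNA position; 0 = gap) and `cleavage_offset` (0-based
#'   inter-base coordinate within the window, or NA for translation mode).
#' @export
score_duplex <- function(mirna, window, config = default_config()$targets) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  window <- chartr("Uu", "Tt", toupper(window))
  res <- nw_duplex_cpp(mirna, window, config$wobble, config$mismatch,
                       config$gap, config$seed_lo, config$seed_hi,
                       config$seed_mult)
  central_bad <- FALSE
  last_m <- 0L
  for (k in seq_along(res$col_mirna)) {
    if (res$col_mirna[k] > 0L) {
      last_m <- res$col_mirna[k]
      if (last_m >= config$central_lo && last_m <= config$central_hi &&
          res$col_type[k] %in% c("mismatch", "gap_target")) {
        central_bad <- TRUE
      }
    } else if (res$col_type[k] == "gap_mirna") {
      # target bulge between miRNA positions last_m and last_m + 1
      if (last_m >= config$central_lo - 1L && last_m < config$central_hi) {
        central_bad <- TRUE
      }
    }
  }
  inhibition <- if (central_bad) "translation" else "cleavage"
  cleav <- NA_integer_
  if (inhibition == "cleavage") {
    p10 <- res$pair_of[10]
    if (p10 > 0L) cleav <- p10 - 1L # boundary 5' of the base paired to pos 10
  }
  if (is.na(cleav) && inhibition == "cleavage") inhibition <- "translation"
  # three-row alignment rendering: miRNA 5'->3' over target 3'->5'
  sym <- vapply(seq_along(res$col_mirna), function(k) {
    switch(res$col_type[k], match = "|", wobble = "o", mismatch = " ",
           gap_mirna = " ", gap_target = " ")
  }, "")
  mrow <- ifelse(res$col_mirna > 0L,
                 strsplit(mirna, "")[[1]][pmax(res$col_mirna, 1L)], "-")
  trow <- ifelse(res$col_target > 0L,
                 strsplit(window, "")[[1]][pmax(res$col_target, 1L)], "-")
  alignment <- c(paste0("miR 5' ", paste(mrow, collapse = ""), " 3'"),
                 paste0("       ", paste(sym, collapse = "")),
                 paste0("tgt 3' ", paste(trow, collapse = ""), " 5'"))
  list(expectation = res$score, inhibition = inhibition,
       alignment = alignment, pair_of = res$pair_of, cleavage_offset = cleav)
}

#' Scan miRNAs against a transcriptome for target sites
#'
#' Every window whose expectation is at or below the cutoff is reported;
#' several window sizes around the miRNA length admit small bulges.
#' Overlapping reports of the same site keep the lowest expectation
#' (shorter window, then smaller start on ties). Order is deterministic:
#' miRNA, transcript, position.
#'
#' @param mirnas data.frame (`id`, `sequence`).
#' @param transcriptome data.frame (`id`, `sequence`) of cDNAs.
#' @param config the `targets` section of [default_config()].
#' @return data.frame `mirna`, `transcript`, `t_start`, `t_end` (0-based
#'   half-open), `expectation`, `inhibition`, `cleavage_site` (0-based
#'   inter-base transcript coordinate, NA for translation mode).
#' @export
scan_transcriptome <- function(mirnas, transcriptome,
                               config = default_config()$targets) {
  rows <- list()
  for (mi in seq_len(nrow(mirnas))) {
    mseq <- chartr("Uu", "Tt", toupper(mirnas$sequence[mi]))
    for (ti in seq_len(nrow(transcriptome))) {
      tseq <- toupper(transcriptome$sequence[ti])
      if (nchar(tseq) < nchar(mseq)) next
      raw <- scan_windows_cpp(mseq, tseq, config$expectation_cutoff,
                              config$len_delta, config$wobble, config$mismatch,
                              config$gap, config$seed_lo, config$seed_hi,
                              config$seed_mult)
      if (nrow(raw) == 0L) next
      raw <- raw[order(raw$score, abs(raw$len - nchar(mseq)), raw$start), ]
      # greedy overlap dedup: best-scoring representative per site
      kept <- list()
      for (k in seq_len(nrow(raw))) {
        s <- raw$start[k]; e <- raw$start[k] + raw$len[k]
        clash <- any(vapply(kept, function(iv) s < iv[2] && iv[1] < e, TRUE))
        if (!clash) kept[[length(kept) + 1L]] <- c(s, e, raw$score[k])
      }
      for (iv in kept) {
        win <- substr(tseq, iv[1] + 1L, iv[2])
        sd <- score_duplex(mseq, win, config)
        cs <- if (is.na(sd$cleavage_offset)) NA_integer_ else iv[1] + sd$cleavage_offset
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mirnas$id[mi], transcript = transcriptome$id[ti],
          t_start = iv[1], t_end = iv[2], expectation = sd$expectation,
          inhibition = sd$inhibition, cleavage_site = cs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      t_start = integer(0), t_end = integer(0),
                      expectation = numeric(0), inhibition = character(0),
                      cleavage_site = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$transcript, out$t_start), ]
  rownames(out) <- NULL
  out
}

#' Predicted cleavage coordinate of a target hit
#'
#' For a cleavage-mode hit, the slice site is the inter-base transcript
#' coordinate between the bases paired to miRNA positions 10 and 11 (5'
#' numbering), mapped gap-aware through the alignment.
#'
#' @param hit one row of [scan_transcriptome()] output (or a list with
#'   `inhibition` and `cleavage_site`).
#' @return The 0-based inter-base transcript coordinate.
#' @export
predict_cleavage <- function(hit) {
  if (!identical(hit$inhibition, "cleavage")) {
    stop("cleavage site is undefined for translation-mode hits")
  }
  hit$cleavage_site
}

#' Singular enrichment analysis over GO terms
#'
#' Per-term hypergeometric upper-tail test of the target gene set against
#' the background, with Benjamini-Hochberg FDR across terms; a term is
#' significant when FDR < 0.05.
#'
#' @param target_genes character vector of genes of interest (must all be
#'   in the background).
#' @param background_genes character vector: the gene universe.
#' @param go_map data.frame `gene`, `term` (optionally `name`, `ontology`).
#' @param fdr_max significance threshold on the FDR.
#' @return data.frame `term`, `k`, `n`, `K`, `N`, `pvalue`, `fdr`,
#'   `significant` (plus `name`/`ontology` when present in `go_map`).
#' @export
sea_enrichment <- function(target_genes, background_genes, go_map,
                           fdr_max = 0.05) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  missing <- setdiff(target_genes, background_genes)
  if (length(missing) > 0L) {
    stop("target genes absent from background: ",
         paste(missing, collapse = ", "))
  }
  go_map <- go_map[go_map$gene %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(target_genes)
  terms <- sort(unique(go_map$term))
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes_tm <- unique(go_map$gene[go_map$term == tm])
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, target_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), pvalue = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
  res$significant <- res$fdr < fdr_max
  extra <- intersect(c("name", "ontology"), names(go_map))
  if (length(extra) > 0L) {
    ann <- go_map[!duplicated(go_map$term), c("term", extra), drop = FALSE]
    res <- merge(res, ann, by = "term", all.x = TRUE, sort = TRUE)
  }
  res[order(res$pvalue, res$term), ]
}
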