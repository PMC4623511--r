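#' @importFrom Rcpp sourceCpp
#' @useDynLib halomiR, .registration = TRUE
NULL

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into `id` and `description`;
#' multi-line sequences are concatenated and upper-cased. The storage
#' alphabet is DNA; conversion to RNA happens explicitly at the folding
#' boundary, never here.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`, one
#'   row per record in file order. An empty file yields zero rows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first)) & !startsWith(first, ";")]
  if (length(first) > 0L && !startsWith(first[1], ">")) {
    stop("FASTA format error in ", path, ": sequence line before any header")
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(x))
  bad <- which(!nzchar(sequence))
  if (length(bad) > 0L) {
    stop("FASTA format error in ", path, ": empty sequence for record '",
         id[bad[1]], "'")
  }
  if (any(!nzchar(id))) stop("FASTA format error in ", path, ": empty id")
  data.frame(id = unname(id), description = unname(description),
             sequence = unname(sequence), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with `id`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]).
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @export
write_fasta <- function(records, path, width = 60L) {
  x <- Biostrings::BStringSet(records$sequence)
  desc <- if (!is.null(records$description)) records$description else ""
  names(x) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @param phred_offset quality encoding offset (33 by default; configurable,
#'   never auto-detected).
#' @return A data.frame with columns `id`, `sequence`, `quality` (the raw
#'   quality string). Use [phred_scores()] to decode qualities to integers.
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error in ", path, ": truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L)
  }
  hd <- lines[seq(1L, length(lines), by = 4L)]
  sq <- toupper(lines[seq(2L, length(lines), by = 4L)])
  pl <- lines[seq(3L, length(lines), by = 4L)]
  ql <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad) > 0L) {
    stop("FASTQ format error in ", path, ": expected '@' at line ",
         (bad[1] - 1L) * 4L + 1L)
  }
  bad <- which(!startsWith(pl, "+"))
  if (length(bad) > 0L) {
    stop("FASTQ format error in ", path, ": expected '+' at line ",
         (bad[1] - 1L) * 4L + 3L)
  }
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad) > 0L) {
    stop("FASTQ format error in ", path,
         ": sequence/quality length mismatch at line ", (bad[1] - 1L) * 4L + 4L)
  }
  id <- sub("\\s.*$", "", substring(hd, 2L))
  data.frame(id = id, sequence = sq, quality = ql, stringsAsFactors = FALSE)
}

#' Decode a Phred quality string to integer scores
#'
#' @param quality character vector of quality strings.
#' @param phred_offset encoding offset (Phred+33 default).
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality, phred_offset = 33L) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - phred_offset)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$sequence
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features (1-based inclusive coordinates)
#' into one gene model per mRNA with internal 0-based half-open intervals.
#' Introns are derived as the gaps between consecutive exons.
#'
#' @param path path to a GFF3 file.
#' @return A list of `GeneModel` objects: each a list with `gene_id`,
#'   `mrna_id`, `chrom`, `strand`, and `exons`, `cds`, `utr5`, `utr3`,
#'   `introns` -- each a two-column matrix of 0-based half-open intervals,
#'   sorted and non-overlapping.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  get_id <- function(x) as.character(x$ID)
  parents <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }, character(1))
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  gene_span <- stats::setNames(
    lapply(seq_along(genes), function(i) {
      c(GenomicRanges::start(genes)[i] - 1L, GenomicRanges::end(genes)[i])
    }), get_id(genes))
  iv_mat <- function(sub) {
    if (length(sub) == 0L) {
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    m <- cbind(start = as.integer(GenomicRanges::start(sub) - 1L),
               end = as.integer(GenomicRanges::end(sub)))
    m[order(m[, 1]), , drop = FALSE]
  }
  out <- lapply(seq_along(mrnas), function(i) {
    mid <- get_id(mrnas)[i]
    gid <- parents[which(type == "mRNA")[i]]
    keep <- !is.na(parents) & parents == mid
    exons <- iv_mat(gr[keep & type == "exon"])
    if (nrow(exons) == 0L) stop("mRNA '", mid, "' has no exons")
    if (nrow(exons) > 1L && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("overlapping exons in mRNA '", mid, "'")
    }
    span <- gene_span[[gid]]
    if (!is.null(span) && (exons[1, 1] < span[1] || exons[nrow(exons), 2] > span[2])) {
      stop("GFF3 format error: exon outside gene span for mRNA '", mid, "'")
    }
    introns <- if (nrow(exons) > 1L) {
      cbind(start = unname(exons[-nrow(exons), 2]),
            end = unname(exons[-1, 1]))
    } else {
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    }
    list(gene_id = gid, mrna_id = mid,
         chrom = as.character(GenomicRanges::seqnames(mrnas))[i],
         strand = as.character(GenomicRanges::strand(mrnas))[i],
         exons = exons,
         cds = iv_mat(gr[keep & type == "CDS"]),
         utr5 = iv_mat(gr[keep & type == "five_prime_UTR"]),
         utr3 = iv_mat(gr[keep & type == "three_prime_UTR"]),
         introns = introns)
  })
  out
}

#' Write gene models to a GFF3 file
#'
#' The inverse of [read_gff3()]: internal 0-based half-open intervals are
#' emitted as 1-based inclusive GFF3 rows with gene/mRNA/exon/CDS/UTR
#' features and Parent links.
#'
#' @param models list of `GeneModel` objects.
#' @param path output path.
#' @param chrom_lengths named integer vector of chromosome lengths (used for
#'   the sequence-region pragmas).
#' @export
write_gff3 <- function(models, path, chrom_lengths = NULL) {
  rows <- list()
  add <- function(chrom, type, start0, end0, strand, id, parent = NA) {
    attrs <- if (is.na(parent)) sprintf("ID=%s", id) else
      sprintf("ID=%s;Parent=%s", id, parent)
    rows[[length(rows) + 1L]] <<- sprintf(
      "%s\thalomiR\t%s\t%d\t%d\t.\t%s\t.\t%s",
      chrom, type, start0 + 1L, end0, strand, attrs)
  }
  seen_gene <- character(0)
  for (m in models) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    if (!(m$gene_id %in% seen_gene)) {
      add(m$chrom, "gene", span[1], span[2], m$strand, m$gene_id)
      seen_gene <- c(seen_gene, m$gene_id)
    }
    add(m$chrom, "mRNA", span[1], span[2], m$strand, m$mrna_id, m$gene_id)
    feat <- function(mat, type, tag) {
      if (nrow(mat) == 0L) return()
      for (k in seq_len(nrow(mat))) {
        add(m$chrom, type, mat[k, 1], mat[k, 2], m$strand,
            sprintf("%s.%s%d", m$mrna_id, tag, k), m$mrna_id)
      }
    }
    feat(m$exons, "exon", "e")
    feat(m$cds, "CDS", "c")
    feat(m$utr5, "five_prime_UTR", "u5.")
    feat(m$utr3, "three_prime_UTR", "u3.")
  }
  header <- "##gff-version 3"
  if (!is.null(chrom_lengths)) {
    header <- c(header, sprintf("##sequence-region %s 1 %d",
                                names(chrom_lengths), chrom_lengths))
  }
  writeLines(c(header, unlist(rows)), path)
  invisible(path)
}

#' Write a result table as TSV with '#' metadata lines
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta optional character vector of metadata lines (written as
#'   '# '-prefixed comments above the header).
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table, skipping '#' metadata lines
#'
#' @param path path to a TSV file written by [write_tsv()].
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Explicit alphabet conversion: DNA is the storage alphabet throughout the
#' package; folding converts at its boundary via these helpers.
#'
#' @param x character vector of sequences.
#' @return Converted character vector.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)
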