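#' Run the full small RNA analysis pipeline
#'
#' Executes the stages in order -- simulate, clean, map, annotate, discover,
#' homology, de, targets, enrich, report -- against an output directory.
#' Every stage reads its inputs from, and writes its outputs to, plain-text
#' files in `outdir`, so a rerun is byte-identical under the same
#' configuration and seed, and deleting one stage's outputs resumes from
#' there (stages whose outputs exist are skipped unless `force`). The
#' `simulate` stage can be replaced by placing equivalent input files in
#' `outdir` and disabling it via `stages`.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @param seed RNG seed; all randomness flows from here.
#' @param stages character vector of stages to run.
#' @param force rerun stages whose outputs already exist.
#' @return Invisibly, a named list of the output file paths per stage.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = config$seed,
                         stages = c("simulate", "clean", "map", "annotate",
                                    "discover", "homology", "de", "targets",
                                    "enrich", "report"),
                         force = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_config(config, p("config_used.yaml"))
  outputs <- list()

  stage_outputs <- list(
    simulate = c("genome.fasta", "genes.gff3", "control.fastq", "treated.fastq",
                 "transcripts.fasta", "go_map.tsv", "ct.tsv",
                 "ref_mature.fasta", "ref_precursor.fasta", "ref_genbank.fasta",
                 "ref_rfam.fasta", "ref_repeats.fasta", "ref_mrna.fasta",
                 "ref_intron.fasta", "manifest_known.tsv", "manifest_novel.tsv",
                 "manifest_background.tsv", "manifest_cleaning.tsv",
                 "manifest_targets.tsv", "manifest_homologs.tsv"),
    clean = c("tags.tsv", "tags.fasta", "cleaning_stats.tsv", "length_dist.tsv"),
    map = c("alignments.tsv", "tag_status.tsv"),
    annotate = c("known_mirnas.tsv", "annotation.tsv"),
    discover = c("novel_mirnas.tsv", "rejections.tsv", "novel_precursors.txt"),
    homology = "homology_hits.tsv",
    de = c("expression.tsv", "rq.tsv"),
    targets = "targets.tsv",
    enrich = "enrichment.tsv",
    report = "summary.tsv")

  run_stage <- function(name, fun) {
    outs <- p(stage_outputs[[name]])
    if (!(name %in% stages)) return(invisible(NULL))
    if (!force && all(file.exists(outs))) {
      message("stage ", name, ": outputs exist, skipping")
    } else {
      ok <- tryCatch({ fun(); TRUE }, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      })
    }
    outputs[[name]] <<- outs
  }

  run_stage("simulate", function() {
    bundle <- build_genome(config, seed)
    sim <- simulate_libraries(bundle, config, seed)
    write_fasta(data.frame(id = names(bundle$genome), description = "",
                           sequence = unname(bundle$genome)), p("genome.fasta"))
    write_gff3(bundle$models, p("genes.gff3"),
               stats::setNames(nchar(bundle$genome), names(bundle$genome)))
    write_fastq(sim$control, p("control.fastq"))
    write_fastq(sim$treated, p("treated.fastq"))
    write_fasta(cbind(bundle$transcripts[, c("id", "sequence")],
                      description = bundle$transcripts$gene_id),
                p("transcripts.fasta"))
    write_tsv(bundle$go_map, p("go_map.tsv"))
    write_tsv(bundle$ct, p("ct.tsv"))
    refmap <- c(mature = "ref_mature.fasta", precursor = "ref_precursor.fasta",
                genbank = "ref_genbank.fasta", rfam = "ref_rfam.fasta",
                repeats = "ref_repeats.fasta", exon = "ref_mrna.fasta",
                intron = "ref_intron.fasta")
    for (nm in names(refmap)) write_fasta(bundle$refs[[nm]], p(refmap[[nm]]))
    man <- sim$manifest
    write_tsv(man$known, p("manifest_known.tsv"))
    write_tsv(man$novel, p("manifest_novel.tsv"))
    write_tsv(man$library_truth, p("manifest_background.tsv"))
    write_tsv(man$cleaning_truth, p("manifest_cleaning.tsv"))
    write_tsv(man$targets, p("manifest_targets.tsv"))
    write_tsv(man$homologs, p("manifest_homologs.tsv"))
  })

  run_stage("clean", function() {
    ctl <- clean_reads(read_fastq(p("control.fastq")), config$cleaning)
    trt <- clean_reads(read_fastq(p("treated.fastq")), config$cleaning)
    tags <- collapse_tags(ctl$clean$insert, trt$clean$insert)
    write_tsv(tags, p("tags.tsv"))
    write_fasta(data.frame(
      id = tags$tag_id,
      description = paste(tags$count_control, tags$count_treated),
      sequence = tags$sequence), p("tags.fasta"))
    stats <- rbind(cbind(library = "control", ctl$stats),
                   cbind(library = "treated", trt$stats))
    write_tsv(stats, p("cleaning_stats.tsv"))
    write_tsv(length_distribution(tags, config$cleaning$min_len,
                                  config$cleaning$max_len), p("length_dist.tsv"))
  })

  run_stage("map", function() {
    genome <- read_fasta(p("genome.fasta"))
    tags <- read_tsv(p("tags.tsv"))
    idx <- build_index(genome, config$mapping$seed_len)
    res <- map_tags(tags, idx, config$mapping$max_mismatch,
                    config$mapping$max_hits)
    write_tsv(res$alignments, p("alignments.tsv"))
    write_tsv(res$status, p("tag_status.tsv"))
  })

  run_stage("annotate", function() {
    tags <- read_tsv(p("tags.tsv"))
    status <- read_tsv(p("tag_status.tsv"))
    mapped <- tags[tags$tag_id %in% status$tag_id[status$status != "unmapped"], ]
    known <- identify_known(mapped, read_fasta(p("ref_mature.fasta")),
                            read_fasta(p("ref_precursor.fasta")),
                            config$annotation)
    refs <- list(genbank = read_fasta(p("ref_genbank.fasta")),
                 rfam = read_fasta(p("ref_rfam.fasta")),
                 repeats = read_fasta(p("ref_repeats.fasta")),
                 exon = read_fasta(p("ref_mrna.fasta")),
                 intron = read_fasta(p("ref_intron.fasta")))
    ann <- classify_tags(mapped, known$tag_id, refs, config$annotation)
    write_tsv(known, p("known_mirnas.tsv"))
    write_tsv(ann, p("annotation.tsv"))
  })

  run_stage("discover", function() {
    tags <- read_tsv(p("tags.tsv"))
    ann <- read_tsv(p("annotation.tsv"))
    status <- read_tsv(p("tag_status.tsv"))
    aln <- read_tsv(p("alignments.tsv"))
    genome <- read_fasta(p("genome.fasta"))
    gseq <- stats::setNames(genome$sequence, genome$id)
    models <- read_gff3(p("genes.gff3"))
    dc <- config$discovery
    cand_ids <- ann$tag_id[ann$category == "unannotated"]
    cand_ids <- intersect(cand_ids, status$tag_id[status$status == "mapped"])
    lens <- nchar(tags$sequence)[match(cand_ids, tags$tag_id)]
    cand_ids <- cand_ids[lens >= dc$min_tag_len & lens <= dc$max_tag_len]
    wins <- excise_candidates(aln[aln$tag_id %in% cand_ids, , drop = FALSE],
                              gseq, dc$flank, dc$max_distance)
    accepted <- list(); rejected <- list(); prec_lines <- character(0)
    for (k in seq_len(nrow(wins))) {
      wn <- wins[k, ]
      tag <- tags[match(wn$tag_id, tags$tag_id), ]
      cand <- evaluate_candidate(wn$sequence, wn$mature_offset,
                                 nchar(tag$sequence), dc)
      if (cand$verdict == "ACCEPT") {
        # precursor locus back in genome coordinates
        plen <- nchar(cand$precursor)
        if (wn$strand == "+") {
          ps <- wn$win_start + cand$prec_offset
        } else {
          ps <- wn$win_end - cand$prec_offset - plen
        }
        # mature/star reported as spelled by the precursor: a tag aligning
        # with mismatches still names the genomic miRNA species
        accepted[[length(accepted) + 1L]] <- data.frame(
          tag_id = wn$tag_id, chrom = wn$chrom, start = ps, end = ps + plen,
          strand = wn$strand, arm = cand$arm,
          mature_seq = substr(cand$precursor, cand$mature[1] + 1L,
                              cand$mature[2]),
          star_seq = substr(cand$precursor, cand$star[1] + 1L, cand$star[2]),
          precursor_seq = cand$precursor, structure = cand$fold$structure,
          mfe = cand$mfe, mfei = cand$mfei, au_fraction = cand$au_fraction,
          context = classify_context(wn$chrom, ps, ps + plen, models),
          count_control = tag$count_control, count_treated = tag$count_treated,
          stringsAsFactors = FALSE)
      } else {
        rejected[[length(rejected) + 1L]] <- data.frame(
          tag_id = wn$tag_id, chrom = wn$chrom, side = wn$side,
          reasons = paste(cand$rejection_reasons, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    acc <- if (length(accepted) > 0L) do.call(rbind, accepted) else
      data.frame(tag_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 arm = character(0), mature_seq = character(0),
                 star_seq = character(0), precursor_seq = character(0),
                 structure = character(0), mfe = numeric(0), mfei = numeric(0),
                 au_fraction = numeric(0), context = character(0),
                 count_control = integer(0), count_treated = integer(0),
                 stringsAsFactors = FALSE)
    # one candidate per tag/locus: drop duplicate windows of the same locus
    acc <- acc[!duplicated(acc[, c("tag_id", "chrom", "start", "strand")]), ,
               drop = FALSE]
    novel <- name_and_deduplicate(acc)
    write_tsv(novel, p("novel_mirnas.tsv"))
    rej <- if (length(rejected) > 0L) do.call(rbind, rejected) else
      data.frame(tag_id = character(0), chrom = character(0),
                 side = character(0), reasons = character(0))
    write_tsv(rej, p("rejections.tsv"))
    for (k in seq_len(nrow(novel))) {
      prec_lines <- c(prec_lines,
                      paste0(">", novel$name[k], " ", novel$chrom[k], ":",
                             novel$start[k] + 1L, "-", novel$end[k], "(",
                             novel$strand[k], ")"),
                      dna_to_rna(novel$precursor_seq[k]), novel$structure[k])
    }
    writeLines(prec_lines, p("novel_precursors.txt"))
  })

  run_stage("homology", function() {
    prec <- read_fasta(p("ref_precursor.fasta"))
    mature <- read_fasta(p("ref_mature.fasta"))
    mature_of <- stats::setNames(
      mature$sequence[match(sub("-MI$", "", prec$id), mature$id)], prec$id)
    hits <- search_homologs(prec, read_fasta(p("transcripts.fasta")),
                            config$homology, config$discovery, mature_of)
    write_tsv(hits, p("homology_hits.tsv"))
  })

  run_stage("de", function() {
    stats_tbl <- read_tsv(p("cleaning_stats.tsv"))
    N1 <- stats_tbl$clean_reads[stats_tbl$library == "control"]
    N2 <- stats_tbl$clean_reads[stats_tbl$library == "treated"]
    known <- read_tsv(p("known_mirnas.tsv"))
    novel <- if (file.exists(p("novel_mirnas.tsv"))) {
      read_tsv(p("novel_mirnas.tsv")) # absent when discovery is disabled
    } else {
      data.frame(name = character(0), mature_seq = character(0),
                 count_control = integer(0), count_treated = integer(0))
    }
    counts <- rbind(
      if (nrow(known) > 0L) {
        km <- known[!known$is_star, , drop = FALSE]
        do.call(rbind, lapply(split(km, km$name), function(g) data.frame(
          id = g$name[1], class = "known",
          sequence = g$sequence[which.max(g$count_control + g$count_treated)],
          count_control = sum(g$count_control),
          count_treated = sum(g$count_treated), stringsAsFactors = FALSE)))
      },
      if (nrow(novel) > 0L) data.frame(
        id = novel$name, class = "novel", sequence = novel$mature_seq,
        count_control = novel$count_control,
        count_treated = novel$count_treated, stringsAsFactors = FALSE))
    expr <- expression_table(counts, N1, N2, config$expression)
    write_tsv(expr, p("expression.tsv"))
    rq <- relative_quantity(read_tsv(p("ct.tsv")))
    write_tsv(rq, p("rq.tsv"))
  })

  run_stage("targets", function() {
    expr <- read_tsv(p("expression.tsv"))
    de <- expr[expr$call != "neutral", , drop = FALSE]
    if (nrow(de) == 0L) de <- expr # fall back to all miRNAs
    mirnas <- data.frame(id = de$id, sequence = de$sequence,
                         stringsAsFactors = FALSE)
    hits <- scan_transcriptome(mirnas, read_fasta(p("transcripts.fasta")),
                               config$targets)
    write_tsv(hits, p("targets.tsv"))
  })

  run_stage("enrich", function() {
    hits <- read_tsv(p("targets.tsv"))
    tx <- read_fasta(p("transcripts.fasta"))
    go <- read_tsv(p("go_map.tsv"))
    gene_of <- stats::setNames(tx$description, tx$id)
    target_genes <- unique(gene_of[hits$transcript])
    background <- unique(tx$description)
    enr <- if (length(target_genes) > 0L) {
      sea_enrichment(target_genes, background, go, config$enrichment$fdr_max)
    } else {
      data.frame(term = character(0), k = integer(0), n = integer(0),
                 K = integer(0), N = integer(0), pvalue = numeric(0),
                 fdr = numeric(0), significant = logical(0))
    }
    write_tsv(enr, p("enrichment.tsv"))
  })

  run_stage("report", function() {
    stats_tbl <- read_tsv(p("cleaning_stats.tsv"))
    tags <- read_tsv(p("tags.tsv"))
    known <- read_tsv(p("known_mirnas.tsv"))
    novel <- if (file.exists(p("novel_mirnas.tsv"))) {
      read_tsv(p("novel_mirnas.tsv"))
    } else {
      data.frame(name = character(0), count_control = integer(0),
                 count_treated = integer(0))
    }
    ann <- read_tsv(p("annotation.tsv"))
    row_for <- function(lib, cc) {
      s <- stats_tbl[stats_tbl$library == lib, ]
      known_tags <- known$tag_id
      unann <- ann$tag_id[ann$category == "unannotated"]
      data.frame(
        library = lib,
        raw_reads = s$raw_reads,
        removed = s$raw_reads - s$clean_reads,
        clean_reads = s$clean_reads,
        unique_tags = sum(tags[[cc]] > 0L),
        reads_mapped_to_mirbase = sum(tags[[cc]][tags$tag_id %in% known_tags]),
        reads_unannotated = sum(tags[[cc]][tags$tag_id %in% unann]),
        known_mirnas = length(unique(known$name[!known$is_star &
                                                  known[[cc]] > 0L])),
        novel_mirnas = sum(novel[[cc]] > 0L),
        stringsAsFactors = FALSE)
    }
    summary <- rbind(row_for("control", "count_control"),
                     row_for("treated", "count_treated"))
    write_tsv(summary, p("summary.tsv"))
  })

  invisible(outputs)
}
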