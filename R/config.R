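#' Default run configuration
#'
#' Every threshold used anywhere in the pipeline has a key here, with the
#' study's printed value as default where one exists; the remaining knobs
#' (cleaning-rule numerics, matching tolerances, scoring schema) are the
#' package's own documented defaults. The configuration is a nested list
#' serialized as YAML by [read_config()]/[write_config()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cleaning = list(
      min_mean_phred = 20,        # rule (i): mean Phred below this is low quality
      max_frac_below10 = 0.10,    # rule (i): >10% of bases under Phred 10
      adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
      adapter5_min_prefix = 8L,   # rule (ii): leading >=8 nt of the 5' adapter
      adapter5_max_mm = 1L,
      adapter3 = "TGGAATTCTCGG",  # fixed documented 12-mer 3' adapter
      adapter3_max_prefix = 12L,  # rule (iii): exact prefix search 12 -> 6
      adapter3_min_prefix = 6L,
      polya_frac = 0.80,          # rule (v): insert >= 80% A
      min_len = 16L,              # rule (vi)
      max_len = 36L
    ),
    mapping = list(
      seed_len = 12L,
      max_mismatch = 2L,          # "no more than 2 mismatches"
      max_hits = 20L              # copy-number cap
    ),
    annotation = list(
      max_mismatch = 2L,          # reference matching uses the mapping matcher
      max_shift = 2L              # end shifts tolerated against mature refs
    ),
    discovery = list(
      min_tag_len = 18L,          # Mireap (i)
      max_tag_len = 26L,          # Mireap (ii)
      max_copy = 20L,             # Mireap (v)
      mfe_max = -18.0,            # Mireap (vi), kcal/mol
      max_distance = 300L,        # Mireap (vii), mature-star distance
      min_paired = 19L,           # Mireap (viii), bp
      max_bulge = 8L,             # Mireap (ix)
      max_asymmetry = 4L,         # Mireap (x)
      flank = 20L,                # Mireap (xi), precursor flank
      max_duplex_mismatch = 2L,   # candidate criterion (iii)
      au_min = 0.30,              # criterion (v)
      au_max = 0.70,
      mfei_min = 0.85             # |MFEI| floor; set 0 to disable
    ),
    homology = list(
      word_size = 11L,
      min_identity = 0.90,
      min_coverage = 0.90,
      xdrop = 10
    ),
    expression = list(
      zero_floor = 0.01,          # TPM floor for fold-change only
      log2fc_up = 1.0,
      log2fc_down = -1.0,
      max_pvalue = 0.05
    ),
    targets = list(
      wobble = 0.5,
      mismatch = 1.0,
      gap = 2.0,
      seed_lo = 2L,               # seed region: miRNA positions 2-13
      seed_hi = 13L,
      seed_mult = 2.0,
      central_lo = 9L,            # mismatch/gap here switches to translation
      central_hi = 11L,
      expectation_cutoff = 3.0,
      len_delta = 2L              # window sizes len(miRNA) +/- this
    ),
    enrichment = list(
      fdr_max = 0.05
    ),
    synthetic = list(
      n_chrom = 12L,
      chrom_len = 50000L,
      n_genes = 30L,
      n_known = 14L,
      n_novel = 10L,
      n_decoys_genbank = 6L,      # rRNA / tRNA decoy loci
      n_decoys_rfam = 6L,         # snoRNA / snRNA / scRNA decoy loci
      n_repeats = 2L,
      repeat_copies = 4L,
      n_background = 400L,
      n_unannotated_bg = 60L,
      read_len = 50L,
      error_rate = 0.001,
      contaminant_fracs = c(low_quality = 0.02, adapter5_contaminant = 0.01,
                            no_adapter3 = 0.02, no_insert = 0.01,
                            polyA = 0.01, length_out_of_range = 0.02)
    )
  )
}

#' Load / save a run configuration
#'
#' Configurations are nested YAML documents; [read_config()] overlays the
#' file's values onto [default_config()] so partial files are valid.
#'
#' @param path path to a YAML configuration file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_cfg(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
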