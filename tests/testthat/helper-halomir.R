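# shared fixtures and oracles, built in code at test time

# exhaustive-enumeration folding oracle: minimum energy over every
# non-crossing structure (hairpin loops >= 3), scored independently of the
# dynamic program by structure_energy()
enum_fold_min <- function(seq) {
  n <- nchar(seq)
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  canp <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  structs <- function(i, j) {
    if (j - i + 1 <= 0) return("")
    if (j - i + 1 == 1) return(".")
    out <- paste0(".", structs(i + 1, j))
    for (k in (i + 4):j) {
      if (k > j) break
      if (canp(ch[i], ch[k])) {
        inner <- structs(i + 1, k - 1)
        rest <- structs(k + 1, j)
        out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
      }
    }
    out
  }
  ss <- structs(1, n)
  min(0, min(vapply(ss, function(s) structure_energy(seq, s), 0)))
}

# brute-force log-space tail-sum oracle for the exact count test
ac_pvalue_bruteforce <- function(x, y, N1, N2, kmax = NULL) {
  lpmf <- function(k) {
    k * (log(N2) - log(N1)) + lgamma(x + k + 1) - lgamma(x + 1) -
      lgamma(k + 1) - (x + k + 1) * log1p(N2 / N1)
  }
  if (is.null(kmax)) kmax <- max(1000, y + x + 50 * sqrt(x + y + 4))
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  lower <- exp(lse(lpmf(0:y)))
  upper <- exp(lse(lpmf(y:kmax)))
  min(1, 2 * min(lower, upper))
}

# exact hypergeometric upper tail by direct combinatorial summation
hyper_pvalue_exact <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# small synthetic configuration for fast unit-level runs
small_config <- function() {
  cfg <- default_config()
  cfg$synthetic$n_chrom <- 4L
  cfg$synthetic$chrom_len <- 20000L
  cfg$synthetic$n_genes <- 10L
  cfg$synthetic$n_known <- 6L
  cfg$synthetic$n_novel <- 5L
  cfg$synthetic$n_decoys_genbank <- 4L
  cfg$synthetic$n_decoys_rfam <- 3L
  cfg$synthetic$n_background <- 150L
  cfg$synthetic$n_unannotated_bg <- 25L
  cfg
}

# the default synthetic study run, produced once per test session
default_run_env <- new.env()
get_default_run <- function() {
  if (is.null(default_run_env$paths)) {
    outdir <- file.path(tempdir(), "halomir-default-run")
    t0 <- Sys.time()
    run_pipeline(default_config(), outdir, seed = 1L)
    default_run_env$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    default_run_env$paths <- outdir
  }
  list(dir = default_run_env$paths, elapsed = default_run_env$elapsed)
}

read_run <- function(run, file) read_tsv(file.path(run$dir, file))

random_fasta_records <- function(n, minlen = 10L, maxlen = 80L) {
  data.frame(
    id = sprintf("rec%03d", seq_len(n)),
    description = ifelse(seq_len(n) %% 2 == 0, sprintf("desc %d", seq_len(n)), ""),
    sequence = vapply(seq_len(n),
                      function(i) rand_dna(sample(minlen:maxlen, 1L)), ""),
    stringsAsFactors = FALSE)
}
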