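#' Tags-per-million normalization
#'
#' Normalized expression = count / library clean-read total x 10^6. Zero
#' counts are reported as 0; the zero floor applies only inside fold-change
#' computation, never in reports.
#'
#' @param count non-negative count (vectorized).
#' @param library_total library clean-read total (> 0).
#' @return TPM value(s).
#' @export
normalize_tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / library_total * 1e6
}

#' log2 fold-change of treated over control TPM
#'
#' Fold-change = log2(treated / control), with both arguments floored at
#' `zero_floor` TPM so library-exclusive miRNAs get a finite value.
#' Antisymmetric under swapping the two arguments.
#'
#' @param tpm_treated,tpm_control TPM values (>= 0, vectorized).
#' @param zero_floor TPM floor substituted for values below it.
#' @return log2 fold-change(s).
#' @export
log2_fold_change <- function(tpm_treated, tpm_control, zero_floor = 0.01) {
  log2(pmax(tpm_treated, zero_floor) / pmax(tpm_control, zero_floor))
}

.ac_log_pmf <- function(k, x, N1, N2) {
  # log P(k | x) for the Audic-Claverie exact count test:
  # P(k|x) = (N2/N1)^k (x+k)! / (x! k!) / (1 + N2/N1)^(x+k+1)
  lr <- log(N2) - log(N1)
  k * lr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(exp(lr))
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Exact count test for differential tag abundance
#'
#' The Audic-Claverie test: conditional on observing `x` counts in a
#' library of `N1` clean reads, the probability of `y` counts in a library
#' of `N2` reads is `P(y|x) = (N2/N1)^y (x+y)!/(x! y!) (1+N2/N1)^-(x+y+1)`.
#' The two-sided p-value is twice the smaller tail (capped at 1). All sums
#' run in log space; the distribution over k is normalized to within 1e-12.
#'
#' @param x,y observed counts in the two libraries (non-negative integers).
#' @param N1,N2 the corresponding library clean-read totals.
#' @return Two-sided p-value in (0, 1].
#' @export
count_pvalue <- function(x, y, N1, N2) {
  if (length(x) > 1L) {
    return(mapply(count_pvalue, x, y, MoreArgs = list(N1 = N1, N2 = N2)))
  }
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  lower <- .logsumexp(.ac_log_pmf(0:y, x, N1, N2))
  # upper tail summed directly until the remaining mass is negligible; the
  # term ratio P(k+1|x)/P(k|x) decreases in k, so once it is < 1 a geometric
  # sum bounds the remainder
  block <- 256L
  terms <- .ac_log_pmf(y, x, N1, N2)
  k0 <- y
  repeat {
    ks <- (k0 + 1L):(k0 + block)
    terms <- c(terms, .ac_log_pmf(ks, x, N1, N2))
    k0 <- k0 + block
    rk <- (N2 / N1) * (x + k0 + 1) / ((k0 + 1) * (1 + N2 / N1))
    if (rk < 1) {
      tail_bound <- terms[length(terms)] + log(rk) - log1p(-rk)
      if (tail_bound < max(terms) + log(1e-16)) break
    }
    if (k0 > y + 1e6) break
  }
  upper <- .logsumexp(terms)
  p <- 2 * min(exp(lower), exp(upper))
  min(1, p)
}

#' Classify a miRNA as up-, down-regulated or neutral
#'
#' Thresholds applied as printed, boundaries inclusive: up when log2FC >= 1
#' at P <= 0.05; down when log2FC <= -1 at P <= 0.05; neutral otherwise.
#'
#' @param log2fc,pvalue vectors of fold-changes and p-values.
#' @param config the `expression` section of [default_config()].
#' @return Character vector in {"up", "down", "neutral"}.
#' @export
classify_de <- function(log2fc, pvalue, config = default_config()$expression) {
  ifelse(log2fc >= config$log2fc_up & pvalue <= config$max_pvalue, "up",
         ifelse(log2fc <= config$log2fc_down & pvalue <= config$max_pvalue,
                "down", "neutral"))
}

#' Full differential-expression table for a set of miRNAs
#'
#' @param counts data.frame with `id`, `count_control`, `count_treated`.
#' @param N_control,N_treated library clean-read totals.
#' @param config the `expression` section of [default_config()].
#' @return data.frame adding `tpm_control`, `tpm_treated`, `log2fc`,
#'   `pvalue`, `qvalue` (Benjamini-Hochberg) and `call`.
#' @export
expression_table <- function(counts, N_control, N_treated,
                             config = default_config()$expression) {
  out <- counts
  out$N_control <- N_control
  out$N_treated <- N_treated
  out$tpm_control <- normalize_tpm(counts$count_control, N_control)
  out$tpm_treated <- normalize_tpm(counts$count_treated, N_treated)
  out$log2fc <- log2_fold_change(out$tpm_treated, out$tpm_control,
                                 config$zero_floor)
  out$pvalue <- count_pvalue(counts$count_control, counts$count_treated,
                             N_control, N_treated)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$call <- classify_de(out$log2fc, out$pvalue, config)
  out
}

#' Relative quantification by the comparative Ct method
#'
#' RQ = 2^-ddCt with ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control); replicates are averaged on the Ct
#' scale and the replicate standard deviation of dCt is propagated.
#'
#' @param ct data.frame with columns `target`, `sample`
#'   ("control"/"treated"), `ct_target`, `ct_reference`, `replicate`.
#' @return data.frame `target`, `rq`, `sd_log2` (standard deviation of the
#'   per-replicate ddCt estimates on the log2 scale).
#' @export
relative_quantity <- function(ct) {
  need <- c("target", "sample", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) stop("missing Ct columns: ",
                                      paste(setdiff(need, names(ct)), collapse = ", "))
  if (any(is.na(ct$ct_reference))) stop("missing reference Ct values")
  out <- lapply(split(ct, ct$target), function(g) {
    dct <- g$ct_target - g$ct_reference
    co <- g$sample == "control"
    tr <- g$sample == "treated"
    if (!any(co) || !any(tr)) stop("both samples required for ", g$target[1])
    ddct <- mean(dct[tr]) - mean(dct[co])
    sd_l2 <- sqrt(stats::var(dct[tr]) / sum(tr) + stats::var(dct[co]) / sum(co))
    data.frame(target = g$target[1], rq = 2^(-ddct),
               sd_log2 = if (is.finite(sd_l2)) sd_l2 else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
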