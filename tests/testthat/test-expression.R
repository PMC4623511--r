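test_that("TPM normalization follows the count-over-total formula", {
  expect_equal(normalize_tpm(5, 1e6), 5.0)
  expect_equal(normalize_tpm(0, 12345), 0.0)
  # the study's own library scale: miRBase-mapped reads over clean reads
  expect_equal(normalize_tpm(369307, 14638300), 369307 / 14638300 * 1e6)
  expect_error(normalize_tpm(5, 0), "positive")
  expect_error(normalize_tpm(-1, 10), "non-negative")
})

test_that("fold-change is antisymmetric and floored at the zero floor", {
  expect_equal(log2_fold_change(2, 1), 1.0)
  expect_equal(log2_fold_change(1, 2), -1.0)
  expect_equal(log2_fold_change(0, 10), log2(0.01 / 10))
  set.seed(91)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("the exact count test matches brute-force log-space summation", {
  cases <- list(c(0, 0, 1e6, 1e6), c(5, 9, 1e6, 1e6), c(50, 20, 2e6, 1e6),
                c(3, 40, 5e5, 8e5), c(120, 80, 1e6, 1.2e6), c(0, 12, 1e6, 9e5))
  for (cs in cases) {
    expect_equal(count_pvalue(cs[1], cs[2], cs[3], cs[4]),
                 ac_pvalue_bruteforce(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9,
                 label = paste(cs, collapse = ","))
  }
  expect_equal(count_pvalue(0, 0, 1e6, 1e6), 1.0)
  expect_lt(count_pvalue(100, 0, 1e6, 1e6), 1e-20)
})

test_that("the count-test distribution is normalized and symmetric", {
  # normalization: sum over k of P(k | x) == 1 to 1e-12
  for (x in c(0, 3, 25)) {
    N1 <- 1.4e6; N2 <- 0.9e6
    lpmf <- function(k) k * (log(N2) - log(N1)) + lgamma(x + k + 1) -
      lgamma(x + 1) - lgamma(k + 1) - (x + k + 1) * log1p(N2 / N1)
    ks <- 0:(5000 + 20 * x)
    expect_equal(sum(exp(lpmf(ks))), 1.0, tolerance = 1e-12)
  }
  # exchange behavior: the tails obey the exact complement identity
  # P(K <= y | x; N1, N2) + P(K <= x | y; N2, N1) = 1, so equal observed
  # counts give p = 1 and swapping the libraries changes the two-sided
  # min-tail p by at most the two boundary pmf terms (discreteness)
  set.seed(92)
  for (i in 1:10) {
    x <- rpois(1, 20); y <- rpois(1, 20)
    N1 <- runif(1, 5e5, 2e6); N2 <- runif(1, 5e5, 2e6)
    expect_equal(count_pvalue(x, x, N1, N1), 1.0, tolerance = 1e-12)
    lp <- function(k, x, N1, N2) k * (log(N2) - log(N1)) +
      lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(N2 / N1)
    slack <- 2 * (exp(lp(y, x, N1, N2)) + exp(lp(x, y, N2, N1)))
    expect_lte(abs(count_pvalue(x, y, N1, N2) - count_pvalue(y, x, N2, N1)),
               slack + 1e-12)
    # only the size ratio matters, not the absolute depths
    expect_equal(count_pvalue(x, y, N1, 1.3 * N1),
                 count_pvalue(x, y, 2 * N1, 2.6 * N1), tolerance = 1e-12)
  }
})

test_that("p decreases as the observed count departs from expectation", {
  x <- 30; N1 <- N2 <- 1e6
  ys <- c(30, 45, 60, 90, 150)
  ps <- vapply(ys, function(y) count_pvalue(x, y, N1, N2), 0)
  expect_true(all(diff(ps) < 0))
  ys2 <- c(30, 20, 10, 3, 0)
  ps2 <- vapply(ys2, function(y) count_pvalue(x, y, N1, N2), 0)
  expect_true(all(diff(ps2) < 0))
})

test_that("up/down calls apply thresholds with inclusive boundaries", {
  expect_equal(classify_de(1.0, 0.05), "up")
  expect_equal(classify_de(-1.0, 0.05), "down")
  expect_equal(classify_de(0.9, 0.001), "neutral")
  expect_equal(classify_de(2.5, 0.06), "neutral")
  expect_equal(classify_de(1.2, 0.01), "up")
  # directional consistency on a full table
  set.seed(93)
  counts <- data.frame(id = sprintf("m%02d", 1:30),
                       count_control = rpois(30, 40),
                       count_treated = rpois(30, 40))
  tab <- expression_table(counts, 1e6, 1e6)
  up <- tab$call == "up"
  expect_true(all(tab$tpm_treated[up] > tab$tpm_control[up]))
  dn <- tab$call == "down"
  expect_true(all(tab$tpm_treated[dn] < tab$tpm_control[dn]))
  expect_true(all(tab$qvalue >= tab$pvalue))
})

test_that("comparative Ct quantification matches the 2^-ddCt formula", {
  mk <- function(ct_tc, ct_rc, ct_tt, ct_rt) {
    do.call(rbind, lapply(1:3, function(r) data.frame(
      target = "miRX", sample = c("control", "treated"),
      ct_target = c(ct_tc, ct_tt), ct_reference = c(ct_rc, ct_rt),
      replicate = r)))
  }
  expect_equal(relative_quantity(mk(20, 15, 20, 15))$rq, 1.0)
  expect_equal(relative_quantity(mk(20, 15, 19, 15))$rq, 2.0)
  expect_equal(relative_quantity(mk(22, 15, 20, 15))$rq, 4.0)
  bad <- mk(20, 15, 20, 15)
  bad$ct_reference[2] <- NA
  expect_error(relative_quantity(bad), "reference")
})

test_that("pipeline qPCR quantities track the planted fold-changes", {
  run <- get_default_run()
  rq <- read_run(run, "rq.tsv")
  # planted: two up-regulated (RQ ~= 4), one down (RQ ~= 0.25), one neutral
  expect_gte(nrow(rq), 3L)
  expect_true(any(rq$rq > 3))
  expect_true(any(rq$rq < 0.4))
})
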