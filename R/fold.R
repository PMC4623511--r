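#' Nearest-neighbor RNA energy parameters
#'
#' The parameter table used by the bundled folding backend: stacking energies
#' for adjacent canonical pairs (Watson-Crick plus G:U), tabulated
#' hairpin/bulge/internal loop penalties with logarithmic extrapolation for
#' larger loops, and a linear multiloop model. Values are rounded
#' Turner-style constants in kcal/mol; they are the model's own documented
#' table, and folding optimality is always stated relative to this table.
#'
#' Pair order for the stacking matrix rows/columns is AU, CG, GC, UA, GU, UG;
#' row = outer (closing) pair, column = inner (stacked) pair.
#'
#' @return A list with components `stack` (6x6 matrix), `hairpin` (penalty
#'   for loop sizes 1..9; sizes below `min_hairpin` are infinite), `bulge`
#'   (sizes 1..6), `internal` (total sizes 1..6; size 1 unused), `ml_a`,
#'   `ml_b`, `ml_c` (multiloop offset/branch/unpaired terms), `lxc`
#'   (log-extrapolation coefficient), `asym_coef` and `asym_max` (internal
#'   loop asymmetry penalty), `max_loop` (largest interior loop considered)
#'   and `min_hairpin` (minimum hairpin loop size, 3).
#' @export
energy_params <- function() {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU    CG    GC    UA    GU    UG      outer:
    -0.9, -2.2, -2.1, -1.1, -0.6, -1.4, # AU
    -2.1, -3.3, -2.4, -2.1, -1.4, -2.1, # CG
    -2.4, -3.4, -3.3, -2.2, -1.5, -2.5, # GC
    -1.3, -2.4, -2.1, -0.9, -1.0, -1.3, # UA
    -1.3, -2.5, -2.1, -1.4, -0.5, +1.3, # GU
    -1.0, -1.5, -1.4, -0.6, +0.3, -0.5  # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(
    stack = stack,
    hairpin = c(Inf, Inf, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),
    bulge = c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4),
    internal = c(Inf, 1.5, 1.6, 1.7, 2.0, 2.2),
    ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
    lxc = 1.08,
    asym_coef = 0.5, asym_max = 3.0,
    max_loop = 30L, min_hairpin = 3L
  )
}

.base_code <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L)
.pair_idx <- matrix(0L, 4, 4)
.pair_idx[1, 4] <- 1L # AU
.pair_idx[2, 3] <- 2L # CG
.pair_idx[3, 2] <- 3L # GC
.pair_idx[4, 1] <- 4L # UA
.pair_idx[3, 4] <- 5L # GU
.pair_idx[4, 3] <- 6L # UG

#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' The default backend is the bundled dynamic program over the
#' [energy_params()] table; it returns the optimal non-pseudoknotted
#' structure under that table (verified against exhaustive enumeration in
#' the test suite). Any function with the same contract (sequence in,
#' list with `structure` and `mfe` out) can be plugged in via `backend`.
#'
#' @param seq RNA sequence (A/C/G/U; T is accepted and read as U; N allowed,
#'   never pairs).
#' @param backend folding backend; defaults to the bundled dynamic program.
#' @param par energy parameter table for the bundled backend.
#' @return A `FoldResult`: list with `structure` (dot-bracket string, same
#'   length as `seq`) and `mfe` (kcal/mol, <= 0; 0 iff no base pairs).
#' @export
fold <- function(seq, backend = NULL, par = energy_params()) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGUTN]", seq)) {
    stop("fold(): sequence contains characters outside {A,C,G,U,N}")
  }
  seq <- chartr("T", "U", seq)
  if (!is.null(backend)) {
    res <- backend(seq)
  } else {
    res <- fold_backend_cpp(seq, par)
  }
  if (!is.list(res) || is.null(res$structure) || is.null(res$mfe) ||
      nchar(res$structure) != nchar(seq)) {
    stop("folding backend returned an invalid FoldResult")
  }
  structure(list(structure = res$structure, mfe = as.numeric(res$mfe)),
            class = "FoldResult")
}

#' Pair table of a dot-bracket structure
#'
#' @param db dot-bracket string (balanced, non-crossing).
#' @return Integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or 0 if unpaired.
#' @export
pair_table <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (chars[i] != ".") {
      stop("invalid character in dot-bracket string: ", chars[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pt
}

#' Free energy of a given structure under the bundled energy model
#'
#' Decomposes a dot-bracket structure into its loops (hairpin, stack, bulge,
#' internal, multiloop, exterior) and sums the same energy terms the folding
#' dynamic program uses. Serves as an independent scorer: the energy of the
#' structure returned by [fold()] must equal its reported MFE.
#'
#' @inheritParams fold
#' @param db dot-bracket structure, same length as `seq`.
#' @return Energy in kcal/mol (possibly `Inf` for loops the model excludes).
#' @export
structure_energy <- function(seq, db, par = energy_params()) {
  seq <- chartr("T", "U", toupper(seq))
  codes <- .base_code[strsplit(seq, "")[[1]]]
  codes[is.na(codes)] <- 0L
  pt <- pair_table(db)
  n <- length(pt)
  if (nchar(seq) != n) stop("sequence and structure lengths differ")
  pidx <- function(i, j) {
    if (codes[i] == 0L || codes[j] == 0L) return(0L)
    .pair_idx[codes[i], codes[j]]
  }
  eH <- function(sz) {
    if (sz < par$min_hairpin) return(Inf)
    if (sz <= 9) return(par$hairpin[sz])
    par$hairpin[9] + par$lxc * log(sz / 9)
  }
  eB <- function(sz) {
    if (sz > par$max_loop) return(Inf)
    if (sz <= 6) return(par$bulge[sz])
    par$bulge[6] + par$lxc * log(sz / 6)
  }
  eI <- function(n1, n2) {
    sz <- n1 + n2
    if (sz > par$max_loop) return(Inf)
    base <- if (sz <= 6) par$internal[sz] else par$internal[6] + par$lxc * log(sz / 6)
    base + min(par$asym_max, par$asym_coef * abs(n1 - n2))
  }
  # direct children (enclosed pairs) of region (i, j), exclusive bounds
  children <- function(i, j) {
    out <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (pt[k] > k) {
        out[[length(out) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    out
  }
  total <- 0
  # exterior loop contributes nothing; walk every pair and score its loop
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next
    if (pidx(i, j) == 0L) return(Inf) # non-canonical pair is not in the model
    kids <- children(i, j)
    if (length(kids) == 0L) {
      total <- total + eH(j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        q <- pidx(k, l)
        if (q == 0L) return(Inf)
        total <- total + par$stack[pidx(i, j), q]
      } else if (n1 == 0L || n2 == 0L) {
        total <- total + eB(n1 + n2)
      } else {
        total <- total + eI(n1, n2)
      }
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(kids, function(kk) kk[2] - kk[1] + 1L, 1L))
      total <- total + par$ml_a + par$ml_b * (1L + length(kids)) + par$ml_c * unpaired
    }
  }
  total
}
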