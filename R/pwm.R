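#' Position weight matrices
#'
#' A `pwm` is a per-position nucleotide probability model of a DNA motif:
#' a 4 x width matrix of probabilities (rows A, C, G, T; every column sums
#' to 1) together with a 0-order background distribution. Scores are
#' log2-odds against the background, in bits.
#'
#' @param mat numeric 4 x width matrix of column probabilities, rows in
#'   A, C, G, T order.
#' @param background numeric length-4 background probabilities (default
#'   uniform).
#' @return An object of class `pwm`.
#' @examples
#' p <- pwm(matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), nrow = 4))
#' consensus(p)
#' @export
pwm <- function(mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("pwm matrix must have 4 rows (A, C, G, T)")
  if (any(mat < 0) || any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("pwm columns must be probabilities summing to 1")
  }
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  rownames(mat) <- .BASES
  structure(list(mat = mat, background = background, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, consensus %s\n", x$width, consensus(x)))
  print(round(x$mat, 3))
  invisible(x)
}

#' @export
dim.pwm <- function(x) c(4L, x$width)

#' Build a PWM from aligned sites
#'
#' Column frequencies of equal-length ACGT sites with an additive
#' pseudocount per base.
#'
#' @param sites character vector of equal-length DNA strings.
#' @param pseudocount additive count per base per column (default 0.25).
#' @param background background distribution passed to [pwm()].
#' @return A `pwm`.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.25,
                           background = rep(0.25, 4)) {
  sites <- as.character(sites)
  if (length(sites) == 0L) stop("no sites supplied")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must be of equal length")
  codes <- vapply(sites, seq_encode, integer(w))  # w x n
  if (anyNA(codes)) stop("sites must contain only A, C, G, T")
  codes <- matrix(codes, nrow = w)
  counts <- vapply(seq_len(w), function(j) {
    tabulate(codes[j, ], nbins = 4L)
  }, numeric(4))
  counts <- counts + pseudocount
  pwm(sweep(counts, 2, colSums(counts), "/"), background = background)
}

#' IUPAC-style consensus of a PWM
#'
#' Emits the base letter wherever the maximum column probability reaches
#' `threshold`, and `N` elsewhere.
#'
#' @param x a `pwm`.
#' @param threshold minimum column probability for a fixed base
#'   (default 0.8).
#' @return A character string of length `width`.
#' @export
consensus <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "pwm"))
  idx <- apply(x$mat, 2, which.max)
  top <- x$mat[cbind(idx, seq_len(x$width))]
  out <- ifelse(top >= threshold, .BASES[idx], "N")
  paste(out, collapse = "")
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and complements the base order; an
#' involution (`pwm_revcomp(pwm_revcomp(p))` equals `p`).
#'
#' @param x a `pwm`.
#' @return A `pwm` modelling the motif on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$mat[4:1, rev(seq_len(x$width)), drop = FALSE]
  pwm(m, background = x$background)
}

# log2-odds matrix (4 x width), in bits
pwm_logodds <- function(x) {
  log2(x$mat / x$background)
}

#' Log-odds score of a k-mer
#'
#' Sum over positions of `log2(column[base] / background[base])`, in
#' bits. Any non-ACGT base yields `NA` (such windows are skipped when
#' scanning).
#'
#' @param x a `pwm`.
#' @param kmer a DNA string of length `width`.
#' @return Score in bits, or `NA`.
#' @export
score_kmer <- function(x, kmer) {
  stopifnot(inherits(x, "pwm"))
  codes <- seq_encode(kmer)
  if (length(codes) != x$width) stop("kmer length must equal pwm width")
  if (anyNA(codes)) return(NA_real_)
  lo <- pwm_logodds(x)
  sum(lo[cbind(codes, seq_len(x$width))])
}

# Null score distribution of a PWM under the background model.
# Exact for width <= max_exact (all achievable scores enumerated by
# successive outer addition); otherwise a lattice DP at `granularity`
# bits. Returns list(score = increasing numeric, tail = P(S >= score)).
pwm_score_distribution <- function(x, max_exact = 10L, granularity = 1e-3) {
  lo <- pwm_logodds(x)
  bg <- x$background
  w <- x$width
  if (w <= max_exact) {
    sc <- 0
    pr <- 1
    for (j in seq_len(w)) {
      sc <- outer(sc, lo[, j], "+")
      pr <- outer(pr, bg, "*")
      sc <- as.numeric(sc)
      pr <- as.numeric(pr)
      # collapse identical scores to keep the table small
      o <- order(sc)
      sc <- sc[o]; pr <- pr[o]
      grp <- cumsum(c(TRUE, diff(sc) > 0))
      pr <- as.numeric(rowsum(pr, grp))
      sc <- sc[!duplicated(grp)]
    }
    tail <- rev(cumsum(rev(pr)))
    return(list(score = sc, tail = pmin(tail, 1), fuzz = 1e-9))
  }
  # lattice DP: integer-scaled scores, rounded to `granularity` bits
  step <- granularity
  loi <- round(lo / step)
  offset <- apply(loi, 2, min)
  span <- sum(apply(loi, 2, max) - offset)
  dist <- numeric(span + 1L)  # index k -> P(shifted score == k)
  dist[1L] <- 1
  upto <- 0L
  for (j in seq_len(w)) {
    shifts <- loi[, j] - offset[j]
    newdist <- numeric(span + 1L)
    idx <- seq_len(upto + 1L)
    for (b in 1:4) {
      rng <- idx + shifts[b]
      newdist[rng] <- newdist[rng] + dist[idx] * bg[b]
    }
    dist <- newdist
    upto <- upto + max(shifts)
  }
  sc <- (seq_along(dist) - 1L + sum(offset)) * step
  keep <- dist > 0
  sc <- sc[keep]; pr <- dist[keep]
  tail <- rev(cumsum(rev(pr)))
  # per-column rounding can shift an achievable score by up to step/2
  list(score = sc, tail = pmin(tail, 1), fuzz = w * step)
}

#' Exact p-value of a PWM score
#'
#' `P(S >= score)` for a random k-mer drawn from the PWM's background
#' model, from the exact null score distribution (a dynamic program over
#' column score sums; a discretized lattice is used only for very wide
#' matrices, at 1e-3 bit granularity).
#'
#' @param x a `pwm`.
#' @param score score(s) in bits.
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(x, score) {
  stopifnot(inherits(x, "pwm"))
  dist <- pwm_score_distribution(x)
  score_pvalue_from_dist(dist, score)
}

# P(S >= score) looked up in a precomputed distribution; `fuzz` absorbs
# float noise so a score equal to an achievable one lands in its bin.
score_pvalue_from_dist <- function(dist, score, fuzz = dist$fuzz) {
  n <- length(dist$score)
  # first achievable score >= score - fuzz
  j <- findInterval(score - fuzz, dist$score) + 1L
  # exact hit: findInterval counts score[i] <= s - fuzz, so an achievable
  # score within fuzz of s indexes itself
  out <- ifelse(j > n, .Machine$double.xmin, dist$tail[pmin(j, n)])
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' Reference FixK-family PWM (TTGAT-N4-ATCAA)
#'
#' The canonical Fnr/Crp-family palindromic binding-site consensus used
#' as a comparison reference: ten fixed positions at probability
#' `p_fixed`, four central spacer positions uniform.
#'
#' @param p_fixed probability mass on the consensus base at fixed
#'   positions (default 0.97).
#' @return A `pwm` of width 14 whose [consensus()] is
#'   `"TTGATNNNNATCAA"`.
#' @export
fixk_pwm <- function(p_fixed = 0.97) {
  cons <- "TTGATNNNNATCAA"
  codes <- seq_encode(cons)
  m <- matrix(0.25, nrow = 4, ncol = nchar(cons))
  for (j in seq_along(codes)) {
    if (!is.na(codes[j])) {
      m[, j] <- (1 - p_fixed) / 3
      m[codes[j], j] <- p_fixed
    }
  }
  pwm(m)
}
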