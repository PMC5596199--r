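# Vectorized window scoring: codes is an integer vector (1..4, NA for
# ambiguous), returns the log-odds score of every window of `pwm` width,
# NA where the window contains a non-ACGT base.
score_windows <- function(lo, codes) {
  w <- ncol(lo)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  na <- is.na(codes)
  codes2 <- ifelse(na, 1L, codes)
  sc <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    seg <- j:(j + n - 1L)
    sc <- sc + lo[codes2[seg] + (j - 1L) * 4L]
    bad <- bad | na[seg]
  }
  sc[bad] <- NA_real_
  sc
}

#' Scan sequences for PWM matches
#'
#' Scores every window of every sequence on both strands and reports
#' occurrences whose exact p-value (see [score_pvalue()]) is at or below
#' `p_threshold`. Coordinates are 1-based inclusive on the forward
#' strand; a minus-strand hit is the reverse-complement motif matching
#' the forward sequence at those coordinates.
#'
#' @param x a [pwm()].
#' @param sequences `DNAStringSet` or named character vector.
#' @param p_threshold report hits with p-value at or below this
#'   (default 1e-4).
#' @param both_strands scan the minus strand too (default TRUE).
#' @return data.frame with columns `replicon, start, end, strand, score,
#'   p_value`.
#' @export
scan_pwm <- function(x, sequences, p_threshold = 1e-4, both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"))
  seqs <- as_seq_character(sequences)
  dist <- pwm_score_distribution(x)
  lo <- pwm_logodds(x)
  lor <- pwm_logodds(pwm_revcomp(x))
  res <- list()
  for (nm in names(seqs)) {
    codes <- seq_encode(seqs[[nm]])
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      sc <- score_windows(if (st == "+") lo else lor, codes)
      if (!length(sc)) next
      p <- rep(NA_real_, length(sc))
      ok <- !is.na(sc)
      p[ok] <- score_pvalue_from_dist(dist, sc[ok])
      keep <- which(!is.na(p) & p <= p_threshold)
      if (!length(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        replicon = nm,
        start = keep,
        end = keep + x$width - 1L,
        strand = st,
        score = sc[keep],
        p_value = p[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$replicon, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Converts 1-based inclusive hit coordinates to BED's 0-based half-open
#' convention; the score column carries the hit score in bits.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param path output path.
#' @param name feature name prefix (default "hit").
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = "hit") {
  bed <- data.frame(
    chrom = hits$replicon,
    chromStart = hits$start - 1L,
    chromEnd = hits$end,
    name = paste0(name, seq_len(nrow(hits))),
    score = round(hits$score, 4),
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 motif hits back to the internal 1-based representation
#'
#' @param path BED file path.
#' @return data.frame with `replicon, start, end, strand, score`.
#' @export
read_hits_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(replicon = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
             strand = bed[[6]], score = bed[[5]], stringsAsFactors = FALSE)
}
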