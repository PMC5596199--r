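# Integer sequence codes: A=1, C=2, G=3, T=4; anything else NA.
# Complement is 5 - code, so reverse-complement is rev(5 - codes).

.CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("a")] <- 1L
  x[utf8ToInt("C")] <- 2L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("g")] <- 3L
  x[utf8ToInt("T")] <- 4L; x[utf8ToInt("t")] <- 4L
  x
})

.BASES <- c("A", "C", "G", "T")

seq_encode <- function(x) {
  .CODE[utf8ToInt(as.character(x))]
}

seq_decode <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- .BASES[codes[ok]]
  paste(out, collapse = "")
}

revcomp_codes <- function(codes) {
  rev(5L - codes)
}

revcomp_string <- function(x) {
  seq_decode(revcomp_codes(seq_encode(x)))
}

# Coerce DNAStringSet / character to a named character vector of sequences.
as_seq_character <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else {
    out <- as.character(sequences)
    names(out) <- names(sequences)
  }
  if (is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}
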