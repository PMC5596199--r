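#' Read motifs from a minimal MEME text file
#'
#' Parses `MOTIF` and `letter-probability matrix` blocks (and an optional
#' `Background letter frequencies` line) from MEME motif format.
#'
#' @param path file path.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)]
    if (length(bg) != 4L) bg <- rep(0.25, 4)
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    wtok <- regmatches(lines[h], regexpr("w=\\s*\\d+", lines[h]))
    w <- as.integer(sub("w=\\s*", "", wtok))
    rows <- lines[(h + 1L):(h + w)]
    # each file row is one motif position (A C G T); columns of the pwm
    m <- vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE)
    m <- sweep(m, 2, colSums(m), "/")  # normalize float fuzz
    out[[name]] <- pwm(m, background = bg)
  }
  out
}

#' Write motifs to a minimal MEME text file
#'
#' @param motifs a [pwm()] or named list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "pwm")) motifs <- list(motif_1 = motifs)
  if (is.null(names(motifs))) {
    names(motifs) <- paste0("motif_", seq_along(motifs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies"), con)
  bg <- motifs[[1]]$background
  writeLines(sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3],
                     bg[4]), con)
  for (nm in names(motifs)) {
    p <- motifs[[nm]]
    writeLines(c("", paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         p$width)), con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$mat[1, j], p$mat[2, j],
                         p$mat[3, j], p$mat[4, j]), con)
    }
  }
  invisible(path)
}
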