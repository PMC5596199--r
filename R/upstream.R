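#' Extract upstream promoter windows
#'
#' Strand-aware 5' windows: for a + strand gene the `window` bp ending
#' just before its start; for a - strand gene the reverse complement of
#' the `window` bp just after its end. Windows are truncated only at
#' replicon ends (neighbouring ORFs are not masked); truncated windows
#' are flagged.
#'
#' @param annotation annotation data.frame.
#' @param sequences named character vector or `DNAStringSet`.
#' @param window upstream window length in bp (default 200).
#' @param genes optional subset of gene ids.
#' @return list with `sequences` (named character, one per gene) and
#'   `truncated` (logical vector).
#' @export
extract_upstream <- function(annotation, sequences, window = 200,
                             genes = NULL) {
  stopifnot(window >= 1)
  seqs <- as_seq_character(sequences)
  ann <- annotation
  if (!is.null(genes)) {
    ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  }
  out <- character(nrow(ann))
  trunc <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    L <- nchar(seqs[[g$replicon]])
    if (g$strand == "+") {
      s <- max(1L, g$start - window)
      e <- g$start - 1L
      trunc[i] <- g$start - window < 1L
      out[i] <- if (e >= s) substr(seqs[[g$replicon]], s, e) else ""
    } else {
      s <- g$end + 1L
      e <- min(L, g$end + window)
      trunc[i] <- g$end + window > L
      out[i] <- if (e >= s) {
        revcomp_string(substr(seqs[[g$replicon]], s, e))
      } else {
        ""
      }
    }
  }
  names(out) <- ann$gene_id
  names(trunc) <- ann$gene_id
  list(sequences = out, truncated = trunc)
}
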