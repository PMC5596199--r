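# Dataset readers/writers: FASTA via Biostrings, GFF3 via rtracklayer,
# counts and truth tables as TSV.

#' Write a simulated dataset to disk
#'
#' Emits `genome.fasta`, `annotation.gff3` (1-based inclusive; gene
#' features carry `ID`, `operon_id`, `operon_order`), `counts.tsv`
#' (header `gene_id, length, <strain>.<condition>.<rep>...`) and truth
#' TSVs.
#'
#' @param dataset list from [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(out_dir, "genome.fasta"),
             gff = file.path(out_dir, "annotation.gff3"),
             counts = file.path(out_dir, "counts.tsv"),
             hits = file.path(out_dir, "truth_hits.tsv"),
             lfc = file.path(out_dir, "truth_lfc.tsv"),
             regulated = file.path(out_dir, "truth_regulated.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$sequences), paths[["fasta"]])
  write_annotation_gff3(dataset$annotation, paths[["gff"]])
  write_counts_tsv(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$truth$planted_hits, paths[["hits"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$true_lfc, paths[["lfc"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$regulated_genes, paths[["regulated"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write / read the gene annotation as GFF3
#'
#' @param annotation annotation data.frame.
#' @param path GFF3 path.
#' @return `path` (write) or the annotation data.frame (read).
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$operon_id <- annotation$operon_id
  S4Vectors::mcols(gr)$operon_order <- annotation$operon_order
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = as.character(S4Vectors::mcols(gr)$ID),
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             operon_id = as.character(S4Vectors::mcols(gr)$operon_id),
             operon_order = as.integer(S4Vectors::mcols(gr)$operon_order),
             stringsAsFactors = FALSE)
}

#' Write / read a counts table as TSV
#'
#' @param table an `abundance_table`.
#' @param path TSV path.
#' @return `path` (write) or an `abundance_table` (read).
#' @export
write_counts_tsv <- function(table, path) {
  df <- data.frame(gene_id = table$gene_id, length = table$length,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  parts <- strsplit(colnames(counts), ".", fixed = TRUE)
  samples <- data.frame(
    strain = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    replicate = as.integer(vapply(parts, `[`, "", 3L)),
    label = colnames(counts), stringsAsFactors = FALSE)
  tab <- list(gene_id = df$gene_id, length = df$length,
              samples = samples, counts = counts)
  class(tab) <- "abundance_table"
  tab
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_seq_character(x)
}
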