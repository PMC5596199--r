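# Motif/operon classification of genes, ANOVA + Tukey HSD on group log2
# fold changes, within-operon signal decay, and region enrichment of
# flagged regulator genes.

# does each transcription unit (operon) have a motif hit within `window`
# bp upstream of its first gene, in either orientation?
operon_has_motif <- function(annotation, hits, window = 200) {
  heads <- annotation[annotation$operon_order == 1L, , drop = FALSE]
  d <- upstream_distances(heads, hits, max_window = window)
  has <- !is.na(d)
  names(has) <- heads$operon_id
  has
}

#' Four-group motif/operon classification
#'
#' A: single-gene transcription unit with a motif upstream; B: single
#' without; C: member of an operon with a motif upstream of its first
#' gene; D: member of an operon without. Hits within ORFs are excluded
#' before classification; multiple upstream hits count as one.
#'
#' @param annotation annotation data.frame.
#' @param hits motif hit data.frame.
#' @param window upstream window in bp (default 200).
#' @return named character vector (A/B/C/D), one per gene.
#' @export
classify_four_groups <- function(annotation, hits, window = 200) {
  clean <- filter_orf_hits(hits, annotation)
  has <- operon_has_motif(annotation, clean, window)
  op_size <- table(annotation$operon_id)
  single <- as.vector(op_size[annotation$operon_id] == 1L)
  motif <- as.vector(has[annotation$operon_id])
  out <- ifelse(single, ifelse(motif, "A", "B"), ifelse(motif, "C", "D"))
  names(out) <- annotation$gene_id
  out
}

#' Five-group order-resolved classification
#'
#' A: first-order gene of a motif-bearing transcription unit (singletons
#' count as first-order); B/C: second/third-order genes of motif-bearing
#' operons; E: member of a motif-less multi-gene operon; Z: single-gene
#' transcription unit without a motif. Orders beyond `max_order` in
#' motif-bearing operons are labelled `">max"` and excluded from
#' testing.
#'
#' @inheritParams classify_four_groups
#' @param max_order deepest order given its own group (default 3).
#' @return named character vector (A/B/C/E/Z or ">max").
#' @export
classify_five_groups <- function(annotation, hits, window = 200,
                                 max_order = 3) {
  clean <- filter_orf_hits(hits, annotation)
  has <- operon_has_motif(annotation, clean, window)
  motif <- as.vector(has[annotation$operon_id])
  ord <- annotation$operon_order
  op_size <- table(annotation$operon_id)
  single <- as.vector(op_size[annotation$operon_id] == 1L)
  out <- character(nrow(annotation))
  out[motif & ord == 1L] <- "A"
  out[motif & ord == 2L] <- "B"
  out[motif & ord == 3L] <- "C"
  out[motif & ord > max_order] <- ">max"
  out[!motif & single] <- "Z"
  out[!motif & !single] <- "E"
  names(out) <- annotation$gene_id
  out
}

#' One-way ANOVA with Tukey HSD on group log2 fold changes
#'
#' Fixed-effects ANOVA via [stats::aov()] and studentized-range adjusted
#' pairwise p-values via [stats::TukeyHSD()]. Groups with fewer than 2
#' members are dropped with a warning.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param labels named character vector of group labels (same genes).
#' @return list: `group_means`, `anova` (F, df1, df2, p), `tukey`
#'   (data.frame of pairwise diffs and adjusted p).
#' @export
group_anova_tukey <- function(log2fc, labels) {
  genes <- intersect(names(log2fc), names(labels))
  y <- log2fc[genes]
  g <- labels[genes]
  keep <- !is.na(y) & !is.na(g) & g != ">max"
  y <- y[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping groups with fewer than 2 members: ",
            paste(small, collapse = ", "))
    sel <- !(g %in% small)
    y <- y[sel]; g <- g[sel]
  }
  if (length(unique(g)) < 2) stop("need at least 2 groups of size >= 2")
  d <- data.frame(y = y, g = factor(g))
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    group_means = tapply(y, g, mean),
    anova = list(F = an[1, "F value"], df1 = an[1, "Df"],
                 df2 = an[2, "Df"], p = an[1, "Pr(>F)"]),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE)
  )
}

#' Within-operon expression decay profile
#'
#' Mean log2 fold change by within-operon order (1..`max_order`),
#' separately for motif-bearing and motif-less transcription units, with
#' a monotonicity flag: TRUE when motif-set means increase strictly
#' toward zero across the observed orders.
#'
#' @param log2fc named per-gene log2 fold changes.
#' @param labels five-group labels from [classify_five_groups()].
#' @param annotation annotation data.frame.
#' @param max_order deepest order profiled (default 3).
#' @return list: `motif` and `no_motif` data.frames (`order, mean, se,
#'   n`), `monotone` flag (NA when fewer than 2 orders observed).
#' @export
operon_decay_profile <- function(log2fc, labels, annotation,
                                 max_order = 3) {
  ord <- annotation$operon_order[match(names(labels), annotation$gene_id)]
  per_order <- function(sel) {
    do.call(rbind, lapply(seq_len(max_order), function(k) {
      y <- log2fc[names(labels)[sel & ord == k]]
      y <- y[!is.na(y)]
      data.frame(order = k,
                 mean = if (length(y)) mean(y) else NA_real_,
                 se = if (length(y) > 1) stats::sd(y) / sqrt(length(y))
                      else NA_real_,
                 n = length(y))
    }))
  }
  motif_sel <- labels %in% c("A", "B", "C")
  nomotif_sel <- labels %in% c("Z", "E")
  prof_m <- per_order(motif_sel)
  prof_n <- per_order(nomotif_sel)
  means <- prof_m$mean[!is.na(prof_m$mean)]
  monotone <- if (length(means) < 2) NA else all(diff(means) > 0)
  list(motif = prof_m, no_motif = prof_n, monotone = monotone)
}

#' Region enrichment of flagged regulator genes
#'
#' Fold overrepresentation of flagged genes in a region relative to a
#' genome-length-proportional expectation:
#' `(k/K) / (region_bp/genome_bp)`, with an auxiliary hypergeometric
#' tail p when gene counts are supplied.
#'
#' @param k flagged genes inside the region.
#' @param K flagged genes genome-wide (>= k, > 0).
#' @param region_bp,genome_bp region and genome lengths in bp.
#' @param genes_in_region,genes_total optional gene counts for the
#'   hypergeometric p-value.
#' @return list: `fold`, `p_hyper` (NA without gene counts).
#' @export
region_enrichment <- function(k, K, region_bp, genome_bp,
                              genes_in_region = NULL, genes_total = NULL) {
  if (K == 0) stop("K must be positive")
  stopifnot(k >= 0, K >= k, region_bp > 0, genome_bp >= region_bp)
  fold <- (k / K) / (region_bp / genome_bp)
  p <- NA_real_
  if (!is.null(genes_in_region) && !is.null(genes_total)) {
    p <- stats::phyper(k - 1, genes_in_region, genes_total - genes_in_region,
                       K, lower.tail = FALSE)
  }
  list(fold = fold, p_hyper = p)
}
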