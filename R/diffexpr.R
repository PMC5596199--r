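# FPKM normalization, per-contrast log2 fold change, Welch t-test with
# minimum-count gating, Benjamini-Hochberg FDR.

#' Fragments per kilobase per million mapped reads
#'
#' `1e9 * count / (gene_length_bp * total_mapped_in_sample)`.
#'
#' @param count raw count(s).
#' @param gene_length_bp gene length(s), bp (> 0).
#' @param total_mapped_in_sample total mapped fragments in the sample
#'   (> 0).
#' @return FPKM value(s).
#' @export
fpkm <- function(count, gene_length_bp, total_mapped_in_sample) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(total_mapped_in_sample <= 0)) stop("total mapped must be positive")
  1e9 * count / (gene_length_bp * total_mapped_in_sample)
}

#' FPKM matrix of an abundance table
#'
#' Column totals are the per-sample count sums (the pipeline has no
#' alignment stage, so the table itself defines the sequencing depth).
#'
#' @param table an `abundance_table` (see [simulate_expression()] /
#'   [read_counts_tsv()]).
#' @return numeric matrix, genes x samples.
#' @export
fpkm_matrix <- function(table) {
  totals <- colSums(table$counts)
  sweep(1e9 * table$counts / table$length, 2, totals, "/")
}

#' Log2 fold change of two group means
#'
#' `log2(mean_b / mean_a)`; `NA` when either mean is zero.
#'
#' @param mean_fpkm_a,mean_fpkm_b non-negative group means.
#' @return log2 ratio or `NA`.
#' @export
log2_fold_change <- function(mean_fpkm_a, mean_fpkm_b) {
  stopifnot(all(mean_fpkm_a >= 0, na.rm = TRUE),
            all(mean_fpkm_b >= 0, na.rm = TRUE))
  out <- ifelse(mean_fpkm_a == 0 | mean_fpkm_b == 0, NA_real_,
                log2(mean_fpkm_b / mean_fpkm_a))
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, order-preserving with the input; `NA` inputs
#' propagate `NA` and are excluded from the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Define a two-group contrast
#'
#' @param label contrast name.
#' @param group_a,group_b disjoint non-empty character vectors of sample
#'   labels (A is the reference; log2FC is `log2(mean_b / mean_a)`).
#' @param kind "between-strain" (mutant vs parent, one condition) or
#'   "within-strain" (one strain, two conditions).
#' @return list of class `contrast`.
#' @export
contrast <- function(label, group_a, group_b,
                     kind = c("between-strain", "within-strain")) {
  kind <- match.arg(kind)
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  structure(list(label = label, group_a = group_a, group_b = group_b,
                 kind = kind), class = "contrast")
}

#' Default contrasts of a simulated dataset
#'
#' Between-strain: each mutant vs the parent under each condition
#' (labelled `<strain>.<condition>`). Within-strain: second condition vs
#' first for each strain (labelled `<strain>.within`).
#'
#' @param table an `abundance_table`.
#' @param parent parent strain name (default "parent").
#' @param within include within-strain contrasts (default FALSE).
#' @return named list of [contrast()] objects.
#' @export
default_contrasts <- function(table, parent = "parent", within = FALSE) {
  s <- table$samples
  strains <- setdiff(unique(s$strain), parent)
  conds <- unique(s$condition)
  out <- list()
  for (st in strains) {
    for (cd in conds) {
      lab <- paste(st, cd, sep = ".")
      out[[lab]] <- contrast(lab,
                             s$label[s$strain == parent & s$condition == cd],
                             s$label[s$strain == st & s$condition == cd],
                             kind = "between-strain")
    }
  }
  if (within) {
    for (st in unique(s$strain)) {
      lab <- paste(st, "within", sep = ".")
      out[[lab]] <- contrast(lab,
                             s$label[s$strain == st & s$condition == conds[1]],
                             s$label[s$strain == st & s$condition == conds[2]],
                             kind = "within-strain")
    }
  }
  out
}

# vectorized Welch two-sided t-test on rows of two matrices;
# zero-variance rows: p = 1 when means equal, p = 0 otherwise
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, length(ma))
  zerovar <- se2 == 0
  p[zerovar & abs(ma - mb) < 1e-12] <- 1
  degenerate <- zerovar & abs(ma - mb) >= 1e-12
  if (any(degenerate)) {
    warning("zero-variance genes with unequal means: p set to 0")
    p[degenerate] <- 0
  }
  ok <- !zerovar
  tstat <- (mb[ok] - ma[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' Differential expression test for one contrast
#'
#' A gene is tested iff its total raw count across the contrast's
#' samples reaches `min_count`; tested genes get a two-sided t on
#' `log2(FPKM + 1)`, Benjamini-Hochberg q over tested genes, and are
#' significant iff `q <= alpha`. The log2 fold change is the ratio of
#' mean FPKM values (B over A), `NA` if either mean is zero.
#'
#' With `method = "moderated"` (the default) the per-gene variance is
#' shrunk across genes with limma's empirical-Bayes moderated t
#' (mean-variance trend on), the field's standard remedy for two-
#' replicate designs, where a per-gene t has essentially no power after
#' FDR correction. `method = "welch"` is a plain per-gene Welch t with
#' deterministic degenerate-case conventions: zero variance with equal
#' means gives p = 1, with unequal means p = 0 (warning).
#'
#' @param table an `abundance_table`.
#' @param contrast a [contrast()].
#' @param min_count minimum total raw count to allow testing
#'   (default 10).
#' @param alpha significance level on q (default 0.05).
#' @param method "moderated" (limma) or "welch".
#' @return data.frame: `gene_id, mean_fpkm_a, mean_fpkm_b, log2fc, p, q,
#'   tested, significant`.
#' @export
de_test <- function(table, contrast, min_count = 10, alpha = 0.05,
                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  labs <- colnames(table$counts)
  if (!all(c(contrast$group_a, contrast$group_b) %in% labs)) {
    stop("contrast samples missing from table")
  }
  fp <- fpkm_matrix(table)
  a <- fp[, contrast$group_a, drop = FALSE]
  b <- fp[, contrast$group_b, drop = FALSE]
  raw <- table$counts[, c(contrast$group_a, contrast$group_b), drop = FALSE]
  tested <- rowSums(raw) >= min_count
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  l2fc <- log2_fold_change(mean_a, mean_b)
  p <- rep(NA_real_, nrow(fp))
  if (length(contrast$group_a) < 2 || length(contrast$group_b) < 2) {
    warning("a contrast group has fewer than 2 replicates; tests skipped")
    tested[] <- FALSE
  } else if (any(tested)) {
    la <- log2(a[tested, , drop = FALSE] + 1)
    lb <- log2(b[tested, , drop = FALSE] + 1)
    p[tested] <- switch(method,
                        welch = welch_rows(la, lb),
                        moderated = moderated_rows(la, lb))
  }
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_fdr(p[tested])
  data.frame(gene_id = table$gene_id,
             mean_fpkm_a = mean_a, mean_fpkm_b = mean_b,
             log2fc = l2fc, p = p, q = q, tested = tested,
             significant = !is.na(q) & q <= alpha,
             stringsAsFactors = FALSE)
}

# limma moderated t on a two-group log-expression matrix; falls back to
# the Welch conventions when variance moderation is impossible (e.g. a
# degenerate all-zero-variance toy)
moderated_rows <- function(a, b) {
  y <- cbind(a, b)
  design <- cbind(intercept = 1,
                  group = c(rep(0, ncol(a)), rep(1, ncol(b))))
  fit <- limma::lmFit(y, design)
  fit <- tryCatch(
    limma::eBayes(fit, trend = nrow(y) >= 10),
    error = function(e) NULL)
  if (is.null(fit)) return(welch_rows(a, b))
  fit$p.value[, "group"]
}

#' Run a set of contrasts
#'
#' @param table an `abundance_table`.
#' @param contrasts named list of [contrast()] objects (default:
#'   [default_contrasts()]).
#' @inheritParams de_test
#' @return named list of [de_test()] data.frames.
#' @export
de_all <- function(table, contrasts = default_contrasts(table),
                   min_count = 10, alpha = 0.05) {
  lapply(contrasts, function(ct) de_test(table, ct, min_count, alpha))
}
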