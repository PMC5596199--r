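# Genome-scale overlay of motif occurrence and expression effect:
# kernel-density tracks, DE-region detection, composite effect profiles,
# motif-ORF distances, and density-effect correlation.

#' Gaussian kernel-density track of motif hits
#'
#' The track is the sum of Gaussian kernels (SD = `bandwidth`) centred
#' on hit midpoints, evaluated on a regular grid; it integrates to the
#' number of hits (away from the edges), so multiplicity scales the
#' track linearly.
#'
#' @param hits data.frame with `start`, `end` (one replicon).
#' @param replicon_length replicon length in bp.
#' @param bandwidth kernel SD in bp (default 30000).
#' @param grid_step evaluation grid step in bp (default 1000).
#' @return data.frame of class `density_track`: `pos, density`.
#' @export
motif_density <- function(hits, replicon_length, bandwidth = 30000,
                          grid_step = 1000) {
  pos <- seq(1, replicon_length, by = grid_step)
  if (nrow(hits) == 0) {
    return(structure(data.frame(pos = pos, density = 0),
                     class = c("density_track", "data.frame"),
                     bandwidth = bandwidth))
  }
  mid <- (hits$start + hits$end) / 2
  dens <- rowSums(vapply(mid, function(m) {
    stats::dnorm(pos, mean = m, sd = bandwidth)
  }, numeric(length(pos))))
  structure(data.frame(pos = pos, density = dens),
            class = c("density_track", "data.frame"),
            bandwidth = bandwidth)
}

#' Composite expression effect over a strain set
#'
#' Per-gene arithmetic mean of log2 fold changes over the named
#' contrasts (NA-skipping); genes with no defined value get NA.
#'
#' @param de_results named list of [de_test()] results; names
#'   `<strain>.<condition>`.
#' @param strain_set strains to average (default the four synthesis
#'   mutants).
#' @param condition condition name.
#' @return named numeric vector of per-gene composite log2FC.
#' @export
composite_effect <- function(de_results,
                             strain_set = c("phbA", "phbB", "phbAB", "phbC"),
                             condition = "limited") {
  if (!length(strain_set)) stop("strain set must be non-empty")
  wanted <- paste(strain_set, condition, sep = ".")
  missing <- setdiff(wanted, names(de_results))
  if (length(missing)) {
    stop("contrasts not found: ", paste(missing, collapse = ", "))
  }
  genes <- de_results[[wanted[1]]]$gene_id
  m <- vapply(wanted, function(nm) {
    de_results[[nm]]$log2fc[match(genes, de_results[[nm]]$gene_id)]
  }, numeric(length(genes)))
  m <- matrix(m, nrow = length(genes))
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  names(out) <- genes
  out
}

#' Detect differentially expressed gene regions
#'
#' Scans genes in annotation order per replicon for maximal runs
#' containing at most `max_gap` consecutive unflagged genes, keeping
#' runs with at least `min_genes` members and a flagged fraction of at
#' least `min_fraction`. Runs are trimmed to start and end on flagged
#' genes.
#'
#' @param annotation annotation data.frame.
#' @param de_flags named logical: gene differentially expressed in at
#'   least one mutant.
#' @param min_fraction minimum flagged fraction (default 0.5).
#' @param max_gap maximum consecutive unflagged genes inside a run
#'   (default 3).
#' @param min_genes minimum genes per region (default 5).
#' @return data.frame: `replicon, start, end, n_genes, fraction_de,
#'   gene_ids` (comma-separated).
#' @export
detect_de_regions <- function(annotation, de_flags, min_fraction = 0.5,
                              max_gap = 3, min_genes = 5) {
  out <- list()
  for (rep_name in unique(annotation$replicon)) {
    a <- annotation[annotation$replicon == rep_name, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    fl <- de_flags[a$gene_id]
    fl[is.na(fl)] <- FALSE
    i <- 1L
    n <- nrow(a)
    while (i <= n) {
      if (!fl[i]) { i <- i + 1L; next }
      # extend while gaps of unflagged genes stay within max_gap
      j <- i
      gap <- 0L
      k <- i + 1L
      while (k <= n) {
        if (fl[k]) { j <- k; gap <- 0L } else {
          gap <- gap + 1L
          if (gap > max_gap) break
        }
        k <- k + 1L
      }
      members <- a[i:j, , drop = FALSE]
      frac <- mean(fl[i:j])
      if (nrow(members) >= min_genes && frac >= min_fraction) {
        out[[length(out) + 1L]] <- data.frame(
          replicon = rep_name, start = min(members$start),
          end = max(members$end), n_genes = nrow(members),
          fraction_de = frac,
          gene_ids = paste(members$gene_id, collapse = ","),
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      fraction_de = numeric(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# hits overlapping any ORF on their replicon
hits_in_orfs <- function(hits, annotation) {
  vapply(seq_len(nrow(hits)), function(i) {
    a <- annotation[annotation$replicon == hits$replicon[i], , drop = FALSE]
    any(hits$start[i] <= a$end & hits$end[i] >= a$start)
  }, logical(1))
}

#' Drop motif hits that overlap any ORF
#'
#' Occurrences inside genes are ignored throughout the position-based
#' analyses.
#'
#' @param hits motif hit data.frame.
#' @param annotation annotation data.frame.
#' @return the intergenic subset of `hits`.
#' @export
filter_orf_hits <- function(hits, annotation) {
  if (!nrow(hits)) return(hits)
  hits[!hits_in_orfs(hits, annotation), , drop = FALSE]
}

#' Upstream motif distances for every gene
#'
#' Batch version of [upstream_distance()]: hits are ORF-filtered once,
#' then each gene's nearest 5' hit within `max_window` is reported.
#'
#' @inheritParams upstream_distance
#' @param annotation annotation data.frame (all genes scored).
#' @return named numeric vector of distances (NA where none).
#' @export
upstream_distances <- function(annotation, hits, max_window = 200) {
  clean <- filter_orf_hits(hits, annotation)
  out <- rep(NA_real_, nrow(annotation))
  names(out) <- annotation$gene_id
  for (rep_name in unique(annotation$replicon)) {
    h <- clean[clean$replicon == rep_name, , drop = FALSE]
    if (!nrow(h)) next
    idx <- which(annotation$replicon == rep_name)
    for (i in idx) {
      g <- annotation[i, ]
      d <- if (g$strand == "+") g$start - h$end else h$start - g$end
      d <- d[d >= 1 & d <= max_window]
      if (length(d)) out[i] <- min(d)
    }
  }
  out
}

#' Distance from an ORF start to its nearest upstream motif
#'
#' Strand-aware: for a + strand gene, `gene_start - hit_end`; for a -
#' strand gene, `hit_start - gene_end`. Hits overlapping any ORF are
#' excluded first; returns NA when no hit lies within `max_window`.
#'
#' @param gene one-row annotation data.frame.
#' @param hits motif hits (same replicon; any strand).
#' @param annotation full annotation (for the in-ORF exclusion).
#' @param max_window maximum distance considered (default 200).
#' @return distance in bp (>= 1) or NA.
#' @export
upstream_distance <- function(gene, hits, annotation, max_window = 200) {
  h <- hits[hits$replicon == gene$replicon, , drop = FALSE]
  if (nrow(h)) h <- h[!hits_in_orfs(h, annotation), , drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  d <- if (gene$strand == "+") gene$start - h$end else h$start - gene$end
  d <- d[d >= 1 & d <= max_window]
  if (!length(d)) return(NA_real_)
  min(d)
}

#' Kernel density of motif-ORF distances
#'
#' 1-D Gaussian KDE of upstream distances via [stats::density()].
#'
#' @param distances numeric vector of distances (>= 1).
#' @param bandwidth kernel SD (default 10).
#' @param max_window evaluation range upper bound (default 200).
#' @return data.frame `x, y`; attribute `mode` holds the argmax.
#' @export
distance_density <- function(distances, bandwidth = 10, max_window = 200) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) stop("no distances supplied")
  d <- stats::density(distances, bw = bandwidth, from = 0, to = max_window,
                      n = 512)
  out <- data.frame(x = d$x, y = d$y)
  attr(out, "mode") <- d$x[which.max(d$y)]
  out
}

#' Correlate motif density with expression effect
#'
#' Samples the density track at each gene's midpoint and correlates it
#' with the per-gene composite log2 fold change (genes with defined
#' values only).
#'
#' @param track a [motif_density()] track (one replicon).
#' @param composite named per-gene composite log2FC.
#' @param annotation annotation rows for the track's replicon.
#' @return list: `pearson_r, spearman_rho, n`.
#' @export
density_effect_correlation <- function(track, composite, annotation) {
  mid <- (annotation$start + annotation$end) / 2
  step <- track$pos[2] - track$pos[1]
  idx <- pmin(pmax(round((mid - track$pos[1]) / step) + 1, 1), nrow(track))
  dens <- track$density[idx]
  eff <- composite[annotation$gene_id]
  ok <- !is.na(eff) & !is.na(dens)
  if (sum(ok) < 3) stop("need at least 3 genes with defined values")
  if (stats::sd(eff[ok]) == 0 || stats::sd(dens[ok]) == 0) {
    warning("constant input; correlation undefined")
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                n = sum(ok)))
  }
  list(pearson_r = stats::cor(dens[ok], eff[ok]),
       spearman_rho = stats::cor(dens[ok], eff[ok], method = "spearman"),
       n = sum(ok))
}
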