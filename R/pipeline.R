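# End-to-end orchestration: simulate (or load) -> differential expression
# -> clustering -> upstream extraction -> motif discovery -> reference
# comparison -> genome scan -> colocalization -> operon statistics.

pipeline_defaults <- function() {
  list(
    seed = 7L,
    out_dir = NULL,
    genome = NULL, gff = NULL, counts = NULL, flags = NULL,
    reference_motifs = NULL,
    window = 200, bw = 30000, grid_step = 1000,
    e_threshold = 1e-15, compare_p = 0.001, scan_p = 1e-4,
    min_count = 10, alpha = 0.05,
    top_k = 2, sub_threshold = 7,
    discover_widths = c(10, 14, 18), n_motifs = 1, restarts = 20,
    target_cluster = NULL,
    parent = "parent",
    strain_set = c("phbA", "phbB", "phbAB", "phbC"),
    condition = "limited",
    sim = list()
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and checks key
#' names and ranges. Normalizing an already-normalized config is a
#' no-op.
#'
#' @param config path to a YAML file, or a named list (empty for
#'   defaults-only).
#' @return normalized config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (file.exists(config) && file.size(config) > 0) {
      yaml::read_yaml(config)
    } else {
      list()
    }
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$window >= 1, "window must be >= 1")
  chk(cfg$bw > 0, "bw must be positive")
  chk(cfg$grid_step >= 1, "grid_step must be >= 1")
  chk(cfg$e_threshold > 0, "e_threshold must be positive")
  chk(cfg$compare_p > 0 && cfg$compare_p <= 1, "compare_p must be in (0,1]")
  chk(cfg$scan_p > 0 && cfg$scan_p <= 1, "scan_p must be in (0,1]")
  chk(cfg$min_count >= 0, "min_count must be non-negative")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0,1]")
  chk(cfg$top_k >= 1, "top_k must be >= 1")
  chk(is.null(cfg$sub_threshold) || cfg$sub_threshold > 0,
      "sub_threshold must be positive")
  chk(all(cfg$discover_widths >= 4), "discover_widths must be >= 4")
  chk(cfg$n_motifs >= 1, "n_motifs must be >= 1")
  for (f in c("genome", "gff", "counts", "flags", "reference_motifs")) {
    if (!is.null(cfg[[f]])) {
      chk(file.exists(cfg[[f]]), sprintf("%s: file not found", f))
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(manifest, stage, path) {
  rbind(manifest, data.frame(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data (default) or user-supplied
#' files, writing per-stage artifacts and a `manifest.tsv` of output
#' hashes under `config$out_dir` when set. Identical config and seed
#' give identical manifests.
#'
#' @param config a [validate_config()] config (or anything it accepts).
#' @return list with per-stage results: `dataset`, `de`, `clusters`,
#'   `discovered`, `comparison`, `hits`, `density`, `regions`,
#'   `correlation`, `groups`, `manifest`.
#' @export
run_all <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), path = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  emit <- function(stage, fname, writer) {
    if (!write_out) return(invisible(NULL))
    path <- file.path(out_dir, fname)
    writer(path)
    manifest <<- write_stage(manifest, stage, path)
  }

  # stage 1: simulate or load
  if (is.null(cfg$genome)) {
    sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    dataset <- simulate_dataset(sim_cfg)
  } else {
    dataset <- list(
      sequences = read_genome_fasta(cfg$genome),
      annotation = read_annotation_gff3(cfg$gff),
      counts = read_counts_tsv(cfg$counts),
      truth = NULL)
  }
  if (is.null(dataset$counts)) stop("stage de: no counts available")
  emit("simulate", "counts.tsv",
       function(p) write_counts_tsv(dataset$counts, p))

  # stage 2: differential expression
  cts <- default_contrasts(dataset$counts, parent = cfg$parent)
  de <- de_all(dataset$counts, cts, min_count = cfg$min_count,
               alpha = cfg$alpha)
  emit("de", "de_summary.tsv", function(p) {
    sm <- do.call(rbind, lapply(names(de), function(nm) {
      data.frame(contrast = nm, n_significant = sum(de[[nm]]$significant),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(sm, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # stage 3: clustering
  em <- expression_matrix(de)
  dend <- complete_linkage(em)
  labels <- cut_clusters(dend, top_k = cfg$top_k,
                         sub_threshold = cfg$sub_threshold)
  emit("cluster", "heatmap_matrix.tsv",
       function(p) heatmap_export(em, dend, labels, p))
  profiles <- cluster_profiles(em, labels)
  # discovery feeds on the strongest-response TOP-LEVEL cluster (the
  # A/B split), not on sub-threshold fragments
  top_labels <- sub("\\..*$", "", labels)
  top_profiles <- cluster_profiles(em, top_labels)
  target <- if (!is.null(cfg$target_cluster)) cfg$target_cluster else
    top_profiles$cluster[which.min(top_profiles$mean)]
  target_genes <- names(labels)[labels == target |
                                  top_labels == target]

  # stage 4: upstream extraction of the target cluster
  ups <- extract_upstream(dataset$annotation, dataset$sequences,
                          window = cfg$window, genes = target_genes)
  ok <- nchar(ups$sequences) >= min(cfg$discover_widths)
  emit("upstream", "upstream.fasta", function(p) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ups$sequences[ok]), p)
  })

  # stage 5: de novo discovery
  discovered <- discover_zoops(ups$sequences[ok],
                               width_range = range(cfg$discover_widths),
                               n_motifs = cfg$n_motifs,
                               restarts = cfg$restarts, seed = cfg$seed)
  if (!length(discovered)) stop("stage discover: no motif found")
  reported <- Filter(function(m) m$e_value <= cfg$e_threshold, discovered)
  top <- discovered[[which.min(vapply(discovered, `[[`, 0, "log10_e"))]]
  emit("discover", "discovered.meme", function(p) {
    write_meme(stats::setNames(lapply(discovered, `[[`, "pwm"),
                               paste0("motif_", seq_along(discovered))), p)
  })

  # stage 6: comparison to the reference motif(s)
  refs <- if (is.null(cfg$reference_motifs)) list(FixK = fixk_pwm()) else
    read_meme(cfg$reference_motifs)
  comparison <- compare_motifs(top$pwm, refs, seed = cfg$seed,
                               p_threshold = cfg$compare_p)
  emit("compare", "comparison.tsv", function(p) {
    utils::write.table(comparison, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # stage 7: genome-wide scan
  hits <- scan_pwm(top$pwm, dataset$sequences, p_threshold = cfg$scan_p)
  emit("scan", "hits.bed", function(p) write_hits_bed(hits, p))

  # stage 8: colocalization
  clean_hits <- filter_orf_hits(hits, dataset$annotation)
  density <- lapply(stats::setNames(nm = names(dataset$sequences)),
                    function(nm) {
    motif_density(clean_hits[clean_hits$replicon == nm, , drop = FALSE],
                  nchar(dataset$sequences[[nm]]), bandwidth = cfg$bw,
                  grid_step = cfg$grid_step)
  })
  strain_set <- intersect(cfg$strain_set,
                          unique(dataset$counts$samples$strain))
  comp <- composite_effect(de, strain_set, cfg$condition)
  de_flag_mat <- vapply(de, function(d) {
    d$significant[match(dataset$annotation$gene_id, d$gene_id)]
  }, logical(nrow(dataset$annotation)))
  de_flags <- apply(de_flag_mat, 1, any)
  names(de_flags) <- dataset$annotation$gene_id
  regions <- detect_de_regions(dataset$annotation, de_flags)
  emit("colocalize", "regions.tsv", function(p) {
    utils::write.table(regions[, setdiff(names(regions), "gene_ids")], p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  genome_dens <- unlist(lapply(names(density), function(nm) {
    a <- dataset$annotation[dataset$annotation$replicon == nm, ,
                            drop = FALSE]
    tr <- density[[nm]]
    step <- tr$pos[2] - tr$pos[1]
    mid <- (a$start + a$end) / 2
    stats::setNames(
      tr$density[pmin(pmax(round((mid - tr$pos[1]) / step) + 1, 1),
                      nrow(tr))], a$gene_id)
  }))
  eff <- comp[names(genome_dens)]
  okc <- !is.na(eff)
  correlation <- list(
    pearson_r = stats::cor(genome_dens[okc], eff[okc]),
    n = sum(okc))

  # stage 9: operon statistics
  four <- classify_four_groups(dataset$annotation, hits,
                               window = cfg$window)
  five <- classify_five_groups(dataset$annotation, hits,
                               window = cfg$window)
  dists <- upstream_distances(dataset$annotation, hits,
                              max_window = cfg$window)
  groups <- list(four = four, five = five, distances = dists)
  test5 <- tryCatch(group_anova_tukey(comp, five), error = function(e) NULL)
  decay <- operon_decay_profile(comp, five, dataset$annotation)
  emit("operon_stats", "labels.tsv", function(p) {
    utils::write.table(data.frame(
      gene_id = dataset$annotation$gene_id,
      four_group = unname(four[dataset$annotation$gene_id]),
      five_group = unname(five[dataset$annotation$gene_id]),
      order = dataset$annotation$operon_order,
      upstream_distance = unname(dists[dataset$annotation$gene_id]),
      stringsAsFactors = FALSE), p, sep = "\t", quote = FALSE,
      row.names = FALSE)
  })
  if (write_out) {
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(config = cfg, dataset = dataset, de = de,
       clusters = list(matrix = em, dendrogram = dend, labels = labels,
                       profiles = profiles, target = target),
       discovered = discovered, reported = reported, top_motif = top,
       comparison = comparison, hits = hits, density = density,
       regions = regions, correlation = correlation, groups = groups,
       group_test = test5, decay = decay, manifest = manifest)
}
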