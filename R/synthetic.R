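# Seeded synthetic datasets: multi-replicon genomes with operon-structured
# annotations, a contiguous "hot region" whose operons carry an upstream
# palindromic motif, and strain x condition count tables in which affected
# strains downregulate motif-bearing operons under the limited condition
# only, with the effect attenuating down the operon.

#' Simulation configuration
#'
#' Defaults emulate a three-replicon rhizobial genome
#' (chromosome/megaplasmid/chromid proportions), operons of 1-7 genes,
#' a 120-kb hot region on the second replicon whose operons carry the
#' palindromic TTGAT-N4-ATCAA motif upstream, eight affected PHB-cycle
#' mutant strains plus one unaffected glycogen-synthase-like mutant and
#' the parent, two conditions (limited/balanced) with two replicates,
#' a first-order effect of -3 log2 units halving with each step down the
#' operon, and negative-binomial counts.
#'
#' @param seed integer master seed.
#' @param replicon_lengths replicon lengths in bp.
#' @param replicon_names names for the replicons.
#' @param n_genes genes per replicon.
#' @param operon_size_probs probabilities of operon sizes 1..7.
#' @param gene_length_range min/max gene length (bp).
#' @param intergenic_min minimum separation between genes (bp).
#' @param hot_region list(replicon, start, length) of the motif-rich
#'   region.
#' @param motif consensus string (N positions sampled uniformly when
#'   planting) or a [pwm()].
#' @param planted_fraction fraction of hot-region operons receiving an
#'   upstream motif.
#' @param decoy_rate background intergenic motif placements per Mb
#'   outside the hot region.
#' @param strains data.frame with columns `name`, `affected`; the parent
#'   is the reference and is never affected.
#' @param conditions two condition names; the effect applies to the
#'   first only.
#' @param replicates replicates per strain x condition.
#' @param effect_beta first-order log2 fold-change magnitude.
#' @param decay_delta per-order attenuation factor in (0, 1].
#' @param noise_sd log2 fold-change noise SD.
#' @param baseline_mu_log mean of per-gene log baseline abundance.
#' @param baseline_sd_log SD of per-gene log baseline abundance.
#' @param dispersion negative-binomial overdispersion (rnbinom size =
#'   1/dispersion).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       replicon_lengths = c(3650000, 1350000, 1680000),
                       replicon_names = c("chromosome", "pSymA", "pSymB"),
                       n_genes = c(1600, 600, 750),
                       operon_size_probs = c(0.45, 0.20, 0.13, 0.09,
                                             0.06, 0.04, 0.03),
                       gene_length_range = c(300, 3000),
                       intergenic_min = 250,
                       hot_region = list(replicon = 2, start = 600000,
                                         length = 120000),
                       motif = "TTGATNNNNATCAA",
                       planted_fraction = 0.9,
                       decoy_rate = 2,
                       strains = default_strains(),
                       conditions = c("limited", "balanced"),
                       replicates = 2,
                       effect_beta = 3,
                       decay_delta = 0.5,
                       noise_sd = 0.5,
                       baseline_mu_log = log(500),
                       baseline_sd_log = 1,
                       dispersion = 0.1) {
  cfg <- list(seed = as.integer(seed),
              replicon_lengths = as.numeric(replicon_lengths),
              replicon_names = replicon_names, n_genes = as.integer(n_genes),
              operon_size_probs = operon_size_probs / sum(operon_size_probs),
              gene_length_range = gene_length_range,
              intergenic_min = intergenic_min, hot_region = hot_region,
              motif = motif, planted_fraction = planted_fraction,
              decoy_rate = decoy_rate, strains = strains,
              conditions = conditions, replicates = as.integer(replicates),
              effect_beta = effect_beta, decay_delta = decay_delta,
              noise_sd = noise_sd, baseline_mu_log = baseline_mu_log,
              baseline_sd_log = baseline_sd_log, dispersion = dispersion)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_strains <- function() {
  data.frame(
    name = c("parent", "phbA", "phbB", "phbAB", "phbC", "phaZ", "bdhA",
             "acsA2", "phaZ2", "glgA1"),
    affected = c(FALSE, rep(TRUE, 8), FALSE),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(
    all(cfg$replicon_lengths > 0),
    length(cfg$n_genes) == length(cfg$replicon_lengths),
    all(cfg$n_genes >= 0),
    length(cfg$operon_size_probs) == 7,
    all(cfg$operon_size_probs >= 0),
    cfg$gene_length_range[1] > 0,
    cfg$gene_length_range[2] >= cfg$gene_length_range[1],
    cfg$intergenic_min >= 0,
    cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
    cfg$decay_delta > 0, cfg$decay_delta <= 1,
    cfg$decoy_rate >= 0,
    cfg$replicates >= 1,
    cfg$noise_sd >= 0, cfg$dispersion > 0,
    is.data.frame(cfg$strains),
    all(c("name", "affected") %in% names(cfg$strains)),
    length(cfg$conditions) == 2
  )
  hr <- cfg$hot_region
  if (hr$replicon < 1 || hr$replicon > length(cfg$replicon_lengths) ||
      hr$start < 1 ||
      hr$start + hr$length - 1 > cfg$replicon_lengths[hr$replicon]) {
    stop("hot_region must lie within its replicon")
  }
  invisible(cfg)
}

# planting PWM from the config's motif spec: consensus letters are fixed
# (probability 1), N columns uniform -- so emitted instances match the
# consensus exactly at fixed positions while staying degenerate at N.
planting_pwm <- function(motif) {
  if (inherits(motif, "pwm")) return(motif)
  codes <- seq_encode(motif)
  m <- matrix(0.25, 4, length(codes))
  fixed <- which(!is.na(codes))
  m[, fixed] <- 0
  m[cbind(codes[fixed], fixed)] <- 1
  pwm(m)
}

#' Generate a genome and operon-structured annotation
#'
#' Packs operons of seeded sizes and strands onto each replicon with at
#' least `intergenic_min` bp between genes, leftover space spread over
#' the gaps between operons. Gene order along a minus-strand operon is
#' transcription order (first gene = highest coordinate).
#'
#' @param config a [sim_config()].
#' @param seed seed (defaults to `config$seed`).
#' @return list with `sequences` (named character vector) and
#'   `annotation` (data.frame: gene_id, replicon, start, end, strand,
#'   operon_id, operon_order).
#' @export
generate_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  seqs <- character(length(config$replicon_lengths))
  names(seqs) <- config$replicon_names
  ann <- list()
  for (r in seq_along(config$replicon_lengths)) {
    L <- config$replicon_lengths[r]
    seqs[r] <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
    ng <- config$n_genes[r]
    if (ng == 0L) next
    # operon sizes until ng genes are grouped
    sizes <- integer(0)
    while (sum(sizes) < ng) {
      sizes <- c(sizes, sample.int(7L, ceiling(ng / 2), replace = TRUE,
                                   prob = config$operon_size_probs))
    }
    sizes <- sizes[cumsum(sizes) - sizes < ng]
    sizes[length(sizes)] <- ng - sum(sizes[-length(sizes)])
    glen <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                   ng, replace = TRUE)
    n_op <- length(sizes)
    min_span <- sum(glen) + (ng - n_op) * config$intergenic_min +
      (n_op + 1L) * config$intergenic_min
    slack <- L - min_span
    if (slack < 0) {
      stop(sprintf("infeasible packing: %d genes need %d bp > replicon %d (%d bp)",
                   ng, min_span, r, as.integer(L)))
    }
    # split slack over the n_op + 1 inter-operon gaps
    cuts <- sort(sample.int(slack + 1L, n_op, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts, slack))
    pos <- 1L
    gi <- 0L
    for (o in seq_len(n_op)) {
      pos <- pos + config$intergenic_min + extra[o]
      strand <- sample(c("+", "-"), 1L)
      k <- sizes[o]
      starts <- integer(k); ends <- integer(k)
      for (g in seq_len(k)) {
        gi <- gi + 1L
        starts[g] <- pos
        ends[g] <- pos + glen[gi] - 1L
        pos <- ends[g] + 1L + config$intergenic_min
      }
      pos <- pos - config$intergenic_min  # operon-final gap comes from extra
      order_in_op <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%04d", config$replicon_names[r],
                          (gi - k + 1L):gi),
        replicon = config$replicon_names[r],
        start = starts, end = ends, strand = strand,
        operon_id = sprintf("%s_op%04d", config$replicon_names[r], o),
        operon_order = order_in_op,
        stringsAsFactors = FALSE
      )
    }
  }
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(), replicon = character(),
               start = integer(), end = integer(), strand = character(),
               operon_id = character(), operon_order = integer(),
               stringsAsFactors = FALSE)
  rownames(annotation) <- NULL
  list(sequences = seqs, annotation = annotation)
}

# first (promoter-proximal) gene of each operon, strand aware
operon_heads <- function(annotation) {
  heads <- annotation[annotation$operon_order == 1L, , drop = FALSE]
  heads[order(heads$replicon, heads$start), , drop = FALSE]
}

# the intergenic upstream room available before the first gene of an
# operon head, capped at `window`
upstream_room <- function(head, annotation, window) {
  same <- annotation[annotation$replicon == head$replicon &
                       annotation$gene_id != head$gene_id, , drop = FALSE]
  if (head$strand == "+") {
    lim <- max(c(0L, same$end[same$end < head$start]))
    room <- head$start - 1L - lim
  } else {
    ends <- same$start[same$start > head$end]
    lim <- if (length(ends)) min(ends) else Inf
    room <- min(lim - 1, head$end + window) - head$end
  }
  max(0L, min(window, room))
}

#' Plant motif instances into a genome
#'
#' Writes one PWM-sampled motif instance (uniform strand) into the 200
#' bp upstream of the first gene of each selected hot-region operon, and
#' seeds background "decoy" instances into intergenic space elsewhere.
#'
#' @param sequences named character vector of replicon sequences.
#' @param annotation annotation data.frame from [generate_genome()].
#' @param config a [sim_config()].
#' @param seed seed (defaults to `config$seed + 1`).
#' @param window upstream window for planting (default 200).
#' @return list with modified `sequences` and `planted_hits` data.frame
#'   (`replicon, start, end, strand, kind, operon_id`).
#' @export
plant_motifs <- function(sequences, annotation, config,
                         seed = config$seed + 1L, window = 200L) {
  validate_sim_config(config)
  set.seed(seed)
  pw <- planting_pwm(config$motif)
  w <- pw$width
  hits <- list()
  hr <- config$hot_region
  hr_name <- config$replicon_names[hr$replicon]
  hr_end <- hr$start + hr$length - 1L
  heads <- operon_heads(annotation)
  sample_instance <- function() {
    codes <- vapply(seq_len(w), function(j) {
      sample.int(4L, 1L, prob = pw$mat[, j])
    }, integer(1))
    seq_decode(codes)
  }
  # interval bookkeeping so placements never overlap ORFs or each other
  occupied <- lapply(config$replicon_names, function(nm) {
    a <- annotation[annotation$replicon == nm, , drop = FALSE]
    cbind(a$start, a$end)
  })
  names(occupied) <- config$replicon_names
  overlaps_occupied <- function(nm, s, e) {
    occ <- occupied[[nm]]
    nrow(occ) > 0 && any(s <= occ[, 2] & e >= occ[, 1])
  }
  place <- function(nm, s, e, strand, kind, operon_id) {
    inst <- sample_instance()
    if (strand == "-") inst <- revcomp_string(inst)
    substr(sequences[[nm]], s, e) <<- inst
    occupied[[nm]] <<- rbind(occupied[[nm]], c(s, e))
    hits[[length(hits) + 1L]] <<- data.frame(
      replicon = nm, start = s, end = e, strand = strand, kind = kind,
      operon_id = operon_id, stringsAsFactors = FALSE)
  }
  # hot-region operons with adequate upstream room
  in_hot <- heads$replicon == hr_name & heads$start >= hr$start &
    heads$end <= hr_end
  hot_heads <- heads[in_hot, , drop = FALSE]
  eligible <- hot_heads[vapply(seq_len(nrow(hot_heads)), function(i) {
    upstream_room(hot_heads[i, ], annotation, window) >= w
  }, logical(1)), , drop = FALSE]
  n_plant <- round(config$planted_fraction * nrow(eligible))
  if (nrow(eligible) < nrow(hot_heads)) {
    warning(sprintf("%d hot-region operons lacked upstream room and were skipped",
                    nrow(hot_heads) - nrow(eligible)))
  }
  if (n_plant > 0) {
    chosen <- eligible[sort(sample.int(nrow(eligible), n_plant)), ,
                       drop = FALSE]
    for (i in seq_len(nrow(chosen))) {
      head <- chosen[i, ]
      room <- upstream_room(head, annotation, window)
      off <- sample.int(room - w + 1L, 1L)  # distance of motif end to ORF
      if (head$strand == "+") {
        e <- head$start - off
        s <- e - w + 1L
      } else {
        s <- head$end + off
        e <- s + w - 1L
      }
      place(head$replicon, s, e, sample(c("+", "-"), 1L), "planted",
            head$operon_id)
    }
  }
  # decoys: Poisson(rate per Mb) over the genome outside the hot region,
  # intergenic only
  mb_outside <- (sum(config$replicon_lengths) - hr$length) / 1e6
  n_decoy <- stats::rpois(1L, config$decoy_rate * mb_outside)
  tries <- 0L
  placed <- 0L
  while (placed < n_decoy && tries < n_decoy * 50L) {
    tries <- tries + 1L
    r <- sample.int(length(config$replicon_lengths), 1L,
                    prob = config$replicon_lengths)
    nm <- config$replicon_names[r]
    s <- sample.int(as.integer(config$replicon_lengths[r]) - w, 1L)
    e <- s + w - 1L
    if (nm == hr_name && s <= hr_end && e >= hr$start) next
    if (overlaps_occupied(nm, s, e)) next
    place(nm, s, e, sample(c("+", "-"), 1L), "decoy", NA_character_)
    placed <- placed + 1L
  }
  planted_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(replicon = character(), start = integer(), end = integer(),
               strand = character(), kind = character(),
               operon_id = character(), stringsAsFactors = FALSE)
  rownames(planted_hits) <- NULL
  list(sequences = sequences, planted_hits = planted_hits)
}

#' Simulate strain x condition count tables
#'
#' For affected strains under the first (limited) condition, a gene at
#' within-operon order k of a motif-bearing hot-region operon has true
#' log2FC `-effect_beta * decay_delta^(k-1) + Normal(0, noise_sd)`; all
#' other gene/strain/condition combinations have true log2FC 0.
#' Replicate counts are negative-binomial around
#' `baseline * (length/1000) * 2^true_lfc`.
#'
#' @param annotation annotation data.frame.
#' @param planted_hits truth hits from [plant_motifs()].
#' @param config a [sim_config()].
#' @param seed seed (defaults to `config$seed + 2`).
#' @return list with `counts` (abundance table: gene_id, length, samples,
#'   counts matrix), `true_lfc` (long data.frame of nonzero effects) and
#'   `regulated_genes` (gene_id, operon_id, operon_order).
#' @export
simulate_expression <- function(annotation, planted_hits, config,
                                seed = config$seed + 2L) {
  validate_sim_config(config)
  set.seed(seed)
  genes <- annotation$gene_id
  n <- length(genes)
  reg_ops <- unique(planted_hits$operon_id[planted_hits$kind == "planted"])
  reg <- annotation[annotation$operon_id %in% reg_ops, , drop = FALSE]
  regulated <- data.frame(gene_id = reg$gene_id, operon_id = reg$operon_id,
                          operon_order = reg$operon_order,
                          stringsAsFactors = FALSE)
  strains <- config$strains
  conds <- config$conditions
  reps <- config$replicates
  samples <- expand.grid(replicate = seq_len(reps), condition = conds,
                         strain = strains$name, stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "condition", "replicate")]
  samples$label <- paste(samples$strain, samples$condition,
                         samples$replicate, sep = ".")
  baseline <- exp(stats::rnorm(n, config$baseline_mu_log,
                               config$baseline_sd_log))
  lfc_mat <- matrix(0, n, nrow(strains),
                    dimnames = list(genes, strains$name))
  true_lfc <- NULL
  affected <- strains$name[strains$affected]
  if (nrow(regulated) > 0 && length(affected) > 0) {
    idx <- match(regulated$gene_id, genes)
    for (st in affected) {
      eff <- -config$effect_beta *
        config$decay_delta^(regulated$operon_order - 1L) +
        stats::rnorm(nrow(regulated), 0, config$noise_sd)
      lfc_mat[idx, st] <- eff
      true_lfc <- rbind(true_lfc, data.frame(
        gene_id = regulated$gene_id, strain = st, condition = conds[1],
        lfc = eff, stringsAsFactors = FALSE))
    }
  }
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes, samples$label))
  lenfac <- (annotation$end - annotation$start + 1L) / 1000
  for (j in seq_len(nrow(samples))) {
    lfc <- if (samples$condition[j] == conds[1]) {
      lfc_mat[, samples$strain[j]]
    } else {
      0
    }
    mu <- baseline * lenfac * 2^lfc
    counts[, j] <- stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
  }
  tab <- list(gene_id = genes,
              length = annotation$end - annotation$start + 1L,
              samples = samples, counts = counts)
  class(tab) <- "abundance_table"
  if (is.null(true_lfc)) {
    true_lfc <- data.frame(gene_id = character(), strain = character(),
                           condition = character(), lfc = numeric(),
                           stringsAsFactors = FALSE)
  }
  list(counts = tab, true_lfc = true_lfc, regulated_genes = regulated)
}

#' Simulate a full dataset
#'
#' Runs [generate_genome()], [plant_motifs()] and
#' [simulate_expression()] under one config.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return list: `sequences`, `annotation`, `truth` (planted_hits,
#'   true_lfc, regulated_genes), `counts`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  gen <- generate_genome(config, seed = seed)
  pl <- plant_motifs(gen$sequences, gen$annotation, config,
                     seed = seed + 1L)
  ex <- simulate_expression(gen$annotation, pl$planted_hits, config,
                            seed = seed + 2L)
  list(sequences = pl$sequences, annotation = gen$annotation,
       truth = list(planted_hits = pl$planted_hits,
                    true_lfc = ex$true_lfc,
                    regulated_genes = ex$regulated_genes),
       counts = ex$counts)
}
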