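test_that("zero-gene config yields an empty annotation of full length", {
  cfg <- sim_config(seed = 1, replicon_lengths = 50000,
                    replicon_names = "chr", n_genes = 0,
                    hot_region = list(replicon = 1, start = 10000,
                                      length = 5000))
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation), 0)
  expect_equal(nchar(g$sequences[["chr"]]), 50000)
})

test_that("generation is deterministic and annotations satisfy invariants", {
  cfg <- small_config(seed = 4)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  a <- g1$annotation
  expect_true(all(a$end >= a$start))
  # genes separated by at least the configured intergenic minimum
  for (r in unique(a$replicon)) {
    ar <- a[a$replicon == r, ]
    ar <- ar[order(ar$start), ]
    expect_true(all(diff(ar$start) > 0))
    expect_true(all(ar$start[-1] - ar$end[-nrow(ar)] - 1 >=
                      cfg$intergenic_min))
  }
  # operons are contiguous, same strand, order is transcription order
  for (op in unique(a$operon_id)) {
    ao <- a[a$operon_id == op, ]
    expect_length(unique(ao$strand), 1)
    o <- order(ao$start)
    expected <- if (ao$strand[1] == "+") seq_len(nrow(ao)) else
      rev(seq_len(nrow(ao)))
    expect_equal(ao$operon_order[o], expected)
  }
})

test_that("infeasible packing is an explicit error", {
  expect_error(
    generate_genome(sim_config(seed = 1, replicon_lengths = 30000,
                               replicon_names = "chr", n_genes = 100,
                               hot_region = list(replicon = 1, start = 1,
                                                 length = 1000))),
    "infeasible packing")
})

test_that("operon size distribution matches the configuration", {
  frac <- vapply(1:6, function(s) {
    g <- generate_genome(small_config(seed = s))
    a <- g$annotation
    sizes <- table(a$operon_id)
    mean(sizes[a$operon_id] >= 2)
  }, numeric(1))
  p <- sim_config()$operon_size_probs
  expected <- sum((2:7) * p[2:7]) / sum((1:7) * p)
  expect_lt(abs(mean(frac) - expected), 0.05)
})

test_that("planting writes exact consensus cores and honours fractions", {
  cfg <- small_config(seed = 2)
  g <- generate_genome(cfg)
  pl <- plant_motifs(g$sequences, g$annotation, cfg)
  ph <- pl$planted_hits
  expect_gt(sum(ph$kind == "planted"), 0)
  for (i in seq_len(nrow(ph))) {
    s <- substr(pl$sequences[[ph$replicon[i]]], ph$start[i], ph$end[i])
    if (ph$strand[i] == "-") s <- regulocate:::revcomp_string(s)
    expect_match(s, "^TTGAT....ATCAA$")
  }
  # planted count = round(fraction x eligible operon count)
  heads <- regulocate:::operon_heads(g$annotation)
  hr_end <- cfg$hot_region$start + cfg$hot_region$length - 1
  hot <- heads[heads$replicon == "pA" & heads$start >= cfg$hot_region$start &
                 heads$end <= hr_end, ]
  eligible <- sum(vapply(seq_len(nrow(hot)), function(i) {
    regulocate:::upstream_room(hot[i, ], g$annotation, 200) >= 14
  }, logical(1)))
  expect_equal(sum(ph$kind == "planted"),
               round(cfg$planted_fraction * eligible))
  # planted hits are intergenic
  expect_false(any(regulocate:::hits_in_orfs(ph, g$annotation)))
})

test_that("no planting occurs with fraction and decoy rate zero", {
  cfg <- small_config(seed = 3, planted_fraction = 0, decoy_rate = 0)
  g <- generate_genome(cfg)
  pl <- plant_motifs(g$sequences, g$annotation, cfg)
  expect_identical(pl$sequences, g$sequences)
  expect_equal(nrow(pl$planted_hits), 0)
})

test_that("expression effects follow the order-decay model", {
  # noiseless: true lfc is exactly -beta * delta^(k-1)
  cfg <- small_config(seed = 5, noise_sd = 0)
  ds <- simulate_dataset(cfg)
  tl <- ds$truth$true_lfc
  reg <- ds$truth$regulated_genes
  ordv <- reg$operon_order[match(tl$gene_id, reg$gene_id)]
  expect_equal(unname(tl$lfc), -3 * 0.5^(ordv - 1))
  # effects exist only for affected strains, first condition
  expect_true(all(tl$condition == "limited"))
  expect_false(any(tl$strain %in% c("parent", "glgA1")))
})

test_that("realized order-1 effects average to -beta", {
  # wide hot region so one dataset carries hundreds of order-1 genes
  cfg <- sim_config(seed = 8,
                    replicon_lengths = c(100000, 3000000),
                    replicon_names = c("chr", "pA"),
                    n_genes = c(40, 1300),
                    hot_region = list(replicon = 2, start = 10000,
                                      length = 2950000))
  ds <- simulate_dataset(cfg)
  tl <- ds$truth$true_lfc
  reg <- ds$truth$regulated_genes
  o1 <- tl[tl$gene_id %in% reg$gene_id[reg$operon_order == 1] &
             tl$strain == "phbA", ]
  expect_gte(nrow(o1), 200)
  expect_lt(abs(mean(o1$lfc) + 3), 3 * 0.5 / sqrt(nrow(o1)))
})

test_that("the unaffected strain recovers a near-zero mean effect", {
  cfg <- sim_config(seed = 9,
                    replicon_lengths = c(100000, 3000000),
                    replicon_names = c("chr", "pA"),
                    n_genes = c(40, 1300),
                    hot_region = list(replicon = 2, start = 10000,
                                      length = 2950000))
  ds <- simulate_dataset(cfg)
  reg <- ds$truth$regulated_genes$gene_id
  expect_gte(length(reg), 1000)
  de <- de_test(ds$counts, default_contrasts(ds$counts)$glgA1.limited)
  est <- de$log2fc[match(reg, de$gene_id)]
  est <- est[!is.na(est)]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 4 * se)
})

test_that("datasets round-trip through their file formats", {
  cfg <- small_config(seed = 6)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_identical(read_genome_fasta(paths[["fasta"]]), ds$sequences)
  ann <- read_annotation_gff3(paths[["gff"]])
  expect_equal(ann[order(ann$gene_id), ],
               ds$annotation[order(ds$annotation$gene_id), ],
               ignore_attr = TRUE)
  back <- read_counts_tsv(paths[["counts"]])
  expect_equal(back$counts, ds$counts$counts)
  expect_equal(back$length, ds$counts$length)
  expect_equal(back$samples$strain, ds$counts$samples$strain)
  # rerunning the DE stage from files equals the in-memory run
  de_mem <- de_test(ds$counts, default_contrasts(ds$counts)$phbA.limited)
  de_file <- de_test(back, default_contrasts(back)$phbA.limited)
  expect_equal(de_file, de_mem)
})

test_that("simulated datasets are fully reproducible from the seed", {
  d1 <- simulate_dataset(small_config(seed = 11))
  d2 <- simulate_dataset(small_config(seed = 11))
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$truth$planted_hits, d2$truth$planted_hits)
  expect_identical(d1$counts$counts, d2$counts$counts)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_dataset(d1, dir1); p2 <- write_dataset(d2, dir2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})
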