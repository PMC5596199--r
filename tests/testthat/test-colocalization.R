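test_that("motif density is a sum of Gaussian kernels", {
  one <- data.frame(replicon = "chr", start = 499994, end = 500006)
  tr <- motif_density(one, 1e6)
  expect_equal(tr$pos[which.max(tr$density)], 500001, tolerance = 1000)
  expect_equal(max(tr$density), 1 / (30000 * sqrt(2 * pi)),
               tolerance = 1e-3)
  # two hits far apart: local maxima at both positions
  two <- data.frame(replicon = "chr", start = c(2e5, 5e5), end = c(2e5, 5e5))
  tr2 <- motif_density(two, 1e6)
  near <- function(p) tr2$density[which.min(abs(tr2$pos - p))]
  expect_gt(near(2e5), near(3.5e5))
  expect_gt(near(5e5), near(3.5e5))
  # multiplicity doubles the track everywhere
  dup <- rbind(one, one)
  expect_equal(motif_density(dup, 1e6)$density, 2 * tr$density)
  # no hits: all-zero track
  expect_true(all(motif_density(one[0, ], 1e6)$density == 0))
})

test_that("density integrates to approximately the hit count", {
  hits <- data.frame(replicon = "chr",
                     start = c(3e5, 5e5, 7e5), end = c(3e5, 5e5, 7e5))
  tr <- motif_density(hits, 1e6)
  integral <- sum(tr$density) * 1000
  expect_equal(integral, 3, tolerance = 0.01)
})

test_that("composite effect averages log2FC across a strain set", {
  mk <- function(lfc) data.frame(gene_id = c("g1", "g2"),
                                 mean_fpkm_a = 1, mean_fpkm_b = 1,
                                 log2fc = lfc, p = 0.5, q = 0.5,
                                 tested = TRUE, significant = FALSE)
  de <- list(a.limited = mk(c(-2, 1)), b.limited = mk(c(-4, NA)))
  expect_equal(unname(composite_effect(de, c("a", "b"), "limited")),
               c(-3, 1))
  expect_equal(unname(composite_effect(de, "a", "limited")), c(-2, 1))
  expect_error(composite_effect(de, character(0)), "non-empty")
  expect_error(composite_effect(de, "zz"), "not found")
})

test_that("DE region detection follows the run/gap/fraction rules", {
  ann <- data.frame(gene_id = paste0("g", 1:10), replicon = "chr",
                    start = seq(1000, by = 2000, length.out = 10),
                    end = seq(2500, by = 2000, length.out = 10),
                    strand = "+", operon_id = paste0("o", 1:10),
                    operon_order = 1L, stringsAsFactors = FALSE)
  fl <- function(x) setNames(as.logical(x), ann$gene_id)
  r1 <- detect_de_regions(ann, fl(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_genes, 5)
  expect_equal(r1$fraction_de, 1.0)
  expect_equal(r1$start, ann$start[1])
  expect_equal(r1$end, ann$end[5])
  r2 <- detect_de_regions(ann, fl(c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1)),
                          max_gap = 1)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_genes, 10)
  expect_equal(r2$fraction_de, 0.7)
  expect_equal(nrow(detect_de_regions(ann, fl(rep(0, 10)))), 0)
})

test_that("regions recover the synthetic hot region from truth flags", {
  for (s in 1:3) {
    ds <- simulate_dataset(small_config(seed = s))
    flags <- setNames(ds$annotation$gene_id %in%
                        ds$truth$regulated_genes$gene_id,
                      ds$annotation$gene_id)
    regs <- detect_de_regions(ds$annotation, flags)
    expect_gte(nrow(regs), 1)
    best <- regs[which.max(regs$n_genes), ]
    hot_genes <- ds$truth$regulated_genes$gene_id
    members <- strsplit(best$gene_ids, ",")[[1]]
    expect_gte(length(intersect(members, hot_genes)) / length(hot_genes),
               0.9)
  }
})

test_that("upstream distances use strand, adjacency and ORF exclusion", {
  ann <- toy_annotation()
  # + strand gene at 1001 with a hit ending at 1000 -> distance 1
  g <- data.frame(gene_id = "g", replicon = "chr", start = 1001, end = 1500,
                  strand = "+", operon_id = "op", operon_order = 1L)
  h <- data.frame(replicon = "chr", start = 987, end = 1000, strand = "+")
  expect_equal(upstream_distance(g, h, g), 1)
  # hit overlapping an ORF contributes nothing
  h_in <- data.frame(replicon = "chr", start = 1200, end = 1213,
                     strand = "+")
  expect_true(is.na(upstream_distance(g, h_in, g)))
  # two upstream hits at distances 30 and 150: nearest wins
  h2 <- data.frame(replicon = "chr",
                   start = c(1001 - 30 - 13, 1001 - 150 - 13),
                   end = c(1001 - 30, 1001 - 150), strand = "+")
  g2 <- data.frame(gene_id = "g", replicon = "chr", start = 1001,
                   end = 1500, strand = "+", operon_id = "op",
                   operon_order = 1L)
  expect_equal(upstream_distance(g2, h2, g2), 30)
  # beyond the window: none
  expect_true(is.na(upstream_distance(g2, h2, g2, max_window = 20)))
})

test_that("distance density finds modes where distances concentrate", {
  d1 <- distance_density(rep(40, 20))
  expect_equal(attr(d1, "mode"), 40, tolerance = 2)
  bim <- distance_density(c(rep(30, 30), rep(150, 30)), bandwidth = 8)
  y <- d1$y
  dens <- bim$y
  locmax <- which(diff(sign(diff(dens))) == -2) + 1
  expect_gte(length(locmax), 2)
  expect_error(distance_density(numeric(0)), "no distances")
})

test_that("density-effect correlation behaves at its edge cases", {
  # 2,000 evenly spaced genes on a 2-Mb replicon with clustered hits
  n <- 2000
  ann <- data.frame(gene_id = paste0("g", seq_len(n)), replicon = "chr",
                    start = seq(500, by = 1000, length.out = n),
                    end = seq(1300, by = 1000, length.out = n),
                    strand = "+", operon_id = paste0("o", seq_len(n)),
                    operon_order = 1L, stringsAsFactors = FALSE)
  set.seed(8)
  hpos <- sort(c(round(runif(30, 9e5, 10e5)), round(runif(10, 1, 2e6))))
  hits <- data.frame(replicon = "chr", start = hpos, end = hpos + 13)
  tr <- motif_density(hits, 2e6)
  step <- tr$pos[2] - tr$pos[1]
  dens <- tr$density[pmin(pmax(round(((ann$start + ann$end) / 2 -
                                        tr$pos[1]) / step) + 1, 1),
                          nrow(tr))]
  # perfectly anti-proportional composite gives r = -1
  comp <- setNames(-5 * dens, ann$gene_id)
  r <- density_effect_correlation(tr, comp, ann)
  expect_equal(r$pearson_r, -1)
  expect_equal(r$n, n)
  # permuted composite decorrelates
  rs <- replicate(20, {
    density_effect_correlation(tr, setNames(sample(comp), ann$gene_id),
                               ann)$pearson_r
  })
  expect_lt(median(abs(rs)), 0.05)
  # constant composite: undefined, with warning
  const <- setNames(rep(1, nrow(ann)), ann$gene_id)
  expect_warning(rc <- density_effect_correlation(tr, const, ann),
                 "constant")
  expect_true(is.na(rc$pearson_r))
  expect_error(density_effect_correlation(tr, comp[1:2], ann[1:2, ]),
               "at least 3")
})
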