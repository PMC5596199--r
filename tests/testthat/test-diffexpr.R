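test_that("fpkm follows its defining formula", {
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_error(fpkm(1, 0, 1e6), "positive")
  expect_error(fpkm(1, 1000, 0), "positive")
})

test_that("fpkm_matrix reproduces a hand-computed 3-gene table", {
  counts <- matrix(c(10, 20, 70, 5, 15, 80), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("a.limited.1", "a.limited.2")))
  tab <- structure(list(gene_id = rownames(counts),
                        length = c(500, 1000, 2000),
                        samples = data.frame(strain = "a",
                                             condition = "limited",
                                             replicate = 1:2,
                                             label = colnames(counts)),
                        counts = counts), class = "abundance_table")
  fp <- fpkm_matrix(tab)
  # hand: sample 1 total 100; g1 = 1e9*10/(500*100) = 2e5
  expect_equal(fp["g1", 1], 1e9 * 10 / (500 * 100))
  expect_equal(fp["g2", 1], 1e9 * 20 / (1000 * 100))
  expect_equal(fp["g3", 2], 1e9 * 80 / (2000 * 100))
})

test_that("log2 fold change handles zeros by the stated convention", {
  expect_equal(log2_fold_change(4, 16), 2)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_true(is.na(log2_fold_change(5, 0)))
  expect_true(is.na(log2_fold_change(0, 5)))
})

test_that("BH q-values match hand computations and propagate NA", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  out <- bh_fdr(c(0.005, NA, 0.1))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.01, 0.1))  # NA excluded from m
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH agrees with the smallest-rejecting-alpha brute force", {
  for (s in 1:8) {
    set.seed(400 + s)
    n <- sample(3:50, 1)
    p <- round(runif(n), 3)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

# toy table with controllable per-gene totals across a 2v2 contrast
toy_table <- function(counts) {
  labs <- c("p.limited.1", "p.limited.2", "m.limited.1", "m.limited.2")
  colnames(counts) <- labs
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  structure(list(gene_id = rownames(counts),
                 length = rep(1000, nrow(counts)),
                 samples = data.frame(
                   strain = rep(c("p", "m"), each = 2),
                   condition = "limited", replicate = rep(1:2, 2),
                   label = labs),
                 counts = counts), class = "abundance_table")
}

test_that("minimum-count gating controls which genes are tested", {
  counts <- rbind(c(3, 3, 3, 3),    # total 12 -> tested
                  c(2, 2, 2, 3),    # total 9  -> not tested
                  c(2, 3, 2, 3))    # total 10 -> tested
  tab <- toy_table(counts)
  ct <- contrast("m.limited", paste0("p.limited.", 1:2),
                 paste0("m.limited.", 1:2))
  de <- de_test(tab, ct, min_count = 10)
  expect_equal(de$tested, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(de$p[!de$tested])))
  expect_true(all(is.na(de$q[!de$tested])))
  expect_false(any(de$significant[!de$tested]))
})

test_that("welch mode applies the degenerate zero-variance conventions", {
  # equal column totals keep FPKM comparable across samples
  counts <- rbind(c(10, 10, 10, 10),   # identical everywhere -> p = 1
                  c(30, 30, 60, 60),   # zero variance, unequal means
                  c(60, 60, 30, 30))
  tab <- toy_table(counts)
  ct <- contrast("m.limited", paste0("p.limited.", 1:2),
                 paste0("m.limited.", 1:2))
  expect_warning(de <- de_test(tab, ct, method = "welch"),
                 "zero-variance")
  expect_equal(de$p[1], 1)
  expect_equal(de$p[2], 0)
  expect_equal(de$p[3], 0)
})

test_that("swapping contrast groups negates log2FC and keeps p", {
  set.seed(77)
  counts <- matrix(rnbinom(40, mu = 300, size = 10), nrow = 10)
  tab <- toy_table(counts)
  a <- paste0("p.limited.", 1:2); b <- paste0("m.limited.", 1:2)
  for (m in c("moderated", "welch")) {
    d1 <- de_test(tab, contrast("f", a, b), method = m)
    d2 <- de_test(tab, contrast("r", b, a), method = m)
    expect_equal(d1$log2fc, -d2$log2fc)
    expect_equal(d1$p, d2$p, tolerance = 1e-12)
  }
})

test_that("groups with fewer than 2 replicates skip testing with warning", {
  counts <- matrix(rep(c(10, 12, 30, 33), 3), nrow = 3, byrow = TRUE)
  tab <- toy_table(counts)
  ct <- contrast("x", "p.limited.1", paste0("m.limited.", 1:2))
  expect_warning(de <- de_test(tab, ct), "fewer than 2")
  expect_false(any(de$tested))
  expect_false(all(is.na(de$log2fc)))  # log2FC still reported
})

test_that("no low-count gene is ever significant", {
  set.seed(99)
  counts <- matrix(rpois(200, lambda = 4), nrow = 50)
  tab <- toy_table(counts)
  ct <- contrast("m", paste0("p.limited.", 1:2), paste0("m.limited.", 1:2))
  de <- de_test(tab, ct, min_count = 10)
  low <- rowSums(counts) < 10
  expect_false(any(de$significant[low]))
})

test_that("regulated genes are detected with high sensitivity and few
          false positives on synthetic data", {
  sens <- numeric(3); fpr <- numeric(3)
  for (s in 1:3) {
    ds <- simulate_dataset(sim_config(seed = s))
    de <- de_test(ds$counts, default_contrasts(ds$counts)$phbA.limited)
    reg <- ds$truth$regulated_genes
    o1 <- reg$gene_id[reg$operon_order == 1]
    sens[s] <- mean(de$significant[match(o1, de$gene_id)])
    un <- setdiff(ds$annotation$gene_id, reg$gene_id)
    fpr[s] <- mean(de$significant[match(un, de$gene_id)])
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(max(fpr), 0.07)
})
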