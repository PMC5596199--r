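# Shared fixtures and small oracles, all built in code.

# fast two-replicon config used across module tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             replicon_lengths = c(200000, 150000),
             replicon_names = c("chr", "pA"),
             n_genes = c(90, 65),
             hot_region = list(replicon = 2, start = 30000, length = 60000),
             ...)
}

# hand-built annotation: operon (g1,g2,g3) with an upstream hit, singleton
# g4 with a hit, singleton g5 without, operon (g6,g7) without
toy_annotation <- function() {
  data.frame(
    gene_id = paste0("g", 1:7),
    replicon = "chr",
    start = c(1000, 2000, 3000, 5000, 7000, 9000, 10000),
    end = c(1800, 2800, 3800, 5800, 7800, 9800, 10800),
    strand = "+",
    operon_id = c("op1", "op1", "op1", "op2", "op3", "op4", "op4"),
    operon_order = c(1L, 2L, 3L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

toy_hits <- function() {
  data.frame(replicon = "chr",
             start = c(950, 4950),
             end = c(963, 4963),
             strand = "+",
             stringsAsFactors = FALSE)
}

# random PWM from Dirichlet-ish gamma draws
random_pwm <- function(w, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * w, 1), nrow = 4)
  pwm(sweep(m, 2, colSums(m), "/"))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample one instance of the TTGAT-N4-ATCAA motif (fixed positions exact,
# spacer uniform)
sample_fixk_instance <- function() {
  pw <- regulocate:::planting_pwm("TTGATNNNNATCAA")
  paste(regulocate:::.BASES[vapply(1:14, function(j) {
    sample.int(4L, 1L, prob = pw$mat[, j])
  }, integer(1))], collapse = "")
}

# 60 x 200 bp discovery fixture with `n_planted` embedded instances
planted_sequences <- function(seed, n_seq = 60, n_planted = 50, len = 200) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_seq), function(i) random_dna(len), "")
  for (i in seq_len(n_planted)) {
    inst <- sample_fixk_instance()
    if (stats::runif(1) < 0.5) inst <- regulocate:::revcomp_string(inst)
    pos <- sample.int(len - 13L, 1L)
    substr(seqs[i], pos, pos + 13L) <- inst
  }
  names(seqs) <- paste0("s", seq_len(n_seq))
  seqs
}

# best match count of a consensus string against the 14-position FixK
# reference, over all offsets and both orientations; reference N
# positions always count as matching
match_fixk_consensus <- function(cons, ref = "TTGATNNNNATCAA") {
  score1 <- function(cs) {
    w <- nchar(cs)
    best <- 0L
    for (o in (-13L):(w - 1L)) {
      m <- 0L
      for (k in 1:14) {
        rc <- substr(ref, k, k)
        j <- o + k
        if (rc == "N") m <- m + 1L
        else if (j >= 1 && j <= w && substr(cs, j, j) == rc) m <- m + 1L
      }
      best <- max(best, m)
    }
    best
  }
  max(score1(cons), score1(regulocate:::revcomp_string(cons)))
}

# brute-force BH oracle: each gene's q is the smallest alpha at which
# the step-up procedure rejects it, searched over all threshold flip
# points p_i * m / k
bh_oracle <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  alphas <- sort(unique(as.vector(outer(pv * m, 1 / seq_len(m)))))
  o <- order(pv)
  qv <- rep(1, m)
  assigned <- rep(FALSE, m)
  for (a in alphas) {
    # tolerance absorbs float round-trip at the exact flip points
    kset <- which(pv[o] <= seq_len(m) * a / m + 1e-12)
    if (length(kset)) {
      rej <- o[seq_len(max(kset))]
      newly <- rej[!assigned[rej]]
      qv[newly] <- a
      assigned[newly] <- TRUE
    }
    if (all(assigned)) break
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(qv, 1)
  q
}

# brute-force O(n^3) complete-linkage agglomeration; returns merge
# heights and the partition after each merge
complete_linkage_oracle <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (labels renumbered by first appearance)
canon_partition <- function(lab) {
  match(lab, unique(lab))
}

# two-pass sums-of-squares one-way ANOVA F
anova_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}
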