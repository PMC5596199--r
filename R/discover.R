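# De novo motif discovery: ZOOPS (zero-or-one occurrence per sequence)
# EM over both strands, seeded from enriched candidate windows, with a
# QFAST-combined E-value per reported motif.

# window table for one width over a list of code vectors; masked (NA)
# positions exclude the windows that touch them.
# offsets are 1-based starts on the FORWARD strand for both strands.
build_windows <- function(code_list, w) {
  rows <- list(); seq_id <- list(); strand <- list(); offset <- list()
  for (i in seq_along(code_list)) {
    codes <- code_list[[i]]
    L <- length(codes)
    n <- L - w + 1L
    if (n < 1L) next
    for (st in c("+", "-")) {
      cc <- if (st == "+") codes else revcomp_codes(codes)
      m <- matrix(cc[outer(0:(w - 1L), 1:n, "+")], nrow = w)  # w x n
      keep <- which(colSums(is.na(m)) == 0L)
      if (!length(keep)) next
      rows[[length(rows) + 1L]] <- t(m[, keep, drop = FALSE])
      seq_id[[length(seq_id) + 1L]] <- rep(i, length(keep))
      strand[[length(strand) + 1L]] <- rep(st, length(keep))
      off <- if (st == "+") keep else (L - (keep + w - 1L) + 1L)
      offset[[length(offset) + 1L]] <- off
    }
  }
  if (!length(rows)) {
    return(list(W = matrix(integer(), 0, w), seq_id = integer(),
                strand = character(), offset = integer()))
  }
  list(W = do.call(rbind, rows), seq_id = unlist(seq_id),
       strand = unlist(strand), offset = unlist(offset))
}

# log-odds score of every window row
score_window_rows <- function(W, lo) {
  w <- ncol(W)
  sc <- numeric(nrow(W))
  for (j in seq_len(w)) sc <- sc + lo[W[, j] + (j - 1L) * 4L]
  sc
}

# one EM pass; returns updated theta (4 x w), gamma and the observed-data
# log-likelihood term that varies with the parameters
zoops_em_step <- function(W, seq_id, n_win_by_seq, theta, gamma, bg,
                          pseudocount) {
  w <- ncol(W)
  lo <- log2(theta / bg)
  sc <- score_window_rows(W, lo)
  lr <- 2^sc
  n_seq <- length(n_win_by_seq)
  tot <- rep(0, n_seq)
  sums <- rowsum(lr, seq_id)
  tot[as.integer(rownames(sums))] <- sums[, 1]
  prior <- gamma / n_win_by_seq
  denom <- (1 - gamma) + prior * tot
  z <- (prior[seq_id] * lr) / denom[seq_id]
  # the M-step maximizes the pseudocount-penalized (MAP) objective, so
  # the monotone quantity is log-likelihood + Dirichlet log-prior
  loglik <- sum(log(denom)) + pseudocount * sum(log(theta))
  counts <- matrix(0, 4, w)
  for (j in seq_len(w)) {
    cs <- rowsum(z, W[, j])
    counts[as.integer(rownames(cs)), j] <- cs[, 1]
  }
  counts <- counts + pseudocount
  theta_new <- sweep(counts, 2, colSums(counts), "/")
  gamma_new <- min(max(sum(z) / n_seq, 1e-4), 1 - 1e-4)
  list(theta = theta_new, gamma = gamma_new, loglik = loglik, z = z)
}

# initial column model from a seed k-mer
seed_theta <- function(kmer_codes, p0 = 0.5) {
  w <- length(kmer_codes)
  m <- matrix((1 - p0) / 3, 4, w)
  m[cbind(kmer_codes, seq_len(w))] <- p0
  m
}

# rank candidate windows by match-count enrichment against all windows:
# candidates are a seeded subsample; a candidate's score is the number of
# windows matching it at >= 70% of positions (one-hot inner product)
rank_candidates <- function(W, n_candidates, restarts, seed) {
  n <- nrow(W); w <- ncol(W)
  set.seed(seed)
  cand <- if (n <= n_candidates) seq_len(n) else
    sort(sample.int(n, n_candidates))
  X <- matrix(0, n, 4L * w)
  # one-hot: column block j holds the indicator of base b at position j
  X[cbind(rep(seq_len(n), w),
          as.integer(W) + rep(4L * (seq_len(w) - 1L), each = n))] <- 1
  thr <- ceiling(0.7 * w)
  # enrichment is estimated against a window subsample when the window
  # set is large; ranking only needs relative counts
  tgt <- if (n > 12000L) sort(sample.int(n, 12000L)) else seq_len(n)
  tX <- t(X[tgt, , drop = FALSE])
  score <- numeric(length(cand))
  chunk <- max(50L, min(500L, floor(2e7 / length(tgt))))
  for (s in seq(1L, length(cand), by = chunk)) {
    e <- min(s + chunk - 1L, length(cand))
    M <- X[cand[s:e], , drop = FALSE] %*% tX
    score[s:e] <- rowSums(M >= thr)
  }
  cand[order(-score, cand)][seq_len(min(restarts, length(cand)))]
}

# ZOOPS fit for one width; `init` (theta, gamma, trace) resumes EM from
# a previous state instead of seeding. Returns NULL when no windows
# exist.
zoops_fit_width <- function(code_list, w, restarts, n_candidates, bg,
                            pseudocount, max_iter, tol, quick_iter,
                            seed, init = NULL) {
  win <- build_windows(code_list, w)
  if (nrow(win$W) < 2L) return(NULL)
  n_win_by_seq <- rep(0L, length(code_list))
  tb <- table(win$seq_id)
  n_win_by_seq[as.integer(names(tb))] <- as.integer(tb)
  present <- which(n_win_by_seq > 0L)
  if (is.null(init)) {
    starts <- rank_candidates(win$W, n_candidates, restarts, seed)
    best <- NULL
    for (s in starts) {
      theta <- seed_theta(win$W[s, ])
      gamma <- 0.5
      ll <- -Inf
      for (it in seq_len(quick_iter)) {
        st <- zoops_em_step(win$W, win$seq_id, n_win_by_seq, theta, gamma,
                            bg, pseudocount)
        theta <- st$theta; gamma <- st$gamma; ll <- st$loglik
      }
      if (is.null(best) || ll > best$ll) {
        best <- list(theta = theta, gamma = gamma, ll = ll, start = s)
      }
    }
    theta <- best$theta; gamma <- best$gamma
    trace <- numeric(0)
  } else {
    theta <- init$theta; gamma <- init$gamma
    trace <- init$trace
  }
  for (it in seq_len(max_iter)) {
    st <- zoops_em_step(win$W, win$seq_id, n_win_by_seq, theta, gamma, bg,
                        pseudocount)
    trace <- c(trace, st$loglik)
    delta <- max(abs(st$theta - theta))
    theta <- st$theta; gamma <- st$gamma
    if (delta < tol) break
  }
  final <- zoops_em_step(win$W, win$seq_id, n_win_by_seq, theta, gamma, bg,
                         pseudocount)
  z <- final$z
  # site per sequence: best-posterior window, kept when the sequence's
  # total site posterior exceeds 1/2
  sites <- NULL
  for (i in present) {
    sel <- which(win$seq_id == i)
    q_i <- sum(z[sel])
    if (q_i > 0.5) {
      jbest <- sel[which.max(z[sel])]
      sites <- rbind(sites, data.frame(
        seq = i, offset = win$offset[jbest], strand = win$strand[jbest],
        kmer = seq_decode(win$W[jbest, ]), stringsAsFactors = FALSE))
    }
  }
  list(theta = theta, gamma = gamma, sites = sites, trace = trace,
       n_candidates_used = min(n_candidates, nrow(win$W)))
}

# QFAST product-of-p combination on the log10 scale:
# P = p * sum_{k=0}^{n-1} (-ln p)^k / k!
qfast_log10 <- function(log_p_values) {
  n <- length(log_p_values)
  lnp <- sum(log_p_values) * log(10)  # natural log of the product
  if (lnp >= 0) return(0)
  lt <- (0:(n - 1)) * log(-lnp) - lgamma(1:n)
  m <- max(lt)
  (lnp + m + log(sum(exp(lt - m)))) / log(10)
}

#' Combined E-value of a discovered motif
#'
#' Per-site scan p-values (see [score_pvalue()]) are combined with the
#' QFAST product-of-p formula `P = p * sum_{k=0}^{n-1} (-ln p)^k / k!`
#' and multiplied by the number of (width, start-seed) configurations
#' searched.
#'
#' @param x a [pwm()].
#' @param site_kmers character vector of the motif's site k-mers.
#' @param n_configs size of the search space the motif came from
#'   (default 1).
#' @return list with `e_value` and `log10_e` (the latter safe against
#'   underflow).
#' @export
motif_evalue <- function(x, site_kmers, n_configs = 1) {
  stopifnot(inherits(x, "pwm"), length(site_kmers) >= 1L)
  dist <- pwm_score_distribution(x)
  sc <- vapply(site_kmers, function(k) score_kmer(x, k), numeric(1))
  p <- score_pvalue_from_dist(dist, sc[!is.na(sc)])
  log10_p <- qfast_log10(log10(p))
  log10_e <- log10_p + log10(n_configs)
  list(e_value = max(10^log10_e, .Machine$double.xmin), log10_e = log10_e)
}

#' De novo ZOOPS motif discovery
#'
#' Fits a zero-or-one-occurrence-per-sequence motif model by
#' expectation-maximization on both strands, for every width in
#' `width_range`. Starting points are seeded from candidate windows
#' ranked by match-count enrichment; the best start per width is run to
#' convergence and widths compete by E-value. Reported sites are masked
#' and the search repeats for `n_motifs` motifs.
#'
#' @param sequences `DNAStringSet` or character vector (>= 2 sequences).
#' @param width_range integer length-2, motif widths to try
#'   (default c(8, 18)).
#' @param n_motifs motifs to report (default 3).
#' @param restarts starting points refined per width (default 20).
#' @param seed RNG seed for candidate subsampling.
#' @param n_candidates candidate windows ranked per width (default 2000).
#' @param max_iter,tol EM stopping rule: stop when the largest column
#'   probability change drops below `tol` (default 1e-4) or after
#'   `max_iter` (default 200) iterations.
#' @param pseudocount additive base pseudocount in the M-step.
#' @return list of discovered motifs, each a list with elements `pwm`,
#'   `consensus`, `sites` (data.frame: seq, offset, strand, kmer),
#'   `e_value`, `log10_e`, `gamma`, `loglik_trace`, `n_configs`.
#' @export
discover_zoops <- function(sequences, width_range = c(8, 18), n_motifs = 3,
                           restarts = 20, seed = 1, n_candidates = 2000,
                           max_iter = 200, tol = 1e-4, pseudocount = 0.25) {
  seqs <- as_seq_character(sequences)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  widths <- seq(min(width_range), max(width_range))
  code_list <- lapply(seqs, seq_encode)
  if (all(lengths(code_list) < min(widths))) {
    stop("all sequences are shorter than the minimum motif width")
  }
  # background: 0-order model estimated from the input set
  allc <- unlist(code_list)
  bg <- tabulate(allc[!is.na(allc)], 4L)
  bg <- (bg + 1) / sum(bg + 1)
  out <- list()
  for (m in seq_len(n_motifs)) {
    # scout every width with a short EM, then run only the E-value
    # winner to full convergence
    fits <- list()
    n_configs_total <- 0
    for (w in widths) {
      fit <- zoops_fit_width(code_list, w, restarts, n_candidates, bg,
                             pseudocount, max_iter = min(40L, max_iter),
                             tol = tol, quick_iter = 3,
                             seed = (seed + 131L * w + 7919L * m) %% 2147483647L)
      if (is.null(fit) || is.null(fit$sites)) next
      n_configs_total <- n_configs_total + fit$n_candidates_used
      fits[[as.character(w)]] <- fit
    }
    if (!length(fits)) break
    evs <- vapply(fits, function(f) {
      p <- pwm(f$theta, background = bg)
      motif_evalue(p, f$sites$kmer, n_configs = 1)$log10_e
    }, numeric(1))
    w_win <- as.integer(names(fits)[which.min(evs)])
    scout <- fits[[which.min(evs)]]
    best <- zoops_fit_width(code_list, w_win, restarts, n_candidates, bg,
                            pseudocount, max_iter = max_iter, tol = tol,
                            quick_iter = 3, seed = seed,
                            init = list(theta = scout$theta,
                                        gamma = scout$gamma,
                                        trace = scout$trace))
    bp <- pwm(best$theta, background = bg)
    ev <- motif_evalue(bp, best$sites$kmer, n_configs = n_configs_total)
    out[[m]] <- list(
      pwm = bp,
      consensus = consensus(bp),
      sites = data.frame(seq = names(seqs)[best$sites$seq],
                         offset = best$sites$offset,
                         strand = best$sites$strand,
                         kmer = best$sites$kmer,
                         stringsAsFactors = FALSE),
      e_value = ev$e_value, log10_e = ev$log10_e,
      gamma = best$gamma, loglik_trace = best$trace,
      n_configs = n_configs_total
    )
    # mask reported sites and continue
    w_best <- bp$width
    for (r in seq_len(nrow(best$sites))) {
      i <- best$sites$seq[r]
      span <- best$sites$offset[r]:(best$sites$offset[r] + w_best - 1L)
      code_list[[i]][span] <- NA_integer_
    }
  }
  out
}

#' Compare a motif against target motifs
#'
#' Slides the query over each target in both query orientations,
#' requiring at least `min_overlap` aligned columns; similarity is the
#' mean per-query-column Pearson correlation of aligned probability
#' columns (query columns left unaligned contribute 0, so short
#' overlaps cannot dominate). Significance comes from permuting the
#' target's columns and re-aligning.
#'
#' @param query a [pwm()].
#' @param targets a [pwm()] or named list of them.
#' @param min_overlap minimum aligned columns (default 4).
#' @param permutations column permutations for the null (default 1000).
#' @param seed RNG seed.
#' @param p_threshold matches at or below this p are flagged
#'   (default 0.001).
#' @return data.frame: `target, offset, orientation, similarity,
#'   p_value, match`.
#' @export
compare_motifs <- function(query, targets, min_overlap = 4,
                           permutations = 1000, seed = 1,
                           p_threshold = 0.001) {
  stopifnot(inherits(query, "pwm"))
  if (inherits(targets, "pwm")) targets <- list(target_1 = targets)
  if (is.null(names(targets))) {
    names(targets) <- paste0("target_", seq_along(targets))
  }
  qmats <- list(`+` = query$mat, `-` = pwm_revcomp(query)$mat)
  # columnwise Pearson r of two 4 x k matrices; a pair of zero-variance
  # columns counts as 1 when identical (else 0), a single zero-variance
  # column as 0, keeping self-similarity exactly 1
  column_cor <- function(A, B) {
    ac <- sweep(A, 2, colMeans(A)); bc <- sweep(B, 2, colMeans(B))
    sa <- sqrt(colSums(ac^2)); sb <- sqrt(colSums(bc^2))
    num <- colSums(ac * bc)
    r <- ifelse(sa > 0 & sb > 0, num / (sa * sb), 0)
    both0 <- sa == 0 & sb == 0
    r[both0] <- as.numeric(colSums(abs(A - B))[both0] < 1e-12)
    r
  }
  best_align <- function(tm) {
    wq <- ncol(qmats[[1]]); wt <- ncol(tm)
    best <- list(sim = -Inf, offset = NA_integer_, orientation = NA)
    for (orient in names(qmats)) {
      qm <- qmats[[orient]]
      for (o in (-(wq - min_overlap)):(wt - min_overlap)) {
        qcols <- max(1, 1 - o):min(wq, wt - o)
        if (length(qcols) < min_overlap) next
        tcols <- qcols + o
        # mean over ALL query columns (unaligned ones contribute 0), so
        # a lucky short overlap cannot outscore a full-length alignment
        sim <- sum(column_cor(qm[, qcols, drop = FALSE],
                              tm[, tcols, drop = FALSE])) / wq
        if (sim > best$sim) {
          best <- list(sim = sim, offset = o, orientation = orient)
        }
      }
    }
    best
  }
  set.seed(seed)
  res <- lapply(names(targets), function(nm) {
    tm <- targets[[nm]]$mat
    obs <- best_align(tm)
    null <- vapply(seq_len(permutations), function(b) {
      best_align(tm[, sample.int(ncol(tm)), drop = FALSE])$sim
    }, numeric(1))
    p <- (1 + sum(null >= obs$sim)) / (permutations + 1)
    data.frame(target = nm, offset = obs$offset,
               orientation = obs$orientation, similarity = obs$sim,
               p_value = p, match = p <= p_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
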