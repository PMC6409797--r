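# Brute-force reference implementations, kept deliberately independent of
# the package internals: naive loops and full enumeration only.

# O(N^2) step-up BH: q_i = min over {j : p_(j) >= p_(i)} of p_(j) * N / j
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    candidates <- vapply(rank_i:n, function(j) {
      p[ord[j]] * n / j
    }, numeric(1L))
    q[i] <- min(1, min(candidates))
  }
  q
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcoxon_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2L, function(idx) {
    sum(ranks[idx]) - n_a * (n_a + 1) / 2
  })
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# exact two-sided Spearman p by enumerating all permutations of y
# (tie-free inputs: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)))
spearman_exact_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  perms <- all_permutations(n)
  y_perm <- matrix(ry[perms], nrow(perms), n)
  d2 <- rowSums((y_perm - matrix(rx, nrow(perms), n, byrow = TRUE))^2)
  rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
  list(
    rho = rho_obs,
    p_value = min(1, 2 * min(mean(rhos <= rho_obs + 1e-12),
                             mean(rhos >= rho_obs - 1e-12)))
  )
}

all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# naive reciprocal-best-hits over full score matrices
rbh_oracle <- function(hits_ab, hits_ba) {
  pairs <- list()
  for (q in unique(hits_ab$query)) {
    sub <- hits_ab[hits_ab$query == q, ]
    best <- sub[sub$score == max(sub$score), ]
    if (nrow(best) != 1L) next
    s <- best$subject
    back <- hits_ba[hits_ba$query == s, ]
    if (nrow(back) == 0L) next
    best_back <- back[back$score == max(back$score), ]
    if (nrow(best_back) != 1L) next
    if (best_back$subject == q) {
      pairs[[length(pairs) + 1L]] <- data.frame(gene_a = q, gene_b = s)
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  out <- do.call(rbind, pairs)
  out[order(out$gene_a), , drop = FALSE]
}

# O(N * M) site-in-interval scan (1-based site vs 0-based half-open feature)
interval_assign_oracle <- function(sites, features) {
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(features))) {
      if (sites$chrom[i] == features$chrom[j] &&
          sites$pos[i] > features$start[j] &&
          sites$pos[i] <= features$end[j]) {
        hits[[length(hits) + 1L]] <- data.frame(
          site = i, feature_id = features$id[j], kind = features$kind[j]
        )
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(site = integer(), feature_id = character(),
                      kind = character()))
  }
  do.call(rbind, hits)
}

# naive TE context: genic iff contained in a gene, intergenic iff no overlap
te_context_oracle <- function(te, genes) {
  contained <- FALSE
  overlaps <- FALSE
  for (j in seq_len(nrow(genes))) {
    if (te$chrom != genes$chrom[j]) next
    if (te$start < genes$end[j] && genes$start[j] < te$end) {
      overlaps <- TRUE
      if (te$start >= genes$start[j] && te$end <= genes$end[j]) {
        contained <- TRUE
      }
    }
  }
  if (contained) "genic" else if (overlaps) "boundary" else "intergenic"
}

# independent window scan for the codon-alignment filter
codon_filter_oracle <- function(seq_a, seq_b, window = 60L,
                                max_mismatch = 10L) {
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  mm <- a != b | a == "-" | b == "-"
  n_codons <- length(a) / 3L
  w_codons <- window / 3L
  kept <- rep(FALSE, n_codons)
  for (c_i in seq_len(n_codons)) {
    for (w in seq_len(max(0L, n_codons - w_codons + 1L))) {
      if (c_i < w || c_i > w + w_codons - 1L) next
      bp <- (3L * (w - 1L) + 1L):(3L * (w + w_codons - 1L))
      if (sum(mm[bp]) <= max_mismatch) {
        kept[c_i] <- TRUE
        break
      }
    }
  }
  kept
}

# small random alignment pair with controlled mismatch/gap rates
random_alignment <- function(n_codons, mismatch_rate = 0.1,
                             gap_rate = 0.02) {
  len <- 3L * n_codons
  a <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  b <- a
  flip <- runif(len) < mismatch_rate
  b[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
  gap <- runif(len) < gap_rate
  b[gap] <- "-"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
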