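# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive, transparent code paths so they can cross-check the
# package's implementations.

# One-sided hypergeometric upper tail P(X >= k) by explicit summation of
# choose() terms (log scale for stability).
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Literal transcription of the CAST loop (Ben-Dor et al.): recomputes mean
# affinities from scratch at every step, no incremental bookkeeping.
cast_oracle <- function(S, t) {
  ids <- rownames(S)
  n <- length(ids)
  unassigned <- ids
  assignment <- stats::setNames(integer(n), ids)
  k <- 0L
  while (length(unassigned) > 0) {
    k <- k + 1L
    tot <- vapply(unassigned, function(i)
      sum(S[i, setdiff(unassigned, i)]), numeric(1))
    seed <- unassigned[order(-tot, unassigned)][1]
    members <- seed
    unassigned <- setdiff(unassigned, seed)
    repeat {
      changed <- FALSE
      repeat {
        if (!length(unassigned)) break
        ma <- vapply(unassigned, function(u)
          mean(S[u, members]), numeric(1))
        if (max(ma) < t) break
        add <- unassigned[order(-ma, unassigned)][1]
        members <- c(members, add)
        unassigned <- setdiff(unassigned, add)
        changed <- TRUE
      }
      repeat {
        if (length(members) <= 1) break
        ma <- vapply(members, function(v)
          mean(S[v, members]), numeric(1))
        if (min(ma) >= t) break
        drop_el <- members[order(ma, members)][1]
        members <- setdiff(members, drop_el)
        unassigned <- c(unassigned, drop_el)
        changed <- TRUE
      }
      if (!changed) break
    }
    assignment[members] <- k
  }
  assignment
}

# random symmetric affinity matrix in [0,1] with unit diagonal
random_affinity <- function(n) {
  S <- matrix(stats::runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(letters[seq_len(n)], letters[seq_len(n)])
  S
}

# Noise-free per-gene log2 enrichment profiles predicted directly from the
# clone abundance recursion, relative to the neutral baseline (which LOWESS
# normalization removes), by brute-force interval overlap.
oracle_profiles <- function(library_, genome, truth, n_steps = 4) {
  genes <- genome$genes
  cl <- library_$clones
  n_clones <- nrow(cl)
  s <- truth$s_butanol
  a0 <- rep(1 / n_clones, n_clones)
  gene_cov <- lapply(seq_len(nrow(genes)), function(i)
    which(cl$start < genes$end[i] & cl$end > genes$start[i]))
  ref <- vapply(gene_cov, function(ix) sum(a0[ix]), numeric(1))
  covered <- ref > 0
  out <- matrix(NA_real_, nrow(genes), n_steps,
                dimnames = list(genes$gene_id, NULL))
  for (k in seq_len(n_steps)) {
    # closed form of the multiplicative recursion: a_i(k) oc exp(s_i * k)
    a <- exp(s * k)
    a <- a / sum(a)
    sig <- vapply(gene_cov, function(ix) sum(a[ix]), numeric(1))
    # a neutral (s = 0) gene's ratio to the reference is 1/mean(exp(s*k));
    # LOWESS normalization subtracts this bulk baseline
    neutral_log2 <- -log2(mean(exp(s * k)))
    out[covered, k] <- log2(sig[covered] / ref[covered]) - neutral_log2
  }
  out
}

# closed-form one-sample two-sided t p-value
t_p_oracle <- function(x) {
  n <- length(x)
  tt <- mean(x) / (stats::sd(x) / sqrt(n))
  2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
}
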