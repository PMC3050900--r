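# CAST (Cluster Affinity Search Technique) clustering of enrichment
# profiles, after Ben-Dor, Shamir & Yakhini (1999) as popularized by the
# MeV/TM4 suite.

#' Pairwise affinity between enrichment profiles
#'
#' Pearson correlation shifted to `[0,1]`: `s(i,j) = (r(i,j) + 1) / 2`
#' (the MeV convention). A constant profile has no defined correlation; its
#' r is taken as 0 (affinity 0.5) and the profile is flagged. A Euclidean
#' mode maps distances to `1 - d/max(d)`.
#'
#' @param profiles gene x step numeric matrix (>= 2 rows, >= 2 columns, all
#'   rows equal length by construction).
#' @param method `"pearson"` (default) or `"euclidean"`.
#' @return object of class `affinity_matrix`: symmetric matrix in `[0,1]`
#'   with unit diagonal; attribute `constant_profiles` names flagged rows.
#' @export
profile_similarity <- function(profiles, method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  if (!is.matrix(profiles)) profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2 || ncol(profiles) < 2)
    stop("need >= 2 profiles of length >= 2")
  if (anyNA(profiles)) stop("profiles contain missing values")
  constant <- apply(profiles, 1, stats::sd) == 0
  if (method == "pearson") {
    r <- suppressWarnings(stats::cor(t(profiles)))
    r[is.na(r)] <- 0
    s <- (r + 1) / 2
  } else {
    d <- as.matrix(stats::dist(profiles))
    mx <- max(d)
    s <- if (mx > 0) 1 - d / mx else matrix(1, nrow(d), ncol(d),
                                            dimnames = dimnames(d))
  }
  diag(s) <- 1
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  attr(s, "constant_profiles") <- rownames(profiles)[constant]
  class(s) <- c("affinity_matrix", class(s))
  s
}

#' CAST clustering
#'
#' Greedy one-cluster-at-a-time search: open a cluster seeded by the
#' unassigned element with the highest total affinity to the other
#' unassigned elements; alternately ADD the unassigned element with the
#' highest mean affinity to the cluster while that mean is `>= t`, and
#' REMOVE the member with the lowest mean affinity while that mean is
#' `< t` (means include the self-affinity of members, which is 1); when
#' neither applies the cluster is closed and the search restarts on the
#' remainder. Ties are broken by lexicographic element name so runs are
#' reproducible.
#'
#' @param affinity symmetric affinity matrix in `[0,1]` with named rows
#'   (see [profile_similarity()]).
#' @param t affinity threshold in `[0,1]` (default 0.8).
#' @return object of class `cast_clusters`: data.frame `gene_id`,
#'   `cluster` (1-based, in order of creation); attribute `threshold`.
#' @export
cast_cluster <- function(affinity, t = 0.8) {
  if (t < 0 || t > 1) stop("threshold t must be in [0, 1]")
  ids <- rownames(affinity)
  n <- length(ids)
  if (n == 0) {
    out <- data.frame(gene_id = character(), cluster = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- t
    class(out) <- c("cast_clusters", "data.frame")
    return(out)
  }
  S <- unclass(affinity)
  # lexicographic order index used for all tie-breaks
  lex <- order(ids)
  rank_lex <- match(seq_len(n), lex)

  unassigned <- rep(TRUE, n)
  cluster <- integer(n)
  k <- 0L
  while (any(unassigned)) {
    k <- k + 1L
    u_idx <- which(unassigned)
    # seed: max total affinity to the other unassigned elements
    tot <- colSums(S[u_idx, u_idx, drop = FALSE]) - 1  # minus self
    best <- u_idx[order(-tot, rank_lex[u_idx])][1]
    members <- best
    unassigned[best] <- FALSE
    # affinity sums to the open cluster (self included for members)
    a <- S[, best]
    repeat {
      changed <- FALSE
      # ADD phase
      repeat {
        u_idx <- which(unassigned)
        if (!length(u_idx)) break
        mean_aff <- a[u_idx] / length(members)
        cand <- u_idx[mean_aff >= t]
        if (!length(cand)) break
        add <- cand[order(-mean_aff[match(cand, u_idx)], rank_lex[cand])][1]
        members <- c(members, add)
        unassigned[add] <- FALSE
        a <- a + S[, add]
        changed <- TRUE
      }
      # REMOVE phase
      repeat {
        if (length(members) <= 1) break
        mean_aff <- a[members] / length(members)
        cand <- members[mean_aff < t]
        if (!length(cand)) break
        drop_el <- cand[order(mean_aff[match(cand, members)], rank_lex[cand])][1]
        members <- setdiff(members, drop_el)
        unassigned[drop_el] <- TRUE
        a <- a - S[, drop_el]
        changed <- TRUE
      }
      if (!changed) break
    }
    cluster[members] <- k
  }
  out <- data.frame(gene_id = ids, cluster = cluster,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- t
  class(out) <- c("cast_clusters", "data.frame")
  out
}

#' Mean profile per cluster
#'
#' @param profiles gene x step matrix.
#' @param clusters a `cast_clusters` assignment over the same genes.
#' @return cluster x step matrix of mean profiles.
#' @export
cluster_means <- function(profiles, clusters) {
  idx <- match(rownames(profiles), clusters$gene_id)
  if (anyNA(idx)) stop("clusters do not cover all profiled genes")
  grp <- clusters$cluster[idx]
  m <- rowsum(profiles, grp) / as.vector(table(grp))
  rownames(m) <- paste0("cluster", sort(unique(grp)))
  m
}
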