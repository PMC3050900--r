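# GO term enrichment: hypergeometric tests with log2 odds-ratios and
# multiple-testing correction, plus ancestor propagation over parent edges.

#' Propagate annotations to ancestor terms
#'
#' Adds, for every gene, all ancestors (transitive closure over the
#' term -> parent edges) of its directly annotated terms. Standard GO
#' practice: a gene annotated to a term is implicitly annotated to every
#' ancestor of that term.
#'
#' @param gene2go data.frame `gene_id`, `term`.
#' @param term_parents data.frame `term`, `parent` (may be empty).
#' @return data.frame `gene_id`, `term` with propagated rows, deduplicated.
#' @export
propagate_annotation <- function(gene2go, term_parents = NULL) {
  if (is.null(term_parents) || nrow(term_parents) == 0) {
    return(unique(gene2go[c("gene_id", "term")]))
  }
  # ancestor closure per term, iteratively following parent edges
  parent_of <- split(term_parents$parent, term_parents$term)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    seen <- character()
    frontier <- unlist(parent_of[term], use.names = FALSE)
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unlist(parent_of[frontier], use.names = FALSE)
    }
    anc_cache[[term]] <- seen
    seen
  }
  extra <- lapply(unique(gene2go$term), ancestors)
  names(extra) <- unique(gene2go$term)
  n_anc <- lengths(extra[gene2go$term])
  prop <- data.frame(gene_id = rep(gene2go$gene_id, n_anc),
                     term = unlist(extra[gene2go$term], use.names = FALSE),
                     stringsAsFactors = FALSE)
  unique(rbind(gene2go[c("gene_id", "term")], prop))
}

#' GO term enrichment of a study set against a population
#'
#' For every annotated term with at least one population gene, counts
#' `k` (study genes with the term), `n` (study size), `K` (population genes
#' with the term) and `N` (population size), and reports the log odds-ratio
#' `log2((k/n)/(K/N))` and a one-sided hypergeometric p-value
#' `P(X >= k)`, corrected across terms.
#'
#' @param study_set character vector of gene ids (must be a subset of the
#'   population).
#' @param population character vector of gene ids (the gene universe).
#' @param gene2go data.frame `gene_id`, `term`.
#' @param term_parents optional data.frame `term`, `parent` for ancestor
#'   propagation.
#' @param correction `"BH"` (default), `"BY"` or `"none"`.
#' @param propagate propagate annotations to ancestor terms first
#'   (default TRUE).
#' @return data.frame of class `go_results`: `term`, `k`, `n`, `K`, `N`,
#'   `log_odds_ratio` (`-Inf` when `k = 0`), `p_value`, `corrected_p`,
#'   sorted by p-value.
#' @export
go_enrich <- function(study_set, population, gene2go, term_parents = NULL,
                      correction = c("BH", "BY", "none"), propagate = TRUE) {
  correction <- match.arg(correction)
  if (length(population) == 0) stop("population must be nonempty")
  if (!all(study_set %in% population))
    stop("study_set must be a subset of the population")
  ann <- if (propagate) propagate_annotation(gene2go, term_parents)
         else unique(gene2go[c("gene_id", "term")])
  ann <- ann[ann$gene_id %in% population, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(structure(data.frame(term = character(), k = integer(),
                                n = integer(), K = integer(), N = integer(),
                                log_odds_ratio = numeric(),
                                p_value = numeric(), corrected_p = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("go_results", "data.frame")))
  }
  N <- length(unique(population))
  n <- length(unique(study_set))
  K_tab <- table(ann$term)
  in_study <- ann$gene_id %in% study_set
  k_tab <- table(factor(ann$term[in_study], levels = names(K_tab)))
  K <- as.integer(K_tab)
  k <- as.integer(k_tab)
  if (any(k > 0 & K == 0))
    stop("inconsistent annotation: study gene annotated to a term absent ",
         "from the population")
  keep <- K > 0
  K <- K[keep]; k <- k[keep]
  terms <- names(K_tab)[keep]
  lor <- ifelse(k == 0, -Inf, log2((k / n) / (K / N)))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- if (correction == "none") p else
    stats::p.adjust(p, method = correction)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    log_odds_ratio = lor, p_value = p,
                    corrected_p = pmax(padj, p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("go_results", "data.frame")
  out
}

#' Fraction of a gene set annotated to membrane-related terms
#'
#' After ancestor propagation, the proportion of genes carrying at least
#' one of the listed membrane-related terms. Used to compare a candidate
#' set (about 30% membrane-related in the solvent screen) with the genome
#' background (about 17%).
#'
#' @param gene_set character vector of gene ids.
#' @param gene2go data.frame `gene_id`, `term`.
#' @param membrane_terms nonempty character vector of term ids.
#' @param term_parents optional parent edges for propagation.
#' @return proportion in `[0, 1]`.
#' @export
membrane_fraction <- function(gene_set, gene2go, membrane_terms,
                              term_parents = NULL) {
  if (length(membrane_terms) == 0) stop("membrane_terms must be nonempty")
  if (length(gene_set) == 0) return(0)
  ann <- propagate_annotation(gene2go, term_parents)
  hit <- unique(ann$gene_id[ann$term %in% membrane_terms])
  mean(gene_set %in% hit)
}
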