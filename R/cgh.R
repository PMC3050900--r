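# Array-CGH stage: LOWESS normalization of two-channel scans, per-gene
# enrichment profiles across challenge steps, differential calling, and
# control-arm subtraction.

#' LOWESS-normalize a two-channel array scan
#'
#' Computes `M = log2(sample/reference)` and
#' `A = 0.5 * log2(sample * reference)` per probe, fits a LOWESS trend of M
#' on A and returns the residual `M - fit(A)`, removing intensity-dependent
#' dye bias. Rows with a non-positive intensity in either channel are
#' dropped (the count is recorded); more than 50% dropped is an error.
#'
#' @param scan data.frame with `probe_id`, `sample_intensity`,
#'   `reference_intensity` (an `array_scan`).
#' @param span LOWESS smoother span (fraction of points; default 0.3).
#' @return data.frame `probe_id`, `A`, `M` (normalized log2 ratio), with
#'   attributes `n_dropped`, `step`, `arm`.
#' @export
lowess_normalize <- function(scan, span = 0.3) {
  stopifnot(all(c("probe_id", "sample_intensity", "reference_intensity")
                %in% names(scan)))
  ok <- scan$sample_intensity > 0 & scan$reference_intensity > 0 &
    is.finite(scan$sample_intensity) & is.finite(scan$reference_intensity)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.5 * nrow(scan)) {
    stop("more than 50% of probes (", n_dropped, "/", nrow(scan),
         ") have non-positive intensities")
  }
  s <- scan[ok, , drop = FALSE]
  M <- log2(s$sample_intensity / s$reference_intensity)
  A <- 0.5 * log2(s$sample_intensity * s$reference_intensity)
  if (stats::var(A) == 0) {
    # degenerate A-range: the trend is just the mean
    fit_at <- rep(mean(M), length(M))
  } else {
    lo <- stats::lowess(A, M, f = span)
    fit_at <- stats::approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
  }
  out <- data.frame(probe_id = s$probe_id, A = A, M = M - fit_at,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "step") <- attr(scan, "step")
  attr(out, "arm") <- attr(scan, "arm")
  out
}

#' Summarize normalized scans into per-gene enrichment profiles
#'
#' Maps probes to genes and takes the median normalized log2 ratio of a
#' gene's probes at each challenge step, separately per arm. Genes with no
#' probe in the map are omitted (their count is recorded).
#'
#' @param normalized list of normalized scans as returned by
#'   [lowess_normalize()] (each carrying `step` and `arm` attributes).
#' @param probe_map data.frame `probe_id`, `gene_id`; every probe maps to
#'   at most one gene.
#' @param schedule data.frame with a `step` column; a scan step not in the
#'   schedule is an error.
#' @return object of class `enrichment_profiles`: list of gene x step
#'   matrices, one per arm, plus `steps` and `n_unmapped_probes`.
#' @export
gene_profiles <- function(normalized, probe_map, schedule = default_schedule()) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id))
    stop("a probe maps to more than one gene")
  steps <- schedule$step
  arms <- unique(vapply(normalized, function(x) attr(x, "arm"), ""))
  n_unmapped <- 0L
  out <- list()
  for (arm in arms) {
    mats <- list()
    for (x in normalized) {
      if (!identical(attr(x, "arm"), arm)) next
      step <- attr(x, "step")
      if (!step %in% steps)
        stop("scan step '", step, "' is not in the schedule")
      gid <- probe_map$gene_id[match(x$probe_id, probe_map$probe_id)]
      n_unmapped <- n_unmapped + sum(is.na(gid))
      keep <- !is.na(gid)
      med <- tapply(x$M[keep], gid[keep], stats::median)
      mats[[step]] <- med
    }
    genes <- sort(unique(unlist(lapply(mats, names))))
    m <- matrix(NA_real_, length(genes), length(steps),
                dimnames = list(genes, steps))
    for (step in names(mats)) m[names(mats[[step]]), step] <- mats[[step]]
    out[[arm]] <- m
  }
  structure(list(profiles = out, steps = steps,
                 n_unmapped_probes = n_unmapped),
            class = "enrichment_profiles")
}

#' Call significantly enriched and depleted genes
#'
#' One-sample two-sided Student's t-test of each gene's step values against
#' mean zero; a gene is called significant when `p < alpha`, with direction
#' given by the sign of its mean log2 ratio. Genes whose step values have
#' zero variance get `p = 0` (flagged degenerate) when the mean is nonzero
#' and `p = 1` when it is zero.
#'
#' @param profiles a gene x step matrix of normalized log2 ratios (one arm
#'   of an `enrichment_profiles`), with >= 2 steps.
#' @param alpha significance level on the (optionally corrected) p-value.
#' @param correction `"none"` (the default; raw p < alpha) or `"BH"` for
#'   Benjamini-Hochberg across genes.
#' @return data.frame of class `differential_calls`: `gene_id`, `direction`
#'   (`enriched`/`depleted`), `mean_log2`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
detect_differential <- function(profiles, alpha = 0.05,
                                correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (inherits(profiles, "enrichment_profiles"))
    stop("pass one arm's matrix, e.g. profiles$profiles$butanol")
  if (ncol(profiles) < 2) stop("need >= 2 steps per profile")
  n <- ncol(profiles)
  mu <- rowMeans(profiles)
  sdv <- apply(profiles, 1, stats::sd)
  tstat <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degenerate <- sdv == 0
  p[degenerate & mu != 0] <- 0
  p[degenerate & mu == 0] <- 1
  if (correction == "BH") p_use <- stats::p.adjust(p, "BH") else p_use <- p
  out <- data.frame(gene_id = rownames(profiles),
                    direction = ifelse(mu > 0, "enriched", "depleted"),
                    mean_log2 = mu,
                    p_value = p,
                    significant = p_use < alpha,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  out
}

#' Subtract control-arm hits from butanol-arm calls
#'
#' Removes from the candidate set any gene whose (gene, direction) pair is
#' also significant in the solvent-free control arm: those reflect a general
#' growth advantage under serial transfer, not solvent tolerance. Returns
#' the butanol calls with a `passed_control_filter` flag; candidates are
#' rows that are significant and pass the filter.
#'
#' @param butanol_calls,control_calls `differential_calls` from the two arms.
#' @return `butanol_calls` with an added logical `passed_control_filter`.
#' @export
filter_control <- function(butanol_calls, control_calls) {
  sig_ctrl <- control_calls[control_calls$significant, , drop = FALSE]
  key_b <- paste(butanol_calls$gene_id, butanol_calls$direction)
  key_c <- paste(sig_ctrl$gene_id, sig_ctrl$direction)
  butanol_calls$passed_control_filter <- !(key_b %in% key_c)
  butanol_calls
}

#' Extract the candidate genes from filtered calls
#'
#' @param calls output of [filter_control()].
#' @param direction `"enriched"` or `"depleted"`.
#' @return character vector of gene ids.
#' @export
candidate_genes <- function(calls, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  ok <- calls$significant & calls$direction == direction
  if (!is.null(calls$passed_control_filter))
    ok <- ok & calls$passed_control_filter
  calls$gene_id[ok]
}
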