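# Synthetic screen generator: genome, clone library, serial-enrichment array
# scans and plate-reader growth curves, all with recorded ground truth.

#' Build a synthetic annotated genome
#'
#' Places `n_genes` non-overlapping genes uniformly on a linear genome and
#' assigns each gene 1--5 terms from a synthetic ontology with parent edges
#' (a random forest over the term set, so ancestor propagation can be
#' exercised).
#'
#' Coordinates are 0-based, half-open `[start, end)`.
#'
#' @param n_genes number of genes to place.
#' @param mean_gene_length mean gene length in bp (lengths are gamma
#'   distributed around this, floored at 50 bp).
#' @param genome_length genome length in bp.
#' @param n_go_terms number of terms in the synthetic ontology.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `genome_annotation`: a list with
#'   `genome_length`, `genes` (data.frame `gene_id`, `start`, `end`,
#'   `strand`), `gene2go` (data.frame `gene_id`, `term`) and `term_parents`
#'   (data.frame `term`, `parent`).
#' @export
build_genome <- function(n_genes, mean_gene_length = 1000, genome_length,
                         n_go_terms = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 0, genome_length > 0)
  if (n_genes == 0) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    gene2go <- data.frame(gene_id = character(), term = character(),
                          stringsAsFactors = FALSE)
    return(structure(list(genome_length = genome_length, genes = genes,
                          gene2go = gene2go,
                          term_parents = .synthetic_ontology(n_go_terms)),
                     class = "genome_annotation"))
  }
  lens <- pmax(50L, as.integer(round(
    stats::rgamma(n_genes, shape = 10, rate = 10 / mean_gene_length))))
  if (sum(as.numeric(lens)) > genome_length) {
    stop("cannot place ", n_genes, " genes of total length ", sum(lens),
         " bp on a ", genome_length, " bp genome (non-overlap constraint)")
  }
  free <- genome_length - sum(as.numeric(lens))
  # spread the free space over n_genes + 1 inter-gene gaps
  gaps <- as.vector(stats::rmultinom(1, free, rep(1, n_genes + 1)))
  starts <- cumsum(c(gaps[seq_len(n_genes)])) + c(0, cumsum(as.numeric(lens)))[seq_len(n_genes)]
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  ontology <- .synthetic_ontology(n_go_terms)
  n_terms_per_gene <- sample(1:5, n_genes, replace = TRUE)
  gene2go <- data.frame(
    gene_id = rep(genes$gene_id, n_terms_per_gene),
    term = unlist(lapply(n_terms_per_gene, function(k)
      sample(ontology$all_terms, k))),
    stringsAsFactors = FALSE)
  structure(list(genome_length = genome_length, genes = genes,
                 gene2go = gene2go, term_parents = ontology$parents),
            class = "genome_annotation")
}

# Random forest over GO-like term ids: every term after the first gets a
# parent with a smaller index, so the parent relation is acyclic.
.synthetic_ontology <- function(n_terms) {
  if (n_terms < 1) {
    return(list(all_terms = character(),
                parents = data.frame(term = character(), parent = character(),
                                     stringsAsFactors = FALSE)))
  }
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  if (n_terms == 1) {
    parents <- data.frame(term = character(), parent = character(),
                          stringsAsFactors = FALSE)
  } else {
    child <- terms[-1]
    parent <- terms[vapply(2:n_terms, function(i) sample.int(i - 1L, 1L), 1L)]
    parents <- data.frame(term = child, parent = parent,
                          stringsAsFactors = FALSE)
  }
  list(all_terms = terms, parents = parents)
}

#' Simulate a random-fragment clone library
#'
#' Draws `n_clones` inserts with lengths uniform over `insert_range`
#' (2000--3000 bp by default) and start positions uniform over the genome.
#' The reported fold-coverage is the exact sum of insert lengths divided by
#' the genome length.
#'
#' @param genome a `genome_annotation` (or a bare genome length in bp).
#' @param n_clones number of clones (colonies recovered).
#' @param insert_range length-2 vector, min and max insert length in bp.
#' @param seed integer seed.
#' @return an object of class `clone_library`: list with `clones`
#'   (data.frame `clone_id`, `start`, `end`), `insert_range` and `coverage`
#'   (fold).
#' @export
simulate_library <- function(genome, n_clones = 14000,
                             insert_range = c(2000, 3000), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_length <- if (inherits(genome, "genome_annotation"))
    genome$genome_length else as.numeric(genome)
  if (n_clones <= 0) stop("n_clones must be positive")
  if (insert_range[1] <= 0 || insert_range[2] > genome_length ||
      insert_range[1] > insert_range[2])
    stop("insert_range must lie within (0, genome_length] with min <= max")
  lens <- if (insert_range[1] == insert_range[2]) {
    rep(insert_range[1], n_clones)
  } else {
    sample(seq(insert_range[1], insert_range[2]), n_clones, replace = TRUE)
  }
  starts <- floor(stats::runif(n_clones, 0, genome_length - lens + 1))
  clones <- data.frame(
    clone_id = sprintf("c%05d", seq_len(n_clones)),
    start = as.integer(starts),
    end = as.integer(starts + lens),
    stringsAsFactors = FALSE)
  structure(list(clones = clones, insert_range = insert_range,
                 coverage = sum(as.numeric(lens)) / genome_length),
            class = "clone_library")
}

#' Default serial-transfer challenge schedule
#'
#' Four batch serial transfers at increasing n-butanol concentrations
#' (0.5, 0.9, 1.3, 1.7 % v/v) in the challenge arm, with a matched
#' solvent-free control arm.
#'
#' @return data.frame with `step`, `butanol` (% v/v in the challenge arm).
#' @export
default_schedule <- function() {
  data.frame(step = paste0("S", 1:4),
             butanol = c(0.5, 0.9, 1.3, 1.7),
             stringsAsFactors = FALSE)
}

#' Draw per-clone selection coefficients (ground truth)
#'
#' A fraction of clones carries a positive (or negative) selection
#' coefficient in the butanol arm; control-arm coefficients are drawn
#' independently (all zero by default, i.e. no general growth advantage).
#'
#' @param library a `clone_library`.
#' @param n_positive,n_negative number of clones under positive / negative
#'   selection in the butanol arm.
#' @param s_positive,s_negative selection coefficients (per transfer, on the
#'   natural-log scale) assigned to those clones.
#' @param control_sd sd of control-arm coefficients (0 = strict neutrality).
#' @param seed integer seed (recorded in the returned object).
#' @return object of class `screen_truth`: data.frame `clone_id`,
#'   `s_butanol`, `s_control` with attributes `seed`,
#'   `positive_clones`, `negative_clones`.
#' @export
screen_truth <- function(library, n_positive = 0, n_negative = 0,
                         s_positive = 1.0, s_negative = -1.0,
                         control_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- library$clones$clone_id
  n <- length(ids)
  stopifnot(n_positive + n_negative <= n)
  s_b <- rep(0, n)
  pick <- sample.int(n, n_positive + n_negative)
  pos <- pick[seq_len(n_positive)]
  neg <- pick[n_positive + seq_len(n_negative)]
  s_b[pos] <- s_positive
  s_b[neg] <- s_negative
  s_c <- if (control_sd > 0) stats::rnorm(n, 0, control_sd) else rep(0, n)
  out <- data.frame(clone_id = ids, s_butanol = s_b, s_control = s_c,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "positive_clones") <- ids[pos]
  attr(out, "negative_clones") <- ids[neg]
  class(out) <- c("screen_truth", "data.frame")
  out
}

# clone -> gene incidence: which clones overlap which genes
.clone_gene_hits <- function(library, genome) {
  g <- genome$genes
  cl <- library$clones
  if (nrow(g) == 0 || nrow(cl) == 0)
    return(data.frame(gene = integer(), clone = integer()))
  # 0-based half-open -> 1-based closed for IRanges
  gr <- IRanges::IRanges(start = g$start + 1L, end = g$end)
  cr <- IRanges::IRanges(start = cl$start + 1L, end = cl$end)
  hits <- IRanges::findOverlaps(gr, cr)
  data.frame(gene = S4Vectors::queryHits(hits),
             clone = S4Vectors::subjectHits(hits))
}

#' Simulate serial-enrichment array scans
#'
#' Clone abundances start uniform and are updated multiplicatively at each
#' transfer, `a_i <- a_i * exp(s_i)`, then renormalized to sum to one. The
#' per-gene "sample" signal at a step is the summed abundance of the clones
#' covering the gene; the "reference" channel is the unchallenged starting
#' library. Probe intensities are the gene signals scaled by a per-probe
#' affinity (log2-uniform across probes, giving the scans a realistic
#' mean-intensity range), optionally distorted by a smooth cubic
#' intensity-dependent dye bias, plus Gaussian noise on the log2 scale.
#'
#' @param library a `clone_library`.
#' @param genome a `genome_annotation`.
#' @param truth a `screen_truth` with one row per clone.
#' @param schedule data.frame with a `step` column (see
#'   [default_schedule()]); both arms run the same number of transfers.
#' @param noise_sd sd of Gaussian noise added to log2 ratios (per probe per
#'   scan). Must be >= 0.
#' @param dye_bias `TRUE` for the default cubic bias, `FALSE`/`NULL` for
#'   none, or a numeric length-3 vector of cubic coefficients applied to the
#'   centered mean log2 intensity A: `c[1]*x + c[2]*x^2 + c[3]*x^3`.
#' @param probes_per_gene probes spotted per gene.
#' @param seed integer seed.
#' @return object of class `enrichment_sim`: list with `scans` (a list of
#'   `array_scan` data.frames of `probe_id`, `sample_intensity`,
#'   `reference_intensity`, each with attributes `step` and `arm`),
#'   `probe_map` (data.frame `probe_id`, `gene_id`), `truth_log2` (gene x
#'   step matrix of noise-free log2 ratios per arm) and `schedule`.
#' @export
simulate_enrichment <- function(library, genome, truth, schedule = default_schedule(),
                                noise_sd = 0.1, dye_bias = TRUE,
                                probes_per_gene = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(nrow(truth) == nrow(library$clones))
  bias_coef <- .dye_bias_coef(dye_bias)

  hits <- .clone_gene_hits(library, genome)
  n_genes <- nrow(genome$genes)
  n_clones <- nrow(library$clones)
  gene_ids <- genome$genes$gene_id
  steps <- schedule$step
  n_steps <- length(steps)

  gene_signal <- function(a) {
    s <- numeric(n_genes)
    if (nrow(hits)) {
      agg <- rowsum(a[hits$clone], hits$gene)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    s
  }

  a0 <- rep(1 / n_clones, n_clones)
  ref_sig <- gene_signal(a0)
  covered <- ref_sig > 0

  # abundance trajectories per arm
  traj <- list()
  for (arm in c("butanol", "control")) {
    s <- if (arm == "butanol") truth$s_butanol else truth$s_control
    a <- a0
    m <- matrix(0, n_genes, n_steps, dimnames = list(gene_ids, steps))
    for (k in seq_len(n_steps)) {
      a <- a * exp(s)
      a <- a / sum(a)
      m[, k] <- gene_signal(a)
    }
    traj[[arm]] <- m
  }

  truth_log2 <- lapply(traj, function(m) {
    out <- matrix(NA_real_, n_genes, n_steps, dimnames = dimnames(m))
    out[covered, ] <- log2(m[covered, , drop = FALSE] / ref_sig[covered])
    out
  })

  # probe layout: per-probe affinity on log2 scale, range typical of scans
  probe_map <- data.frame(
    probe_id = if (probes_per_gene == 1) gene_ids else
      paste0(rep(gene_ids, each = probes_per_gene), "_p",
             rep(seq_len(probes_per_gene), n_genes)),
    gene_id = rep(gene_ids, each = probes_per_gene),
    stringsAsFactors = FALSE)
  affinity <- stats::runif(nrow(probe_map), 6, 14)
  gidx <- match(probe_map$gene_id, gene_ids)

  scans <- list()
  for (arm in c("butanol", "control")) {
    for (k in seq_len(n_steps)) {
      m_true <- truth_log2[[arm]][gidx, k]
      r_int <- 2^affinity * ref_sig[gidx] / mean(ref_sig[covered])
      s0 <- r_int * 2^ifelse(is.na(m_true), 0, m_true)
      a_val <- 0.5 * (log2(pmax(s0, .Machine$double.xmin)) +
                      log2(pmax(r_int, .Machine$double.xmin)))
      b <- if (is.null(bias_coef)) 0 else {
        x <- a_val - mean(a_val[is.finite(a_val)])
        bias_coef[1] * x + bias_coef[2] * x^2 + bias_coef[3] * x^3
      }
      eps <- if (noise_sd > 0) stats::rnorm(length(s0), 0, noise_sd) else 0
      scan <- data.frame(probe_id = probe_map$probe_id,
                         sample_intensity = s0 * 2^(b + eps),
                         reference_intensity = r_int,
                         stringsAsFactors = FALSE)
      attr(scan, "step") <- steps[k]
      attr(scan, "arm") <- arm
      class(scan) <- c("array_scan", "data.frame")
      scans[[paste(arm, steps[k], sep = ".")]] <- scan
    }
  }
  structure(list(scans = scans, probe_map = probe_map,
                 truth_log2 = truth_log2, schedule = schedule,
                 covered = stats::setNames(covered, gene_ids)),
            class = "enrichment_sim")
}

.dye_bias_coef <- function(dye_bias) {
  if (isTRUE(dye_bias)) return(c(0.2, -0.008, 0.003))
  if (is.numeric(dye_bias) && length(dye_bias) == 3) return(dye_bias)
  NULL
}

#' Simulate a lagged logistic growth curve
#'
#' OD stays at `od0` during the lag, then follows the logistic
#' `OD(t) = K*od0*exp(mu*(t-lag)) / (K - od0 + od0*exp(mu*(t-lag)))`.
#' Additive Gaussian noise (sd `noise_sd`, in OD units) is truncated at 0.
#'
#' @param mu_max maximum specific growth rate, 1/h (>= 0).
#' @param lag lag time in hours.
#' @param carrying_capacity plateau OD (`K`); must exceed `od0`.
#' @param od0 inoculation OD.
#' @param times sampling times in hours (non-empty, increasing).
#' @param noise_sd additive OD noise sd.
#' @param strain_id,condition,replicate metadata carried in the result.
#' @param seed integer seed (optional; inherits the RNG state if NULL).
#' @return object of class `growth_curve`: data.frame `time_h`, `od600`,
#'   with `strain_id`, `condition`, `replicate` attributes.
#' @export
simulate_growth <- function(mu_max, lag = 2, carrying_capacity = 2,
                            od0 = 0.02, times = seq(0, 24, by = 0.25),
                            noise_sd = 0.005, strain_id = "strain",
                            condition = 0, replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mu_max < 0) stop("mu_max must be non-negative")
  if (length(times) == 0) stop("times must be non-empty")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (carrying_capacity <= od0) stop("carrying capacity K must exceed od0")
  t2 <- pmax(times - lag, 0)
  K <- carrying_capacity
  e <- exp(mu_max * t2)
  od <- K * od0 * e / (K - od0 + od0 * e)
  if (noise_sd > 0) od <- pmax(od + stats::rnorm(length(od), 0, noise_sd), 0)
  out <- data.frame(time_h = times, od600 = od)
  attr(out, "strain_id") <- strain_id
  attr(out, "condition") <- condition
  attr(out, "replicate") <- replicate
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Simulate a replicated plate-reader experiment
#'
#' Generates `n_replicates` growth curves for each row of a strain x
#' condition design table and returns them in long format, the layout a
#' plate reader export is reshaped into.
#'
#' @param design data.frame with columns `strain_id`, `condition` (% v/v
#'   n-butanol) and `mu_max` (true rate, 1/h).
#' @param n_replicates biological replicates per design row (default 4).
#' @param ... passed to [simulate_growth()] (lag, carrying_capacity, od0,
#'   times, noise_sd).
#' @param seed integer seed.
#' @return long data.frame: `strain_id`, `condition`, `replicate`,
#'   `time_h`, `od600`.
#' @export
simulate_growth_set <- function(design, n_replicates = 4, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("strain_id", "condition", "mu_max") %in% names(design)))
  out <- vector("list", nrow(design) * n_replicates)
  idx <- 1
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(n_replicates)) {
      cv <- simulate_growth(design$mu_max[i], ...,
                            strain_id = design$strain_id[i],
                            condition = design$condition[i], replicate = r)
      out[[idx]] <- data.frame(strain_id = design$strain_id[i],
                               condition = design$condition[i],
                               replicate = r,
                               time_h = cv$time_h, od600 = cv$od600,
                               stringsAsFactors = FALSE)
      idx <- idx + 1
    }
  }
  do.call(rbind, out)
}
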