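# End-to-end orchestration of the screen on synthetic data: generate ->
# normalize -> call candidates -> cluster -> GO-enrich -> kinetics screen ->
# consolidated report.

#' Build a screen configuration
#'
#' All knobs of a synthetic end-to-end run, with the study's defaults:
#' a serially challenged clone library read out by two-channel arrays at
#' four increasing n-butanol steps plus a solvent-free control arm, and a
#' 4-replicate growth-kinetics screen of the surviving candidates.
#'
#' @param n_genes,genome_length,mean_gene_length,n_go_terms genome
#'   generator settings.
#' @param n_clones,insert_range library generator settings.
#' @param n_positive,n_negative,s_positive,s_negative true selection
#'   structure (clones under selection in the butanol arm).
#' @param noise_sd array log2 noise sd; `dye_bias` as in
#'   [simulate_enrichment()].
#' @param probes_per_gene probes spotted per gene.
#' @param alpha_cgh,cgh_correction differential-calling settings.
#' @param cast_threshold CAST affinity threshold.
#' @param go_correction multiple-testing correction for GO enrichment.
#' @param kinetics_true_iie true IIE (percent) given to genes covered by
#'   positively selected clones in the growth-kinetics stage (0 = null).
#' @param kinetics_noise_sd OD noise sd in the kinetics stage.
#' @param alpha_kinetics significance level for the replicate t-test.
#' @param max_kinetics_genes cap on candidates sent to the kinetics stage.
#' @param seed global seed; every stage derives from it.
#' @return named list of class `screen_config`.
#' @export
screen_config <- function(n_genes = 300, genome_length = 600000,
                          mean_gene_length = 1000, n_go_terms = 40,
                          n_clones = 2000, insert_range = c(2000, 3000),
                          n_positive = 12, n_negative = 0,
                          s_positive = 2.0, s_negative = -1.0,
                          noise_sd = 0.1, dye_bias = TRUE,
                          probes_per_gene = 1,
                          alpha_cgh = 0.05, cgh_correction = "none",
                          cast_threshold = 0.8, go_correction = "BH",
                          kinetics_true_iie = 49.1,
                          kinetics_noise_sd = 0.005,
                          alpha_kinetics = 0.05,
                          max_kinetics_genes = 20,
                          seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- c("screen_config", "list")
  cfg
}

#' Run the full synthetic screen
#'
#' Executes every stage in order under one seed: genome and library
#' generation, serial-enrichment simulation, LOWESS normalization,
#' per-gene profiling, differential calling in both arms, control-arm
#' subtraction, CAST clustering of enriched candidates, GO enrichment
#' against the gene universe, and a 4-replicate growth-kinetics screen of
#' the candidates (genes truly under positive selection carry the
#' configured true IIE; all others are null). Rerunning with the same
#' config reproduces identical tables.
#'
#' @param config a `screen_config` (or plain list from
#'   [read_config_yaml()]).
#' @param out_dir optional directory; when given, all result tables are
#'   written as TSV with provenance headers.
#' @return object of class `screen_report`: list with `calls_butanol`,
#'   `calls_control`, `candidates` (enriched/depleted gene vectors),
#'   `clusters`, `go`, `tolerance`, `truth` (true positive gene set),
#'   `counts` and `provenance`.
#' @export
run_screen <- function(config = screen_config(), out_dir = NULL) {
  cfg <- config
  if (!inherits(cfg, "screen_config")) cfg <- do.call(screen_config, cfg)
  set.seed(cfg$seed)

  genome <- build_genome(cfg$n_genes, cfg$mean_gene_length,
                         cfg$genome_length, cfg$n_go_terms)
  library_ <- simulate_library(genome, cfg$n_clones, cfg$insert_range)
  truth <- screen_truth(library_, n_positive = cfg$n_positive,
                        n_negative = cfg$n_negative,
                        s_positive = cfg$s_positive,
                        s_negative = cfg$s_negative)
  sim <- simulate_enrichment(library_, genome, truth,
                             noise_sd = cfg$noise_sd,
                             dye_bias = cfg$dye_bias,
                             probes_per_gene = cfg$probes_per_gene)

  normalized <- lapply(sim$scans, lowess_normalize)
  profiles <- gene_profiles(normalized, sim$probe_map, sim$schedule)
  calls_b <- detect_differential(profiles$profiles$butanol,
                                 alpha = cfg$alpha_cgh,
                                 correction = cfg$cgh_correction)
  calls_c <- detect_differential(profiles$profiles$control,
                                 alpha = cfg$alpha_cgh,
                                 correction = cfg$cgh_correction)
  calls_b <- filter_control(calls_b, calls_c)
  enriched <- candidate_genes(calls_b, "enriched")
  depleted <- candidate_genes(calls_b, "depleted")

  clusters <- NULL
  if (length(enriched) >= 2) {
    prof_e <- profiles$profiles$butanol[enriched, , drop = FALSE]
    aff <- profile_similarity(prof_e)
    clusters <- cast_cluster(aff, t = cfg$cast_threshold)
  }

  go_res <- NULL
  if (length(enriched) >= 1) {
    go_res <- go_enrich(enriched, genome$genes$gene_id, genome$gene2go,
                        genome$term_parents,
                        correction = cfg$go_correction)
  }

  # ground truth at gene level: genes covered by a positively selected clone
  hits <- .clone_gene_hits(library_, genome)
  pos_clones <- match(attr(truth, "positive_clones"), library_$clones$clone_id)
  true_pos <- sort(unique(genome$genes$gene_id[
    hits$gene[hits$clone %in% pos_clones]]))

  kin_genes <- utils::head(enriched, cfg$max_kinetics_genes)
  tolerance <- NULL
  if (length(kin_genes) >= 1) {
    tol <- lapply(kin_genes, function(g) {
      true_iie <- if (g %in% true_pos) cfg$kinetics_true_iie else 0
      ratio_clone <- 0.5 * (1 + true_iie / 100)
      res <- simulate_tolerance_screen(
        true_ratio_clone = ratio_clone,
        noise_sd = cfg$kinetics_noise_sd,
        alpha = cfg$alpha_kinetics)
      res$gene_id <- g
      res
    })
    tolerance <- do.call(rbind, tol)
  }

  counts <- c(genes = cfg$n_genes,
              called_enriched = sum(calls_b$significant &
                                      calls_b$direction == "enriched"),
              called_depleted = sum(calls_b$significant &
                                      calls_b$direction == "depleted"),
              candidates_enriched = length(enriched),
              candidates_depleted = length(depleted),
              clusters = if (is.null(clusters)) 0L
                         else length(unique(clusters$cluster)),
              kinetics_significant = if (is.null(tolerance)) 0L
                                     else sum(tolerance$significant))
  provenance <- c(seed = as.character(cfg$seed),
                  config_hash = .config_hash(unclass(cfg)),
                  package = as.character(utils::packageVersion("butolscreen")))
  report <- structure(list(calls_butanol = calls_b, calls_control = calls_c,
                           candidates = list(enriched = enriched,
                                             depleted = depleted),
                           clusters = clusters, go = go_res,
                           tolerance = tolerance,
                           truth = list(positive_genes = true_pos),
                           counts = counts, provenance = provenance),
                      class = "screen_report")
  if (!is.null(out_dir)) .write_report(report, out_dir, provenance)
  report
}

.write_report <- function(report, out_dir, provenance) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_screen_tsv(report$calls_butanol,
                   file.path(out_dir, "calls_butanol.tsv"), provenance)
  write_screen_tsv(report$calls_control,
                   file.path(out_dir, "calls_control.tsv"), provenance)
  if (!is.null(report$clusters))
    write_screen_tsv(report$clusters,
                     file.path(out_dir, "clusters.tsv"), provenance)
  if (!is.null(report$go))
    write_screen_tsv(report$go, file.path(out_dir, "go_enrichment.tsv"),
                     provenance)
  if (!is.null(report$tolerance))
    write_screen_tsv(report$tolerance,
                     file.path(out_dir, "tolerance.tsv"), provenance)
  invisible(out_dir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Genomic library enrichment screen (synthetic run)\n")
  cat(sprintf("  seed %s, config %s\n", x$provenance["seed"],
              x$provenance["config_hash"]))
  cat(sprintf("  genes: %s | enriched candidates: %s | depleted: %s\n",
              x$counts["genes"], x$counts["candidates_enriched"],
              x$counts["candidates_depleted"]))
  cat(sprintf("  clusters: %s | kinetics-significant genes: %s\n",
              x$counts["clusters"], x$counts["kinetics_significant"]))
  invisible(x)
}

#' Validate screen input tables
#'
#' Schema and consistency checks on user-supplied inputs: scan columns and
#' positive intensities, probe-id uniqueness, step labels against the
#' schedule, growth-table columns, strictly increasing times, and the
#' 4-replicate design (fewer replicates is a warning, not an error).
#'
#' @param scans named list of scan data.frames (each with `step`/`arm`
#'   attributes), or NULL.
#' @param growth long growth data.frame, or NULL.
#' @param schedule challenge schedule (see [default_schedule()]).
#' @param n_replicates_expected expected biological replicates (default 4).
#' @return data.frame `severity` (`error`/`warning`), `where`, `message`;
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(scans = NULL, growth = NULL,
                            schedule = default_schedule(),
                            n_replicates_expected = 4) {
  issues <- list()
  add <- function(severity, where, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.null(scans)) {
    for (nm in names(scans)) {
      sc <- scans[[nm]]
      need <- c("probe_id", "sample_intensity", "reference_intensity")
      if (!all(need %in% names(sc))) {
        add("error", nm, paste("missing columns:",
                               paste(setdiff(need, names(sc)), collapse = ", ")))
        next
      }
      if (anyDuplicated(sc$probe_id))
        add("error", nm, "duplicated probe_id within scan")
      if (any(sc$sample_intensity <= 0 | sc$reference_intensity <= 0))
        add("warning", nm, "non-positive intensities present (will be dropped)")
      step <- attr(sc, "step")
      if (!is.null(step) && !step %in% schedule$step)
        add("error", nm, paste0("unknown step label '", step, "'"))
    }
  }
  if (!is.null(growth)) {
    need <- c("strain_id", "condition", "replicate", "time_h", "od600")
    if (!all(need %in% names(growth))) {
      add("error", "growth", paste("missing columns:",
                                   paste(setdiff(need, names(growth)),
                                         collapse = ", ")))
    } else {
      if (any(growth$od600 < 0))
        add("error", "growth", "negative OD600 readings")
      by_curve <- split(growth$time_h,
                        paste(growth$strain_id, growth$condition,
                              growth$replicate))
      if (any(vapply(by_curve, function(t) any(diff(t) <= 0), TRUE)))
        add("error", "growth", "times not strictly increasing within a curve")
      reps <- stats::aggregate(replicate ~ strain_id + condition, growth,
                               function(r) length(unique(r)))
      short <- reps[reps$replicate < n_replicates_expected, , drop = FALSE]
      for (i in seq_len(nrow(short)))
        add("warning", "growth",
            sprintf("%s at %s%% has %d replicates; the screen design uses %d",
                    short$strain_id[i], short$condition[i],
                    short$replicate[i], n_replicates_expected))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
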