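# Tab-separated readers/writers for the screen's interchange formats, plus
# the YAML scenario/config reader. All writers prepend '#'-comment headers
# carrying provenance (seed, config hash) so outputs are self-describing.

#' Write a table as TSV with provenance header comments
#'
#' @param x data.frame.
#' @param path output file.
#' @param provenance named character vector written as `# name: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_screen_tsv()] (comment lines ignored)
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_screen_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a two-channel array scan TSV
#'
#' Expected columns: `probe_id`, `sample_intensity`, `reference_intensity`.
#'
#' @param path file path.
#' @param step,arm challenge-step label and arm attached as attributes.
#' @return an `array_scan` data.frame.
#' @export
read_scan_tsv <- function(path, step = NULL, arm = NULL) {
  x <- read_screen_tsv(path)
  need <- c("probe_id", "sample_intensity", "reference_intensity")
  if (!all(need %in% names(x)))
    stop("scan file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  attr(x, "step") <- step
  attr(x, "arm") <- arm
  class(x) <- c("array_scan", "data.frame")
  x
}

#' Read a long-format plate-reader growth table
#'
#' Expected columns: `strain_id`, `condition`, `replicate`, `time_h`,
#' `od600`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_growth_tsv <- function(path) {
  x <- read_screen_tsv(path)
  need <- c("strain_id", "condition", "replicate", "time_h", "od600")
  if (!all(need %in% names(x)))
    stop("growth file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  x
}

#' Read a minimal gene annotation TSV
#'
#' Expected columns: `gene_id`, `start`, `end`, `strand` (0-based,
#' half-open coordinates).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  x <- read_screen_tsv(path)
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(x)))
    stop("annotation file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  x
}

#' Read a two-column gene-to-GO association TSV
#'
#' @param path file path.
#' @return data.frame `gene_id`, `term`.
#' @export
read_gene2go_tsv <- function(path) {
  x <- read_screen_tsv(path)
  if (!all(c("gene_id", "term") %in% names(x)))
    stop("association file ", path, " must have columns: gene_id, term")
  x
}

#' Read a YAML scenario / screen configuration
#'
#' @param path YAML file.
#' @return named list (see [screen_config()] for recognized fields).
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

# short stable hash of a config for provenance headers
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}
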