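# Architecture report: single entry point chaining segmentation, exon
# phasing/classification, motif scanning and solenoid bookkeeping.

#' Annotate the repeat architecture of a protein
#'
#' Runs the full pipeline on one protein: consensus-window segmentation into
#' tandem LRRs, type-alternation summary, exon phasing and typical/atypical
#' classification (when an exon table is supplied), motif scanning, and the
#' full-circles summary of the repeat run at the configured solenoid
#' geometry.  Re-running with identical inputs and configuration yields an
#' identical report.
#'
#' @param record A [protein_record()], or a path to a FASTA file (first
#'   record used).
#' @param exons An exon table ([read_exon_table()]), a path to one, or `NULL`.
#' @param patterns Consensus patterns (default [default_type_patterns()]).
#' @param motifs Motif definitions (default [nlrc5_motifs()]).
#' @param config An [lrr_config()].
#' @param geometry A [solenoid_params()] used for the full-circles summary.
#' @param region Optional `c(start, end)` segmentation restriction.
#' @param exon_range Optional `c(first, last)` exon-number restriction.
#' @return A list of class `lrr_report` with elements `id`, `length`,
#'   `molecular_weight_kda`, `repeats`, `n_fitting`, `n_segments`,
#'   `alternation`, `exon_report` (or `NULL`), `modal_phase` (or `NA`),
#'   `motif_hits`, `solenoid` (geometry echo plus `full_turns` over all
#'   repeat segments), `config`, `version`.
#' @export
annotate_architecture <- function(record, exons = NULL,
                                  patterns = default_type_patterns(),
                                  motifs = nlrc5_motifs(),
                                  config = lrr_config(),
                                  geometry = solenoid_params(),
                                  region = NULL, exon_range = NULL) {
  if (is.character(record)) record <- read_fasta(record)[[1L]]
  if (is.character(exons)) exons <- read_exon_table(exons)

  repeats <- segment_repeats(record, patterns, config, region)
  n_fit <- sum(repeats$fits_consensus)
  alternation <- if (n_fit >= 2L) check_alternation(repeats) else NA_real_

  exon_report <- NULL
  phase <- NA_integer_
  if (!is.null(exons)) {
    if (!is.null(exon_range))
      exons <- exons[exons$exon_number >= exon_range[1L] &
                       exons$exon_number <= exon_range[2L], , drop = FALSE]
    phased <- suppressWarnings(phase_exons(exons, repeats = repeats))
    phase <- modal_phase(phased)
    cls <- classify_exon_repeats(record, exons, patterns, config,
                                 phase = if (is.na(phase)) config$exon_phase
                                         else phase)
    cls$exons$phase <- phased$phase
    exon_report <- cls
  }

  hits <- scan_motifs(record, motifs)

  structure(list(
    id = record$id,
    length = residue_count(record),
    molecular_weight_kda = molecular_weight(record),
    repeats = repeats,
    n_fitting = n_fit,
    n_segments = nrow(repeats),
    alternation = alternation,
    exon_report = exon_report,
    modal_phase = phase,
    motif_hits = hits,
    solenoid = list(repeats_per_turn = geometry$repeats_per_turn,
                    rise_per_repeat = geometry$rise_per_repeat,
                    radius = geometry$radius,
                    full_turns = full_turns(nrow(repeats), geometry)),
    config = unclass(config),
    version = as.character(utils::packageVersion("lrrscan"))),
    class = "lrr_report")
}

#' @export
print.lrr_report <- function(x, ...) {
  cat(sprintf("<lrr_report> %s: %d aa, %.1f kDa\n", x$id, x$length,
              x$molecular_weight_kda))
  cat(sprintf("  repeats: %d segments (%d consensus-fitting), alternation %.2f\n",
              x$n_segments, x$n_fitting,
              if (is.na(x$alternation)) NaN else x$alternation))
  if (!is.null(x$exon_report))
    cat(sprintf("  exons: %d analyzed, %d typical, atypical {%s}, modal phase %s\n",
                x$exon_report$analyzed, x$exon_report$typical_count,
                paste(x$exon_report$atypical_exons, collapse = ","),
                x$modal_phase))
  cat(sprintf("  motifs: %d hits; solenoid: %.2f full turns at %.1f repeats/turn\n",
              nrow(x$motif_hits), x$solenoid$full_turns,
              x$solenoid$repeats_per_turn))
  invisible(x)
}

#' Serialize an architecture report to JSON
#'
#' The JSON is schema-stable and contains no timestamp, so identical inputs
#' produce byte-identical files.
#'
#' @param report An [annotate_architecture()] result.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The path (invisibly), or the JSON string when `path` is `NULL`.
#' @export
write_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  if (!is.null(x$exon_report)) x$exon_report <- unclass(x$exon_report)
  if (!is.null(x$repeats)) x$repeats <- as.data.frame(x$repeats)
  json <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
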