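# Exon phaser: map exon boundaries onto repeat-consensus coordinates and
# classify exon-encoded repeats as typical or atypical.

#' Compute the consensus phase of each exon
#'
#' The phase of an exon is the 1-based consensus column at which its first
#' encoded residue falls.  When segmenter output is supplied, the phase is
#' computed within the consensus-fitting repeat that contains the exon start
#' (`exon_start - repeat_start + 1`); exons that do not start inside a
#' fitting repeat get phase `NA` with a warning.  Alternatively a scalar
#' `anchor` (the residue position of consensus column 1 of any repeat) plus a
#' uniform `repeat_length` may be given, in which case
#' `phase = ((exon_start - anchor) mod repeat_length) + 1`.
#'
#' @param exons An exon table (see [read_exon_table()]).
#' @param repeats An `lrr_annotation` from [segment_repeats()], or `NULL`.
#' @param anchor Residue position of consensus column 1 (used when `repeats`
#'   is `NULL`).
#' @param repeat_length Repeat period for the modular-anchor mode.
#' @return The exon table with an added integer `phase` column; the modal
#'   phase over non-`NA` exons is attached as attribute `modal_phase`.
#' @export
phase_exons <- function(exons, repeats = NULL, anchor = NULL,
                        repeat_length = 28L) {
  stopifnot(!is.null(repeats) || !is.null(anchor))
  if (!is.null(repeats)) {
    fit <- repeats[repeats$fits_consensus, , drop = FALSE]
    phase <- vapply(exons$protein_start, function(s) {
      i <- which(fit$start <= s & fit$end >= s)
      if (length(i)) s - fit$start[i[1L]] + 1L else NA_integer_
    }, 1L)
    if (anyNA(phase))
      warning(sprintf("%d exon(s) start outside any consensus-fitting repeat; phase set to NA",
                      sum(is.na(phase))))
  } else {
    phase <- ((exons$protein_start - as.integer(anchor)) %%
                as.integer(repeat_length)) + 1L
  }
  exons$phase <- as.integer(phase)
  ph <- phase[!is.na(phase)]
  attr(exons, "modal_phase") <-
    if (length(ph)) as.integer(names(which.max(table(ph)))) else NA_integer_
  exons
}

#' Modal exon phase
#' @param phased_exons Result of [phase_exons()].
#' @return The most frequent non-`NA` phase.
#' @export
modal_phase <- function(phased_exons) attr(phased_exons, "modal_phase")

#' Classify exon-encoded repeats as typical or atypical
#'
#' Each analyzed exon is scored as a repeat candidate: it is *typical* when
#' its length matches a supplied pattern length (28 or 29 by default) and its
#' peptide scores at least `config$min_score` against that pattern rotated to
#' the exon reading frame (see [rotate_pattern()]); it is *atypical* when it
#' is too short/long or does not fit the consensus pattern (the disjunction
#' is reported per exon in the `reason` column).  The final exon is exempted
#' as the C-terminal capping repeat when its length falls within
#' `config$capping_range` (the capping repeat of the RI family is longer than
#' the internal repeats).
#'
#' @param record A [protein_record()].
#' @param exons An exon table; restrict with `exon_range` to analyze a
#'   sub-range of exon numbers (e.g. `c(7, 49)`).
#' @param patterns List of `consensus_pattern` objects.
#' @param config An [lrr_config()].
#' @param phase Consensus column at which exons start (default
#'   `config$exon_phase`); pass the modal phase from [phase_exons()] when it
#'   differs.
#' @param exon_range Optional `c(first, last)` exon numbers to analyze.
#' @return A list of class `exon_classification`:
#'   `exons` (data.frame with `exon_number`, span, `length_aa`, `score`,
#'   `best_type`, `typical`, `reason`), `typical_count`, `atypical_exons`
#'   (integer vector of exon numbers), `analyzed`.
#' @export
classify_exon_repeats <- function(record, exons,
                                  patterns = default_type_patterns(),
                                  config = lrr_config(),
                                  phase = config$exon_phase,
                                  exon_range = NULL) {
  if (!is.null(exon_range))
    exons <- exons[exons$exon_number >= exon_range[1L] &
                     exons$exon_number <= exon_range[2L], , drop = FALSE]
  n <- residue_count(record)
  if (nrow(exons) && max(exons$protein_end) > n)
    stop("exon span outside sequence", call. = FALSE)
  pat_len <- vapply(patterns, `[[`, 0L, "length")
  rotated <- lapply(patterns, rotate_pattern, phase = phase)

  score <- rep(NA_real_, nrow(exons))
  best_type <- rep(NA_character_, nrow(exons))
  typical <- logical(nrow(exons))
  reason <- character(nrow(exons))
  last_row <- which.max(exons$exon_number)
  for (i in seq_len(nrow(exons))) {
    len <- exons$length_aa[i]
    pep <- protein_record("exon", subseq_residues(record,
                                                  exons$protein_start[i],
                                                  exons$protein_end[i]))
    same_len <- which(pat_len == len)
    if (length(same_len)) {
      sc <- vapply(same_len, function(j) {
        w <- score_window(pep, 1L, rotated[[j]])
        if (w$hard_fail) -Inf else w$score
      }, 0)
      score[i] <- max(sc)
      best_type[i] <- patterns[[same_len[which.max(sc)]]]$name
      if (score[i] >= config$min_score) {
        typical[i] <- TRUE
        reason[i] <- "consensus"
      } else {
        reason[i] <- "low score"
      }
    } else if (i == last_row && len >= config$capping_range[1L] &&
               len <= config$capping_range[2L]) {
      typical[i] <- TRUE
      reason[i] <- "C-terminal capping"
    } else {
      reason[i] <- if (len < min(pat_len)) "too short" else "length"
    }
  }
  out <- exons
  out$score <- score
  out$best_type <- best_type
  out$typical <- typical
  out$reason <- reason
  structure(list(exons = out,
                 typical_count = sum(typical),
                 atypical_exons = out$exon_number[!typical],
                 analyzed = nrow(out)),
            class = "exon_classification")
}

#' @export
print.exon_classification <- function(x, ...) {
  cat(sprintf("<exon_classification> %d exons analyzed: %d typical, %d atypical (%s)\n",
              x$analyzed, x$typical_count, length(x$atypical_exons),
              paste(x$atypical_exons, collapse = ",")))
  invisible(x)
}
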