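#' lrrscan: leucine-rich repeat architecture annotation
#'
#' Detects ribonuclease-inhibitor-like leucine-rich repeats (LRRs) in protein
#' sequences by consensus-pattern scoring with two alternating repeat types,
#' segments tandem repeat runs by dynamic programming, maps exon boundaries
#' onto repeat-consensus coordinates, scans for NACHT functional motifs and
#' cysteine-spacing capping motifs, and builds coarse-grained C-alpha solenoid
#' traces.  A seeded synthetic generator with planted ground truth makes the
#' whole pipeline testable offline.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Residue chemistry tables
# ---------------------------------------------------------------------------

#' The 20 standard amino-acid one-letter codes
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average (isotope-weighted) residue masses in Da, i.e. the free amino-acid
# mass minus one water.  One water (18.01528 Da) is added back per chain.
.RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760)

.WATER_MASS <- 18.01528

# Swiss-Prot-like background residue frequencies; used by the synthetic
# generator for unconstrained positions so that composition (and hence
# molecular weight) of generated proteins matches natural proteins.
.BACKGROUND_FREQ <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  E = 0.0674, Q = 0.0393, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0966, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0109, Y = 0.0292)

#' Residue synonym classes used by consensus patterns
#'
#' Returns the table of residue classes that consensus-pattern class codes
#' resolve against: `L` aliphatic \{L, I, V\}, `S` hydroxyl \{S, T\},
#' `E` acid/amide \{E, D, Q, N\}, `R` basic \{R, K\}, `o` nonpolar,
#' `g` glycine, and the wildcard `X` (any residue).  Pattern characters that
#' are not class codes are taken as literal residues.
#'
#' @return A named list of character vectors, class `residue_class_table`.
#' @export
#' @examples
#' residue_class_table()$L
residue_class_table <- function() {
  structure(list(
    L = c("L", "I", "V"),
    S = c("S", "T"),
    E = c("E", "D", "Q", "N"),
    R = c("R", "K"),
    o = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W"),
    g = "G",
    X = AA_ALPHABET
  ), class = "residue_class_table")
}

# ---------------------------------------------------------------------------
# ProteinRecord
# ---------------------------------------------------------------------------

#' Create a protein record
#'
#' A `protein_record` is an identified amino-acid sequence with 1-based
#' residue numbering: position `n` addresses the `n`-th character of
#' `sequence`.
#'
#' @param id Accession-like identifier.
#' @param sequence Amino-acid sequence (one string); coerced to upper case.
#' @param description Free-text description.
#' @param allow_unknown Permit `X` (unknown residue) in the sequence.
#'   Defaults to `FALSE`: the downstream analysis is pattern-based and `X`
#'   breaks residue-class matching.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `description`.
#' @export
#' @examples
#' protein_record("x", "MKL")
protein_record <- function(id, sequence, description = "",
                           allow_unknown = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  validate_residues(sequence, id = id, allow_unknown = allow_unknown)
  structure(list(id = id, sequence = sequence,
                 description = as.character(description)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Number of residues in a protein record
#' @param record A [protein_record()].
#' @return Integer sequence length.
#' @export
residue_count <- function(record) nchar(record$sequence)

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

#' Extract a 1-based inclusive residue span
#' @param record A [protein_record()].
#' @param start,end 1-based inclusive residue positions.
#' @return The sub-sequence string.
#' @export
subseq_residues <- function(record, start, end) {
  n <- nchar(record$sequence)
  if (start < 1L || end > n || start > end)
    stop(sprintf("span %d-%d out of range for '%s' (1-%d)",
                 start, end, record$id, n), call. = FALSE)
  substr(record$sequence, start, end)
}

validate_residues <- function(sequence, id = "?", allow_unknown = FALSE) {
  if (!nzchar(sequence))
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  ok <- AA_ALPHABET
  if (allow_unknown) ok <- c(ok, "X")
  ch <- seq_chars(sequence)
  bad <- which(!ch %in% ok)
  if (length(bad))
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, ch[bad[1L]], bad[1L]), call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Molecular weight
# ---------------------------------------------------------------------------

#' Average molecular weight of a protein, in kDa
#'
#' Sum of average residue masses plus one water per chain, i.e.
#' `sum(residue masses) + 18.015 Da`, reported in kilodalton.  Monoisotopic
#' masses are deliberately not used: predicted masses of large proteins are
#' conventionally quoted on the average-mass scale.
#'
#' @param record A [protein_record()], or a plain sequence string.
#' @param x_mass Average mass (Da) to assume for an unknown residue `X`;
#'   `NULL` (default) makes `X` an error.
#' @return Mass in kDa (numeric scalar).
#' @export
#' @examples
#' molecular_weight(protein_record("g", "G"))  # 0.0750672
molecular_weight <- function(record, x_mass = NULL) {
  sequence <- if (inherits(record, "protein_record")) record$sequence
              else toupper(record)
  ch <- seq_chars(sequence)
  masses <- .RESIDUE_MASS[ch]
  if (anyNA(masses)) {
    bad <- ch[which(is.na(masses))[1L]]
    if (bad == "X" && !is.null(x_mass)) {
      masses[ch == "X"] <- x_mass
    } else {
      stop(sprintf("no mass for residue '%s' (supply x_mass for X)", bad),
           call. = FALSE)
    }
  }
  (sum(masses) + .WATER_MASS) / 1000
}

# ---------------------------------------------------------------------------
# Domain spans
# ---------------------------------------------------------------------------

#' Construct a table of named domain spans
#'
#' Spans are 1-based inclusive, must be non-overlapping, and are returned
#' sorted by start.
#'
#' @param name Character vector of domain names.
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @return A `data.frame` with columns `name`, `start`, `end`.
#' @export
domain_spans <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("domain start > end", call. = FALSE)
  o <- order(start)
  d <- data.frame(name = as.character(name)[o], start = start[o],
                  end = end[o], stringsAsFactors = FALSE)
  if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
    stop("overlapping domain spans", call. = FALSE)
  d
}

#' Domain architecture of human NLRC5
#'
#' The reference domain spans for the 1866-residue human NLRC5 receptor:
#' untypical CARD (uCARD) Met1-Gly197, NACHT Asp198-Gly369, small helical
#' AxP domain Pro370-Pro453, winged-helix/superhelical region to Ala652,
#' SH-LRR linker Thr653-Gln687, and the LRR domain Ile688-Thr1866.
#'
#' @return A `data.frame` of domain spans (see [domain_spans()]).
#' @export
nlrc5_domains <- function() {
  domain_spans(
    name  = c("uCARD", "NACHT", "AxP", "WH_SH", "linker", "LRR"),
    start = c(1L, 198L, 370L, 454L, 653L, 688L),
    end   = c(197L, 369L, 453L, 652L, 687L, 1866L))
}

# ---------------------------------------------------------------------------
# Coordinate helpers (internal)
# ---------------------------------------------------------------------------
# All user-facing coordinates are 1-based inclusive.  These helpers convert
# to/from 0-based half-open for internal arithmetic; the round trip is the
# identity.

to_zero_half_open <- function(start, end) c(start - 1L, end)

to_one_inclusive <- function(lo, hi) c(lo + 1L, hi)
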