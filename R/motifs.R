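# Motif scanner: Walker A/B, Sensor 1, AxP, winged-helix consensus, basic
# nuclear-localization clusters, and cysteine-spacing capping motifs.

#' Define a sequence motif
#'
#' @param name Motif label.
#' @param mode `"literal"` (exact substring), `"class"` (per-position residue
#'   class/set pattern, same token syntax as [compile_pattern()]) or
#'   `"spacing"` (a residue repeated with fixed gaps, e.g. cysteine capping
#'   spacings).
#' @param body The literal string, the class-pattern string, or (for
#'   spacing mode) the integer vector of gap lengths between consecutive
#'   anchor residues.
#' @param tolerance Per-gap slack for spacing mode (default 0).
#' @param region Optional `c(start, end)` restricting the scan; used for
#'   motifs too short for reliable de novo scanning (e.g. Sensor 1 within the
#'   NACHT domain).
#' @param residue Anchor residue for spacing mode (default `"C"`).
#' @return An object of class `motif_definition`.
#' @export
motif_definition <- function(name, mode = c("literal", "class", "spacing"),
                             body, tolerance = 0L, region = NULL,
                             residue = "C") {
  mode <- match.arg(mode)
  if (mode == "spacing") {
    body <- as.integer(body)
    stopifnot(length(body) >= 1L, all(body >= 0L))
  } else {
    stopifnot(is.character(body), length(body) == 1L, nzchar(body))
    if (mode == "literal") validate_residues(body, id = name)
  }
  if (!is.null(region)) region <- as.integer(region[1:2])
  structure(list(name = name, mode = mode, body = body,
                 tolerance = as.integer(tolerance), region = region,
                 residue = residue),
            class = "motif_definition")
}

#' Scan a protein for motif hits
#'
#' Literal motifs are exact substring matches; class motifs require every
#' constrained position to match its residue set; spacing motifs delegate to
#' [find_cys_spacing()].  For literal and class modes the reported hits are
#' the leftmost-first non-overlapping set per motif.
#'
#' @param record A [protein_record()].
#' @param definitions A list of [motif_definition()] objects.
#' @param classes A [residue_class_table()] (for class mode).
#' @return A `data.frame` with columns `motif`, `start`, `end`, `matched`,
#'   `detail` (comma-separated anchor positions for spacing hits, else `""`).
#' @export
scan_motifs <- function(record, definitions, classes = residue_class_table()) {
  if (inherits(definitions, "motif_definition"))
    definitions <- list(definitions)
  rows <- lapply(definitions, function(def) {
    if (def$mode == "spacing") {
      hits <- find_cys_spacing(record, spacing = def$body,
                               tolerance = def$tolerance,
                               residue = def$residue, region = def$region)
      if (nrow(hits))
        data.frame(motif = def$name, start = hits$start, end = hits$end,
                   matched = hits$matched, detail = hits$detail,
                   stringsAsFactors = FALSE)
      else NULL
    } else {
      starts <- .motif_starts(record, def, classes)
      if (!length(starts)) return(NULL)
      len <- if (def$mode == "literal") nchar(def$body)
             else length(.tokenize_pattern(def$body))
      starts <- .leftmost_nonoverlap(starts, len)
      data.frame(motif = def$name, start = starts, end = starts + len - 1L,
                 matched = vapply(starts, function(s)
                   subseq_residues(record, s, s + len - 1L), ""),
                 detail = "", stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.motif_starts <- function(record, def, classes) {
  n <- residue_count(record)
  lo <- 1L; hi <- n
  if (!is.null(def$region)) {
    lo <- max(1L, def$region[1L]); hi <- min(n, def$region[2L])
  }
  if (def$mode == "literal") {
    len <- nchar(def$body)
    if (hi - lo + 1L < len) return(integer(0))
    hay <- substr(record$sequence, lo, hi)
    starts <- integer(0)
    from <- 1L
    repeat {
      p <- regexpr(def$body, substr(hay, from, nchar(hay)), fixed = TRUE)
      if (p == -1L) break
      starts <- c(starts, from + p - 1L)
      from <- from + p  # allow overlapping discovery; pruned later
      if (from > nchar(hay)) break
    }
    starts + lo - 1L
  } else {
    pat <- compile_pattern(def$body, name = def$name, classes = classes,
                           allow_any_length = TRUE)
    if (hi - lo + 1L < pat$length) return(integer(0))
    ch <- seq_chars(record$sequence)
    starts <- lo:(hi - pat$length + 1L)
    ok <- rep(TRUE, length(starts))
    for (i in which(pat$constrained))
      ok <- ok & ch[starts + i - 1L] %in% pat$sets[[i]]
    starts[ok]
  }
}

.leftmost_nonoverlap <- function(starts, len) {
  starts <- sort(starts)
  keep <- integer(0)
  last_end <- 0L
  for (s in starts) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + len - 1L
    }
  }
  keep
}

#' Find cysteine (or other anchor) spacing motifs
#'
#' Locates runs of the anchor residue whose consecutive gaps equal the stated
#' spacing, e.g. `spacing = c(23, 5, 6, 12)` finds the `Cx23Cx5Cx6Cx12C`
#' capping pattern (span length 51).  With `tolerance = t` each gap may
#' deviate by at most `t` residues.  All matching anchor chains are reported
#' (they may overlap); the hit span runs from the first to the last anchor.
#'
#' @param record A [protein_record()].
#' @param spacing Integer vector of gap lengths between consecutive anchors.
#' @param tolerance Per-gap slack (default 0).
#' @param residue Anchor residue (default `"C"`).
#' @param region Optional `c(start, end)` scan restriction.
#' @return A `data.frame` with columns `start`, `end`, `matched` (the anchor
#'   residues), `detail` (comma-separated anchor positions).
#' @export
find_cys_spacing <- function(record, spacing = c(23L, 5L, 6L, 12L),
                             tolerance = 0L, residue = "C", region = NULL) {
  stopifnot(length(spacing) >= 1L)
  spacing <- as.integer(spacing)
  ch <- seq_chars(record$sequence)
  pos <- which(ch == residue)
  if (!is.null(region))
    pos <- pos[pos >= region[1L] & pos <= region[2L]]
  chains <- list()
  extend <- function(chain, level) {
    if (level > length(spacing)) {
      chains[[length(chains) + 1L]] <<- chain
      return(invisible())
    }
    want <- spacing[level]
    nxt <- pos[pos > chain[length(chain)] &
                 abs((pos - chain[length(chain)] - 1L) - want) <= tolerance]
    for (p in nxt) extend(c(chain, p), level + 1L)
  }
  for (p0 in pos) extend(p0, 1L)
  if (!length(chains))
    return(data.frame(start = integer(0), end = integer(0),
                      matched = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    start = vapply(chains, `[`, 1L, 1L),
    end = vapply(chains, function(x) x[length(x)], 1L),
    matched = strrep(residue, length(spacing) + 1L),
    detail = vapply(chains, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
}

#' Find basic-residue clusters (nuclear localization signal candidates)
#'
#' Reports maximal regions formed by merging all windows of length at most
#' `window` that contain at least `min_basics` basic residues (K/R); each
#' merged region is trimmed to its first and last basic residue, so a
#' poly-basic run is reported once rather than as many overlapping windows.
#' The defaults (5 basics within 14 residues) correspond to a bipartite-style
#' basic cluster such as the NLRC5 NLS Lys121/Arg122...Arg132/Arg133/Lys134,
#' which spans 14 residues.
#'
#' @param record A [protein_record()].
#' @param min_basics Minimum number of K/R residues in a qualifying window.
#' @param window Window length (must be at least `min_basics`).
#' @return A `data.frame` with columns `start`, `end`, `n_basic`, `matched`.
#' @export
find_basic_cluster <- function(record, min_basics = 5L, window = 14L) {
  stopifnot(window >= min_basics)
  ch <- seq_chars(record$sequence)
  basic <- ch %in% c("K", "R")
  n <- length(ch)
  if (n < window)
    return(data.frame(start = integer(0), end = integer(0),
                      n_basic = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  counts <- as.integer(stats::filter(as.integer(basic), rep(1L, window),
                                     sides = 1L))[window:n]
  qual_start <- which(counts >= min_basics)  # window = qual_start..+window-1
  if (!length(qual_start))
    return(data.frame(start = integer(0), end = integer(0),
                      n_basic = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  # merge overlapping qualifying windows into maximal regions
  regions <- list()
  cur <- c(qual_start[1L], qual_start[1L] + window - 1L)
  for (s in qual_start[-1L]) {
    if (s <= cur[2L]) cur[2L] <- s + window - 1L
    else { regions[[length(regions) + 1L]] <- cur; cur <- c(s, s + window - 1L) }
  }
  regions[[length(regions) + 1L]] <- cur
  rows <- lapply(regions, function(r) {
    b <- which(basic[r[1L]:r[2L]]) + r[1L] - 1L
    lo <- min(b); hi <- max(b)
    data.frame(start = lo, end = hi, n_basic = length(b),
               matched = paste(ch[lo:hi], collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rolling cysteine density
#'
#' Cys-count-per-window reporting used to inspect cysteine-rich regions (no
#' classifier threshold is applied: the notion of "cysteine-rich" is left to
#' the user).
#'
#' @param record A [protein_record()].
#' @param window Window length in residues.
#' @return A `data.frame` with columns `start`, `end`, `n_cys`.
#' @export
cys_density <- function(record, window = 30L) {
  ch <- seq_chars(record$sequence)
  isc <- as.integer(ch == "C")
  n <- length(ch)
  if (n < window)
    return(data.frame(start = integer(0), end = integer(0),
                      n_cys = integer(0)))
  counts <- as.integer(stats::filter(isc, rep(1L, window),
                                     sides = 1L))[window:n]
  data.frame(start = seq_len(n - window + 1L),
             end = window:n, n_cys = counts)
}

#' Check the residue identity at a fixed position
#'
#' Used for single-residue expectations such as the conserved winged-helix
#' histidine (His491 in NLRC5 numbering), which is too short to scan for.
#'
#' @param record A [protein_record()].
#' @param position 1-based residue position.
#' @param residue Expected one-letter residue.
#' @return `TRUE`/`FALSE`.
#' @export
residue_identity <- function(record, position, residue) {
  subseq_residues(record, position, position) == toupper(residue)
}

#' Read a motif configuration file
#'
#' A headered TSV with columns `name`, `mode`, `body`, `tolerance`,
#' `region_start`, `region_end` (the latter three may be `NA`).  Spacing-mode
#' bodies are comma-separated gap lists, e.g. `23,5,6,12`.
#'
#' @param path Path to the TSV.
#' @return A list of [motif_definition()] objects.
#' @export
read_motif_config <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    region <- if (!is.na(tab$region_start[i]))
      c(tab$region_start[i], tab$region_end[i]) else NULL
    body <- if (tab$mode[i] == "spacing")
      as.integer(strsplit(tab$body[i], ",", fixed = TRUE)[[1L]])
    else tab$body[i]
    motif_definition(tab$name[i], tab$mode[i], body,
                     tolerance = ifelse(is.na(tab$tolerance[i]), 0L,
                                        tab$tolerance[i]),
                     region = region)
  })
}

#' Default NLRC5 motif definitions
#'
#' The validation profile for NLRC5-numbering inputs: literal Walker A
#' (`GKAGMGKT`, Gly228-Thr235) and Walker B (`LLIFDGLDEAL`, Leu303-Leu313),
#' Sensor 1 (`TSR`, restricted to the NACHT span since a 3-mer cannot be
#' scanned reliably de novo), the AxP structural motif (`AVP`, restricted to
#' the small helical domain), the winged-helix consensus (`FYAKDI`), the
#' N-terminal cysteine capping spacing `Cx23Cx5Cx6Cx12C`, plus generalized
#' class-pattern Walker A/B for non-NLRC5 inputs.  Loaded from the shipped
#' config at `system.file("extdata", "nlrc5_motifs.tsv", package = "lrrscan")`.
#'
#' @return A list of [motif_definition()] objects.
#' @export
nlrc5_motifs <- function() {
  read_motif_config(system.file("extdata", "nlrc5_motifs.tsv",
                                package = "lrrscan"))
}
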