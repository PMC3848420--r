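# Consensus-pattern engine: RI-like LRR repeat patterns (two alternating
# types) and window scoring against them.

#' Compile a consensus pattern from its textual specification
#'
#' One token per consensus position: a class code from the
#' [residue_class_table()] (`L`, `S`, `E`, `R`, `o`, `g`), the wildcard
#' `x`/`X`, a bracketed literal set such as `[NC]`, or a single literal
#' residue letter that is not a class code.  Class codes resolve through the
#' table so that identical codes mean identical residue sets across all
#' patterns in a run.
#'
#' @param spec Pattern string, e.g. `"LxxLxLxxNxLxx..."`.
#' @param name Pattern label (e.g. `"type1"`, `"type2"`, `"generic_RI"`).
#' @param classes A [residue_class_table()].
#' @param insertion_site Optional consensus column index immediately before
#'   which the 29th residue of a 29-mer pattern is considered inserted
#'   relative to the 28-column frame (metadata used for reporting only;
#'   scoring always uses the explicit per-column classes).
#' @param required Integer vector of positions whose mismatch sets a
#'   hard-fail flag on any scored window (default none).
#' @param allow_any_length Accept lengths other than 28/29 (used for short
#'   motif-style patterns).
#' @return An object of class `consensus_pattern` with fields `name`,
#'   `length`, `codes`, `sets` (list of allowed residue vectors),
#'   `constrained` (logical), `required` (logical), `insertion_site`.
#' @export
#' @examples
#' p <- compile_pattern(paste0("LxxLxLxx[NC]xL", strrep("x", 17)), "strand")
#' sum(p$constrained)  # 5
compile_pattern <- function(spec, name = "pattern",
                            classes = residue_class_table(),
                            insertion_site = NULL, required = integer(0),
                            allow_any_length = FALSE) {
  stopifnot(is.character(spec), length(spec) == 1L)
  tokens <- .tokenize_pattern(spec)
  n <- length(tokens)
  if (!allow_any_length && !n %in% c(28L, 29L))
    stop(sprintf("pattern '%s' has length %d; expected 28 or 29 (set allow_any_length for generic patterns)",
                 name, n), call. = FALSE)
  sets <- vector("list", n)
  codes <- character(n)
  for (i in seq_len(n)) {
    tk <- tokens[i]
    if (startsWith(tk, "[")) {
      res <- seq_chars(substr(tk, 2L, nchar(tk) - 1L))
      bad <- setdiff(res, AA_ALPHABET)
      if (length(bad))
        stop(sprintf("pattern '%s' position %d: '%s' is not a residue",
                     name, i, bad[1L]), call. = FALSE)
      sets[[i]] <- res
      codes[i] <- tk
    } else if (tk %in% c("x", "X")) {
      sets[[i]] <- classes$X
      codes[i] <- "x"
    } else if (tk %in% names(classes)) {
      sets[[i]] <- classes[[tk]]
      codes[i] <- tk
    } else if (tk %in% AA_ALPHABET) {
      sets[[i]] <- tk
      codes[i] <- tk
    } else {
      stop(sprintf("pattern '%s' position %d: unknown code '%s'",
                   name, i, tk), call. = FALSE)
    }
  }
  constrained <- !vapply(sets, function(s) length(s) == length(AA_ALPHABET),
                         TRUE)
  req <- rep(FALSE, n)
  if (length(required)) {
    stopifnot(all(required >= 1L), all(required <= n))
    req[required] <- TRUE
  }
  if (!is.null(insertion_site)) {
    insertion_site <- as.integer(insertion_site)
    stopifnot(insertion_site >= 1L, insertion_site <= n)
  }
  structure(list(name = name, length = n, codes = codes, sets = sets,
                 constrained = constrained, required = req,
                 insertion_site = insertion_site),
            class = "consensus_pattern")
}

.tokenize_pattern <- function(spec) {
  chars <- seq_chars(spec)
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated '[' in pattern", call. = FALSE)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      tokens <- c(tokens, chars[i])
      i <- i + 1L
    }
  }
  tokens
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("<consensus_pattern> %s (%d positions, %d constrained%s)\n%s\n",
              x$name, x$length, sum(x$constrained),
              if (!is.null(x$insertion_site))
                paste0(", insertion at ", x$insertion_site) else "",
              paste(x$codes, collapse = "")))
  invisible(x)
}

#' Rotate a consensus pattern to an exon reading frame
#'
#' Returns the pattern whose column order is `phase..length, 1..(phase-1)`:
#' the frame seen by a peptide that starts at consensus column `phase` of one
#' repeat and runs into the head of the next repeat.
#'
#' @param pattern A [compile_pattern()] result.
#' @param phase 1-based consensus column at which the rotated frame starts.
#' @return A `consensus_pattern` of the same length.
#' @export
rotate_pattern <- function(pattern, phase) {
  stopifnot(inherits(pattern, "consensus_pattern"),
            phase >= 1L, phase <= pattern$length)
  if (phase == 1L) return(pattern)
  ord <- c(phase:pattern$length, 1:(phase - 1L))
  structure(list(name = paste0(pattern$name, "@", phase),
                 length = pattern$length, codes = pattern$codes[ord],
                 sets = pattern$sets[ord],
                 constrained = pattern$constrained[ord],
                 required = pattern$required[ord], insertion_site = NULL),
            class = "consensus_pattern")
}

#' Score one sequence window against a consensus pattern
#'
#' The score is the unweighted fraction of constrained pattern positions
#' whose window residue belongs to the position's residue class; wildcard
#' positions never contribute.  A mismatch at a `required` position sets the
#' `hard_fail` flag.
#'
#' @param record A [protein_record()].
#' @param start 1-based window start; the window covers
#'   `start .. start + pattern$length - 1`.
#' @param pattern A [compile_pattern()] result.
#' @return A list of class `window_score`: `start`, `length`, `pattern`,
#'   `score` in `[0, 1]`, `matched`, `constrained`, `hard_fail`.
#' @export
score_window <- function(record, start, pattern) {
  n <- residue_count(record)
  if (start < 1L || start + pattern$length - 1L > n)
    stop(sprintf("window %d..%d out of range (sequence length %d)",
                 start, start + pattern$length - 1L, n), call. = FALSE)
  ch <- seq_chars(subseq_residues(record, start, start + pattern$length - 1L))
  hit <- vapply(seq_len(pattern$length),
                function(i) ch[i] %in% pattern$sets[[i]], TRUE)
  k <- sum(pattern$constrained)
  matched <- sum(hit[pattern$constrained])
  structure(list(start = as.integer(start), length = pattern$length,
                 pattern = pattern$name,
                 score = if (k > 0L) matched / k else 0,
                 matched = matched, constrained = k,
                 hard_fail = any(pattern$required & !hit)),
            class = "window_score")
}

#' @export
print.window_score <- function(x, ...) {
  cat(sprintf("<window_score> %s @%d..%d score %.3f (%d/%d)%s\n",
              x$pattern, x$start, x$start + x$length - 1L, x$score,
              x$matched, x$constrained,
              if (x$hard_fail) " HARD-FAIL" else ""))
  invisible(x)
}

#' Classify a window as one repeat type (or none)
#'
#' Scores the window against each supplied pattern (anchored at the same
#' start) and returns the name of the best-scoring pattern if its score
#' reaches `min_score`.  An exact tie is broken toward the type that
#' continues alternation (i.e. away from `context`, the previous repeat's
#' type) when a context is given, otherwise toward the first pattern in the
#' list.
#'
#' @param record A [protein_record()].
#' @param start 1-based window start.
#' @param patterns A list of `consensus_pattern` objects (both types).
#' @param min_score Acceptance threshold on the score.
#' @param context Optional name of the preceding repeat's type.
#' @return The winning pattern name, or `NA_character_` if no pattern
#'   reaches `min_score` (hard-failed windows never win).
#' @export
classify_window <- function(record, start, patterns,
                            min_score = lrr_config()$min_score,
                            context = NULL) {
  n <- residue_count(record)
  scores <- vapply(patterns, function(p) {
    if (start + p$length - 1L > n) return(-Inf)
    s <- score_window(record, start, p)
    if (s$hard_fail) -Inf else s$score
  }, 0)
  names(scores) <- vapply(patterns, `[[`, "", "name")
  best <- max(scores)
  if (!is.finite(best) || best < min_score) return(NA_character_)
  top <- names(scores)[scores == best]
  if (length(top) > 1L && !is.null(context) && context %in% top) {
    alt <- setdiff(top, context)
    if (length(alt)) return(alt[1L])
  }
  top[1L]
}

#' Scan a sequence for all consensus-fitting windows
#'
#' Enumerates every start position for every pattern and returns windows with
#' score at or above `min_score` (hard-failed windows excluded).  This is the
#' candidate-generation step of the segmenter; it is exhaustive, so its
#' output equals a brute-force enumeration of all start positions.
#'
#' @param record A [protein_record()].
#' @param patterns A list of `consensus_pattern` objects.
#' @param min_score Score threshold.
#' @param region Optional `c(start, end)` 1-based inclusive restriction;
#'   windows must lie entirely inside it.
#' @return A `data.frame` with columns `start`, `end`, `length`, `type`,
#'   `score`.
#' @export
scan_windows <- function(record, patterns = default_patterns(),
                         min_score = lrr_config()$min_score, region = NULL) {
  n <- residue_count(record)
  lo <- 1L; hi <- n
  if (!is.null(region)) {
    lo <- max(1L, as.integer(region[1L]))
    hi <- min(n, as.integer(region[2L]))
  }
  ch <- seq_chars(record$sequence)
  out <- list()
  for (p in patterns) {
    L <- p$length
    if (hi - lo + 1L < L) next
    starts <- lo:(hi - L + 1L)
    k <- sum(p$constrained)
    matched <- numeric(length(starts))
    failed <- logical(length(starts))
    for (i in which(p$constrained)) {
      hit_i <- ch[starts + i - 1L] %in% p$sets[[i]]
      matched <- matched + hit_i
      if (p$required[i]) failed <- failed | !hit_i
    }
    score <- matched / k
    keep <- score >= min_score & !failed
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        start = starts[keep], end = starts[keep] + L - 1L, length = L,
        type = p$name, score = score[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), type = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# Pattern configuration
# ---------------------------------------------------------------------------

#' Read a pattern configuration file
#'
#' One pattern per block, blocks separated by blank lines, `#` comments
#' allowed.  Each block has lines `name <label>`, `spec <pattern string>` and
#' optionally `insertion <column|NA>`.  The shipped default file is at
#' `system.file("extdata", "lrr_patterns.txt", package = "lrrscan")` and can
#' be replaced wholesale to use different consensus strings.
#'
#' @param path Path to the configuration file.
#' @param classes A [residue_class_table()].
#' @return A named list of `consensus_pattern` objects.
#' @export
read_pattern_config <- function(path, classes = residue_class_table()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blocks <- split(lines, cumsum(lines == ""))
  pats <- list()
  for (b in blocks) {
    b <- b[nzchar(b)]
    if (!length(b)) next
    kv <- strsplit(b, "\\s+")
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), "")
    names(vals) <- keys
    if (!all(c("name", "spec") %in% keys))
      stop("pattern block missing 'name' or 'spec' in ", path, call. = FALSE)
    ins <- if ("insertion" %in% keys && vals[["insertion"]] != "NA")
      as.integer(vals[["insertion"]]) else NULL
    p <- compile_pattern(vals[["spec"]], name = vals[["name"]],
                         classes = classes, insertion_site = ins)
    pats[[p$name]] <- p
  }
  pats
}

#' The shipped default consensus patterns
#'
#' Two alternating RI-like repeat types: `type1`, a 28-residue pattern, and
#' `type2`, a 29-residue pattern carrying one inserted wildcard position
#' (insertion site column 16) and a cysteine in place of the strand
#' asparagine.  Both encode the RI-like subfamily skeleton: the
#' `LxxLxLxx[N/C]xL` concave-strand motif followed by convex-side aliphatic,
#' glycine, hydroxyl, acid/amide and basic positions.  A `generic_RI`
#' 28-residue pattern with a bracketed `[NC]` strand position and nonpolar
#' convex constraints is included for single-pattern scans.
#'
#' @param classes A [residue_class_table()].
#' @return Named list of `consensus_pattern` objects
#'   (`type1`, `type2`, `generic_RI`).
#' @export
default_patterns <- function(classes = residue_class_table()) {
  path <- system.file("extdata", "lrr_patterns.txt", package = "lrrscan")
  read_pattern_config(path, classes = classes)
}

#' The two alternating default repeat types
#' @inheritParams default_patterns
#' @return Named list with patterns `type1` and `type2`.
#' @export
default_type_patterns <- function(classes = residue_class_table()) {
  default_patterns(classes)[c("type1", "type2")]
}
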