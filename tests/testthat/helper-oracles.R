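# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results by brute force / direct enumeration,
# separately from the package's implementation paths.

# Per-window consensus score by direct per-position counting.
oracle_window_score <- function(sequence, start, pattern) {
  ch <- strsplit(sequence, "")[[1]]
  matched <- 0L
  total <- 0L
  for (i in seq_len(pattern$length)) {
    if (!pattern$constrained[i]) next
    total <- total + 1L
    if (ch[start + i - 1L] %in% pattern$sets[[i]]) matched <- matched + 1L
  }
  matched / total
}

# Brute-force window scan: score every start with score_window (the scalar
# path), independent of the vectorized scan_windows accumulation.
oracle_scan <- function(record, patterns, min_score) {
  out <- list()
  for (p in patterns) {
    n <- residue_count(record)
    if (n < p$length) next
    for (s in 1:(n - p$length + 1L)) {
      w <- score_window(record, s, p)
      if (w$score >= min_score && !w$hard_fail)
        out[[length(out) + 1L]] <- data.frame(start = s,
                                              end = s + p$length - 1L,
                                              length = p$length,
                                              type = p$name, score = w$score)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), type = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive best chain over candidate windows, maximizing the documented
# objective: sum of scores + adjacency bonus (gap 0) + alternation bonus
# (different types within max_gap).  Exponential; keep candidates small.
oracle_chain_objective <- function(chain, config) {
  if (!nrow(chain)) return(0)
  total <- sum(chain$score)
  if (nrow(chain) > 1L) {
    for (i in 2:nrow(chain)) {
      gap <- chain$start[i] - chain$end[i - 1L] - 1L
      if (gap == 0L) total <- total + config$adjacency_bonus
      if (gap <= config$max_gap && chain$type[i] != chain$type[i - 1L])
        total <- total + config$alternation_bonus
    }
  }
  total
}

oracle_best_chain <- function(cand, config) {
  stopifnot(nrow(cand) <= 18L)  # exponential enumeration guard
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  best <- 0
  n <- nrow(cand)
  recurse <- function(i, rows) {
    if (i > n) {
      obj <- oracle_chain_objective(cand[rows, , drop = FALSE], config)
      if (obj > best) best <<- obj
      return(invisible())
    }
    recurse(i + 1L, rows)                     # skip window i
    if (!length(rows) || cand$start[i] > cand$end[rows[length(rows)]])
      recurse(i + 1L, c(rows, i))             # take window i
  }
  recurse(1L, integer(0))
  best
}

# Exhaustive cysteine-subset spacing oracle: every combination of anchor
# positions whose consecutive gaps equal the spacing (within tolerance).
oracle_cys_chains <- function(record, spacing, tolerance = 0L,
                              residue = "C") {
  ch <- strsplit(record$sequence, "")[[1]]
  pos <- which(ch == residue)
  k <- length(spacing) + 1L
  if (length(pos) < k)
    return(data.frame(start = integer(0), end = integer(0)))
  combos <- utils::combn(pos, k)
  hits <- list()
  for (j in seq_len(ncol(combos))) {
    p <- combos[, j]
    gaps <- diff(p) - 1L
    if (all(abs(gaps - spacing) <= tolerance))
      hits[[length(hits) + 1L]] <- data.frame(start = p[1L], end = p[k])
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  out <- unique(do.call(rbind, hits))
  out[order(out$start, out$end), , drop = FALSE]
}

# Deterministic perfect repeat instance: first residue of each position's
# allowed set (wildcards get 'A').
perfect_repeat <- function(pattern) {
  paste(vapply(seq_len(pattern$length), function(i) {
    if (pattern$constrained[i]) pattern$sets[[i]][1L] else "A"
  }, ""), collapse = "")
}

# Shared NLRC5-architecture mimic instance (seeded once for the whole suite).
mimic_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_protein(nlrc5_mimic_config(),
                                                   seed = 1)
    cache
  }
})
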