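# Synthetic-data generator: ground-truth-labelled proteins and exon tables
# with the statistical structure the repeat analysis assumes (tandem 28/29
# residue repeats with alternating types, point-mutation noise over residue
# synonym classes, degenerate repeats, planted motifs, exon boundaries at a
# configured consensus phase).

#' Generator configuration
#'
#' @param n_repeats Number of repeat slots (including degenerate and capping
#'   slots).
#' @param patterns Patterns to sample repeats from (default
#'   [default_type_patterns()], resolved at generation time).
#' @param type_policy `"alternating"` (types strictly alternate along the
#'   consensus-fitting slots, as in ribonuclease inhibitor) or `"random"`.
#' @param mutation_rate Per-position point-mutation probability applied to
#'   consensus-sampled repeat residues.
#' @param within_class_prob Probability that a mutation substitutes within
#'   the position's residue synonym class (constrained positions only;
#'   otherwise, and for wildcard positions, the substitute is drawn from the
#'   background).
#' @param flank Lengths of the N- and C-terminal non-repeat flanks.
#' @param motifs List of motif plants.  Each element is a list with `name`,
#'   `at` (1-based start) and either `body` (literal string; `"."` keeps the
#'   background residue) or `spacing` (integer gaps) plus optional `residue`
#'   (spacing anchor, default `"C"`).  Motifs must lie inside the N-terminal
#'   flank; collisions with the repeat region or with each other are layout
#'   errors.
#' @param deplete List of background-depletion zones, each a list with
#'   `residues`, `start`, `end`; used e.g. to clear basic residues around a
#'   planted NLS so its window is unambiguous.
#' @param cys_deplete_flanks Remove cysteine from the flank background so
#'   planted Cys-spacing motifs are unambiguous (default `TRUE`).
#' @param exon_phase Consensus column at which generated exon boundaries
#'   fall (default 6), or `NULL` for no exon table.
#' @param exon_offset Exon-number offset: repeat-slot exons are numbered
#'   `exon_offset + 1 ...`; when positive, `exon_offset` leading exons are
#'   emitted covering the sequence before the first repeat-exon boundary.
#' @param degenerate_slots Indices of slots emitted as short random
#'   (non-consensus) segments.
#' @param degenerate_lengths Lengths for degenerate slots (recycled).
#' @param capping Emit the last slot as a C-terminal capping repeat: a
#'   consensus repeat extended with background residues to `capping_length`.
#' @param capping_length Total capping-slot length (full-receptor default 36).
#' @param composition `"background"` (Swiss-Prot-like frequencies; default)
#'   or `"uniform"` for unconstrained positions.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_repeats = 8L, patterns = NULL,
                             type_policy = c("alternating", "random"),
                             mutation_rate = 0, within_class_prob = 0.5,
                             flank = c(50L, 50L), motifs = list(),
                             deplete = list(), cys_deplete_flanks = TRUE,
                             exon_phase = 6L, exon_offset = 0L,
                             degenerate_slots = integer(0),
                             degenerate_lengths = 18L,
                             capping = FALSE, capping_length = 36L,
                             composition = c("background", "uniform")) {
  type_policy <- match.arg(type_policy)
  composition <- match.arg(composition)
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            within_class_prob >= 0, within_class_prob <= 1,
            n_repeats >= 0)
  structure(list(n_repeats = as.integer(n_repeats), patterns = patterns,
                 type_policy = type_policy, mutation_rate = mutation_rate,
                 within_class_prob = within_class_prob,
                 flank = as.integer(flank), motifs = motifs,
                 deplete = deplete, cys_deplete_flanks = cys_deplete_flanks,
                 exon_phase = if (is.null(exon_phase)) NULL
                              else as.integer(exon_phase),
                 exon_offset = as.integer(exon_offset),
                 degenerate_slots = as.integer(degenerate_slots),
                 degenerate_lengths = as.integer(degenerate_lengths),
                 capping = capping, capping_length = as.integer(capping_length),
                 composition = composition),
            class = "generator_config")
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sample_background <- function(n, composition = "background",
                               exclude = character(0)) {
  if (n <= 0L) return(character(0))
  probs <- if (composition == "uniform")
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET) else .BACKGROUND_FREQ
  if (length(exclude)) {
    probs <- probs[setdiff(names(probs), exclude)]
    probs <- probs / sum(probs)
  }
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.sample_repeat <- function(pattern, composition) {
  ch <- character(pattern$length)
  for (i in seq_len(pattern$length)) {
    ch[i] <- if (pattern$constrained[i])
      sample(pattern$sets[[i]], 1L)
    else .sample_background(1L, composition)
  }
  ch
}

#' Generate a synthetic protein with planted ground truth
#'
#' Repeats are sampled from the consensus patterns (constrained positions
#' uniformly from their residue class, wildcards from the background
#' composition), point mutations are applied at `mutation_rate`
#' (within-class with probability `within_class_prob`), motifs are planted
#' in the N-terminal flank, and an exon table is laid out so that every exon
#' starts at consensus column `exon_phase` of its repeat slot.  Fully
#' reproducible per seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed fixing all randomness.
#' @param id Identifier for the generated record.
#' @return A list with elements `record` (a [protein_record()]) and `truth`,
#'   where `truth` contains `slots` (all repeat slots with `role`, span,
#'   `type`), `fitting` (the consensus windows a segmenter should recover:
#'   `start`, `end`, `length`, `type`), `motifs`, `exons` (or `NULL`),
#'   `mutations` (log of planted point mutations), `mutable_positions`,
#'   `exon_phase` and `seed`.
#' @export
generate_protein <- function(config, seed, id = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, .generate_protein_impl(config, seed, id))
}

.generate_protein_impl <- function(config, seed, id) {
  patterns <- config$patterns
  if (is.null(patterns)) patterns <- default_type_patterns()
  comp <- config$composition
  n <- config$n_repeats

  # --- slot layout -------------------------------------------------------
  role <- rep("fitting", n)
  if (length(config$degenerate_slots)) {
    stopifnot(all(config$degenerate_slots >= 1L),
              all(config$degenerate_slots <= n))
    role[config$degenerate_slots] <- "degenerate"
  }
  if (config$capping && n >= 1L) {
    if (role[n] == "degenerate")
      stop("layout error: last slot cannot be both degenerate and capping",
           call. = FALSE)
    role[n] <- "capping"
  }
  fit_idx <- which(role != "degenerate")
  type <- rep(NA_character_, n)
  pat_of <- vector("list", n)
  pnames <- names(patterns)
  for (k in seq_along(fit_idx)) {
    j <- if (config$type_policy == "alternating")
      ((k - 1L) %% length(patterns)) + 1L
    else sample.int(length(patterns), 1L)
    type[fit_idx[k]] <- pnames[j]
    pat_of[[fit_idx[k]]] <- patterns[[j]]
  }

  deg_len <- rep_len(config$degenerate_lengths,
                     max(1L, length(config$degenerate_slots)))
  slot_seq <- vector("list", n)
  consensus_len <- integer(n)   # length of the consensus-sampled prefix
  di <- 0L
  for (s in seq_len(n)) {
    if (role[s] == "degenerate") {
      di <- di + 1L
      slot_seq[[s]] <- .sample_background(deg_len[di], comp)
      consensus_len[s] <- 0L
    } else {
      rep_ch <- .sample_repeat(pat_of[[s]], comp)
      consensus_len[s] <- length(rep_ch)
      if (role[s] == "capping") {
        extra <- config$capping_length - length(rep_ch)
        if (extra < 0L)
          stop("capping_length shorter than the repeat pattern", call. = FALSE)
        rep_ch <- c(rep_ch, .sample_background(extra, comp))
      }
      slot_seq[[s]] <- rep_ch
    }
  }
  slot_len <- vapply(slot_seq, length, 1L)
  rep_region_start <- config$flank[1L] + 1L
  slot_start <- if (n > 0L)
    rep_region_start + c(0L, cumsum(slot_len))[seq_len(n)] else integer(0)
  slot_end <- slot_start + slot_len - 1L

  # --- point mutations over consensus-sampled residues -------------------
  mut <- list()
  if (config$mutation_rate > 0) {
    for (s in seq_len(n)) {
      if (consensus_len[s] == 0L) next
      pat <- pat_of[[s]]
      for (i in seq_len(consensus_len[s])) {
        if (stats::runif(1L) >= config$mutation_rate) next
        from <- slot_seq[[s]][i]
        within <- pat$constrained[i] &&
          stats::runif(1L) < config$within_class_prob
        pool <- if (within) setdiff(pat$sets[[i]], from)
                else setdiff(AA_ALPHABET, from)
        if (!length(pool)) {       # single-member class: no synonym exists
          within <- FALSE
          pool <- setdiff(AA_ALPHABET, from)
        }
        to <- sample(pool, 1L)
        slot_seq[[s]][i] <- to
        mut[[length(mut) + 1L]] <- data.frame(
          position = slot_start[s] + i - 1L, from = from, to = to,
          within_class = within, stringsAsFactors = FALSE)
      }
    }
  }
  mutations <- if (length(mut)) do.call(rbind, mut)
  else data.frame(position = integer(0), from = character(0),
                  to = character(0), within_class = logical(0),
                  stringsAsFactors = FALSE)

  # --- flanks, depletion zones, planted motifs ---------------------------
  flank_excl <- if (config$cys_deplete_flanks) "C" else character(0)
  nfl <- .sample_background(config$flank[1L], comp, exclude = flank_excl)
  cfl <- .sample_background(config$flank[2L], comp, exclude = flank_excl)
  for (z in config$deplete) {
    idx <- z$start:z$end
    idx <- idx[idx >= 1L & idx <= length(nfl)]
    nfl[idx] <- .sample_background(length(idx), comp,
                                   exclude = c(flank_excl, z$residues))
  }
  motif_rows <- list()
  occupied <- integer(0)
  for (mo in config$motifs) {
    if (!is.null(mo$spacing)) {
      anchor <- if (is.null(mo$residue)) "C" else mo$residue
      pos <- mo$at + cumsum(c(0L, as.integer(mo$spacing) + 1L))
      span <- mo$at:(pos[length(pos)])
      plant <- function(v) { v[pos] <- anchor; v }
    } else {
      body <- seq_chars(mo$body)
      span <- mo$at:(mo$at + length(body) - 1L)
      keep <- body == "."
      plant <- function(v) { v[span[!keep]] <- body[!keep]; v }
      pos <- span[!keep]
    }
    if (min(span) < 1L || max(span) > length(nfl))
      stop(sprintf("layout error: motif '%s' (%d-%d) collides with the repeat region or sequence bounds",
                   mo$name, min(span), max(span)), call. = FALSE)
    if (any(pos %in% occupied))
      stop(sprintf("layout error: motif '%s' overlaps another planted motif",
                   mo$name), call. = FALSE)
    occupied <- c(occupied, pos)
    nfl <- plant(nfl)
    motif_rows[[length(motif_rows) + 1L]] <- data.frame(
      name = mo$name, start = min(span), end = max(span),
      stringsAsFactors = FALSE)
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows)
  else data.frame(name = character(0), start = integer(0), end = integer(0),
                  stringsAsFactors = FALSE)

  sequence <- paste(c(nfl, unlist(slot_seq), cfl), collapse = "")
  record <- protein_record(id, sequence,
                           sprintf("synthetic (seed %d)", seed))

  # --- exon table --------------------------------------------------------
  exons <- NULL
  if (!is.null(config$exon_phase) && n >= 1L) {
    ph <- config$exon_phase
    bnd <- slot_start + ph - 1L           # start of each repeat-slot exon
    ex_start <- bnd
    # the last exon closes the repeat frame: it ends phase-1 residues past
    # the final slot (clipped at the sequence end)
    ex_end <- c(bnd[-1L] - 1L,
                min(slot_end[n] + ph - 1L, nchar(sequence)))
    ex_num <- config$exon_offset + seq_len(n)
    if (config$exon_offset > 0L) {
      lead_ends <- round(seq(0L, bnd[1L] - 1L,
                             length.out = config$exon_offset + 1L))
      ex_start <- c(lead_ends[-length(lead_ends)] + 1L, ex_start)
      ex_end <- c(lead_ends[-1L], ex_end)
      ex_num <- c(seq_len(config$exon_offset), ex_num)
    }
    exons <- exon_table(ex_num, ex_start, ex_end)
  }

  fitting <- data.frame(
    slot = fit_idx,
    start = slot_start[fit_idx],
    length = consensus_len[fit_idx],
    type = type[fit_idx], stringsAsFactors = FALSE)
  fitting$end <- fitting$start + fitting$length - 1L
  fitting <- fitting[, c("slot", "start", "end", "length", "type")]

  truth <- list(
    slots = data.frame(slot = seq_len(n), role = role, start = slot_start,
                       end = slot_end, length = slot_len, type = type,
                       stringsAsFactors = FALSE),
    fitting = fitting,
    motifs = motifs,
    exons = exons,
    mutations = mutations,
    mutable_positions = sum(consensus_len),
    exon_phase = config$exon_phase,
    seed = seed)
  list(record = record, truth = truth)
}

#' Residue-composition-preserving shuffle (null model)
#'
#' @param record A [protein_record()].
#' @param seed Integer seed.
#' @return A [protein_record()] with the same residue multiset in permuted
#'   order.
#' @export
shuffle_null <- function(record, seed) {
  with_seed(seed, {
    ch <- seq_chars(record$sequence)
    protein_record(paste0(record$id, "_shuffled"),
                   paste(sample(ch), collapse = ""),
                   "residue-shuffled null")
  })
}

#' NLRC5-architecture mimic preset
#'
#' A synthetic protein that mirrors the architecture of human NLRC5 at the
#' scale of the full human receptor, for end-to-end pipeline tests without external downloads:
#' 1866 residues; 43 repeat slots behind a 701-residue N-terminal region so
#' that repeat-slot exons are numbered 7-49; slots 5, 6, 10, 11, 15, 20 and
#' 24 (exons 11, 12, 16, 17, 21, 26, 30) degenerate; the last slot a
#' 36-residue C-terminal capping repeat; exon boundaries at consensus
#' column 6; and planted functional motifs at NLRC5 numbering: the basic NLS
#' cluster Lys121...Lys134 (with a basic-depleted buffer so its window is
#' unambiguous), Walker A `GKAGMGKT` at 228, Walker B `LLIFDGLDEAL` at 303,
#' Sensor 1 `TSR` at 345, AxP `AVP` at 404, winged-helix consensus `FYAKDI`
#' at 475 with His491, and the `Cx23Cx5Cx6Cx12C` capping cysteines spanning
#' 648-698.  This object is synthetic throughout: it emulates the
#' architecture, not the residue identity, of the real receptor.
#'
#' @return A [generator_config()].
#' @export
nlrc5_mimic_config <- function() {
  generator_config(
    n_repeats = 43L,
    type_policy = "alternating",
    mutation_rate = 0,
    flank = c(701L, 5L),
    exon_phase = 6L,
    exon_offset = 6L,
    degenerate_slots = c(5L, 6L, 10L, 11L, 15L, 20L, 24L),
    degenerate_lengths = c(19L, 18L, 18L, 18L, 18L, 18L, 18L),
    capping = TRUE,
    capping_length = 36L,
    motifs = list(
      list(name = "NLS", at = 121L, body = "KR.........RRK"),
      list(name = "walker_A", at = 228L, body = "GKAGMGKT"),
      list(name = "walker_B", at = 303L, body = "LLIFDGLDEAL"),
      list(name = "sensor_1", at = 345L, body = "TSR"),
      list(name = "AxP", at = 404L, body = "AVP"),
      list(name = "WH_consensus", at = 475L, body = "FYAKDI"),
      list(name = "WH_His", at = 491L, body = "H"),
      list(name = "cys_capping", at = 648L, spacing = c(23L, 5L, 6L, 12L))),
    deplete = list(list(residues = c("K", "R"), start = 108L, end = 147L)))
}
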