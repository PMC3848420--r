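test_that("planted alternating repeats are recovered exactly at planted boundaries", {
  cfg <- generator_config(n_repeats = 5L, type_policy = "alternating",
                          mutation_rate = 0, flank = c(50L, 50L),
                          exon_phase = NULL)
  g <- generate_protein(cfg, seed = 7)
  rep <- segment_repeats(g$record)
  fit <- rep[rep$fits_consensus, ]
  expect_equal(nrow(fit), 5L)
  expect_equal(fit$start, g$truth$fitting$start)
  expect_equal(fit$end, g$truth$fitting$end)
  expect_equal(fit$type, g$truth$fitting$type)
  expect_equal(fit$type, rep(c("type1", "type2"), length.out = 5L))
  expect_equal(check_alternation(rep), 1.0)
})

test_that("sequences shorter than one repeat yield an empty annotation", {
  rec <- protein_record("short", strrep("ALSG", 5))  # 20 residues
  out <- segment_repeats(rec)
  expect_s3_class(out, "lrr_annotation")
  expect_equal(nrow(out), 0L)
})

test_that("segmentation is deterministic for fixed input and config", {
  g <- generate_protein(generator_config(n_repeats = 6L,
                                         mutation_rate = 0.05), seed = 3)
  expect_identical(segment_repeats(g$record), segment_repeats(g$record))
})

test_that("alternation fraction counts differing adjacent fitting pairs", {
  mk <- function(types) data.frame(type = types,
                                   fits_consensus = TRUE)
  expect_equal(check_alternation(mk(c("1", "2", "1", "2"))), 1.0)
  expect_equal(check_alternation(mk(c("1", "1", "2", "2"))), 1 / 3)
  expect_warning(val <- check_alternation(mk("1")), "undefined")
  expect_true(is.na(val))
})

test_that("the DP chain attains the exhaustive-chaining optimum (<= 150 aa)", {
  pats <- default_type_patterns()
  cfg <- lrr_config(min_score = 0.75)
  set.seed(19)
  for (i in 1:5) {
    # noisy repeats close together create competing overlapping candidates
    g <- generate_protein(generator_config(n_repeats = 3L,
                                           mutation_rate = 0.12,
                                           flank = c(15L, 15L),
                                           exon_phase = NULL),
                          seed = 100 + i)
    rec <- g$record
    expect_lte(residue_count(rec), 150L)
    cand <- scan_windows(rec, pats, min_score = cfg$min_score)
    if (nrow(cand) == 0L || nrow(cand) > 18L) next
    fit <- segment_repeats(rec, pats, cfg)
    fit <- fit[fit$fits_consensus, ]
    expect_equal(oracle_chain_objective(fit, cfg),
                 oracle_best_chain(cand, cfg))
  }
})

test_that("equal-objective chains prefer the earlier first repeat", {
  # two disjoint perfect windows of the same pattern, too far apart to chain
  # with a bonus difference: a single-repeat chain tie at both positions
  pats <- default_type_patterns()["type1"]
  p <- pats$type1
  filler <- strrep("A", 40)
  s <- paste0(perfect_repeat(p), filler, perfect_repeat(p))
  rep <- segment_repeats(protein_record("tie", s), pats)
  # both windows are kept (they do not overlap), chain starts at 1
  expect_equal(rep$start[1], 1L)
  expect_equal(sum(rep$fits_consensus), 2L)
})

test_that("short inter-repeat gaps are reported as atypical segments", {
  g <- generate_protein(
    generator_config(n_repeats = 5L, degenerate_slots = 3L,
                     degenerate_lengths = 15L, exon_phase = NULL),
    seed = 21)
  rep <- segment_repeats(g$record)
  atyp <- rep[!rep$fits_consensus, ]
  expect_equal(nrow(atyp), 1L)
  expect_equal(atyp$length, 15L)
  expect_equal(atyp$type, "atypical")
  expect_equal(atyp$start, g$truth$slots$start[3])
  # indices are ordinal from the N-terminus over all segments
  expect_equal(rep$index, seq_len(nrow(rep)))
})

test_that("planted-boundary recovery >= 95% at mutation rate 0.05 (20 seeds)", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    g <- generate_protein(generator_config(n_repeats = 8L,
                                           mutation_rate = 0.05),
                          seed = seed)
    fit <- segment_repeats(g$record)
    fit <- fit[fit$fits_consensus, ]
    key <- paste(fit$start, fit$end)
    truth_key <- paste(g$truth$fitting$start, g$truth$fitting$end)
    hits <- hits + sum(truth_key %in% key)
    total <- total + length(truth_key)
  }
  expect_gte(hits / total, 0.95)
})

test_that("residue-shuffled nulls yield zero fitting repeats in >= 95% of 100 seeds", {
  zero <- 0L
  for (seed in 1:100) {
    g <- generate_protein(generator_config(n_repeats = 8L), seed = seed)
    null_rec <- shuffle_null(g$record, seed = seed + 1000L)
    n_fit <- sum(segment_repeats(null_rec)$fits_consensus)
    if (n_fit == 0L) zero <- zero + 1L
  }
  expect_gte(zero, 95L)
})

test_that("threshold sensitivity reports the fitting count per threshold", {
  g <- generate_protein(generator_config(n_repeats = 5L), seed = 2)
  sens <- threshold_sensitivity(g$record,
                                thresholds = c(0.6, 0.8, 0.95, 1.0))
  expect_equal(names(sens), c("min_score", "n_fitting"))
  # noise-free planted repeats fit at every threshold up to 1.0
  expect_true(all(sens$n_fitting >= 5L))
  expect_equal(sens$n_fitting[sens$min_score == 1.0], 5L)
})
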