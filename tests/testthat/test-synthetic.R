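test_that("generation is byte-identical per seed and differs across seeds", {
  cfg <- generator_config(n_repeats = 5L, mutation_rate = 0.05)
  a <- generate_protein(cfg, seed = 1)
  b <- generate_protein(cfg, seed = 1)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth, b$truth)
  c <- generate_protein(cfg, seed = 2)
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_protein(generator_config(n_repeats = 2L), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("noise-free repeats score 1.0 on their source pattern", {
  pats <- default_type_patterns()
  g <- generate_protein(generator_config(n_repeats = 6L, mutation_rate = 0),
                        seed = 4)
  for (i in seq_len(nrow(g$truth$fitting))) {
    row <- g$truth$fitting[i, ]
    w <- score_window(g$record, row$start, pats[[row$type]])
    expect_equal(w$score, 1.0)
  }
})

test_that("mutation counts follow Binomial(positions, rate) across seeds", {
  cfg <- generator_config(n_repeats = 5L, mutation_rate = 0.1,
                          flank = c(10L, 10L), exon_phase = NULL)
  counts <- vapply(1:200, function(s) {
    g <- generate_protein(cfg, seed = s)
    nrow(g$truth$mutations)
  }, 0L)
  npos <- generate_protein(cfg, seed = 1)$truth$mutable_positions
  # chi-square goodness of fit against the binomial pmf, pooled tails
  breaks <- c(-Inf, 8:19, Inf)
  obs <- table(cut(counts, breaks))
  probs <- diff(stats::pbinom(c(-Inf, 8:19, Inf), npos, 0.1))
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("within-class mutations stay inside the position's synonym class", {
  cfg <- generator_config(n_repeats = 6L, mutation_rate = 0.2,
                          within_class_prob = 1, exon_phase = NULL)
  g <- generate_protein(cfg, seed = 8)
  mut <- g$truth$mutations
  expect_gt(nrow(mut), 0L)
  within <- mut[mut$within_class, ]
  classes <- residue_class_table()
  pats <- default_type_patterns()
  for (i in seq_len(nrow(within))) {
    slot <- g$truth$fitting[g$truth$fitting$start <= within$position[i] &
                              g$truth$fitting$end >= within$position[i], ]
    pat <- pats[[slot$type]]
    col <- within$position[i] - slot$start + 1L
    expect_true(within$to[i] %in% pat$sets[[col]])
  }
})

test_that("generated exon boundaries realize the configured phase", {
  cfg <- generator_config(n_repeats = 7L, exon_phase = 6L)
  for (seed in 1:5) {
    g <- generate_protein(cfg, seed = seed)
    ph <- phase_exons(g$truth$exons, repeats = segment_repeats(g$record))
    expect_true(all(ph$phase == 6L))
    expect_equal(modal_phase(ph), 6L)
  }
})

test_that("planted Cys spacing motifs are recovered exactly by the scanner", {
  cfg <- generator_config(
    n_repeats = 3L, flank = c(120L, 20L), exon_phase = NULL,
    motifs = list(list(name = "cap", at = 30L, spacing = c(23L, 5L, 6L, 12L))))
  g <- generate_protein(cfg, seed = 6)
  hits <- find_cys_spacing(g$record, c(23L, 5L, 6L, 12L))
  expect_equal(c(hits$start, hits$end), c(30L, 80L))
  expect_equal(g$truth$motifs$start, 30L)
  expect_equal(g$truth$motifs$end, 80L)
})

test_that("colliding or out-of-flank motifs raise layout errors", {
  expect_error(generate_protein(generator_config(
    n_repeats = 2L, flank = c(40L, 10L),
    motifs = list(list(name = "wa", at = 38L, body = "GKAGMGKT"))),
    seed = 1), "layout error")
  expect_error(generate_protein(generator_config(
    n_repeats = 2L, flank = c(60L, 10L),
    motifs = list(list(name = "a", at = 10L, body = "GKAGMGKT"),
                  list(name = "b", at = 12L, body = "LLIFDGLDEAL"))),
    seed = 1), "overlaps")
})

test_that("shuffled nulls preserve length and residue multiset", {
  g <- generate_protein(generator_config(n_repeats = 4L), seed = 11)
  s <- shuffle_null(g$record, seed = 12)
  expect_equal(nchar(s$sequence), nchar(g$record$sequence))
  expect_equal(sort(strsplit(s$sequence, "")[[1]]),
               sort(strsplit(g$record$sequence, "")[[1]]))
  expect_false(identical(s$sequence, g$record$sequence))
  expect_identical(shuffle_null(g$record, seed = 12)$sequence, s$sequence)
})

test_that("the NLRC5 mimic reproduces the full-receptor architecture", {
  g <- mimic_fixture()
  expect_equal(residue_count(g$record), 1866L)
  expect_equal(nrow(g$truth$slots), 43L)
  expect_equal(sum(g$truth$slots$role == "degenerate"), 7L)
  expect_equal(g$truth$slots$length[43], 36L)
  exons <- g$truth$exons
  expect_equal(nrow(exons), 49L)
  expect_equal(range(exons$exon_number), c(1L, 49L))
  # molecular weight lands at the ~204 kDa scale of a 1866-residue receptor
  expect_equal(molecular_weight(g$record), 204, tolerance = 0.05)
})
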