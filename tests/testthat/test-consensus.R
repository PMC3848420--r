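test_that("pattern compilation records constrained positions and rejects bad codes", {
  spec <- paste0("LxxLxLxx[NC]xL", strrep("x", 17))
  p <- compile_pattern(spec, "strand")
  expect_s3_class(p, "consensus_pattern")
  expect_equal(p$length, 28L)
  expect_equal(which(p$constrained), c(1L, 4L, 6L, 9L, 11L))
  expect_equal(p$sets[[9]], c("N", "C"))

  expect_error(compile_pattern(paste0("Zxx", strrep("x", 25)), "bad"),
               "position 1.*unknown code 'Z'")
  expect_error(compile_pattern("LxxL", "short"), "length 4")
  p4 <- compile_pattern("LxxL", "short", allow_any_length = TRUE)
  expect_equal(p4$length, 4L)

  # determinism: two compiles of the same spec are value-identical
  expect_identical(compile_pattern(spec, "strand"),
                   compile_pattern(spec, "strand"))
})

test_that("shipped default patterns load and are information-rich", {
  pats <- default_patterns()
  expect_setequal(names(pats), c("type1", "type2", "generic_RI"))
  expect_equal(pats$type1$length, 28L)
  expect_equal(pats$type2$length, 29L)
  expect_equal(pats$type2$insertion_site, 16L)
  for (p in pats) expect_gte(sum(p$constrained), 8L)
  # same class codes resolve to identical residue sets across patterns
  expect_identical(pats$type1$sets[[1]], pats$type2$sets[[1]])
})

test_that("window scoring: perfect instance 1.0, excluded classes 0.0, oracle agreement", {
  pats <- default_type_patterns()
  rec <- protein_record("perfect", perfect_repeat(pats$type1))
  w <- score_window(rec, 1L, pats$type1)
  expect_equal(w$score, 1.0)
  expect_equal(w$matched, w$constrained)

  # poly-A misses every constrained class of type1 (A is in no type1 set)
  polyA <- protein_record("a", strrep("A", 28))
  expect_equal(score_window(polyA, 1L, pats$type1)$score, 0.0)

  # seeded random windows agree with the independent per-position count
  set.seed(42)
  for (i in 1:25) {
    s <- paste(sample(AA_ALPHABET, 29, replace = TRUE), collapse = "")
    rec <- protein_record("rand", s)
    for (p in pats)
      expect_equal(score_window(rec, 1L, p)$score,
                   oracle_window_score(s, 1L, p))
  }
  expect_error(score_window(polyA, 5L, pats$type1), "out of range")
})

test_that("score is invariant at unconstrained positions and monotone at constrained ones", {
  pats <- default_type_patterns()
  p <- pats$type1
  base <- perfect_repeat(p)
  set.seed(7)
  for (i in 1:20) {
    ch <- strsplit(base, "")[[1]]
    # mutate a random unconstrained position: score unchanged
    j <- sample(which(!p$constrained), 1L)
    ch[j] <- sample(AA_ALPHABET, 1L)
    expect_equal(score_window(protein_record("m", paste(ch, collapse = "")),
                              1L, p)$score, 1.0)
    # mutate a matching constrained position to a non-member: score drops
    k <- sample(which(p$constrained), 1L)
    ch2 <- strsplit(base, "")[[1]]
    ch2[k] <- setdiff(AA_ALPHABET, p$sets[[k]])[1L]
    expect_lt(score_window(protein_record("m", paste(ch2, collapse = "")),
                           1L, p)$score, 1.0)
  }
})

test_that("required-position mismatches set the hard-fail flag", {
  p <- compile_pattern(paste0("LxxLxLxxNxL", strrep("x", 17)), "req",
                       required = 9L)
  ch <- strsplit(perfect_repeat(p), "")[[1]]
  ch[9] <- "A"
  w <- score_window(protein_record("h", paste(ch, collapse = "")), 1L, p)
  expect_true(w$hard_fail)
  expect_lt(w$score, 1)
})

test_that("vectorized scan equals the brute-force per-start oracle (<= 200 aa)", {
  pats <- default_type_patterns()
  set.seed(11)
  for (i in 1:3) {
    # random background plus two planted repeats, so both regimes occur
    s <- paste(sample(AA_ALPHABET, 140, replace = TRUE), collapse = "")
    s <- paste0(substr(s, 1, 60), perfect_repeat(pats$type1),
                perfect_repeat(pats$type2), substr(s, 61, 140))
    rec <- protein_record("scan", s)
    for (t in c(0.4, 0.6, 0.8)) {
      got <- scan_windows(rec, pats, min_score = t)
      want <- oracle_scan(rec, pats, min_score = t)
      expect_equal(got$start, want$start)
      expect_equal(got$type, want$type)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("window classification picks the best type and applies tie-breaks", {
  pats <- default_type_patterns()
  rec1 <- protein_record("t1", perfect_repeat(pats$type1))
  expect_equal(classify_window(rec1, 1L, pats), "type1")

  polyA <- protein_record("a", strrep("A", 29))
  expect_true(is.na(classify_window(polyA, 1L, pats)))

  # exact tie between two same-length patterns: context forces alternation,
  # no context prefers the first pattern
  tie <- list(
    type1 = compile_pattern(paste0("A", strrep("x", 27)), "type1"),
    type2 = compile_pattern(paste0("[AG]", strrep("x", 27)), "type2"))
  recA <- protein_record("tie", strrep("A", 28))
  expect_equal(classify_window(recA, 1L, tie, min_score = 0.5), "type1")
  expect_equal(classify_window(recA, 1L, tie, min_score = 0.5,
                               context = "type1"), "type2")
  expect_equal(classify_window(recA, 1L, tie, min_score = 0.5,
                               context = "type2"), "type1")
})

test_that("pattern rotation reorders columns cyclically and preserves sets", {
  p <- default_type_patterns()$type1
  r <- rotate_pattern(p, 6L)
  expect_equal(r$length, p$length)
  expect_identical(r$sets[[1]], p$sets[[6]])
  expect_identical(r$sets[[p$length]], p$sets[[5]])
  expect_equal(sum(r$constrained), sum(p$constrained))
  expect_identical(rotate_pattern(p, 1L), p)
})
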