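test_that("literal NACHT motifs are found at their anchored coordinates", {
  g <- mimic_fixture()
  hits <- scan_motifs(g$record, nlrc5_motifs())
  wa <- hits[hits$motif == "walker_A", ]
  expect_equal(c(wa$start, wa$end), c(228L, 235L))
  expect_equal(wa$matched, "GKAGMGKT")
  wb <- hits[hits$motif == "walker_B", ]
  expect_equal(c(wb$start, wb$end), c(303L, 313L))
  expect_equal(wb$matched, "LLIFDGLDEAL")
  expect_true(345L %in% hits$start[hits$motif == "sensor_1"])
  expect_true(404L %in% hits$start[hits$motif == "AxP"])
  expect_equal(hits$start[hits$motif == "WH_consensus"], 475L)
  expect_true(residue_identity(g$record, 491L, "H"))
  # generalized class patterns find the planted literal instances
  expect_true(228L %in% hits$start[hits$motif == "walker_A_general"])
  expect_true(303L %in% hits$start[hits$motif == "walker_B_general"])
})

test_that("region-restricted motifs are not reported outside their region", {
  # a TSR outside the NACHT span must be ignored
  rec <- protein_record("r", paste0(strrep("A", 400), "TSR", strrep("A", 30)))
  defs <- list(motif_definition("sensor_1", "literal", "TSR",
                                region = c(198L, 369L)))
  expect_equal(nrow(scan_motifs(rec, defs)), 0L)
})

test_that("poly-alanine yields no hits for any default motif", {
  rec <- protein_record("a", strrep("A", 600))
  expect_equal(nrow(scan_motifs(rec, nlrc5_motifs())), 0L)
})

test_that("every hit re-validates against its own definition", {
  g <- mimic_fixture()
  defs <- nlrc5_motifs()
  names(defs) <- vapply(defs, `[[`, "", "name")
  hits <- scan_motifs(g$record, defs)
  for (i in seq_len(nrow(hits))) {
    expect_equal(hits$matched[i],
                 ifelse(defs[[hits$motif[i]]]$mode == "spacing",
                        hits$matched[i],  # spacing: anchors checked below
                        subseq_residues(g$record, hits$start[i],
                                        hits$end[i])))
    re <- scan_motifs(protein_record("slice",
                                     subseq_residues(g$record, hits$start[i],
                                                     hits$end[i])),
                      local({ d <- defs[[hits$motif[i]]]; d$region <- NULL; d }))
    expect_true(1L %in% re$start)
  }
})

test_that("motif scanning is translation-equivariant", {
  def <- motif_definition("wa", "literal", "GKAGMGKT")
  core <- "GKAGMGKT"
  for (off in c(0L, 7L, 150L)) {
    rec <- protein_record("t", paste0(strrep("P", off), core,
                                      strrep("G", 12)))
    hits <- scan_motifs(rec, def)
    expect_equal(hits$start, off + 1L)
  }
})

test_that("cysteine spacing scanner reproduces the capping-motif arithmetic", {
  # C residues at 648/672/678/685/698 in a Cys-free background
  ch <- rep("A", 720)
  ch[c(648, 672, 678, 685, 698)] <- "C"
  rec <- protein_record("cys", paste(ch, collapse = ""))
  hits <- find_cys_spacing(rec, spacing = c(23L, 5L, 6L, 12L))
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(648L, 698L))
  expect_equal(hits$end - hits$start + 1L, 51L)  # Cx23Cx5Cx6Cx12C span
  expect_equal(hits$detail, "648,672,678,685,698")

  expect_equal(nrow(find_cys_spacing(protein_record("n", strrep("A", 100)))),
               0L)
})

test_that("spacing scanner equals the exhaustive Cys-subset oracle (50 seeds)", {
  spacing <- c(23L, 5L, 6L, 12L)
  set.seed(33)
  for (i in 1:50) {
    ch <- sample(AA_ALPHABET, 300, replace = TRUE)
    at <- sample(1:240, 1L)
    ch[at + cumsum(c(0L, spacing + 1L))] <- "C"
    rec <- protein_record("r", paste(ch, collapse = ""))
    got <- find_cys_spacing(rec, spacing)
    want <- oracle_cys_chains(rec, spacing)
    expect_equal(got[order(got$start, got$end), c("start", "end")],
                 want[, c("start", "end")], ignore_attr = TRUE)
    expect_true(any(got$start == at))
  }
})

test_that("spacing tolerance admits near-miss gaps", {
  ch <- rep("A", 80)
  ch[c(10, 35, 41, 48, 62)] <- "C"   # gaps 24,5,6,13 vs spec 23,5,6,12
  rec <- protein_record("tol", paste(ch, collapse = ""))
  expect_equal(nrow(find_cys_spacing(rec, c(23L, 5L, 6L, 12L))), 0L)
  tol <- find_cys_spacing(rec, c(23L, 5L, 6L, 12L), tolerance = 1L)
  expect_equal(c(tol$start, tol$end), c(10L, 62L))
})

test_that("basic clusters: planted NLS found exactly, maximality collapses runs", {
  ch <- rep("A", 200)
  ch[c(121, 122, 132, 133, 134)] <- c("K", "R", "R", "R", "K")
  rec <- protein_record("nls", paste(ch, collapse = ""))
  hits <- find_basic_cluster(rec, min_basics = 5L, window = 14L)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(121L, 134L))
  expect_equal(hits$n_basic, 5L)

  expect_equal(nrow(find_basic_cluster(protein_record("none",
                                                      strrep("ASDF", 20)))),
               0L)

  polyk <- protein_record("k", paste0(strrep("A", 10), strrep("K", 20),
                                      strrep("A", 10)))
  hk <- find_basic_cluster(polyk)
  expect_equal(nrow(hk), 1L)
  expect_equal(c(hk$start, hk$end), c(11L, 30L))

  g <- mimic_fixture()
  hg <- find_basic_cluster(g$record)
  expect_true(any(hg$start == 121L & hg$end == 134L))
})

test_that("cysteine density reporting counts Cys per window", {
  ch <- rep("A", 60)
  ch[c(5, 10, 15)] <- "C"
  dens <- cys_density(protein_record("d", paste(ch, collapse = "")),
                      window = 20L)
  expect_equal(dens$n_cys[1], 3L)          # window 1..20
  expect_equal(dens$n_cys[nrow(dens)], 0L) # window 41..60
})
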