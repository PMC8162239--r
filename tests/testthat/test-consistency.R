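test_that("residue_at matches direct character indexing", {
  expect_equal(residue_at("MSTY", 2), "S")
  expect_true(is.na(residue_at("MSTY", 9)))
  expect_error(residue_at("MSTY", 0), "position")
  set.seed(2)
  for (i in 1:200) {
    s <- random_aa_seq(sample(5:60, 1))
    p <- sample(1:80, 1)
    expected <- if (p > nchar(s)) NA_character_
                else strsplit(s, "")[[1]][p]
    expect_identical(residue_at(s, p), expected)
  }
})

test_that("nearest_occurrence equals the exhaustive scan oracle, ties included", {
  # deterministic tie case: S at 3 and 7, annotated at 5 -> later wins (-2)
  hit <- nearest_occurrence("AASAAASAAA", "S", 5)
  expect_equal(hit$matched_position, 7)
  expect_equal(hit$signed_offset, -2)
  expect_null(nearest_occurrence("AAAA", "S", 2))

  set.seed(9)
  for (i in 1:2000) {
    s <- random_aa_seq(sample(3:40, 1))
    p <- sample(1:60, 1)
    r <- sample(c("S", "T", "Y", "A"), 1)
    expect_identical(nearest_occurrence(s, r, p), oracle_nearest(s, r, p))
  }
})

test_that("the worked classification examples behave as described", {
  # T annotated at 128 where the canonical has T -> match
  seq1 <- random_aa_seq(200)
  substr(seq1, 128, 128) <- "T"
  rec1 <- sequence_record("P00001", seq1)
  c1 <- classify_site(list(accession = "P00001", residue = "T",
                           position = 128), rec1)
  expect_equal(c1$category, "canonical_match")
  expect_equal(c1$signed_offset, 0L)
  expect_equal(c1$matched_in, "canonical")

  # T annotated at 362 where the canonical has Y -> mismatch
  seq2 <- paste(rep("A", 400), collapse = "")
  substr(seq2, 362, 362) <- "Y"
  rec2 <- sequence_record("P00002", seq2)
  c2 <- classify_site(list(accession = "P00002", residue = "T",
                           position = 362), rec2)
  expect_equal(c2$category, "mismatch")
  expect_true(is.na(c2$signed_offset))

  # S annotated at 495, nearest S at 490 -> offset of magnitude 5, bin "+"
  seq3 <- paste(rep("A", 600), collapse = "")
  substr(seq3, 490, 490) <- "S"
  rec3 <- sequence_record("P00003", seq3)
  c3 <- classify_site(list(accession = "P00003", residue = "S",
                           position = 495), rec3)
  expect_equal(c3$category, "offset")
  expect_equal(abs(c3$signed_offset), 5L)
  expect_equal(c3$matched_position, 490L)
  expect_equal(c3$magnitude_bin, "+")

  # position beyond the canonical length with no isoform -> unmatched
  rec4 <- sequence_record("P00004", paste(rep("S", 400), collapse = ""))
  c4 <- classify_site(list(accession = "P00004", residue = "S",
                           position = 999), rec4)
  expect_equal(c4$category, "unmatched")
  expect_true(is.na(c4$matched_position))
})

test_that("initiator-Met cleavage coordinates give a signed offset of -1", {
  # canonical starts with M; annotation uses Met-cleaved numbering
  canon <- paste0("M", paste(rep("A", 20), collapse = ""))
  substr(canon, 10, 10) <- "S"  # serine at canonical position 10
  rec <- sequence_record("P00001", canon)
  cl <- classify_site(list(accession = "P00001", residue = "S",
                           position = 9), rec)  # Met-cleaved coordinate
  expect_equal(cl$category, "offset")
  expect_equal(cl$signed_offset, -1L)
  expect_equal(cl$magnitude_bin, "1")
})

test_that("isoform search follows the documented precedence", {
  rec <- sequence_record("P00001", "MAAAAAAAAA",
                         isoforms = c("P00001-2" = "MASAAAAAAA",
                                      "P00001-3" = "MASAAAAAAA"))
  # S absent at canonical pos 3 but present in isoform-2 -> isoform match
  cl <- classify_site(list(accession = "P00001", residue = "S",
                           position = 3), rec)
  expect_equal(cl$category, "isoform_match")
  expect_equal(cl$matched_in, "P00001-2")  # first isoform in catalog order

  # canonical mismatch outranks isoform offset when canonical holds T
  rec2 <- sequence_record("P00002", "MATAAAAAAA",
                          isoforms = c("P00002-2" = "MAAAAAAAAS"))
  cl2 <- classify_site(list(accession = "P00002", residue = "S",
                            position = 3), rec2)
  expect_equal(cl2$category, "mismatch")
  expect_equal(cl2$matched_in, "canonical")

  # residue wholly absent from canonical: isoform offset is reachable
  rec3 <- sequence_record("P00003", "MAAAAAAAAA",
                          isoforms = c("P00003-2" = "MAAAAAAAAS"))
  cl3 <- classify_site(list(accession = "P00003", residue = "S",
                            position = 3), rec3)
  expect_equal(cl3$category, "offset")
  expect_equal(cl3$matched_in, "P00003-2")
  expect_equal(cl3$matched_position, 10L)

  # beyond canonical length but within a matching isoform -> isoform match
  rec4 <- sequence_record("P00004", "MAAA",
                          isoforms = c("P00004-2" = "MAAAAAAAS"))
  cl4 <- classify_site(list(accession = "P00004", residue = "S",
                            position = 9), rec4)
  expect_equal(cl4$category, "isoform_match")
})

test_that("non-phosphorylatable occupants fall through to offset, and the residue set is configurable", {
  rec <- sequence_record("P00001", "MAKSAAAAAA")
  # K occupies position 3 (not phospho) and S sits at 4 -> offset -1
  cl <- classify_site(list(accession = "P00001", residue = "S",
                           position = 3), rec)
  expect_equal(cl$category, "offset")
  expect_equal(cl$signed_offset, -1L)
  # with histidine added, an H occupant becomes a mismatch
  rec2 <- sequence_record("P00002", "MAHSAAAAAA")
  cl2 <- classify_site(list(accession = "P00002", residue = "S", position = 3),
                       rec2, residues = phospho_residues(c("S", "T", "Y", "H")))
  expect_equal(cl2$category, "mismatch")
})

test_that("summaries partition sites and exclude isoform matches from the consistent numerator", {
  spec <- synthetic_spec(seed = 42, n_proteins = 150L,
                         category_counts = list(
                           canonical_match = 60L, isoform_match = 10L,
                           mismatch = 5L, offsets = c(1L, -2L, 3L, 7L),
                           unmatched = 5L))
  gen <- make_catalog(spec)
  planted <- plant_sites(gen$catalog, spec$category_counts, seed = 42)
  cls <- classify_sites(planted$set, planted$catalog)
  s <- summarize_consistency(cls)
  expect_equal(s$n_sites, 84L)
  expect_equal(s$n_consistent, 60L)
  expect_equal(s$n_isoform, 10L)
  expect_equal(s$n_mismatch, 5L)
  expect_equal(s$offset_histogram, c("1" = 1L, "2" = 1L, "3" = 1L, "+" = 1L))
  expect_equal(s$n_unmatched, 5L)
  expect_equal(s$pct_consistent, 60 / 84)
  expect_equal(s$n_consistent + s$n_isoform + s$n_mismatch +
                 sum(s$offset_histogram) + s$n_unmatched, s$n_sites)

  empty <- summarize_consistency(cls[0, ])
  expect_equal(empty$n_sites, 0L)
  expect_equal(empty$pct_consistent, 0)
})

test_that("extending a canonical sequence never disturbs in-range classifications", {
  # the appended tail must not introduce a nearer occurrence of the annotated
  # residue, so it is drawn from the other letters
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(6)
  for (i in 1:25) {
    canon <- random_aa_seq(60)
    rec <- sequence_record("P00001", canon)
    res <- sample(c("S", "T", "Y"), 1)
    pos <- sample(1:60, 1)
    before <- classify_site(list(accession = "P00001", residue = res,
                                 position = pos), rec)
    tail_seq <- paste(sample(setdiff(aa, res), 20, replace = TRUE),
                      collapse = "")
    rec2 <- sequence_record("P00001", paste0(canon, tail_seq))
    after <- classify_site(list(accession = "P00001", residue = res,
                                position = pos), rec2)
    expect_equal(after$category, before$category)
    expect_equal(after$signed_offset, before$signed_offset)
  }
})
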