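make_records <- function(rows, pmid_samples) {
  experimental_records(rows, pmid_samples)
}

test_that("single-sample filtering works at PMID granularity and conserves records", {
  rows <- data.frame(
    accession = c("P00001", "P00001", "P00002", "P00003"),
    residue = "S", position = c(10L, 20L, 5L, 7L),
    pmid = c("1", "1", "2", "3"), stringsAsFactors = FALSE)
  rec <- make_records(rows, list(`1` = "HeLa", `2` = c("HeLa", "MCF-7"),
                                 `3` = "Jurkat"))
  flt <- filter_single_sample(rec)
  expect_setequal(names(flt$kept$pmid_samples), c("1", "3"))
  expect_setequal(names(flt$excluded$pmid_samples), "2")
  expect_equal(nrow(flt$kept$records) + nrow(flt$excluded$records),
               nrow(rec$records))

  set.seed(13)
  for (rep in 1:10) {
    n_pmid <- sample(5:20, 1)
    pm <- as.character(seq_len(n_pmid))
    labels <- c("a", "b", "c")
    ps <- lapply(pm, function(p) sample(labels, sample(1:3, 1)))
    names(ps) <- pm
    rows <- data.frame(accession = sprintf("P%05d", sample(1:30, 40,
                                                           replace = TRUE)),
                       residue = "S",
                       position = sample(1:99, 40, replace = TRUE),
                       pmid = sample(pm, 40, replace = TRUE),
                       stringsAsFactors = FALSE)
    rec <- make_records(rows, ps)
    flt <- filter_single_sample(rec)
    expect_equal(nrow(flt$kept$records) + nrow(flt$excluded$records),
                 nrow(rec$records))
    expect_true(all(lengths(flt$kept$pmid_samples) == 1L))
    expect_true(all(lengths(flt$excluded$pmid_samples) > 1L))
  }
})

test_that("samples rank by distinct publication count with name tie-break", {
  rows <- data.frame(accession = "P00001", residue = "S", position = 1L,
                     pmid = as.character(1:10), stringsAsFactors = FALSE)
  ps <- as.list(c(rep("HeLa", 5), rep("MCF-7", 2), rep("Jurkat", 2), "A549"))
  names(ps) <- as.character(1:10)
  rec <- make_records(rows, ps)
  rk <- rank_samples(rec)
  expect_equal(rk$sample, c("HeLa", "Jurkat", "MCF-7", "A549"))
  expect_equal(rk$n_pmids, c(5L, 2L, 2L, 1L))

  # brute-force distinct-PMID tally oracle on a random table
  set.seed(21)
  pm <- as.character(1:30)
  ps <- as.list(sample(c("x", "y", "z"), 30, replace = TRUE))
  names(ps) <- pm
  rows <- data.frame(accession = "P00001", residue = "S",
                     position = sample(1:200, 60, replace = TRUE),
                     pmid = sample(pm, 60, replace = TRUE),
                     stringsAsFactors = FALSE)
  rec <- make_records(rows, ps)
  rk <- rank_samples(rec)
  tally <- sapply(c("x", "y", "z"), function(s) {
    length(unique(names(ps)[unlist(ps) == s]))
  })
  tally <- sort(tally, decreasing = TRUE)
  expect_equal(structure(rk$n_pmids, names = rk$sample)[names(tally)], tally)
  # multi-sample PMIDs are refused
  ps$`1` <- c("x", "y")
  expect_error(rank_samples(make_records(rows, ps)), "single-sample")
})

test_that("sample coverage distinguishes protein-level from site-level hits", {
  rows <- data.frame(accession = c("P00001", "P00002"), residue = "S",
                     position = c(10L, 30L), pmid = c("1", "1"),
                     stringsAsFactors = FALSE)
  rec <- make_records(rows, list(`1` = "HeLa"))
  # database shares the proteins but only one exact site triple
  db <- annotation_set("db", proteins = c("P00001", "P00002"),
                       sites = site_table(c("P00001", "P00002"), "S",
                                          c(10L, 99L)))
  prot <- sample_coverage(rec, list(db), "protein")
  site <- sample_coverage(rec, list(db), "site")
  expect_equal(prot$count["HeLa", "db"], 2L)
  expect_equal(prot$proportion["HeLa", "db"], 1.0)
  expect_equal(site$count["HeLa", "db"], 1L)   # same protein, other position
  expect_equal(site$proportion["HeLa", "db"], 0.5)
  expect_true(prot$proportion["HeLa", "db"] >= site$proportion["HeLa", "db"])
})

test_that("planted per-sample overlap fractions are recovered exactly", {
  # two samples with disjoint measured sites; the database holds a known
  # fraction of each sample's set
  set.seed(7)
  s1 <- site_table(sprintf("P%05d", 1:40), "S", rep(10L, 40))
  s2 <- site_table(sprintf("P%05d", 41:60), "T", rep(20L, 20))
  rows <- rbind(cbind(s1, pmid = "1"), cbind(s2, pmid = "2"))
  rec <- make_records(rows, list(`1` = "HeLa", `2` = "Jurkat"))
  db_sites <- rbind(s1[1:10, ], s2[1:15, ])  # 25% of HeLa, 75% of Jurkat
  db <- annotation_set("db", proteins = unique(db_sites$accession),
                       sites = db_sites)
  cov <- sample_coverage(rec, list(db), "site")
  expect_equal(cov$proportion["HeLa", "db"], 0.25)
  expect_equal(cov$proportion["Jurkat", "db"], 0.75)

  # record order never matters
  perm <- rows[sample(nrow(rows)), ]
  cov2 <- sample_coverage(make_records(perm, list(`1` = "HeLa",
                                                  `2` = "Jurkat")),
                          list(db), "site")
  expect_identical(cov2$count, cov$count)
})

test_that("generated experimental tables recover planted single-sample structure", {
  pool <- site_table(sprintf("P%05d", 1:50), "S", sample(1:300, 50))
  samples <- list(labels = c("HeLa", "MCF-7", "Jurkat"),
                  pmids_per_sample = c(40L, 35L, 25L),
                  sites_per_pmid = 5L, multi_sample_fraction = 0.3)
  gen <- make_experimental(samples, pool, seed = 11)
  expect_length(gen$truth$multi_pmids, round(0.3 * 100))
  flt <- filter_single_sample(gen$records)
  expect_setequal(names(flt$kept$pmid_samples), gen$truth$single_pmids)
  expect_setequal(names(flt$excluded$pmid_samples), gen$truth$multi_pmids)

  none <- make_experimental(modifyList(samples,
                                       list(multi_sample_fraction = 0)),
                            pool, seed = 11)
  expect_length(filter_single_sample(none$records)$excluded$pmid_samples, 0L)
  all_multi <- make_experimental(modifyList(samples,
                                            list(multi_sample_fraction = 1)),
                                 pool, seed = 11)
  expect_length(filter_single_sample(all_multi$records)$kept$pmid_samples, 0L)
})
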