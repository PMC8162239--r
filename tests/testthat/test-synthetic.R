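small_counts <- function(offsets = c(-1L, 5L)) {
  list(canonical_match = 5L, isoform_match = 3L, mismatch = 2L,
       offsets = offsets, unmatched = 2L)
}

test_that("catalog generation is deterministic and honours planted fractions", {
  spec <- synthetic_spec(seed = 3, n_proteins = 200L,
                         category_counts = small_counts())
  g1 <- make_catalog(spec)
  g2 <- make_catalog(spec)
  expect_identical(g1, g2)
  expect_length(g1$catalog$records, 200L + round(0.05 * 200))
  expect_length(g1$catalog$secondary_to_primary, round(0.10 * 200))
  expect_length(g1$catalog$obsolete, round(0.05 * 200))
  expect_identical(validate_catalog(g1$catalog), g1$catalog)

  empty <- make_catalog(synthetic_spec(seed = 1, n_proteins = 0L,
                                       category_counts = list(
                                         canonical_match = 0L,
                                         isoform_match = 0L, mismatch = 0L,
                                         offsets = integer(),
                                         unmatched = 0L)))
  expect_length(empty$catalog$records, 0L)
})

test_that("infeasible specs are refused before generation", {
  expect_error(synthetic_spec(seed = 1, length_range = c(50L, 60L),
                              category_counts = list(canonical_match = 1L,
                                                     isoform_match = 0L,
                                                     mismatch = 0L,
                                                     offsets = c(70L),
                                                     unmatched = 0L)),
               "offset magnitude")
  expect_error(synthetic_spec(seed = 1, n_proteins = 3L,
                              category_counts = small_counts()),
               "exceed available records")
  expect_error(synthetic_spec(), "seed is mandatory")
})

test_that("planting only matches yields only canonical matches", {
  spec <- synthetic_spec(seed = 5, n_proteins = 20L,
                         category_counts = list(canonical_match = 5L,
                                                isoform_match = 0L,
                                                mismatch = 0L,
                                                offsets = integer(),
                                                unmatched = 0L))
  gen <- make_catalog(spec)
  planted <- plant_sites(gen$catalog, spec$category_counts, seed = 5)
  cls <- classify_sites(planted$set, planted$catalog)
  expect_equal(cls$category, rep("canonical_match", 5))
})

test_that("planted signed offsets are recovered exactly, including -1 and +5", {
  spec <- synthetic_spec(seed = 8, n_proteins = 30L,
                         category_counts = list(canonical_match = 0L,
                                                isoform_match = 0L,
                                                mismatch = 0L,
                                                offsets = c(-1L, 5L),
                                                unmatched = 0L))
  gen <- make_catalog(spec)
  planted <- plant_sites(gen$catalog, spec$category_counts, seed = 8)
  cls <- classify_sites(planted$set, planted$catalog)
  expect_setequal(cls$signed_offset, c(-1L, 5L))
  expect_equal(cls$category, rep("offset", 2))
})

test_that("a full mixed plant is recovered category by category for several seeds", {
  for (seed in c(1L, 42L, 202L)) {
    spec <- synthetic_spec(seed = seed, n_proteins = 150L,
                           category_counts = list(
                             canonical_match = 60L, isoform_match = 10L,
                             mismatch = 5L,
                             offsets = c(1L, -2L, 3L, 7L, rep(-1L, 4)),
                             unmatched = 5L))
    gen <- make_catalog(spec)
    planted <- plant_sites(gen$catalog, spec$category_counts, seed = seed + 1L)
    cls <- classify_sites(planted$set, planted$catalog)
    key <- function(df) paste(df$accession, df$residue, df$position)
    truth <- planted$truth[match(key(cls), key(planted$truth)), ]
    expect_equal(cls$category, truth$category)
    off <- cls$category == "offset"
    expect_equal(cls$signed_offset[off], truth$signed_offset[off])
  }
})

test_that("membership generation round-trips through exclusive intersections", {
  vec <- c(A = 3L, "A&B" = 2L)
  gen <- make_membership(c("A", "B"), vec, seed = 2)
  expect_length(gen$sets$A, 5L)
  expect_length(gen$sets$B, 2L)
  expect_length(unique_elements("A", gen$sets), 3L)

  empty <- make_membership(c("A", "B"), integer(), seed = 2)
  expect_equal(lengths(empty$sets), c(A = 0L, B = 0L))

  set.seed(33)
  nm <- paste0("s", 1:5)
  for (rep in 1:5) {
    sigs <- sapply(1:6, function(i) {
      paste(sample(nm, sample(1:5, 1)), collapse = "&")
    })
    vec <- structure(sample(0:9, length(sigs), replace = TRUE), names = sigs)
    vec <- vec[!duplicated(vapply(strsplit(sigs, "&"), function(s)
      paste(sort(s), collapse = "&"), character(1)))]
    gen <- make_membership(nm, vec, seed = rep)
    got <- exclusive_intersections(gen$sets)
    canon <- vapply(strsplit(names(vec), "&", fixed = TRUE), function(s)
      paste(nm[sort(match(s, nm))], collapse = "&"), character(1))
    want <- structure(as.integer(vec), names = canon)
    want <- want[want > 0]
    expect_setequal(got$signature, names(want))
    expect_equal(structure(got$count, names = got$signature)[names(want)],
                 want)
  }
})

test_that("simulate_study writes a complete, re-readable study", {
  spec <- synthetic_spec(seed = 6, n_proteins = 120L,
                         category_counts = small_counts())
  dir <- withr::local_tempdir()
  sim <- simulate_study(spec, dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  cat2 <- read_catalog(sim$paths$fasta, sim$paths$ids)
  expect_identical(cat2, sim$catalog)
  sites <- read_annotation_set(sim$paths$sites, "planted")
  expect_identical(sites$sites, sim$planted$set$sites)
  rec <- read_experimental(sim$paths$experimental)
  attr(rec, "rejects") <- NULL
  expect_identical(rec, sim$experimental$records)
  truth <- jsonlite::fromJSON(sim$paths$truth)
  expect_equal(sort(names(truth)),
               sort(c("identifier", "sites", "membership",
                      "membership_vector", "experimental")))
})
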