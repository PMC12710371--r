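test_that("feature_table validates counts and ids", {
  m <- matrix(c(3, 1, 0, 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ft <- feature_table(m)
  expect_s3_class(ft, "feature_table")
  expect_equal(colSums(ft$counts), c(s1 = 4, s2 = 2))

  m_neg <- m; m_neg[2, 1] <- -1
  expect_error(feature_table(m_neg), "negative or non-integral.*'b'.*'s1'")
  m_frac <- m; m_frac[1, 2] <- 1.5
  expect_error(feature_table(m_frac), "non-integral")
  m_dup <- m; rownames(m_dup) <- c("a", "a")
  expect_error(feature_table(m_dup), "duplicate taxon ids")
})

test_that("feature-table TSV reads back and round-trips", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t3\t0", "b\t1\t2"), tsv)
  ft <- read_feature_table(tsv, "tsv")
  expect_equal(unname(colSums(ft$counts)), c(4, 2))

  for (i in 1:3) {
    ft0 <- rand_ft(6, 4)
    path <- tempfile(fileext = ".tsv")
    write_feature_table(ft0, path)
    ft1 <- read_feature_table(path, "tsv")
    expect_equal(ft1$counts, ft0$counts)
  }
})

test_that("BIOM 1.0 JSON (sparse and dense) is read through biomformat", {
  rows <- list(list(id = "taxA", metadata = NULL),
               list(id = "taxB", metadata = NULL))
  cols <- list(list(id = "s1", metadata = NULL),
               list(id = "s2", metadata = NULL))
  base <- list(id = "fixture", format = "Biological Observation Matrix 1.0.0",
               format_url = "http://biom-format.org",
               type = "OTU table", generated_by = "test",
               date = "2026-01-01T00:00:00",
               matrix_element_type = "int", shape = c(2, 2))
  sparse <- c(base, list(matrix_type = "sparse",
                         data = list(c(0, 0, 5)),
                         rows = rows, columns = cols))
  f1 <- tempfile(fileext = ".biom")
  jsonlite::write_json(sparse, f1, auto_unbox = TRUE, digits = NA)
  ft <- read_feature_table(f1, "biom_json")
  expect_equal(ft$counts["taxA", "s1"], 5)
  expect_equal(sum(ft$counts), 5)

  dense <- c(base, list(matrix_type = "dense",
                        data = list(c(5, 0), c(1, 2)),
                        rows = rows, columns = cols))
  f2 <- tempfile(fileext = ".biom")
  jsonlite::write_json(dense, f2, auto_unbox = TRUE, digits = NA)
  ft2 <- read_feature_table(f2, "biom_json")
  expect_equal(unname(ft2$counts),
               matrix(c(5, 1, 0, 2), 2, 2))
})

test_that("metadata reader validates levels and pairing invariants", {
  path <- tempfile(fileext = ".tsv")
  df <- rbind(stub_meta(c("p1D", "p2D"), "DNA", c("p1", "p2")),
              stub_meta(c("p1R", "p2R"), "RNA", c("p1", "p2")))
  df$extra <- letters[1:4]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- read_metadata(path)
  expect_equal(nrow(md), 4)
  expect_equal(length(unique(md$pair_id)), 2)
  expect_true(is.ordered(md$season))
  expect_equal(md$extra, letters[1:4])  # opaque covariates preserved

  bad <- df; bad$season[1] <- "July"
  expect_error(as_sample_metadata(bad), "July.*June, August, October")
  two_rna <- df; two_rna$assay <- c("RNA", "DNA", "RNA", "RNA")
  expect_error(as_sample_metadata(two_rna), "more than one library")
  dup <- df; dup$sample_id[2] <- "p1D"
  expect_error(as_sample_metadata(dup), "duplicate sample id")
  missing_col <- df[, setdiff(names(df), "pair_id")]
  expect_error(as_sample_metadata(missing_col), "pair_id")
})

test_that("QIIME-style #SampleID header is accepted", {
  path <- tempfile(fileext = ".tsv")
  df <- stub_meta(c("x1", "x2"), c("DNA", "RNA"), c("p1", "p1"))
  names(df)[1] <- "#SampleID"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- read_metadata(path)
  expect_equal(md$sample_id, c("x1", "x2"))
})

test_that("align_pairs keeps complete pairs, unions taxa, preserves counts", {
  rna <- matrix(c(1, 2, 0, 3), 2, 2,
                dimnames = list(c("A", "B"), c("r1", "r2")))
  dna <- matrix(c(4, 5, 6, 7), 2, 2,
                dimnames = list(c("B", "C"), c("d1", "d3")))
  meta <- rbind(stub_meta(c("r1", "r2"), "RNA", c("p1", "p2")),
                stub_meta(c("d1", "d3"), "DNA", c("p1", "p3")))
  pc <- align_pairs(feature_table(rna, assay = "RNA"),
                    feature_table(dna, assay = "DNA"), meta)
  expect_equal(pc$pair_ids, "p1")
  expect_setequal(pc$taxon_universe, c("A", "B", "C"))
  # counts preserved, zero-filled on the union
  expect_equal(pc$active$counts["A", "p1"], 1)
  expect_equal(pc$active$counts["C", "p1"], 0)
  expect_equal(pc$total$counts["C", "p1"], 5)
  expect_equal(sum(pc$active$counts), sum(rna[, "r1"]))
  expect_equal(sum(pc$total$counts), sum(dna[, "d1"]))

  meta_disjoint <- rbind(stub_meta("r1", "RNA", "p1"),
                         stub_meta("d1", "DNA", "p9"))
  expect_error(align_pairs(
    feature_table(rna[, 1, drop = FALSE], assay = "RNA"),
    feature_table(dna[, 1, drop = FALSE], assay = "DNA"),
    meta_disjoint), "no pair_id")
})

test_that("align_pairs output columns are keyed identically by pair id", {
  set.seed(42)
  dna <- rand_counts(8, 5)
  rna <- rand_counts(8, 5)
  colnames(dna) <- colnames(rna) <- sprintf("p%d", 1:5)
  pc <- make_pc(dna, rna)
  expect_identical(colnames(pc$active$counts), colnames(pc$total$counts))
  expect_identical(colnames(pc$active$counts), pc$pair_ids)
})

test_that("distance matrices and reports round-trip", {
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  d <- as.matrix(dist(pts))
  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  d2 <- read_distance_matrix(path)
  expect_equal(d2, validate_distance_matrix(d), tolerance = 1e-12)

  rpt <- tempfile(fileext = ".json")
  write_report(list(a = 1, ids = c("x", "y")), rpt)
  back <- jsonlite::read_json(rpt)
  expect_match(back$schema_version, "^paircomm-")
  expect_equal(back$content$a, 1)
})

test_that("distance matrix validation catches malformed input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_distance_matrix(m), "not symmetric")
  m2 <- matrix(c(0.5, 1, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_distance_matrix(m2), "diagonal")
})
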