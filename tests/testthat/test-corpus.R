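# Ingestion, validation, de-duplication, class-1 filtering, and
# regulation classification.

write_record_file <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

two_file_fixture <- function() {
  man <- make_manifest(c("d1", "d2"), dtype = c("profile", "differential"))
  f1 <- write_record_file(rbind(
    rec_row("d1", "P1", 31, loc_prob = 0.8),
    rec_row("d1", "P1", 944, loc_prob = 0.95),
    rec_row("d1", "P2", 12, loc_prob = 0.9)))
  f2 <- write_record_file(rbind(
    rec_row("d2", "P1", 31, fold_change = 2.0, p_value = 0.01),
    rec_row("d2", "P2", 12, fold_change = 0.5, p_value = 0.02)))
  mf <- write_record_file(man)
  list(records = c(f1, f2), manifest = mf)
}

test_that("ingestion conserves row counts and keeps manifest metadata", {
  fx <- two_file_fixture()
  cc <- read_corpus(fx$records, fx$manifest)
  expect_s3_class(cc, "phospho_corpus")
  expect_equal(nrow(cc$records), 5L)
  expect_equal(nrow(cc$manifest), 2L)
  rep <- ingest_report(cc)
  expect_equal(rep$total_rows, 5L)
  expect_equal(rep$total_accepted, 5L)
  expect_equal(rep$total_rejected, 0L)
  for (f in names(rep$files)) {
    with(rep$files[[f]], expect_equal(accepted + rejected, rows))
  }
  # manifest is authoritative for dataset metadata
  expect_true(all(cc$records$dtype[cc$records$dataset_id == "d1"] ==
                    "profile"))
})

test_that("rows violating type invariants are rejected and counted", {
  man <- write_record_file(make_manifest("d1", dtype = "profile"))
  bad <- rbind(
    rec_row("d1", "P1", 31, loc_prob = 0.8),
    rec_row("d1", "P1", 0, loc_prob = 0.8),          # position 0
    rec_row("d1", "P1", 40, residue = "A"),           # not S/T/Y
    rec_row("d1", "P1", 50, loc_prob = 1.5),          # loc_prob > 1
    rec_row("d1", "P1", 60, peptide = "AASPK", mod_offset = 2))  # A at 2
  f <- write_record_file(bad)
  cc <- read_corpus(f, man)
  rep <- ingest_report(cc)
  expect_equal(nrow(cc$records), 1L)
  expect_equal(rep$total_rejected, 4L)
  expect_equal(rep$total_accepted + rep$total_rejected, 5L)
  reasons <- rep$files[[f]]$reasons
  expect_true("malformed_position" %in% names(reasons))
  expect_true("malformed_residue" %in% names(reasons))
  expect_true("loc_prob_out_of_range" %in% names(reasons))
  expect_true("mod_offset_not_on_STY" %in% names(reasons))
})

test_that("a record referencing an unknown dataset is an ingestion error", {
  man <- write_record_file(make_manifest("d1", dtype = "profile"))
  f <- write_record_file(rec_row("dX", "P1", 31, loc_prob = 0.8))
  expect_error(read_corpus(f, man), "dX")
})

test_that("sequence-aware validation rejects residue mismatches", {
  man <- write_record_file(make_manifest("d1", dtype = "profile"))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 test protein", "MASTKSY"), fa)
  f <- write_record_file(rbind(
    rec_row("d1", "P1", 4, residue = "T", loc_prob = 0.9),   # T at 4: ok
    rec_row("d1", "P1", 3, residue = "T", loc_prob = 0.9),   # S at 3
    rec_row("d1", "P1", 99, residue = "S", loc_prob = 0.9))) # beyond end
  cc <- read_corpus(f, man, fasta_path = fa)
  expect_equal(nrow(cc$records), 1L)
  reasons <- ingest_report(cc)$files[[f]]$reasons
  expect_equal(reasons$residue_sequence_mismatch, 1L)
  expect_equal(reasons$position_beyond_sequence, 1L)
})

test_that("duplicate site-in-dataset records collapse to one vote", {
  man <- write_record_file(make_manifest(c("d1", "d2")))
  f <- write_record_file(rbind(
    # agreeing duplicates: keep extreme fold change
    rec_row("d1", "P1", 31, fold_change = 1.5, p_value = 0.01),
    rec_row("d1", "P1", 31, fold_change = 2.5, p_value = 0.02),
    # conflicting directions: unregulated in that dataset
    rec_row("d2", "P1", 31, fold_change = 2.0, p_value = 0.01),
    rec_row("d2", "P1", 31, fold_change = 0.5, p_value = 0.01)))
  cc <- read_corpus(f, man)
  expect_equal(nrow(cc$records), 2L)
  r1 <- cc$records[cc$records$dataset_id == "d1", ]
  expect_equal(r1$fold_change, 2.5)
  r2 <- cc$records[cc$records$dataset_id == "d2", ]
  expect_equal(classify_regulation(r2$fold_change, r2$p_value),
               "unregulated")
  expect_equal(ingest_report(cc)$n_deduplicated, 2L)
})

test_that("log2 fold-change input converts to linear ratios on read", {
  man <- write_record_file(make_manifest("d1"))
  f <- write_record_file(rec_row("d1", "P1", 31, fold_change = 1,
                                 p_value = 0.01))
  cc <- read_corpus(f, man, log2_fc = TRUE)
  expect_equal(cc$records$fold_change, 2)
})

test_that("canonical write/read round trip is byte-stable", {
  fx <- two_file_fixture()
  cc <- read_corpus(fx$records, fx$manifest)
  s1 <- write_corpus_string(cc)
  path <- tempfile(fileext = ".tsv")
  writeLines(s1, path)
  cc2 <- read_corpus(path, fx$manifest)
  expect_identical(write_corpus_string(cc2), s1)
  expect_equal(cc2$records, cc$records)
})

test_that("class-1 filter keeps any-passing-metric records and is idempotent", {
  man <- make_manifest("d1", dtype = "profile")
  rec <- rbind(
    rec_row("d1", "P1", 10, loc_prob = 0.80, ascore = 15),  # both pass
    rec_row("d1", "P1", 20, loc_prob = 0.75, ascore = NA),  # boundary
    rec_row("d1", "P1", 30, loc_prob = 0.60, ascore = 12),  # both fail
    rec_row("d1", "P1", 40, loc_prob = NA, ascore = 13),    # ascore only
    rec_row("d1", "P1", 50, loc_prob = NA, ascore = NA))    # no metric
  cc <- corpus(rec, man)
  f1 <- filter_class1(cc)
  expect_setequal(f1$records$position, c(10L, 20L, 40L))
  expect_identical(filter_class1(f1)$records, f1$records)
  expect_equal(nrow(f1$manifest), 1L)
  strict <- filter_class1(cc, mode = "both")
  expect_equal(strict$records$position, 10L)
})

test_that("regulation thresholds are inclusive on fold change, strict on p", {
  expect_equal(classify_regulation(1.3, 0.04), "up")
  expect_equal(classify_regulation(0.76, 0.01), "down")
  expect_equal(classify_regulation(2.0, 0.06), "unregulated")
  expect_equal(classify_regulation(2.0, 0.05), "unregulated")
  expect_equal(classify_regulation(1.29, 0.01), "unregulated")
  expect_equal(classify_regulation(0.77, 0.01), "unregulated")
  expect_equal(classify_regulation(NA, 0.01), "unregulated")
  expect_equal(classify_regulation(2.0, NA), "unregulated")
})

test_that("classification partitions fold-change/p space into one label", {
  set.seed(11)
  fc <- exp(rnorm(500, 0, 1))
  p <- runif(500)
  lab <- classify_regulation(fc, p)
  expect_true(all(lab %in% c("up", "down", "unregulated")))
  # up and down mutually exclusive since down_fc < up_fc
  expect_false(any(lab == "up" & fc <= 0.76))
  expect_false(any(lab == "down" & fc >= 1.3))
})

test_that("corpus constructor enforces closed vocabularies", {
  man <- make_manifest("d1")
  man$dtype <- "proteomic"
  expect_error(corpus(rec_row("d1", "P1", 1, fold_change = 2,
                              p_value = 0.01), man),
               "dtype")
  man2 <- make_manifest(c("d1", "d1"))
  expect_error(corpus(rec_row("d1", "P1", 1, fold_change = 2,
                              p_value = 0.01), man2),
               "duplicated dataset_id")
})
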