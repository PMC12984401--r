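# Pair counting, the one-sided FET, ratio statistics, confidence
# filters, and the full co-regulation run.

test_that("pair counts enumerate joint directions over co-detected datasets", {
  cc <- dir_corpus(list(
    d1 = c(A = "U", B = "U"),
    d2 = c(A = "U", B = "D"),
    d3 = c(A = "D", B = "D"),
    d4 = c(A = "D")),
    positions = c(A = 10, B = 20))
  counts <- pair_counts(cc, "A_S10", "B_S20")
  expect_equal(unclass(counts)[c("nUU", "nUD", "nDD", "nDU")],
               c(nUU = 1L, nUD = 1L, nDD = 1L, nDU = 0L))
})

test_that("a never-detected candidate and perfect concordance behave as stated", {
  cc <- dir_corpus(list(
    d1 = c(A = "U", B = "U", C = "0"),
    d2 = c(A = "U", B = "U"),
    d3 = c(A = "U", B = "U")),
    positions = c(A = 10, B = 20, C = 30))
  expect_equal(sum(unclass(pair_counts(cc, "A_S10", "C_S30"))), 0L)
  counts <- pair_counts(cc, "A_S10", "B_S20")
  expect_equal(counts[["nUU"]], 3L)
  expect_equal(sum(unclass(counts)), 3L)
})

test_that("one-sided FET equals closed-form hypergeometric values", {
  expect_equal(fisher_exact_one_sided(coreg_counts(nUU = 3, nDD = 3)),
               1 / choose(6, 3))
  expect_equal(fisher_exact_one_sided(coreg_counts(nUU = 5, nDD = 5)),
               1 / choose(10, 5))
  expect_equal(fisher_exact_one_sided(coreg_counts()), 1.0)
})

test_that("one-sided FET agrees with stats::fisher.test across random tables", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(0:8, 4, replace = TRUE)
    counts <- coreg_counts(nUU = n[1], nDD = n[2], nUD = n[3],
                           nDU = n[4])
    tab <- matrix(c(n[1], n[4], n[3], n[2]), 2)  # [[nUU,nUD],[nDU,nDD]]
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_one_sided(counts),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_one_sided(counts, "discordance"),
                 stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("co-regulation ratios flag zero denominators and empty tables", {
  r <- coreg_ratios(coreg_counts(nUU = 4, nDD = 2, nUD = 1, nDU = 1))
  expect_equal(r$ratio_pos, 3.0)
  expect_equal(r$ratio_neg, 1 / 3)
  expect_identical(coreg_ratios(coreg_counts(nUU = 3, nDD = 1))$ratio_pos,
                   Inf)
  expect_true(is.nan(coreg_ratios(coreg_counts())$ratio_pos))
})

test_that("the joint confidence filter gates classification", {
  counts <- coreg_counts(nUU = 5, nDD = 3, nUD = 1)
  base <- list(counts = counts, fet_p = 0.01, pmid = 4L, exp = 5L,
               freq = 40L)
  expect_equal(classify_cpp(counts, 0.01, 4, 5, 40), "positive")
  # dominant count 3 fails 10% of 40
  expect_equal(classify_cpp(coreg_counts(nUU = 3), 0.01, 4, 5, 40),
               "none")
  # PMID confidence below 3
  expect_equal(classify_cpp(counts, 0.01, 2, 5, 40), "none")
  # expcode confidence below 3
  expect_equal(classify_cpp(counts, 0.01, 4, 2, 40), "none")
  # FET not significant
  expect_equal(classify_cpp(counts, 0.2, 4, 5, 40), "none")
  # tie between n_pos and n_neg
  expect_equal(classify_cpp(coreg_counts(nUU = 4, nUD = 4), 0.01, 4, 5,
                            40), "none")
  # negative side is symmetric
  expect_equal(classify_cpp(coreg_counts(nUD = 5, nDU = 3, nUU = 1),
                            0.01, 4, 5, 40), "negative")
  expect_error(classify_cpp(counts, 0.01, 4, 5, 0), "anchor_diff_freq")
})

test_that("raising the anchor frequency never converts none into a call", {
  counts <- coreg_counts(nUU = 5, nDD = 3, nUD = 1)
  freqs <- c(10, 40, 79, 80, 81, 200, 1000)
  calls <- vapply(freqs, function(f) {
    classify_cpp(counts, 0.01, 4, 5, f)
  }, "")
  # monotone: once none, always none as the frequency grows
  first_none <- match("none", calls)
  if (!is.na(first_none)) {
    expect_true(all(calls[first_none:length(calls)] == "none"))
  }
})

test_that("swapping anchor and candidate transposes but preserves the statistics", {
  for (seed in 1:10) {
    rc <- random_dir_corpus(seed, max_datasets = 25L, max_sites = 6L)
    cc <- rc$corpus
    ab <- pair_counts(cc, "PROT:10", "OTHER:5")
    ba <- pair_counts(cc, "OTHER:5", "PROT:10")
    expect_equal(ab[["nUU"]], ba[["nUU"]])
    expect_equal(ab[["nDD"]], ba[["nDD"]])
    expect_equal(ab[["nUD"]], ba[["nDU"]])
    expect_equal(ab[["nDU"]], ba[["nUD"]])
    expect_equal(ab[["nUU"]] + ab[["nDD"]], ba[["nUU"]] + ba[["nDD"]])
    expect_equal(fisher_exact_one_sided(ab), fisher_exact_one_sided(ba))
  }
})

test_that("a fully concordant planted partner is classified positive", {
  # 12 datasets over 4 PMIDs and 4 experimental codes, partner tracks
  # the anchor perfectly
  dirs <- rep(c("U", "D"), 6)
  datasets <- lapply(seq_len(12), function(i) {
    c(A = dirs[i], B = dirs[i])
  })
  names(datasets) <- sprintf("d%02d", 1:12)
  cc <- dir_corpus(datasets, positions = c(A = 10, B = 20),
                   pmid = rep(sprintf("PM%d", 1:4), each = 3),
                   exp_code = rep(sprintf("EC%d", 1:4), each = 3))
  res <- run_coregulation(cc, "A_S10")
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_pos, 12L)
  expect_equal(res$classification, "positive")
  expect_equal(res$pmid_confidence, 4L)
  expect_equal(res$expcode_confidence, 4L)
})

test_that("an anchor with no differential regulation is an error", {
  man <- make_manifest(c("p1", "d1"), dtype = c("profile", "differential"))
  rec <- rbind(rec_row("p1", "A", 10),
               dir_row("d1", "B", 20, "U"))
  cc <- corpus(rec, man)
  expect_error(run_coregulation(cc, "A_S10"), "site_frequency_table")
})

test_that("same-protein candidates are excluded from CPP results", {
  cc <- dir_corpus(list(
    d1 = c(A = "U", B = "U"),
    d2 = c(A = "U", B = "U")),
    positions = c(A = 10, B = 20))
  # B here is on a different protein; add a same-protein site A2
  cc2 <- augment_corpus(cc, rbind(dir_row("d1", "A", 50, "U"),
                                  dir_row("d2", "A", 50, "U")))
  res <- run_coregulation(cc2, "A_S10")
  expect_false(any(res$cpp_accession == "A"))
})

test_that("pmid and expcode confidence count the dominant category only", {
  # concordant in d1 (PM1/EC1) and d2 (PM2/EC2); discordant in d3..d5
  # sharing PM3/EC3 -> dominant is negative with confidence 1... build
  # the reverse: dominant positive over 3 distinct PMIDs, discordant
  # evidence spread over many PMIDs must not count.
  datasets <- list(
    d1 = c(A = "U", B = "U"), d2 = c(A = "D", B = "D"),
    d3 = c(A = "U", B = "U"), d4 = c(A = "U", B = "D"))
  cc <- dir_corpus(datasets, positions = c(A = 10, B = 20),
                   pmid = c("PM1", "PM2", "PM3", "PM9"),
                   exp_code = c("EC1", "EC2", "EC2", "EC9"))
  res <- run_coregulation(cc, "A_S10")
  i <- which(res$cpp_accession == "B")
  expect_equal(res$n_pos[i], 3L)
  expect_equal(res$pmid_confidence[i], 3L)   # PM1, PM2, PM3
  expect_equal(res$expcode_confidence[i], 2L)  # EC1, EC2
})

test_that("BH correction mode is more conservative than raw p-values", {
  cc <- simulate_corpus(sim_config(seed = 5, n_datasets = 60,
                                   n_background_sites = 80))
  raw <- run_coregulation(cc$corpus, "ANCHOR_S10")
  bh <- run_coregulation(cc$corpus, "ANCHOR_S10",
                         config = coreg_filter_config(p_adjust = "BH"))
  n_calls <- function(x) sum(x$classification != "none")
  expect_lte(n_calls(bh), n_calls(raw))
})
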