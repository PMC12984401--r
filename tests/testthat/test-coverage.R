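# Peptide mapping, coverage percentages, tryptic digestion, and domain
# localization.

test_that("coverage is the union of exact peptide matches", {
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  cov <- map_peptides(seq20, c("ACDEF", "MNPQR"))
  expect_equal(cov$coverage_percent, 50.0)
  expect_equal(sum(cov$mask), 10L)
  expect_true(all(which(cov$mask) %in% c(1:5, 11:15)))
  expect_equal(cov$peptides_mapped, 2L)
  empty <- map_peptides(seq20, character(0))
  expect_equal(empty$coverage_percent, 0.0)
})

test_that("unmapped and empty peptides never alter the mask", {
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  expect_warning(cov <- map_peptides(seq20, c("ACDEF", "", "WWWWW")),
                 "empty peptide")
  expect_equal(cov$peptides_mapped, 1L)
  expect_equal(cov$peptides_unmapped, 2L)
  expect_equal(sum(cov$mask), 5L)
})

test_that("all occurrences of a repeated peptide are marked", {
  cov <- map_peptides("AAASPKAAASPK", "AASPK")
  expect_equal(sum(cov$mask), 10L)
  expect_equal(cov$peptides_mapped, 1L)
})

test_that("peptide order and duplication do not change coverage", {
  seqr <- paste(rep(c("ACDEFGHIK", "LMNPQRSTV"), 4), collapse = "")
  peps <- c("ACDEF", "QRSTV", "HIKLM")
  m1 <- map_peptides(seqr, peps)
  m2 <- map_peptides(seqr, rev(peps))
  m3 <- map_peptides(seqr, c(peps, peps))
  expect_equal(m1$mask, m2$mask)
  expect_equal(m1$mask, m3$mask)
  expect_equal(m1$coverage_percent, m3$coverage_percent)
})

test_that("coverage percent rounds half away from zero to one decimal", {
  # 101 of 400 residues -> 25.25% -> 25.3 (a non-repetitive random
  # sequence so the peptide occurs exactly once)
  set.seed(23)
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
  seq400 <- paste(sample(aa20, 400, replace = TRUE), collapse = "")
  cov <- map_peptides(seq400, substr(seq400, 1, 101))
  expect_equal(sum(cov$mask), 101L)
  expect_equal(cov$coverage_percent, 25.3)
})

test_that("Keil-rule digestion cleaves after K/R except before proline", {
  expect_equal(tryptic_digest("MKRPGK")$peptide, c("MK", "RPGK"))
  expect_equal(tryptic_digest("AGHILM")$peptide, "AGHILM")
  d <- tryptic_digest("AKGK", missed_cleavages = 1)
  expect_setequal(d$peptide, c("AK", "GK", "AKGK"))
  # trailing K is the sequence end, not an internal cleavage site
  expect_equal(tryptic_digest("AK")$peptide, "AK")
})

test_that("m=0 fragments tile the sequence contiguously", {
  set.seed(9)
  for (i in 1:20) {
    s <- paste(sample(c("A", "G", "K", "R", "P", "S", "L"), 60,
                      replace = TRUE), collapse = "")
    d <- tryptic_digest(s)
    expect_equal(paste(d$peptide, collapse = ""), s)
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(s))
    if (nrow(d) > 1L) {
      expect_equal(d$start[-1L], d$end[-nrow(d)] + 1L)
    }
  }
})

test_that("a sequence is fully covered by its own tryptic digest", {
  set.seed(4)
  for (i in 1:10) {
    s <- paste(sample(AA <- c("A", "C", "K", "R", "P", "S", "T", "G"),
                      80, replace = TRUE), collapse = "")
    d <- tryptic_digest(s)
    cov <- map_peptides(s, d$peptide)
    expect_equal(cov$coverage_percent, 100.0)
  }
})

test_that("random fixtures match the generator's interval-union oracle", {
  for (seed in 1:25) {
    fx <- simulate_protein_fixture(200, 12, seed = seed)
    cov <- map_peptides(fx$sequence, fx$peptides$peptide)
    expect_identical(cov$mask, fx$expected_mask)
    expect_equal(cov$coverage_percent, fx$expected_coverage_percent)
  }
  fx0 <- simulate_protein_fixture(50, 0, seed = 1)
  expect_equal(fx0$expected_coverage_percent, 0.0)
})

test_that("domain localization is inclusive on boundaries", {
  domains <- data.frame(
    name = c("KH1", "KH2"),
    start = c(100L, 180L),
    end = c(170L, 240L), stringsAsFactors = FALSE)
  expect_equal(locate_site_in_domains(list(position = 120), domains),
               "KH1")
  expect_equal(locate_site_in_domains(list(position = 100), domains),
               "KH1")
  expect_equal(locate_site_in_domains(list(position = 170), domains),
               "KH1")
  expect_equal(locate_site_in_domains(list(position = 31), domains),
               character(0))
  overlapping <- rbind(domains,
                       data.frame(name = "BIG", start = 1L, end = 500L))
  expect_equal(locate_site_in_domains(list(position = 120), overlapping),
               c("KH1", "BIG"))
  bad <- data.frame(name = "X", start = 5L, end = 2L)
  expect_error(locate_site_in_domains(list(position = 1), bad),
               "start <= end")
})

test_that("FASTA accessions are the first header token", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P12345 some description", "MASTK",
               ">Q99999|alt id text", "GGSSK"), fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), c("P12345", "Q99999|alt"))
  expect_equal(unname(seqs["P12345"]), "MASTK")
})
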