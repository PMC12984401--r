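# In-code fixtures and independent brute-force oracles used across the
# suite. Oracles deliberately take the naive route (row scans, explicit
# enumeration) so they share no code path with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_manifest <- function(ids, dtype = "differential",
                          pmid = paste0("PM", seq_along(ids)),
                          exp_code = paste0("EC", seq_along(ids)),
                          enrichment = "STY") {
  data.frame(dataset_id = ids, pmid = pmid, exp_code = exp_code,
             dtype = dtype, enrichment = enrichment,
             stringsAsFactors = FALSE)
}

rec_row <- function(dataset_id, accession, position,
                    gene = accession, residue = "S",
                    loc_prob = 0.9, ascore = NA, peptide = NA,
                    mod_offset = NA, fold_change = NA, p_value = NA) {
  data.frame(dataset_id = dataset_id, accession = accession, gene = gene,
             residue = residue, position = as.integer(position),
             loc_prob = as.numeric(loc_prob), ascore = as.numeric(ascore),
             peptide = as.character(peptide),
             mod_offset = as.integer(mod_offset),
             fold_change = as.numeric(fold_change),
             p_value = as.numeric(p_value), stringsAsFactors = FALSE)
}

# A differential record with a direction: "U" (fc 2), "D" (fc 0.5), or
# "0" (unregulated: fc 1).
dir_row <- function(dataset_id, accession, position, dir,
                    gene = accession) {
  fc <- switch(dir, U = 2, D = 0.5, `0` = 1)
  rec_row(dataset_id, accession, position, gene = gene,
          fold_change = fc, p_value = 0.01)
}

# Build a small differential corpus from per-dataset direction maps,
# e.g. dir_corpus(list(d1 = c(A = "U", B = "D")), c(A = 10, B = 20)).
dir_corpus <- function(datasets, positions,
                       pmid = NULL, exp_code = NULL) {
  ids <- names(datasets)
  man <- make_manifest(ids,
                       pmid = pmid %||% paste0("PM", seq_along(ids)),
                       exp_code = exp_code %||%
                         paste0("EC", seq_along(ids)))
  rows <- list()
  for (d in ids) {
    for (acc in names(datasets[[d]])) {
      rows[[length(rows) + 1L]] <-
        dir_row(d, acc, positions[[acc]], datasets[[d]][[acc]])
    }
  }
  corpus(do.call(rbind, rows), man)
}

# Exhaustive same-margin enumeration of the one-sided concordance FET on
# [[nUU, nUD], [nDU, nDD]]: hypergeometric weights built from choose().
oracle_fet_concordance <- function(nUU, nDD, nUD, nDU) {
  a <- nUU; b <- nUD; c <- nDU; d <- nDD
  if (a + b + c + d == 0) return(1)
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  w <- choose(r1, ks) * choose(r2, c1 - ks)
  sum(w[ks >= a]) / sum(w)
}

# Naive pair counting: re-scan the raw records dataset by dataset.
oracle_pair_counts <- function(cc, anchor_acc, anchor_pos,
                               cand_acc, cand_pos,
                               thresholds = filter_thresholds()) {
  man <- cc$manifest
  rec <- cc$records
  out <- c(nUU = 0L, nDD = 0L, nUD = 0L, nDU = 0L)
  label_of <- function(ds, acc, pos) {
    r <- rec[rec$dataset_id == ds & rec$accession == acc &
               rec$position == pos, , drop = FALSE]
    if (!nrow(r)) return(NA_character_)
    lab <- classify_regulation(r$fold_change[1], r$p_value[1], thresholds)
    if (lab == "unregulated") NA_character_ else
      if (lab == "up") "U" else "D"
  }
  for (ds in man$dataset_id[man$dtype == "differential"]) {
    a <- label_of(ds, anchor_acc, anchor_pos)
    b <- label_of(ds, cand_acc, cand_pos)
    if (is.na(a) || is.na(b)) next
    key <- paste0("n", a, b)
    out[[key]] <- out[[key]] + 1L
  }
  out
}

# Naive per-site frequency scan.
oracle_site_freq <- function(cc, accession, site_pos,
                             thresholds = filter_thresholds()) {
  man <- cc$manifest
  rec <- cc$records
  prof <- 0L
  diff <- 0L
  for (ds in man$dataset_id) {
    r <- rec[rec$dataset_id == ds & rec$accession == accession &
               rec$position == site_pos, , drop = FALSE]
    if (!nrow(r)) next
    if (man$dtype[man$dataset_id == ds] == "profile") {
      prof <- prof + 1L
    } else {
      lab <- classify_regulation(r$fold_change[1], r$p_value[1],
                                 thresholds)
      if (lab != "unregulated") diff <- diff + 1L
    }
  }
  c(profile = prof, differential = diff)
}

# Random small differential corpus: sites on protein "PROT" plus one
# site on "OTHER" so cross-protein pairs exist.
random_dir_corpus <- function(seed, max_datasets = 50L, max_sites = 30L) {
  set.seed(seed)
  n_ds <- sample.int(max_datasets, 1L)
  n_sites <- sample(2:max_sites, 1L)
  ids <- sprintf("D%03d", seq_len(n_ds))
  man <- make_manifest(ids)
  rows <- list(dir_row(ids[1L], "OTHER", 5L, sample(c("U", "D"), 1L)))
  for (d in ids) {
    if (runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <-
        dir_row(d, "OTHER", 5L, sample(c("U", "D", "0"), 1L))
    }
    for (s in seq_len(n_sites)) {
      r <- runif(1)
      if (r < 0.25) {
        rows[[length(rows) + 1L]] <- dir_row(d, "PROT", s * 10L, "U")
      } else if (r < 0.5) {
        rows[[length(rows) + 1L]] <- dir_row(d, "PROT", s * 10L, "D")
      } else if (r < 0.6) {
        rows[[length(rows) + 1L]] <- dir_row(d, "PROT", s * 10L, "0")
      }
    }
  }
  rec <- do.call(rbind, rows)
  rec <- rec[!duplicated(paste(rec$dataset_id, rec$accession,
                               rec$position)), , drop = FALSE]
  list(corpus = corpus(rec, man), n_sites = n_sites, ids = ids)
}

# Rebuild a corpus with extra record rows (helper rows carry only the
# 11 record columns; drop the manifest-derived metadata for the rbind).
augment_corpus <- function(cc, extra) {
  corpus(rbind(cc$records[names(extra)], extra), cc$manifest)
}

write_corpus_string <- function(cc) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_corpus(cc, path)
  paste(readLines(path), collapse = "\n")
}
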