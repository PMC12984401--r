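# Corpus container and TSV ingestion for phosphoproteomic compendia.
#
# A corpus bundles a dataset manifest (one row per dataset: PMID,
# experimental-condition code, profile/differential type, enrichment
# chemistry), a table of per-dataset phosphosite records, and optional
# protein sequences. Record and manifest files use a strict TSV dialect
# (UTF-8, header, tab-separated, empty string = absent).

CORPUS_COLUMNS <- c("dataset_id", "pmid", "exp_code", "dtype", "enrichment",
                    "accession", "gene", "residue", "position",
                    "loc_prob", "ascore", "peptide", "mod_offset",
                    "fold_change", "p_value")

MANIFEST_COLUMNS <- c("dataset_id", "pmid", "exp_code", "dtype", "enrichment")

DATASET_TYPES <- c("profile", "differential")
ENRICHMENT_TYPES <- c("STY", "ST", "Y")

#' Construct a phosphoproteomic corpus
#'
#' Builds a validated corpus from in-memory tables. Most users will call
#' [read_corpus()] (files) or [simulate_corpus()] (synthetic data) instead.
#'
#' @param records Data frame of phosphosite records; must contain the
#'   columns `dataset_id, accession, gene, residue, position` and may
#'   contain `loc_prob, ascore, peptide, mod_offset, fold_change, p_value`.
#' @param manifest Data frame with columns
#'   `dataset_id, pmid, exp_code, dtype, enrichment`; `dtype` is one of
#'   `"profile"`/`"differential"` and `enrichment` one of
#'   `"STY"`/`"ST"`/`"Y"`.
#' @param sequences Optional named character vector of protein sequences,
#'   names being accessions.
#' @param validate Check invariants (unique dataset ids, closed
#'   vocabularies, referential integrity, residue/position validity)?
#' @return An object of class `phospho_corpus`: a list with elements
#'   `records`, `manifest`, `sequences`.
#' @seealso [read_corpus()], [write_corpus()], [filter_class1()]
#' @export
corpus <- function(records, manifest, sequences = NULL, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  for (col in setdiff(CORPUS_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% c("position", "mod_offset")) {
      NA_integer_
    } else if (col %in% c("loc_prob", "ascore", "fold_change", "p_value")) {
      NA_real_
    } else {
      NA_character_
    }
  }
  # manifest is authoritative for dataset metadata
  mi <- match(records$dataset_id, manifest$dataset_id)
  records$pmid <- manifest$pmid[mi]
  records$exp_code <- manifest$exp_code[mi]
  records$dtype <- manifest$dtype[mi]
  records$enrichment <- manifest$enrichment[mi]
  records$position <- as.integer(records$position)
  records$mod_offset <- as.integer(records$mod_offset)
  for (col in c("loc_prob", "ascore", "fold_change", "p_value")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records <- records[CORPUS_COLUMNS]
  records <- records[order(records$dataset_id, records$accession,
                           records$position), , drop = FALSE]
  rownames(records) <- NULL
  manifest <- manifest[MANIFEST_COLUMNS]
  rownames(manifest) <- NULL
  obj <- structure(list(records = records, manifest = manifest,
                        sequences = sequences),
                   class = "phospho_corpus")
  if (validate) validate_corpus(obj)
  obj
}

validate_corpus <- function(x) {
  man <- x$manifest
  rec <- x$records
  if (anyDuplicated(man$dataset_id)) {
    stop("duplicated dataset_id in manifest: ",
         paste(unique(man$dataset_id[duplicated(man$dataset_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(man$dtype %in% DATASET_TYPES)) {
    stop("manifest dtype must be one of: ",
         paste(DATASET_TYPES, collapse = ", "), call. = FALSE)
  }
  if (!all(man$enrichment %in% ENRICHMENT_TYPES)) {
    stop("manifest enrichment must be one of: ",
         paste(ENRICHMENT_TYPES, collapse = ", "), call. = FALSE)
  }
  missing_ds <- setdiff(rec$dataset_id, man$dataset_id)
  if (length(missing_ds)) {
    stop("record references dataset '", missing_ds[1],
         "' absent from the manifest", call. = FALSE)
  }
  if (nrow(rec)) {
    stopifnot(all(rec$residue %in% PHOSPHO_RESIDUES),
              all(rec$position >= 1L))
    key <- paste(rec$dataset_id, rec$accession, rec$position)
    if (anyDuplicated(key)) {
      stop("duplicate (dataset, site) records; de-duplicate first ",
           "(read_corpus() does this automatically)", call. = FALSE)
    }
  }
  invisible(x)
}

# Row-level validation of a character-mode record table. Returns a
# character vector of rejection reasons (NA = accepted).
validate_record_rows <- function(df, sequences = NULL) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(df$dataset_id == "", "missing_dataset_id")
  flag(df$accession == "", "missing_accession")
  flag(!(df$residue %in% PHOSPHO_RESIDUES), "malformed_residue")
  pos_ok <- grepl("^[0-9]+$", df$position)
  flag(!pos_ok, "malformed_position")
  pos <- suppressWarnings(as.integer(df$position))
  flag(pos_ok & (is.na(pos) | pos < 1L), "malformed_position")
  for (col in c("loc_prob", "ascore", "fold_change", "p_value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    flag(df[[col]] != "" & is.na(v), paste0("unparseable_", col))
  }
  loc <- parse_num(df$loc_prob)
  flag(!is.na(loc) & (loc < 0 | loc > 1), "loc_prob_out_of_range")
  asc <- parse_num(df$ascore)
  flag(!is.na(asc) & asc < 0, "negative_ascore")
  fc <- parse_num(df$fold_change)
  flag(!is.na(fc) & fc <= 0, "nonpositive_fold_change")
  pv <- parse_num(df$p_value)
  flag(!is.na(pv) & (pv < 0 | pv > 1), "p_value_out_of_range")
  off <- parse_int(df$mod_offset)
  flag(!is.na(off) & df$peptide == "", "mod_offset_without_peptide")
  has_off <- !is.na(off) & df$peptide != ""
  if (any(has_off)) {
    plen <- nchar(df$peptide)
    bad_off <- has_off & (off < 1L | off > plen)
    flag(bad_off, "mod_offset_out_of_peptide")
    ok_off <- has_off & !bad_off
    mod_res <- substr(df$peptide, pmax(off, 1L), pmax(off, 1L))
    flag(ok_off & !(mod_res %in% PHOSPHO_RESIDUES),
         "mod_offset_not_on_STY")
  }
  if (!is.null(sequences) && length(sequences)) {
    si <- match(df$accession, names(sequences))
    known <- !is.na(si) & is.na(reason)
    if (any(known)) {
      slen <- nchar(sequences)[si]
      flag(known & pos > slen, "position_beyond_sequence")
      in_seq <- known & !is.na(pos) & pos <= slen
      seq_res <- substr(sequences[si], pos, pos)
      flag(in_seq & seq_res != df$residue, "residue_sequence_mismatch")
    }
  }
  reason
}

#' Read a phosphoproteomic corpus from TSV files
#'
#' Ingests one or more record tables plus a dataset manifest, validates
#' every row, rejects rows violating type invariants (counts and reasons
#' are kept in an ingest report), and collapses duplicate records of the
#' same site within one dataset to a single effective record: profile
#' duplicates keep the maximum localization metrics; differential
#' duplicates whose regulation directions agree keep the most extreme fold
#' change, while conflicting directions mark the site unregulated in that
#' dataset (one vote per dataset).
#'
#' Record files carry the full column dialect
#' (`dataset_id, pmid, exp_code, dtype, enrichment, accession, gene,
#' residue, position, loc_prob, ascore, peptide, mod_offset, fold_change,
#' p_value`); dataset metadata is taken from the manifest, which is
#' authoritative. A record referencing a dataset absent from the manifest
#' is an ingestion error (not a row rejection).
#'
#' @param record_paths Character vector of record TSV paths.
#' @param manifest_path Path of the manifest TSV
#'   (`dataset_id, pmid, exp_code, dtype, enrichment`).
#' @param fasta_path Optional FASTA file of protein sequences; when given,
#'   rows whose residue disagrees with the sequence at the stated position
#'   are rejected.
#' @param thresholds [filter_thresholds()] used only for the
#'   duplicate-direction agreement check during de-duplication.
#' @param log2_fc Set to `TRUE` when the input fold changes are log2
#'   ratios; they are converted to linear ratios on read (the 1.3/0.76
#'   thresholds are linear).
#' @param aliases Optional data frame with columns `from`, `to` mapping
#'   accession aliases applied before validation.
#' @return A `phospho_corpus`; the ingest report is attached as attribute
#'   `"ingest_report"` (see [ingest_report()]).
#' @seealso [write_corpus()], [write_ingest_report()]
#' @export
read_corpus <- function(record_paths, manifest_path, fasta_path = NULL,
                        thresholds = filter_thresholds(),
                        log2_fc = FALSE, aliases = NULL) {
  man <- read_tsv_chr(manifest_path)
  miss <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(miss)) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  man <- man[MANIFEST_COLUMNS]
  sequences <- if (!is.null(fasta_path)) read_fasta(fasta_path) else NULL

  files <- list()
  accepted <- list()
  for (path in record_paths) {
    df <- read_tsv_chr(path)
    need <- c("dataset_id", "accession", "gene", "residue", "position")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("record file ", path, " is missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (col in setdiff(CORPUS_COLUMNS, names(df))) df[[col]] <- ""
    df <- df[CORPUS_COLUMNS]
    if (!is.null(aliases)) {
      ai <- match(df$accession, aliases$from)
      df$accession[!is.na(ai)] <- aliases$to[ai[!is.na(ai)]]
    }
    unknown <- setdiff(unique(df$dataset_id[df$dataset_id != ""]),
                       man$dataset_id)
    if (length(unknown)) {
      stop("record file ", path, " references dataset '", unknown[1],
           "' absent from the manifest", call. = FALSE)
    }
    if (log2_fc) {
      fc <- parse_num(df$fold_change)
      df$fold_change <- chr_or_empty(2^fc)
    }
    reason <- validate_record_rows(df, sequences)
    keep <- is.na(reason)
    tab <- table(reason[!keep])
    files[[path]] <- list(
      rows = nrow(df),
      accepted = sum(keep),
      rejected = sum(!keep),
      reasons = as.list(stats::setNames(as.integer(tab), names(tab)))
    )
    accepted[[path]] <- df[keep, , drop = FALSE]
  }
  rec <- do.call(rbind, c(accepted, list(make.row.names = FALSE)))
  rec <- typed_records(rec)
  dedup <- deduplicate_records(rec, man, thresholds)

  report <- list(
    files = files,
    total_rows = sum(vapply(files, `[[`, 0, "rows")),
    total_accepted = sum(vapply(files, `[[`, 0, "accepted")),
    total_rejected = sum(vapply(files, `[[`, 0, "rejected")),
    n_deduplicated = dedup$n_collapsed
  )
  out <- corpus(dedup$records, man, sequences)
  attr(out, "ingest_report") <- report
  out
}

typed_records <- function(df) {
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      replicate(length(CORPUS_COLUMNS), character(0), simplify = FALSE),
      CORPUS_COLUMNS), stringsAsFactors = FALSE)
  }
  df$position <- parse_int(df$position)
  df$mod_offset <- parse_int(df$mod_offset)
  for (col in c("loc_prob", "ascore", "fold_change", "p_value")) {
    df[[col]] <- parse_num(df[[col]])
  }
  df$peptide[!is.na(df$peptide) & df$peptide == ""] <- NA_character_
  df
}

# Collapse duplicate (dataset, accession, position) rows to one effective
# record per dataset.
deduplicate_records <- function(rec, man, thresholds) {
  if (!nrow(rec)) return(list(records = rec, n_collapsed = 0L))
  key <- paste(rec$dataset_id, rec$accession, rec$position, sep = "\r")
  if (!anyDuplicated(key)) return(list(records = rec, n_collapsed = 0L))
  dtype <- man$dtype[match(rec$dataset_id, man$dataset_id)]
  groups <- split(seq_len(nrow(rec)), key)
  keep_rows <- vector("list", length(groups))
  n_collapsed <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    row <- rec[g[1L], , drop = FALSE]
    if (length(g) > 1L) {
      n_collapsed <- n_collapsed + length(g) - 1L
      lp <- rec$loc_prob[g]
      as_ <- rec$ascore[g]
      row$loc_prob <- if (all(is.na(lp))) NA_real_ else max(lp, na.rm = TRUE)
      row$ascore <- if (all(is.na(as_))) NA_real_ else max(as_, na.rm = TRUE)
      if (dtype[g[1L]] == "differential") {
        lab <- classify_regulation(rec$fold_change[g], rec$p_value[g],
                                   thresholds)
        if (any(lab == "up") && any(lab == "down")) {
          # conflicting directions: one unregulated vote for this dataset
          row$fold_change <- NA_real_
          row$p_value <- NA_real_
        } else if (any(lab == "up")) {
          i <- g[lab == "up"][which.max(rec$fold_change[g[lab == "up"]])]
          row$fold_change <- rec$fold_change[i]
          row$p_value <- rec$p_value[i]
        } else if (any(lab == "down")) {
          i <- g[lab == "down"][which.min(rec$fold_change[g[lab == "down"]])]
          row$fold_change <- rec$fold_change[i]
          row$p_value <- rec$p_value[i]
        }
      }
    }
    keep_rows[[gi]] <- row
  }
  out <- do.call(rbind, c(keep_rows, list(make.row.names = FALSE)))
  list(records = out, n_collapsed = n_collapsed)
}

#' Write a corpus back to canonical TSV files
#'
#' Records are written in the canonical column order and canonical row
#' order (dataset, accession, position), with absent values as empty
#' strings, so repeated read/write cycles are byte-stable.
#'
#' @param x A `phospho_corpus`.
#' @param records_path Output path for the record TSV.
#' @param manifest_path Optional output path for the manifest TSV.
#' @return Invisibly, `records_path`.
#' @export
write_corpus <- function(x, records_path, manifest_path = NULL) {
  stopifnot(inherits(x, "phospho_corpus"))
  rec <- x$records
  out <- data.frame(lapply(rec, chr_or_empty), stringsAsFactors = FALSE)
  write_tsv(out, records_path)
  if (!is.null(manifest_path)) write_tsv(x$manifest, manifest_path)
  invisible(records_path)
}

#' Retrieve the ingest report of a corpus
#'
#' @param x A corpus returned by [read_corpus()].
#' @return A list with per-file row/accepted/rejected counts and rejection
#'   reasons, plus corpus-level totals and the number of duplicate records
#'   collapsed; `NULL` for corpora not created by ingestion.
#' @export
ingest_report <- function(x) {
  attr(x, "ingest_report")
}

#' Write the ingest report as JSON
#'
#' @param x A corpus returned by [read_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ingest_report <- function(x, path) {
  rep <- ingest_report(x)
  if (is.null(rep)) stop("corpus carries no ingest report", call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.phospho_corpus <- function(x, ...) {
  man <- x$manifest
  rec <- x$records
  n_prof <- sum(man$dtype == "profile")
  n_diff <- sum(man$dtype == "differential")
  cat("Phosphoproteomic corpus\n")
  cat("  datasets:  ", nrow(man), " (", n_prof, " profile, ", n_diff,
      " differential)\n", sep = "")
  cat("  records:   ", nrow(rec), "\n", sep = "")
  cat("  sites:     ",
      length(unique(site_uid(rec$accession, rec$position))),
      " across ", length(unique(rec$accession)), " proteins\n", sep = "")
  if (!is.null(x$sequences)) {
    cat("  sequences: ", length(x$sequences), "\n", sep = "")
  }
  invisible(x)
}
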