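# Peptide-to-sequence mapping, coverage, in-silico tryptic digestion, and
# domain localization of phosphosites.

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is used as the
#' accession.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Map peptides onto a protein sequence and compute coverage
#'
#' Marks every residue covered by any exact substring occurrence of any
#' peptide (all occurrences of a repeated peptide are marked) and reports
#' the percentage of covered residues: the ratio of observed to total
#' sequence length, rounded half away from zero to one decimal. Peptides
#' with no occurrence are counted as unmapped and never alter the mask;
#' empty peptide strings are rejected as unmapped with a warning.
#'
#' @param sequence Uppercase amino-acid string.
#' @param peptides Character vector of peptide sequences.
#' @param accession Optional accession stored in the result.
#' @return An object of class `coverage_result`: list with `accession`,
#'   `sequence`, `length`, `mask` (logical per-residue coverage),
#'   `coverage_percent`, `peptides_mapped`, `peptides_unmapped`.
#' @examples
#' map_peptides("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", c("MKTAY", "SHFSR"))
#' @export
map_peptides <- function(sequence, peptides, accession = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  mask <- logical(len)
  mapped <- 0L
  unmapped <- 0L
  for (pep in peptides) {
    if (is.na(pep) || !nzchar(pep)) {
      warning("empty peptide string rejected as unmapped")
      unmapped <- unmapped + 1L
      next
    }
    pep <- toupper(pep)
    hits <- gregexpr(pep, sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      unmapped <- unmapped + 1L
    } else {
      mapped <- mapped + 1L
      plen <- nchar(pep)
      for (s in hits) {
        mask[s:(s + plen - 1L)] <- TRUE
      }
    }
  }
  structure(list(accession = accession, sequence = sequence, length = len,
                 mask = mask,
                 coverage_percent = round_half_up1(100 * sum(mask) / len),
                 peptides_mapped = mapped, peptides_unmapped = unmapped),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("Sequence coverage",
      if (!is.na(x$accession)) paste0(" of ", x$accession) else "",
      ": ", x$coverage_percent, "% of ", x$length, " residues (",
      sum(x$mask), " covered; ", x$peptides_mapped, " peptides mapped, ",
      x$peptides_unmapped, " unmapped)\n", sep = "")
  invisible(x)
}

#' Write a per-residue coverage table
#'
#' Long-format TSV with one row per residue: `position, residue, covered,
#' phosphosite_flag`, suitable for downstream visualization.
#'
#' @param x A [map_peptides()] result.
#' @param path Output TSV path.
#' @param phosphosites Optional integer vector of phosphosite positions
#'   to flag.
#' @return Invisibly, `path`.
#' @export
write_coverage_table <- function(x, path, phosphosites = integer(0)) {
  stopifnot(inherits(x, "coverage_result"))
  df <- data.frame(
    position = seq_len(x$length),
    residue = strsplit(x$sequence, "")[[1L]],
    covered = as.integer(x$mask),
    phosphosite_flag = as.integer(seq_len(x$length) %in% phosphosites),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue
#' is proline (the Keil rule). With `missed_cleavages = m`, every
#' concatenation of up to `m + 1` adjacent fragments is also returned.
#' The extended PeptideCutter exception set beyond the Keil rule is
#' deliberately not modeled.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Non-negative integer.
#' @return Data frame with columns `start, end, peptide,
#'   missed_cleavages`, in N-to-C order (by start, then length).
#' @examples
#' tryptic_digest("MKRPGK")            # "MK", "RPGK" (no cut before P)
#' tryptic_digest("AKGK", missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence), missed_cleavages >= 0L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  is_kr <- chars %in% c("K", "R")
  next_p <- c(chars[-1L], "") == "P"
  cuts <- which(is_kr & !next_p & seq_len(n) < n)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nf <- length(starts)
  rows <- list()
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + missed_cleavages)) {
      rows[[length(rows) + 1L]] <- c(starts[i], ends[j], j - i)
    }
  }
  mat <- do.call(rbind, rows)
  ord <- order(mat[, 1L], mat[, 2L])
  mat <- mat[ord, , drop = FALSE]
  data.frame(start = as.integer(mat[, 1L]), end = as.integer(mat[, 2L]),
             peptide = substring(sequence, mat[, 1L], mat[, 2L]),
             missed_cleavages = as.integer(mat[, 3L]),
             stringsAsFactors = FALSE)
}

#' Locate a phosphosite within annotated domains
#'
#' Returns the names of the domains whose inclusive `[start, end]` range
#' contains the site position, in the order the domains are listed
#' (overlapping domains all reported, first-listed first). An empty
#' character vector means the site lies outside every listed domain.
#'
#' @param site A site (`list` or one-row data frame with `position`, and
#'   optionally `accession` to restrict the domain table).
#' @param domains Data frame with columns `name, start, end` and
#'   optionally `accession`.
#' @param sequence Optional protein sequence used to validate the domain
#'   ranges.
#' @return Character vector of containing domain names (possibly empty).
#' @export
locate_site_in_domains <- function(site, domains, sequence = NULL) {
  site <- as.list(site)
  stopifnot(!is.null(site$position))
  pos <- as.integer(site$position)
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (any(domains$start < 1L) || any(domains$start > domains$end)) {
    stop("domain ranges must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(sequence) && any(domains$end > nchar(sequence))) {
    stop("domain range extends beyond the protein length", call. = FALSE)
  }
  if (!is.null(site$accession) && "accession" %in% names(domains)) {
    domains <- domains[domains$accession == site$accession, , drop = FALSE]
  }
  domains$name[domains$start <= pos & pos <= domains$end]
}
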