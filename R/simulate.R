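# Seeded generators of synthetic compendia with known ground truth:
# planted co-regulated partner sites, independent background sites,
# block-structured PMIDs and experimental-condition codes, plus profile
# corpora and protein/peptide fixtures for the coverage module.

#' Simulation configuration
#'
#' Describes a synthetic differential compendium: an anchor phosphosite
#' detected in a fraction of datasets, planted positive partners that
#' follow the anchor's direction with probability `concordance` when
#' co-detected, planted negative partners that oppose it with probability
#' `discordance`, and independent background sites. Direction labels are
#' planted first and fold changes are then drawn consistently with the
#' regulation thresholds (up: lognormal resampled until >= 1.3; down:
#' until <= 0.76), so the generator's truth table is exact. PMIDs and
#' experimental codes are assigned in contiguous blocks of datasets.
#'
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @param n_datasets Number of differential datasets (>= 1).
#' @param anchor_detect_prob Probability the anchor is detected
#'   (regulated) in a dataset.
#' @param anchor_up_prob Probability a detected anchor is upregulated.
#' @param n_pos_partners,n_neg_partners Numbers of planted positively /
#'   negatively co-regulated partner sites (each on its own protein).
#' @param concordance Probability a positive partner matches the anchor's
#'   direction when both are detected.
#' @param discordance Probability a negative partner opposes the anchor's
#'   direction when both are detected.
#' @param partner_detect_prob Detection probability of each partner per
#'   dataset.
#' @param n_background_sites Number of independent background sites.
#' @param background_detect_prob Detection probability of each background
#'   site per dataset.
#' @param background_up_prob Probability a detected background site is
#'   upregulated (independent of the anchor).
#' @param datasets_per_pmid,datasets_per_expcode Contiguous block sizes
#'   for PMID / experimental-code assignment (>= 1).
#' @param fc_up_logmean,fc_down_logmean,fc_logsd Log-scale location and
#'   spread of the lognormal fold-change draws for up / down records.
#' @param sig_p_max Regulated records draw p-values uniformly on
#'   (0, `sig_p_max`).
#' @param class1_fraction Fraction of profile records generated as
#'   class-1 (localization probability >= 0.75) by
#'   [simulate_profile_corpus()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_datasets = 100L,
                       anchor_detect_prob = 0.8,
                       anchor_up_prob = 0.5,
                       n_pos_partners = 10L,
                       n_neg_partners = 5L,
                       concordance = 0.95,
                       discordance = 0.95,
                       partner_detect_prob = 0.5,
                       n_background_sites = 200L,
                       background_detect_prob = 0.25,
                       background_up_prob = 0.5,
                       datasets_per_pmid = 4L,
                       datasets_per_expcode = 4L,
                       fc_up_logmean = log(2),
                       fc_down_logmean = log(0.5),
                       fc_logsd = 0.35,
                       sig_p_max = 0.05,
                       class1_fraction = 0.8) {
  probs <- c(anchor_detect_prob, anchor_up_prob, concordance, discordance,
             partner_detect_prob, background_detect_prob,
             background_up_prob, sig_p_max, class1_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_datasets < 1L) stop("n_datasets must be >= 1", call. = FALSE)
  if (datasets_per_pmid < 1L || datasets_per_expcode < 1L) {
    stop("datasets_per_pmid and datasets_per_expcode must be >= 1",
         call. = FALSE)
  }
  if (n_pos_partners < 0L || n_neg_partners < 0L ||
      n_background_sites < 0L) {
    stop("site counts must be non-negative", call. = FALSE)
  }
  if (fc_logsd <= 0) stop("fc_logsd must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_datasets = as.integer(n_datasets),
                 anchor_detect_prob = anchor_detect_prob,
                 anchor_up_prob = anchor_up_prob,
                 n_pos_partners = as.integer(n_pos_partners),
                 n_neg_partners = as.integer(n_neg_partners),
                 concordance = concordance,
                 discordance = discordance,
                 partner_detect_prob = partner_detect_prob,
                 n_background_sites = as.integer(n_background_sites),
                 background_detect_prob = background_detect_prob,
                 background_up_prob = background_up_prob,
                 datasets_per_pmid = as.integer(datasets_per_pmid),
                 datasets_per_expcode = as.integer(datasets_per_expcode),
                 fc_up_logmean = fc_up_logmean,
                 fc_down_logmean = fc_down_logmean,
                 fc_logsd = fc_logsd,
                 sig_p_max = sig_p_max,
                 class1_fraction = class1_fraction),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, "): ", x$n_datasets,
      " differential datasets\n", sep = "")
  cat("  anchor detect ", x$anchor_detect_prob, ", ",
      x$n_pos_partners, " positive partners (concordance ",
      x$concordance, "), ", x$n_neg_partners,
      " negative partners (discordance ", x$discordance, ")\n", sep = "")
  cat("  ", x$n_background_sites, " background sites (detect ",
      x$background_detect_prob, "); PMID/exp-code blocks of ",
      x$datasets_per_pmid, "/", x$datasets_per_expcode, "\n", sep = "")
  invisible(x)
}

# Lognormal fold changes consistent with a planted direction.
draw_consistent_fc <- function(dir, config) {
  fc <- numeric(length(dir))
  for (side in c("U", "D")) {
    idx <- which(dir == side)
    if (!length(idx)) next
    meanlog <- if (side == "U") config$fc_up_logmean else
      config$fc_down_logmean
    ok <- if (side == "U") function(v) v >= 1.3 else function(v) v <= 0.76
    todo <- idx
    while (length(todo)) {
      v <- exp(stats::rnorm(length(todo), meanlog, config$fc_logsd))
      good <- ok(v)
      fc[todo[good]] <- v[good]
      todo <- todo[!good]
    }
  }
  fc
}

sim_manifest <- function(config, dtype) {
  n <- config$n_datasets
  data.frame(
    dataset_id = sprintf("DS%04d", seq_len(n)),
    pmid = sprintf("PM%04d", ceiling(seq_len(n) / config$datasets_per_pmid)),
    exp_code = sprintf("EC%04d",
                       ceiling(seq_len(n) / config$datasets_per_expcode)),
    dtype = dtype,
    enrichment = "STY",
    stringsAsFactors = FALSE
  )
}

#' Simulate a differential compendium with planted co-regulation
#'
#' Generates a corpus of differential datasets containing one anchor site
#' (`ANCHOR_S10` on protein `SIM-ANCHOR`), the configured planted
#' partners and background sites, and a ground-truth table with each
#' non-anchor site's role and its realized co-detection tallies against
#' the anchor (`n_joint`, `n_concordant`, `n_discordant`, counted during
#' generation). All records are class-1 (localization probability drawn
#' in \[0.8, 1\]) and regulated (fold change consistent with the planted
#' direction, p-value below 0.05), so the corpus passes ingestion
#' validation with zero rejections.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `corpus` (a `phospho_corpus`), `truth`
#'   (data frame: `accession, gene, residue, position, role, n_detected,
#'   n_joint, n_concordant, n_discordant`), and `anchor` (the anchor's
#'   site key).
#' @examples
#' cc <- simulate_corpus(sim_config(seed = 7, n_datasets = 20,
#'                                  n_background_sites = 10))
#' table(cc$truth$role)
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_datasets
    man <- sim_manifest(config, "differential")
    anchor_det <- stats::runif(n) < config$anchor_detect_prob
    anchor_dir <- ifelse(stats::runif(n) < config$anchor_up_prob, "U", "D")
    anchor_dir[!anchor_det] <- NA_character_

    sites <- data.frame(
      accession = "SIM-ANCHOR", gene = "ANCHOR", residue = "S",
      position = 10L, role = "anchor", stringsAsFactors = FALSE)
    add_sites <- function(k, acc_fmt, gene_fmt, pos0, role) {
      if (k < 1L) return(NULL)
      data.frame(accession = sprintf(acc_fmt, seq_len(k)),
                 gene = sprintf(gene_fmt, seq_len(k)),
                 residue = "S", position = pos0 + seq_len(k),
                 role = role, stringsAsFactors = FALSE)
    }
    sites <- rbind(sites,
                   add_sites(config$n_pos_partners, "SIM-POS%03d",
                             "POSP%03d", 100L, "pos_partner"),
                   add_sites(config$n_neg_partners, "SIM-NEG%03d",
                             "NEGP%03d", 200L, "neg_partner"),
                   add_sites(config$n_background_sites, "SIM-BG%04d",
                             "BGP%04d", 300L, "background"))

    flip <- function(d) ifelse(d == "U", "D", "U")
    rec_list <- list()
    truth_list <- list()
    for (i in seq_len(nrow(sites))) {
      role <- sites$role[i]
      if (role == "anchor") {
        det <- anchor_det
        dir <- anchor_dir
      } else if (role %in% c("pos_partner", "neg_partner")) {
        det <- stats::runif(n) < config$partner_detect_prob
        agree_p <- if (role == "pos_partner") config$concordance else
          config$discordance
        agree <- stats::runif(n) < agree_p
        coin <- ifelse(stats::runif(n) < 0.5, "U", "D")
        dir <- ifelse(anchor_det,
                      ifelse(agree,
                             if (role == "pos_partner") anchor_dir else
                               flip(anchor_dir),
                             if (role == "pos_partner") flip(anchor_dir)
                             else anchor_dir),
                      coin)
        dir[!det] <- NA_character_
      } else {
        det <- stats::runif(n) < config$background_detect_prob
        dir <- ifelse(stats::runif(n) < config$background_up_prob,
                      "U", "D")
        dir[!det] <- NA_character_
      }
      if (role != "anchor") {
        joint <- det & anchor_det
        truth_list[[i]] <- data.frame(
          accession = sites$accession[i], gene = sites$gene[i],
          residue = sites$residue[i], position = sites$position[i],
          role = role,
          n_detected = sum(det),
          n_joint = sum(joint),
          n_concordant = sum(joint & dir == anchor_dir),
          n_discordant = sum(joint & dir != anchor_dir),
          stringsAsFactors = FALSE)
      }
      if (any(det)) {
        rec_list[[i]] <- data.frame(
          dataset_id = man$dataset_id[det],
          accession = sites$accession[i], gene = sites$gene[i],
          residue = sites$residue[i], position = sites$position[i],
          direction = dir[det], stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, c(rec_list, list(make.row.names = FALSE)))
    nr <- nrow(rec)
    rec$loc_prob <- stats::runif(nr, 0.80, 1.0)
    rec$ascore <- NA_real_
    rec$peptide <- NA_character_
    rec$mod_offset <- NA_integer_
    rec$fold_change <- draw_consistent_fc(rec$direction, config)
    rec$p_value <- stats::runif(nr, 0, config$sig_p_max)
    rec$direction <- NULL
    truth <- do.call(rbind, c(truth_list, list(make.row.names = FALSE)))
    list(corpus = corpus(rec, man),
         truth = truth,
         anchor = list(accession = "SIM-ANCHOR", gene = "ANCHOR",
                       residue = "S", position = 10L,
                       label = "ANCHOR_S10"))
  })
}

#' Simulate a qualitative profile corpus
#'
#' Generates profile-flavor records (detections with localization
#' probabilities, no quantitation) for `n_background_sites` sites over
#' `n_datasets` profile datasets. Each record is class-1 with probability
#' `class1_fraction` (localization probability drawn in \[0.75, 1\],
#' otherwise below 0.75; no A-scores), and the generator's own tally of
#' class-1 records is attached as attribute `"sim_tally"` so the
#' [filter_class1()] outcome can be checked exactly.
#'
#' @param config A [sim_config()] object.
#' @return A `phospho_corpus` with attribute `"sim_tally"` (list with
#'   `n_records`, `n_class1`).
#' @export
simulate_profile_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_datasets
    man <- sim_manifest(config, "profile")
    k <- max(config$n_background_sites, 1L)
    rec_list <- list()
    for (i in seq_len(k)) {
      det <- stats::runif(n) < config$background_detect_prob
      if (!any(det)) next
      rec_list[[i]] <- data.frame(
        dataset_id = man$dataset_id[det],
        accession = sprintf("SIM-PR%04d", i),
        gene = sprintf("PRG%04d", i),
        residue = "S", position = 300L + i,
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, c(rec_list, list(make.row.names = FALSE)))
    nr <- if (is.null(rec)) 0L else nrow(rec)
    if (nr == 0L) {
      stop("no profile records generated; increase n_datasets or ",
           "background_detect_prob", call. = FALSE)
    }
    is_class1 <- stats::runif(nr) < config$class1_fraction
    rec$loc_prob <- ifelse(is_class1,
                           stats::runif(nr, 0.75, 1.0),
                           stats::runif(nr, 0.20, 0.7499))
    rec$ascore <- NA_real_
    rec$peptide <- NA_character_
    rec$mod_offset <- NA_integer_
    rec$fold_change <- NA_real_
    rec$p_value <- NA_real_
    out <- corpus(rec, man)
    attr(out, "sim_tally") <- list(n_records = nr,
                                   n_class1 = sum(is_class1))
    out
  })
}

#' Simulate a protein/peptide coverage fixture
#'
#' Draws a random amino-acid sequence and samples peptides as true
#' substrings, then computes the expected coverage with the generator's
#' own interval-union bookkeeping (an independent substring scan, not
#' [map_peptides()]), so coverage computations can be checked against an
#' oracle. Optionally writes the FASTA and one-column peptide TSV.
#'
#' @param length Sequence length (>= 10).
#' @param n_peptides Number of peptides to sample.
#' @param seed Integer seed.
#' @param accession Accession used in the FASTA header.
#' @param fasta_path,peptide_path Optional output paths.
#' @return A list with `accession`, `sequence`, `peptides` (data frame
#'   `peptide, start, end`), `expected_mask`, and
#'   `expected_coverage_percent`.
#' @export
simulate_protein_fixture <- function(length, n_peptides, seed = 1L,
                                     accession = "SIMPROT1",
                                     fasta_path = NULL,
                                     peptide_path = NULL) {
  stopifnot(length >= 10L, n_peptides >= 0L)
  with_seed(seed, {
    sequence <- paste(sample(AA_ALPHABET, length, replace = TRUE),
                      collapse = "")
    max_len <- min(20L, length)
    peptides <- data.frame(peptide = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
    if (n_peptides > 0L) {
      plen <- sample(seq(8L, max_len), n_peptides, replace = TRUE)
      start <- vapply(plen, function(l) {
        sample.int(length - l + 1L, 1L)
      }, 0L)
      peptides <- data.frame(
        peptide = substring(sequence, start, start + plen - 1L),
        start = start, end = start + plen - 1L,
        stringsAsFactors = FALSE)
    }
    # independent bookkeeping: plain substring scan over every start
    mask <- logical(length)
    for (pep in peptides$peptide) {
      l <- nchar(pep)
      for (s in seq_len(length - l + 1L)) {
        if (substr(sequence, s, s + l - 1L) == pep) {
          mask[s:(s + l - 1L)] <- TRUE
        }
      }
    }
    if (!is.null(fasta_path)) {
      writeLines(c(paste0(">", accession, " synthetic"), sequence),
                 fasta_path)
    }
    if (!is.null(peptide_path)) {
      write_tsv(peptides["peptide"], peptide_path)
    }
    list(accession = accession, sequence = sequence, peptides = peptides,
         expected_mask = mask,
         expected_coverage_percent =
           round_half_up1(100 * sum(mask) / length))
  })
}
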