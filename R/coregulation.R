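# Directional co-regulation between an anchor phosphosite and candidate
# phosphosites of other proteins (CPPs).
#
# For each differential dataset in which both sites are classified up or
# down, the pair falls into one of four categories: UU (both up), DD
# (both down), UD (anchor up, candidate down), DU (anchor down, candidate
# up). Concordant evidence n_pos = nUU + nDD supports positive
# co-regulation; discordant evidence n_neg = nUD + nDU supports negative
# co-regulation. Significance is a one-sided Fisher's exact test on the
# 2x2 table [[nUU, nUD], [nDU, nDD]] (anchor direction x candidate
# direction), and high-confidence calls additionally require the dominant
# count to exceed a fraction of the anchor's differential frequency and
# reproducibility across distinct PMIDs and experimental-condition codes.

#' Directional pair counts
#'
#' Creates (or extracts) the four joint direction counts of an
#' (anchor, candidate) phosphosite pair.
#'
#' @param nUU,nDD,nUD,nDU Non-negative integer counts of datasets in which
#'   the pair is both up / both down / anchor up + candidate down /
#'   anchor down + candidate up.
#' @return An object of class `coreg_counts` (named integer vector).
#' @seealso [pair_counts()], [fisher_exact_one_sided()], [coreg_ratios()]
#' @export
coreg_counts <- function(nUU = 0L, nDD = 0L, nUD = 0L, nDU = 0L) {
  x <- c(nUU = as.integer(nUU), nDD = as.integer(nDD),
         nUD = as.integer(nUD), nDU = as.integer(nDU))
  stopifnot(!anyNA(x), all(x >= 0L))
  structure(x, class = "coreg_counts")
}

as_coreg_counts <- function(counts) {
  if (inherits(counts, "coreg_counts")) return(counts)
  counts <- unlist(counts)
  stopifnot(all(c("nUU", "nDD", "nUD", "nDU") %in% names(counts)))
  coreg_counts(counts[["nUU"]], counts[["nDD"]],
               counts[["nUD"]], counts[["nDU"]])
}

#' @export
print.coreg_counts <- function(x, ...) {
  cat("Pair direction counts: nUU=", x[["nUU"]], " nDD=", x[["nDD"]],
      " nUD=", x[["nUD"]], " nDU=", x[["nDU"]],
      "  (n_pos=", x[["nUU"]] + x[["nDD"]],
      ", n_neg=", x[["nUD"]] + x[["nDU"]], ")\n", sep = "")
  invisible(x)
}

#' Count joint regulation directions for a site pair
#'
#' Scans the differential datasets of a corpus and counts, over datasets
#' in which both sites are classified up or down, the four joint
#' categories UU/DD/UD/DU. Datasets where either side is absent or
#' unregulated contribute nothing; each dataset contributes exactly one
#' increment.
#'
#' @param x A `phospho_corpus` (class-1 filtered by the caller if
#'   desired).
#' @param anchor,candidate Sites, each as `"GENE_S31"`,
#'   `"ACCESSION:position"`, or a list with `accession` and `position`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A [coreg_counts()] object.
#' @export
pair_counts <- function(x, anchor, candidate,
                        thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "phospho_corpus"))
  a <- resolve_site(x, anchor)
  b <- resolve_site(x, candidate)
  if (a$uid == b$uid) {
    stop("anchor and candidate must be distinct sites", call. = FALSE)
  }
  dm <- direction_matrix(x, thresholds)
  av <- if (a$uid %in% rownames(dm$directions)) {
    dm$directions[a$uid, ]
  } else {
    rep(NA_character_, length(dm$dataset_ids))
  }
  bv <- if (b$uid %in% rownames(dm$directions)) {
    dm$directions[b$uid, ]
  } else {
    rep(NA_character_, length(dm$dataset_ids))
  }
  both <- !is.na(av) & !is.na(bv)
  coreg_counts(
    nUU = sum(both & av == "U" & bv == "U"),
    nDD = sum(both & av == "D" & bv == "D"),
    nUD = sum(both & av == "U" & bv == "D"),
    nDU = sum(both & av == "D" & bv == "U")
  )
}

# Vectorized one-sided hypergeometric tails on tables
# [[nUU, nUD], [nDU, nDD]]; "concordance" is the upper tail on nUU given
# the margins, "discordance" the lower tail. Empty tables give 1.
fet_tail <- function(nUU, nDD, nUD, nDU,
                     alternative = c("concordance", "discordance")) {
  alternative <- match.arg(alternative)
  m1 <- nUU + nUD   # anchor-up margin
  m2 <- nDU + nDD   # anchor-down margin
  k <- nUU + nDU    # candidate-up margin
  p <- if (alternative == "concordance") {
    stats::phyper(nUU - 1, m1, m2, k, lower.tail = FALSE)
  } else {
    stats::phyper(nUU, m1, m2, k, lower.tail = TRUE)
  }
  p[m1 + m2 == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' One-sided Fisher's exact test on a pair's direction table
#'
#' Computes the one-sided hypergeometric tail probability on the 2x2
#' contingency table rows = anchor direction (U, D), columns = candidate
#' direction (U, D), i.e. `[[nUU, nUD], [nDU, nDD]]`. The default
#' alternative tests for an excess of concordant regulation (UU/DD);
#' `"discordance"` tests the opposite tail, used for negatively
#' co-regulated candidates. An empty table returns 1.
#'
#' @param counts A [coreg_counts()] object, or a list with entries
#'   `nUU, nDD, nUD, nDU` (vector entries are handled elementwise).
#' @param alternative `"concordance"` or `"discordance"`.
#' @return A p-value in \[0, 1\] (vectorized over vector entries).
#' @examples
#' fisher_exact_one_sided(coreg_counts(nUU = 3, nDD = 3))  # 1/choose(6,3)
#' @export
fisher_exact_one_sided <- function(counts,
                                   alternative = c("concordance",
                                                   "discordance")) {
  counts <- as.list(unclass(counts))
  stopifnot(all(c("nUU", "nDD", "nUD", "nDU") %in% names(counts)))
  stopifnot(all(unlist(counts) >= 0))
  fet_tail(counts$nUU, counts$nDD, counts$nUD, counts$nDU,
           match.arg(alternative))
}

#' Co-regulation ratios
#'
#' The positive co-regulation ratio is the concordant-to-discordant count
#' ratio `(nUU + nDD) / (nUD + nDU)`; the negative ratio is its
#' reciprocal. A zero denominator with a positive numerator yields `Inf`;
#' an all-zero table yields `NaN` (undefined, and no classification is
#' possible).
#'
#' @param counts A [coreg_counts()] object.
#' @return A list with elements `ratio_pos` and `ratio_neg`.
#' @export
coreg_ratios <- function(counts) {
  counts <- as_coreg_counts(counts)
  n_pos <- counts[["nUU"]] + counts[["nDD"]]
  n_neg <- counts[["nUD"]] + counts[["nDU"]]
  list(ratio_pos = n_pos / n_neg, ratio_neg = n_neg / n_pos)
}

#' Classify a candidate site's co-regulation with the anchor
#'
#' A candidate is `"positive"` when concordant evidence dominates
#' (`n_pos > n_neg`) and the joint high-confidence filter passes: FET
#' p-value below `config$fet_alpha`, dominant count strictly greater than
#' `config$freq_fraction` times the anchor's differential frequency, and
#' at least `config$pmid_min` distinct PMIDs and `config$expcode_min`
#' distinct experimental codes among the datasets contributing to the
#' dominant category. `"negative"` is symmetric with discordant evidence;
#' anything else (including a tie) is `"none"`.
#'
#' @param counts A [coreg_counts()] object.
#' @param fet_p One-sided FET p-value in the dominant direction.
#' @param pmid_confidence,expcode_confidence Distinct-PMID and
#'   distinct-experimental-code counts over the dominant category's
#'   datasets.
#' @param anchor_diff_freq The anchor site's differential frequency (its
#'   `differential_count` from [site_frequency_table()]); must be >= 1.
#' @param config A [coreg_filter_config()] object.
#' @return `"positive"`, `"negative"`, or `"none"`.
#' @export
classify_cpp <- function(counts, fet_p, pmid_confidence,
                         expcode_confidence, anchor_diff_freq,
                         config = coreg_filter_config()) {
  if (!is.numeric(anchor_diff_freq) || anchor_diff_freq < 1) {
    stop("anchor_diff_freq must be >= 1 (the anchor's differential ",
         "frequency)", call. = FALSE)
  }
  counts <- as_coreg_counts(counts)
  n_pos <- counts[["nUU"]] + counts[["nDD"]]
  n_neg <- counts[["nUD"]] + counts[["nDU"]]
  if (n_pos == n_neg) return("none")
  n_dom <- max(n_pos, n_neg)
  pass <- fet_p < config$fet_alpha &&
    n_dom > config$freq_fraction * anchor_diff_freq &&
    pmid_confidence >= config$pmid_min &&
    expcode_confidence >= config$expcode_min
  if (!pass) return("none")
  if (n_pos > n_neg) "positive" else "negative"
}

#' Site-level co-regulation analysis around an anchor phosphosite
#'
#' For every phosphosite of every other protein that shares at least one
#' informative differential dataset with the anchor, computes the
#' UU/DD/UD/DU counts, co-regulation ratios, a one-sided Fisher's exact
#' p-value in the dominant direction, PMID and experimental-code
#' confidence over the dominant category, and the high-confidence
#' classification. Sites of the anchor's own protein are excluded here;
#' use [cooccurrence_matrix()] for within-protein structure.
#'
#' @param x A `phospho_corpus`, already class-1 filtered if desired.
#' @param anchor The anchor site (`"GENE_S31"`, `"ACCESSION:position"`,
#'   or a list with `accession`/`position`); it must be differentially
#'   regulated in at least one dataset.
#' @param thresholds A [filter_thresholds()] object.
#' @param config A [coreg_filter_config()] object.
#' @return A data frame of class `cpp_analysis` with one row per
#'   candidate site (columns `cpp_accession, cpp_gene, cpp_residue,
#'   cpp_position, nUU, nDD, nUD, nDU, n_pos, n_neg, ratio_pos,
#'   ratio_neg, fet_p, pmid_confidence, expcode_confidence,
#'   classification`), sorted by classification (positive, negative,
#'   none) then dominant frequency descending. The anchor key, its
#'   differential frequency, and the configurations are attached as
#'   attributes.
#' @examples
#' cc <- simulate_corpus(sim_config(seed = 1, n_datasets = 30,
#'                                  n_background_sites = 20))
#' res <- run_coregulation(cc$corpus, "ANCHOR_S10")
#' summary(res)
#' @export
run_coregulation <- function(x, anchor, thresholds = filter_thresholds(),
                             config = coreg_filter_config()) {
  stopifnot(inherits(x, "phospho_corpus"))
  a <- resolve_site(x, anchor)
  dm <- direction_matrix(x, thresholds)
  if (!(a$uid %in% rownames(dm$directions)) ||
      all(is.na(dm$directions[a$uid, ]))) {
    stop("anchor ", a$label, " is never differentially regulated in this ",
         "corpus; inspect site_frequency_table() to choose a predominant ",
         "site", call. = FALSE)
  }
  avec <- dm$directions[a$uid, ]
  au <- !is.na(avec) & avec == "U"
  ad <- !is.na(avec) & avec == "D"
  anchor_diff_freq <- sum(au) + sum(ad)

  cand <- dm$sites[dm$sites$accession != a$accession, , drop = FALSE]
  out <- data.frame(
    cpp_accession = character(0), cpp_gene = character(0),
    cpp_residue = character(0), cpp_position = integer(0),
    nUU = integer(0), nDD = integer(0), nUD = integer(0), nDU = integer(0),
    n_pos = integer(0), n_neg = integer(0),
    ratio_pos = numeric(0), ratio_neg = numeric(0), fet_p = numeric(0),
    pmid_confidence = integer(0), expcode_confidence = integer(0),
    classification = character(0), stringsAsFactors = FALSE
  )
  if (nrow(cand)) {
    M <- dm$directions[cand$uid, , drop = FALSE]
    isU <- !is.na(M) & M == "U"
    isD <- !is.na(M) & M == "D"
    nUU <- as.integer(isU %*% au)
    nDD <- as.integer(isD %*% ad)
    nUD <- as.integer(isD %*% au)
    nDU <- as.integer(isU %*% ad)
    total <- nUU + nDD + nUD + nDU
    keep <- total >= 1L
    if (any(keep)) {
      cand <- cand[keep, , drop = FALSE]
      isU <- isU[keep, , drop = FALSE]
      isD <- isD[keep, , drop = FALSE]
      nUU <- nUU[keep]; nDD <- nDD[keep]; nUD <- nUD[keep]; nDU <- nDU[keep]
      n_pos <- nUU + nDD
      n_neg <- nUD + nDU
      p_conc <- fet_tail(nUU, nDD, nUD, nDU, "concordance")
      p_disc <- fet_tail(nUU, nDD, nUD, nDU, "discordance")
      fet_p <- ifelse(n_pos >= n_neg, p_conc, p_disc)
      n <- nrow(cand)
      pmid_conf <- integer(n)
      exp_conf <- integer(n)
      for (i in seq_len(n)) {
        dom_pos <- n_pos[i] >= n_neg[i]
        mask <- if (dom_pos) {
          (isU[i, ] & au) | (isD[i, ] & ad)
        } else {
          (isU[i, ] & ad) | (isD[i, ] & au)
        }
        pmid_conf[i] <- length(unique(dm$pmid[mask]))
        exp_conf[i] <- length(unique(dm$exp_code[mask]))
      }
      fet_eff <- if (config$p_adjust == "BH") {
        stats::p.adjust(fet_p, method = "BH")
      } else {
        fet_p
      }
      n_dom <- pmax(n_pos, n_neg)
      pass <- fet_eff < config$fet_alpha &
        n_dom > config$freq_fraction * anchor_diff_freq &
        pmid_conf >= config$pmid_min &
        exp_conf >= config$expcode_min
      classification <- rep("none", n)
      classification[pass & n_pos > n_neg] <- "positive"
      classification[pass & n_neg > n_pos] <- "negative"
      out <- data.frame(
        cpp_accession = cand$accession, cpp_gene = cand$gene,
        cpp_residue = cand$residue, cpp_position = cand$position,
        nUU = nUU, nDD = nDD, nUD = nUD, nDU = nDU,
        n_pos = n_pos, n_neg = n_neg,
        ratio_pos = n_pos / n_neg, ratio_neg = n_neg / n_pos,
        fet_p = fet_p,
        pmid_confidence = pmid_conf, expcode_confidence = exp_conf,
        classification = classification, stringsAsFactors = FALSE
      )
      cls_rank <- match(out$classification,
                        c("positive", "negative", "none"))
      ord <- order(cls_rank, -pmax(out$n_pos, out$n_neg),
                   out$cpp_accession, out$cpp_position)
      out <- out[ord, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, class = c("cpp_analysis", "data.frame"),
            anchor = a, anchor_diff_freq = anchor_diff_freq,
            thresholds = thresholds, config = config)
}

#' @export
print.cpp_analysis <- function(x, n = 8L, ...) {
  a <- attr(x, "anchor")
  cat("Co-regulation analysis, anchor ", a$label,
      " (differential frequency ", attr(x, "anchor_diff_freq"), ")\n",
      sep = "")
  tab <- table(factor(x$classification,
                      levels = c("positive", "negative", "none")))
  cat("  candidates: ", nrow(x), "  (", tab[["positive"]], " positive, ",
      tab[["negative"]], " negative, ", tab[["none"]],
      " unclassified)\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(x[, c("cpp_gene", "cpp_residue", "cpp_position",
                              "n_pos", "n_neg", "fet_p",
                              "pmid_confidence", "expcode_confidence",
                              "classification")], n)
    print.data.frame(show, digits = 3)
    if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more candidates\n",
                         sep = "")
  }
  invisible(x)
}

#' @export
summary.cpp_analysis <- function(object, ...) {
  a <- attr(object, "anchor")
  tab <- table(factor(object$classification,
                      levels = c("positive", "negative", "none")))
  structure(list(anchor = a$label,
                 anchor_diff_freq = attr(object, "anchor_diff_freq"),
                 n_candidates = nrow(object),
                 n_positive = tab[["positive"]],
                 n_negative = tab[["negative"]],
                 n_none = tab[["none"]]),
            class = "summary.cpp_analysis")
}

#' @export
print.summary.cpp_analysis <- function(x, ...) {
  cat("Anchor ", x$anchor, ": ", x$n_candidates,
      " candidate sites; ", x$n_positive, " positive and ", x$n_negative,
      " negative high-confidence CPPs (", x$n_none,
      " below confidence filters)\n", sep = "")
  invisible(x)
}

#' Write a co-regulation result table as TSV
#'
#' @param x A `cpp_analysis` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cpp_table <- function(x, path) {
  stopifnot(inherits(x, "cpp_analysis"))
  write_tsv(as.data.frame(x), path)
}
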