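# Class-1 filtering and per-record regulation classification.

#' Retain confidently localized (class-1) phosphosite records
#'
#' A record is retained when at least one reported localization metric
#' passes its threshold: localization probability at or above
#' `thresholds$locprob_min`, or A-score at or above
#' `thresholds$ascore_min`. Records reporting neither metric are dropped.
#' `mode = "both"` is a stricter variant requiring both metrics to be
#' reported and passing. The manifest is left unchanged, so dataset-level
#' frequencies keep their denominators.
#'
#' @param x A `phospho_corpus`.
#' @param thresholds A [filter_thresholds()] object.
#' @param mode `"either"` (default: any reported metric passing suffices)
#'   or `"both"` (both metrics reported and passing).
#' @return The filtered corpus; idempotent.
#' @examples
#' cfg <- sim_config(seed = 1, n_datasets = 6)
#' cc <- simulate_corpus(cfg)
#' filter_class1(cc$corpus)
#' @export
filter_class1 <- function(x, thresholds = filter_thresholds(),
                          mode = c("either", "both")) {
  stopifnot(inherits(x, "phospho_corpus"))
  mode <- match.arg(mode)
  rec <- x$records
  lp_ok <- !is.na(rec$loc_prob) & rec$loc_prob >= thresholds$locprob_min
  as_ok <- !is.na(rec$ascore) & rec$ascore >= thresholds$ascore_min
  keep <- if (mode == "either") lp_ok | as_ok else lp_ok & as_ok
  x$records <- rec[keep, , drop = FALSE]
  rownames(x$records) <- NULL
  x
}

#' Classify per-dataset regulation from fold change and p-value
#'
#' A site in a differential dataset is `"up"` when its linear fold change
#' is at least `thresholds$up_fc` and `p_value < thresholds$alpha`,
#' `"down"` when the fold change is at most `thresholds$down_fc` with the
#' same significance, and `"unregulated"` otherwise. Both fold-change
#' boundaries are inclusive; the significance boundary is strict, so
#' p = 0.05 fails. A missing fold change or p-value yields
#' `"unregulated"`.
#'
#' @param fold_change Numeric vector of linear test/control ratios.
#' @param p_value Numeric vector of p-values, recycled against
#'   `fold_change`.
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector over `c("up", "down", "unregulated")`.
#' @examples
#' classify_regulation(c(1.3, 0.76, 2.0), c(0.04, 0.01, 0.06))
#' @export
classify_regulation <- function(fold_change, p_value,
                                thresholds = filter_thresholds()) {
  n <- max(length(fold_change), length(p_value))
  fold_change <- rep_len(fold_change, n)
  p_value <- rep_len(p_value, n)
  lab <- rep("unregulated", n)
  sig <- !is.na(fold_change) & !is.na(p_value) & p_value < thresholds$alpha
  lab[sig & fold_change >= thresholds$up_fc] <- "up"
  lab[sig & fold_change <= thresholds$down_fc] <- "down"
  lab
}

# "U"/"D"/NA direction matrix over differential datasets:
# rows = site uids, cols = dataset ids. Unregulated or absent -> NA.
direction_matrix <- function(x, thresholds = filter_thresholds()) {
  man <- x$manifest
  diff_ids <- man$dataset_id[man$dtype == "differential"]
  rec <- x$records[x$records$dataset_id %in% diff_ids, , drop = FALSE]
  lab <- classify_regulation(rec$fold_change, rec$p_value, thresholds)
  reg <- lab != "unregulated"
  rec <- rec[reg, , drop = FALSE]
  lab <- lab[reg]
  uids <- unique(site_uid(rec$accession, rec$position))
  m <- matrix(NA_character_, nrow = length(uids), ncol = length(diff_ids),
              dimnames = list(uids, diff_ids))
  if (nrow(rec)) {
    m[cbind(site_uid(rec$accession, rec$position), rec$dataset_id)] <-
      ifelse(lab == "up", "U", "D")
  }
  meta_i <- !duplicated(site_uid(rec$accession, rec$position))
  sites <- data.frame(
    uid = site_uid(rec$accession, rec$position)[meta_i],
    accession = rec$accession[meta_i],
    gene = rec$gene[meta_i],
    residue = rec$residue[meta_i],
    position = rec$position[meta_i],
    stringsAsFactors = FALSE
  )
  list(directions = m, sites = sites, dataset_ids = diff_ids,
       pmid = man$pmid[match(diff_ids, man$dataset_id)],
       exp_code = man$exp_code[match(diff_ids, man$dataset_id)])
}
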