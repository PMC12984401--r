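#' Filtering and regulation-classification thresholds
#'
#' Bundles the thresholds used to retain class-1 phosphosites and to call
#' per-dataset regulation. The defaults are the conventional values used in
#' compendium-scale phosphoproteomic meta-analysis: a site is confidently
#' localized when its localization probability is at least 0.75 or its
#' A-score is at least 13, and a site is called regulated in a differential
#' dataset when its linear fold change is at least 1.3 (up) or at most 0.76
#' (down) with p < 0.05.
#'
#' @param locprob_min Minimum localization probability, in (0, 1].
#' @param ascore_min Minimum A-score (non-negative).
#' @param up_fc Linear fold-change threshold at or above which a site is
#'   upregulated (inclusive).
#' @param down_fc Linear fold-change threshold at or below which a site is
#'   downregulated (inclusive). Must be below `up_fc`.
#' @param alpha Significance level; regulation requires `p_value < alpha`
#'   (strict).
#' @return An object of class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' filter_thresholds(up_fc = 1.5, down_fc = 2 / 3)
#' @export
filter_thresholds <- function(locprob_min = 0.75, ascore_min = 13,
                              up_fc = 1.3, down_fc = 0.76, alpha = 0.05) {
  stopifnot(is.numeric(locprob_min), length(locprob_min) == 1L,
            locprob_min > 0, locprob_min <= 1,
            is.numeric(ascore_min), length(ascore_min) == 1L, ascore_min >= 0,
            is.numeric(up_fc), is.numeric(down_fc),
            down_fc > 0, down_fc < up_fc,
            is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(locprob_min = locprob_min, ascore_min = ascore_min,
                 up_fc = up_fc, down_fc = down_fc, alpha = alpha),
            class = "filter_thresholds")
}

#' Confidence-filter configuration for co-regulation calls
#'
#' High-confidence co-regulated phosphosites (CPPs) must pass a joint
#' filter: a significant one-sided Fisher's exact test, a dominant
#' co-regulation count exceeding a fraction of the anchor site's
#' differential frequency, and reproducibility across at least `pmid_min`
#' distinct publications and `expcode_min` distinct experimental-condition
#' codes (counted over the datasets contributing to the dominant
#' co-regulation category).
#'
#' @param fet_alpha Significance level for the one-sided Fisher's exact
#'   test (strict `<`).
#' @param freq_fraction Fraction of the anchor's differential frequency
#'   that the dominant co-regulation count must strictly exceed.
#' @param pmid_min Minimum number of distinct PMIDs among contributing
#'   datasets.
#' @param expcode_min Minimum number of distinct experimental-condition
#'   codes among contributing datasets.
#' @param p_adjust `"none"` applies the raw FET p-value threshold;
#'   `"BH"` applies a Benjamini-Hochberg correction across all candidate
#'   sites of a [run_coregulation()] call before thresholding.
#' @return An object of class `coreg_filter_config`.
#' @export
coreg_filter_config <- function(fet_alpha = 0.05, freq_fraction = 0.10,
                                pmid_min = 3L, expcode_min = 3L,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(fet_alpha > 0, fet_alpha < 1,
            freq_fraction > 0, freq_fraction < 1,
            pmid_min >= 1, expcode_min >= 1)
  structure(list(fet_alpha = fet_alpha, freq_fraction = freq_fraction,
                 pmid_min = as.integer(pmid_min),
                 expcode_min = as.integer(expcode_min),
                 p_adjust = p_adjust),
            class = "coreg_filter_config")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Class-1 / regulation thresholds:\n",
      "  localization probability >= ", x$locprob_min,
      "  or A-score >= ", x$ascore_min, "\n",
      "  up: fold change >= ", x$up_fc,
      ",  down: fold change <= ", x$down_fc,
      ",  p < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
print.coreg_filter_config <- function(x, ...) {
  cat("Co-regulation confidence filters:\n",
      "  FET p < ", x$fet_alpha, " (", x$p_adjust, " correction)\n",
      "  dominant count > ", x$freq_fraction,
      " x anchor differential frequency\n",
      "  PMID confidence >= ", x$pmid_min,
      ",  experimental-code confidence >= ", x$expcode_min, "\n", sep = "")
  invisible(x)
}
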