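# Within-protein phosphosite co-occurrence across differential datasets:
# the signed pair-frequency matrices behind co-occurrence heatmaps.

#' Within-protein co-occurrence matrix
#'
#' For every unordered pair of a protein's phosphosites, counts over the
#' differential datasets in which both sites are classified up or down:
#' `pos_freq` is the concordant frequency (UU + DD) and `neg_freq` the
#' discordant frequency (UD + DU). Both matrices are symmetric with a
#' zero diagonal; sites are ordered by ascending position.
#'
#' @param x A `phospho_corpus`, class-1 filtered by the caller if
#'   desired.
#' @param accession Protein accession; absent accessions give an empty
#'   matrix.
#' @param thresholds A [filter_thresholds()] object.
#' @param flag_threshold Strict lower bound on the dominant pair
#'   frequency used by [flag_cooccurring()] (pairs with frequency > 3
#'   are flagged by default).
#' @return An object of class `cooc_matrix`: a list with `sites` (data
#'   frame of site keys), `pos_freq`, `neg_freq` (integer matrices), and
#'   `flag_threshold`.
#' @seealso [flag_cooccurring()], [export_heatmap_table()]
#' @export
cooccurrence_matrix <- function(x, accession,
                                thresholds = filter_thresholds(),
                                flag_threshold = 3L) {
  stopifnot(inherits(x, "phospho_corpus"))
  rec <- x$records[x$records$accession == accession, , drop = FALSE]
  first <- !duplicated(site_uid(rec$accession, rec$position))
  sites <- data.frame(accession = rec$accession[first],
                      gene = rec$gene[first],
                      residue = rec$residue[first],
                      position = rec$position[first],
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites$label <- site_display(sites$gene, sites$residue, sites$position)
  n <- nrow(sites)
  pos_freq <- matrix(0L, n, n, dimnames = list(sites$label, sites$label))
  neg_freq <- pos_freq
  if (n > 1L) {
    dm <- direction_matrix(x, thresholds)
    uids <- site_uid(sites$accession, sites$position)
    present <- uids %in% rownames(dm$directions)
    if (any(present)) {
      M <- matrix(NA_character_, n, length(dm$dataset_ids))
      M[present, ] <- dm$directions[uids[present], , drop = FALSE]
      isU <- !is.na(M) & M == "U"
      isD <- !is.na(M) & M == "D"
      pos_freq <- tcrossprod(isU) + tcrossprod(isD)
      neg_freq <- tcrossprod(isU, isD) + tcrossprod(isD, isU)
      storage.mode(pos_freq) <- "integer"
      storage.mode(neg_freq) <- "integer"
      diag(pos_freq) <- 0L
      diag(neg_freq) <- 0L
      dimnames(pos_freq) <- dimnames(neg_freq) <-
        list(sites$label, sites$label)
    }
  }
  structure(list(sites = sites, pos_freq = pos_freq, neg_freq = neg_freq,
                 flag_threshold = as.integer(flag_threshold)),
            class = "cooc_matrix")
}

#' Flag co-occurring site pairs
#'
#' A pair is flagged when its dominant co-regulation frequency
#' (`max(pos_freq, neg_freq)`) strictly exceeds the matrix's
#' `flag_threshold` (default 3, so a frequency of 4 is flagged and 3 is
#' not). The sign is the larger category; a tie above the threshold is
#' reported as `"ambiguous"` rather than silently choosing a sign.
#'
#' @param m A [cooccurrence_matrix()] result.
#' @return Data frame with columns `site_a, site_b, sign, frequency,
#'   pos_freq, neg_freq`, sorted by frequency descending.
#' @export
flag_cooccurring <- function(m) {
  stopifnot(inherits(m, "cooc_matrix"))
  long <- cooc_long(m)
  freq <- pmax(long$pos_freq, long$neg_freq)
  keep <- freq > m$flag_threshold
  long <- long[keep, , drop = FALSE]
  freq <- freq[keep]
  sign <- ifelse(long$pos_freq == long$neg_freq, "ambiguous",
                 ifelse(long$pos_freq > long$neg_freq, "positive",
                        "negative"))
  out <- data.frame(site_a = long$site_a, site_b = long$site_b,
                    sign = sign, frequency = freq,
                    pos_freq = long$pos_freq, neg_freq = long$neg_freq,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$site_a, out$site_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Long format over unordered pairs (site_a before site_b by position).
cooc_long <- function(m) {
  n <- nrow(m$sites)
  if (n < 2L) {
    return(data.frame(site_a = character(0), site_b = character(0),
                      pos_freq = integer(0), neg_freq = integer(0),
                      signed_value = integer(0), stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(m$pos_freq), arr.ind = TRUE)
  pos <- m$pos_freq[idx]
  neg <- m$neg_freq[idx]
  data.frame(site_a = m$sites$label[idx[, 1L]],
             site_b = m$sites$label[idx[, 2L]],
             pos_freq = pos, neg_freq = neg,
             signed_value = ifelse(pos >= neg, pos, -neg),
             stringsAsFactors = FALSE)
}

#' Export a co-occurrence matrix as a long-format heatmap table
#'
#' One row per unordered site pair with `pos_freq`, `neg_freq` and a
#' `signed_value` column (`pos_freq` when concordance dominates or ties,
#' `-neg_freq` otherwise), the numeric encoding of the usual
#' violet/green heatmap gradient.
#'
#' @param m A [cooccurrence_matrix()] result.
#' @param path Optional output TSV path.
#' @return The long-format data frame (invisibly when `path` is given).
#' @export
export_heatmap_table <- function(m, path = NULL) {
  stopifnot(inherits(m, "cooc_matrix"))
  long <- cooc_long(m)
  if (!is.null(path)) {
    write_tsv(long, path)
    return(invisible(long))
  }
  long
}

#' @export
as.data.frame.cooc_matrix <- function(x, ...) {
  cooc_long(x)
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat("Within-protein co-occurrence matrix: ", nrow(x$sites),
      " sites", sep = "")
  if (nrow(x$sites)) {
    cat(" of ", x$sites$accession[1L], sep = "")
  }
  cat("\n")
  flagged <- flag_cooccurring(x)
  cat("  pairs with dominant frequency > ", x$flag_threshold, ": ",
      nrow(flagged), "\n", sep = "")
  if (nrow(flagged)) {
    print.data.frame(utils::head(flagged, 8L))
  }
  invisible(x)
}

#' Heatmap-style plot of a co-occurrence matrix
#'
#' Renders the signed pair frequencies (positive up, negative down) as an
#' image, positive co-regulation in violet and negative in green.
#'
#' @param x A [cooccurrence_matrix()] result.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.cooc_matrix <- function(x, ...) {
  n <- nrow(x$sites)
  if (n < 2L) {
    stop("need at least two sites to plot a co-occurrence matrix",
         call. = FALSE)
  }
  signed <- ifelse(x$pos_freq >= x$neg_freq, x$pos_freq, -x$neg_freq)
  lim <- max(abs(signed), 1L)
  pal <- grDevices::colorRampPalette(c("darkgreen", "white",
                                       "darkviolet"))(64)
  graphics::image(seq_len(n), seq_len(n), t(signed[n:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = x$sites$label, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(x$sites$label), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
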