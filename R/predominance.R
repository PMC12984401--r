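# Frequency ranking of a protein's phosphosites across the compendium.

#' Per-site detection and differential-regulation frequencies
#'
#' For every distinct phosphosite of a protein observed anywhere in the
#' corpus, counts the number of profile datasets in which the site was
#' detected and the number of differential datasets in which it was
#' classified up- or downregulated (a detection that stays unregulated
#' does not count). Each dataset contributes at most one to each count.
#' The corpus is used as given: apply [filter_class1()] first if only
#' class-1 evidence should be counted.
#'
#' @param x A `phospho_corpus`.
#' @param accession Protein accession.
#' @param thresholds A [filter_thresholds()] object used to classify
#'   regulation in differential datasets.
#' @return A data frame of class `site_freq` with columns
#'   `accession, gene, residue, position, profile_count,
#'   differential_count`, sorted by differential count then profile count
#'   (both descending), ties broken by ascending position. Empty when the
#'   accession is absent.
#' @seealso [select_predominant()]
#' @export
site_frequency_table <- function(x, accession,
                                 thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "phospho_corpus"))
  rec <- x$records[x$records$accession == accession, , drop = FALSE]
  man <- x$manifest
  dtype <- man$dtype[match(rec$dataset_id, man$dataset_id)]
  empty <- data.frame(accession = character(0), gene = character(0),
                      residue = character(0), position = integer(0),
                      profile_count = integer(0),
                      differential_count = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(rec)) {
    return(structure(empty, class = c("site_freq", "data.frame"),
                     accession = accession))
  }
  uid <- site_uid(rec$accession, rec$position)
  first <- !duplicated(uid)
  sites <- data.frame(accession = rec$accession[first],
                      gene = rec$gene[first],
                      residue = rec$residue[first],
                      position = rec$position[first],
                      stringsAsFactors = FALSE)
  suid <- uid[first]

  prof <- rec[dtype == "profile", , drop = FALSE]
  prof_uid <- site_uid(prof$accession, prof$position)
  prof_key <- unique(paste(prof_uid, prof$dataset_id, sep = "\r"))
  prof_counts <- table(sub("\r.*$", "", prof_key))

  dif <- rec[dtype == "differential", , drop = FALSE]
  lab <- classify_regulation(dif$fold_change, dif$p_value, thresholds)
  dif <- dif[lab != "unregulated", , drop = FALSE]
  dif_uid <- site_uid(dif$accession, dif$position)
  dif_key <- unique(paste(dif_uid, dif$dataset_id, sep = "\r"))
  dif_counts <- table(sub("\r.*$", "", dif_key))

  sites$profile_count <-
    as.integer(ifelse(is.na(match(suid, names(prof_counts))), 0L,
                      prof_counts[suid]))
  sites$differential_count <-
    as.integer(ifelse(is.na(match(suid, names(dif_counts))), 0L,
                      dif_counts[suid]))
  ord <- order(-sites$differential_count, -sites$profile_count,
               sites$position)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("site_freq", "data.frame"),
            accession = accession)
}

#' Nominate predominant phosphosites
#'
#' Selects the `k` sites with the highest differential-regulation
#' frequency from a [site_frequency_table()]; ties follow the table's
#' ordering (profile count descending, then ascending position).
#'
#' @param rows A `site_freq` table.
#' @param k Number of sites to select; `k <= 0` yields an empty result and
#'   `k` larger than the table is clamped.
#' @return The selected rows (site keys plus their frequencies).
#' @export
select_predominant <- function(rows, k) {
  stopifnot(is.data.frame(rows))
  if (k <= 0 || !nrow(rows)) {
    return(rows[0L, , drop = FALSE])
  }
  ord <- order(-rows$differential_count, -rows$profile_count,
               rows$position)
  out <- rows[ord, , drop = FALSE][seq_len(min(k, nrow(rows))), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.site_freq <- function(x, n = 10L, ...) {
  cat("Site frequency table for ", attr(x, "accession") %||% "<protein>",
      " (", nrow(x), " sites)\n", sep = "")
  if (nrow(x)) {
    print.data.frame(utils::head(x, n))
    if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more sites\n", sep = "")
  }
  invisible(x)
}

#' Lollipop-style frequency plot of a protein's phosphosites
#'
#' Draws per-position detection (profile) and differential-regulation
#' frequencies as vertical stems, the plot behind compendium lollipop
#' figures.
#'
#' @param x A `site_freq` table.
#' @param which `"differential"` or `"profile"` counts.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.site_freq <- function(x, which = c("differential", "profile"), ...) {
  which <- match.arg(which)
  counts <- if (which == "differential") x$differential_count else
    x$profile_count
  graphics::plot(x$position, counts, type = "h", lwd = 2,
                 xlab = "position", ylab = paste(which, "frequency"),
                 main = attr(x, "accession") %||% "", ...)
  graphics::points(x$position, counts, pch = 19)
  invisible(x)
}
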