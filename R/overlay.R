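# Annotation overlays: gene-class (kinase/phosphatase) and
# binary-interactor joins onto co-regulation result tables. Overlays add
# columns and summaries only; the statistical columns are never modified.

#' Read a gene-class table (gene, class)
#'
#' @param path TSV with columns `gene`, `class`.
#' @return Data frame with uppercased gene symbols; duplicate genes with
#'   conflicting classes are an error (one class per gene).
#' @export
read_gene_class_table <- function(path) {
  df <- read_tsv_chr(path)
  stopifnot(all(c("gene", "class") %in% names(df)))
  df$gene <- toupper(df$gene)
  df <- unique(df[c("gene", "class")])
  if (anyDuplicated(df$gene)) {
    stop("gene-class table assigns multiple classes to: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a binary-interactor table (one gene column)
#'
#' @param path TSV with a `gene` column.
#' @return Character vector of unique uppercased gene symbols.
#' @export
read_interactor_table <- function(path) {
  df <- read_tsv_chr(path)
  stopifnot("gene" %in% names(df))
  unique(toupper(df$gene[nzchar(df$gene)]))
}

overlay_guard <- function(cpp) {
  stopifnot(is.data.frame(cpp),
            all(c("cpp_gene", "classification") %in% names(cpp)))
  invisible(cpp)
}

#' Annotate CPPs with gene classes (e.g. kinase / phosphatase)
#'
#' Joins a gene-to-class map onto a co-regulation table by uppercased
#' gene symbol, adding a `gene_class` column (`NA` when unclassified).
#' The per-class, per-classification summary counts both distinct
#' phosphosites (a gene with two CPP sites contributes 2) and distinct
#' genes, attached as attribute `"class_summary"`.
#'
#' @param cpp A [run_coregulation()] result (or any data frame with
#'   `cpp_gene` and `classification` columns).
#' @param classes Data frame with `gene` and `class` columns (see
#'   [read_gene_class_table()]), or `NULL`/empty for no annotation.
#' @return The annotated table; all statistical columns are unchanged.
#' @export
overlay_gene_classes <- function(cpp, classes) {
  overlay_guard(cpp)
  if (is.null(classes) || !nrow(classes)) {
    cpp$gene_class <- NA_character_
    attr(cpp, "class_summary") <- data.frame(
      gene_class = character(0), classification = character(0),
      n_sites = integer(0), n_genes = integer(0),
      stringsAsFactors = FALSE)
    return(cpp)
  }
  stopifnot(all(c("gene", "class") %in% names(classes)))
  classes$gene <- toupper(classes$gene)
  if (anyDuplicated(classes$gene)) {
    stop("gene-class table assigns multiple classes to a gene",
         call. = FALSE)
  }
  g <- toupper(cpp$cpp_gene)
  cpp$gene_class <- classes$class[match(g, classes$gene)]
  ann <- !is.na(cpp$gene_class)
  if (any(ann)) {
    key <- paste(cpp$gene_class[ann], cpp$classification[ann], sep = "\r")
    n_sites <- table(key)
    n_genes <- vapply(split(g[ann], key), function(v) {
      length(unique(v))
    }, 0L)
    parts <- strsplit(names(n_sites), "\r", fixed = TRUE)
    summary <- data.frame(
      gene_class = vapply(parts, `[[`, "", 1L),
      classification = vapply(parts, `[[`, "", 2L),
      n_sites = as.integer(n_sites),
      n_genes = as.integer(n_genes[names(n_sites)]),
      stringsAsFactors = FALSE)
    summary <- summary[order(summary$gene_class, summary$classification), ,
                       drop = FALSE]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(gene_class = character(0),
                          classification = character(0),
                          n_sites = integer(0), n_genes = integer(0),
                          stringsAsFactors = FALSE)
  }
  attr(cpp, "class_summary") <- summary
  cpp
}

#' Flag CPPs whose genes are known binary interactors of the anchor
#'
#' Adds a logical `interactor` column (matched after uppercasing both
#' sides) and a per-classification interactor count as attribute
#' `"interactor_summary"`. Statistical columns are untouched.
#'
#' @param cpp A [run_coregulation()] result (or compatible data frame).
#' @param interactors Character vector of interactor gene symbols (see
#'   [read_interactor_table()]).
#' @return The annotated table.
#' @export
overlay_interactors <- function(cpp, interactors) {
  overlay_guard(cpp)
  interactors <- unique(toupper(interactors))
  cpp$interactor <- toupper(cpp$cpp_gene) %in% interactors
  hit <- cpp$interactor
  summary <- data.frame(
    classification = c("positive", "negative", "none"),
    n_interactor_sites = vapply(c("positive", "negative", "none"),
                                function(cl) {
                                  sum(hit & cpp$classification == cl)
                                }, 0L),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  attr(cpp, "interactor_summary") <- summary
  cpp
}
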