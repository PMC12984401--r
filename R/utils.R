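# Shared internal helpers: site identity, seeded RNG scope, strict TSV I/O.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PHOSPHO_RESIDUES <- c("S", "T", "Y")

# (accession, position) uniquely identifies a site within a corpus
site_uid <- function(accession, position) {
  if (length(accession) == 0L) return(character(0))
  paste0(accession, ":", position)
}

site_display <- function(gene, residue, position) {
  if (length(gene) == 0L) return(character(0))
  paste0(gene, "_", residue, position)
}

# "HDLBP_S31" -> list(gene, residue, position); NULL when not parseable.
parse_site_label <- function(x) {
  m <- regmatches(x, regexec("^(.+)_([STY])([0-9]+)$", x))[[1]]
  if (length(m) != 4L) return(NULL)
  list(gene = m[2], residue = m[3], position = as.integer(m[4]))
}

# Resolve a site given as "GENE_S31", "ACC:31", or a list/data.frame with
# accession+position, against the records of a corpus. Returns a one-row
# site-key list (accession, gene, residue, position, uid, label).
resolve_site <- function(corpus, site) {
  rec <- corpus$records
  hit <- NULL
  if (is.character(site) && length(site) == 1L) {
    parsed <- parse_site_label(site)
    if (!is.null(parsed)) {
      hit <- which(rec$gene == parsed$gene &
                     rec$residue == parsed$residue &
                     rec$position == parsed$position)
    } else if (grepl("^.+:[0-9]+$", site)) {
      acc <- sub(":[0-9]+$", "", site)
      pos <- as.integer(sub("^.*:", "", site))
      hit <- which(rec$accession == acc & rec$position == pos)
    }
    if (is.null(hit) || length(hit) == 0L) {
      stop("site '", site, "' not found in the corpus", call. = FALSE)
    }
  } else {
    site <- as.list(site)
    if (is.null(site$accession) || is.null(site$position)) {
      stop("a site must be given as 'GENE_S31', 'ACCESSION:position', ",
           "or a list with accession and position", call. = FALSE)
    }
    hit <- which(rec$accession == site$accession &
                   rec$position == as.integer(site$position))
    if (length(hit) == 0L) {
      stop("site '", site_uid(site$accession, site$position),
           "' not found in the corpus", call. = FALSE)
    }
  }
  i <- hit[1L]
  list(accession = rec$accession[i], gene = rec$gene[i],
       residue = rec$residue[i], position = rec$position[i],
       uid = site_uid(rec$accession[i], rec$position[i]),
       label = site_display(rec$gene[i], rec$residue[i], rec$position[i]))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero to one decimal (so 25.25 -> 25.3, not 25.2).
round_half_up1 <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

# Strict TSV readers/writers for the record dialect: tab-separated, header
# required, no quoting, empty string = absent.
read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    quote = "", na.strings = NULL,
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

chr_or_empty <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

parse_num <- function(x) {
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

parse_int <- function(x) {
  x[x == ""] <- NA_character_
  suppressWarnings(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
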