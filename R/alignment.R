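# Alignment input, IUPAC bitmask encoding, and site-pattern compression.

# 4-bit IUPAC masks: A=1, C=2, G=4, T=8; ambiguity codes are unions of bits;
# gaps and '?' are fully ambiguous (mask 15).
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  "-" = 15L, "?" = 15L
)

#' Read a nucleotide multiple sequence alignment
#'
#' Reads FASTA or NEXUS (DATA/TAXA/CHARACTERS blocks, sequential or
#' interleaved) alignments of IUPAC nucleotide codes, gaps (`-`) and missing
#' data (`?`). Input is case-insensitive; `U` is accepted as `T`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"`, `"nexus"`, or `"auto"` (sniff the first
#'   non-blank line: a `#NEXUS` header selects NEXUS).
#' @return An object of class `phyfuse_alignment`: a list with
#'   `taxon_labels`, `rows` (named character vector of upper-cased
#'   sequences), `n_taxa` and `n_columns`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
#' aln <- read_alignment(fa)
#' aln$n_taxa
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && grepl("^#NEXUS", trimws(first[1]),
                                         ignore.case = TRUE)) "nexus" else "fasta"
  }
  seqs <- if (format == "fasta") {
    x <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                            forceDNAtolower = FALSE)
    vapply(x, function(s) as.character(s)[1L], "")
  } else {
    x <- ape::read.nexus.data(path)
    vapply(x, function(ch) paste(ch, collapse = ""), "")
  }
  new_alignment(toupper(seqs))
}

# Construct and validate an alignment from a named character vector of rows.
new_alignment <- function(rows) {
  labels <- names(rows)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("alignment format error: every sequence needs a taxon label")
  if (anyDuplicated(labels))
    stop("alignment format error: duplicate taxon label '",
         labels[duplicated(labels)][1], "'")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment format error: ragged rows (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  rows <- toupper(rows)
  legal <- names(IUPAC_MASK)
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% legal)
    if (length(bad))
      stop("alignment format error: illegal character '", ch[bad[1]],
           "' in taxon '", labels[i], "' at column ", bad[1])
  }
  structure(
    list(taxon_labels = labels, rows = rows,
         n_taxa = length(rows), n_columns = unname(lens[1])),
    class = "phyfuse_alignment")
}

#' @export
print.phyfuse_alignment <- function(x, ...) {
  cat("phyfuse alignment:", x$n_taxa, "taxa x", x$n_columns, "columns\n")
  invisible(x)
}

#' Encode alignment characters as 4-bit state masks
#'
#' Maps each character to the union of the one-hot nucleotide bits
#' (A=1, C=2, G=4, T=8) it is compatible with; `N`, `-` and `?` become the
#' fully ambiguous mask 15.
#'
#' @param alignment A `phyfuse_alignment`.
#' @return Integer matrix, taxa in rows (named), columns = alignment columns;
#'   every entry in 1..15.
#' @export
encode_states <- function(alignment) {
  stopifnot(inherits(alignment, "phyfuse_alignment"))
  m <- matrix(0L, alignment$n_taxa, alignment$n_columns,
              dimnames = list(alignment$taxon_labels, NULL))
  for (i in seq_len(alignment$n_taxa)) {
    ch <- strsplit(alignment$rows[i], "", fixed = TRUE)[[1]]
    m[i, ] <- unname(IUPAC_MASK[ch])
  }
  m
}

#' Compress an encoded alignment to unique site patterns
#'
#' Collapses identical columns to unique site patterns with multiplicity
#' weights, keeping first-occurrence order. The per-pattern weight times the
#' pattern likelihood reproduces the full-alignment likelihood.
#'
#' @param x A `phyfuse_alignment` or an encoded state matrix from
#'   [encode_states()].
#' @return An object of class `phyfuse_patterns`: list with `patterns`
#'   (taxa x L integer matrix), `weights` (integer, length L), `L`,
#'   `n_columns`, and `column_map` (original column -> pattern index, so the
#'   compression is invertible).
#' @seealso [decompress_patterns()]
#' @export
compress_patterns <- function(x) {
  enc <- if (inherits(x, "phyfuse_alignment")) encode_states(x) else x
  stopifnot(is.matrix(enc), ncol(enc) >= 1L)
  storage.mode(enc) <- "integer"
  key <- apply(enc, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  patterns <- enc[, first, drop = FALSE]
  weights <- as.integer(tabulate(idx, nbins = sum(first)))
  structure(
    list(patterns = patterns, weights = weights, L = ncol(patterns),
         n_columns = ncol(enc), column_map = idx),
    class = "phyfuse_patterns")
}

#' Reconstruct the encoded matrix from compressed patterns
#'
#' Inverse of [compress_patterns()]: repeats each pattern at its recorded
#' original positions.
#'
#' @param cp A `phyfuse_patterns` object.
#' @return The encoded state matrix that was compressed.
#' @export
decompress_patterns <- function(cp) {
  stopifnot(inherits(cp, "phyfuse_patterns"))
  cp$patterns[, cp$column_map, drop = FALSE]
}

#' @export
print.phyfuse_patterns <- function(x, ...) {
  cat("phyfuse site patterns:", x$L, "unique patterns over", x$n_columns,
      "columns,", nrow(x$patterns), "taxa\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param alignment A `phyfuse_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "phyfuse_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(alignment$n_taxa))
    writeLines(c(paste0(">", alignment$taxon_labels[i]), alignment$rows[i]), con)
  invisible(path)
}

#' Write an alignment to sequential NEXUS
#'
#' Emits a minimal DATA block (DATATYPE=DNA, MISSING=?, GAP=-).
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_nexus <- function(alignment, path) {
  stopifnot(inherits(alignment, "phyfuse_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", alignment$n_taxa, alignment$n_columns),
    "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "MATRIX"), con)
  writeLines(sprintf("%s  %s", format(alignment$taxon_labels), alignment$rows), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}
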