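#' Build a sequence pool from DNA records
#'
#' A sequence pool is the working representation of one side (query or
#' subject) of an alignment-free comparison: all contigs are uppercased,
#' stripped of `N` and other ambiguity codes, and concatenated in input
#' order *without* separators, so that substring matches may span contig
#' borders (they are cut off after a usually short run of chance matches;
#' many contigs therefore inflate the short end of the shustring-length
#' distribution and bias diversity upward). When `strand_double = TRUE`
#' (the default) the reverse complement of the concatenated forward strand
#' is appended, so both strands contribute to every comparison.
#'
#' @param x A character vector of DNA sequences (one element per contig),
#'   a [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param strand_double Append the reverse complement of the concatenated
#'   forward strand? Default `TRUE`.
#' @param sentinel Insert a non-matching separator character between
#'   contigs so matches cannot span borders? Default `FALSE`, replicating
#'   the concatenation behaviour of the reference method. Query and
#'   subject pools use distinct separator characters so separators never
#'   match each other; set `role` accordingly.
#' @param role Either `"query"` or `"subject"`; only used to pick the
#'   separator character in sentinel mode.
#'
#' @return An object of class `sequence_pool`: a list with elements
#'   `sequence` (one concatenated string), `contig_bounds` (tibble with
#'   0-based half-open `start`/`end` per contig on the forward strand, plus
#'   the contig `name`), `strand_doubled`, `half_length` (single-strand
#'   length, excluding separators), `gc` (GC fraction of the forward
#'   strand) and `n_removed` (count of dropped non-ACGT symbols).
#' @export
#' @examples
#' sequence_pool(c("AC", "GG"), strand_double = FALSE)
sequence_pool <- function(x, strand_double = TRUE, sentinel = FALSE,
                          role = c("query", "subject")) {
  role <- match.arg(role)
  if (inherits(x, "DNAStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  } else if (is.character(x) && length(x) == 1 && !grepl("[^A-Za-z./_~-]", x) &&
             file.exists(x)) {
    x <- read_fasta(x)
  }
  if (!is.character(x) || length(x) == 0) {
    stop("`x` must be a non-empty character vector, DNAStringSet or FASTA path")
  }
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("contig_", seq_along(x))

  cleaned <- toupper(x)
  n_before <- nchar(cleaned)
  cleaned <- gsub("[^ACGT]", "", cleaned)
  n_removed <- sum(n_before - nchar(cleaned))
  keep <- nchar(cleaned) > 0
  if (!all(keep)) {
    warning(sum(!keep), " record(s) with no A/C/G/T content skipped")
    cleaned <- cleaned[keep]
    nm <- nm[keep]
  }
  if (length(cleaned) == 0) stop("no usable sequence in input")

  len <- unname(nchar(cleaned))
  ends <- cumsum(len)
  bounds <- tibble::tibble(name = unname(nm), start = ends - len, end = ends)

  sep <- if (sentinel) {
    if (role == "query") "!" else "#"
  } else {
    ""
  }
  forward <- paste(cleaned, collapse = sep)
  gc <- gc_fraction(paste(cleaned, collapse = ""))

  seq <- forward
  if (strand_double) seq <- paste0(forward, revcomp(forward))

  structure(
    list(
      sequence = seq,
      contig_bounds = bounds,
      strand_doubled = strand_double,
      half_length = sum(len),
      sentinel = sentinel,
      sep = sep,
      gc = gc,
      n_removed = n_removed
    ),
    class = "sequence_pool"
  )
}

#' Read a FASTA file into a sequence pool
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] followed by
#' [sequence_pool()].
#'
#' @param path Path to a (possibly multi-record, line-wrapped) FASTA file.
#' @inheritParams sequence_pool
#' @return A `sequence_pool`.
#' @export
read_pool <- function(path, strand_double = TRUE, sentinel = FALSE,
                      role = c("query", "subject")) {
  sequence_pool(read_fasta(path), strand_double = strand_double,
                sentinel = sentinel, role = role)
}

read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Reverse complement of a DNA string
#'
#' Separator characters used in sentinel mode are mapped to themselves.
#'
#' @param s A single DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         intToUtf8(rev(utf8ToInt(s)), multiple = FALSE))
}

gc_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0) return(NA_real_)
  gc <- n - nchar(gsub("[GC]", "", s))
  gc / n
}

#' @export
print.sequence_pool <- function(x, ...) {
  cat("<sequence_pool> ", nrow(x$contig_bounds), " contig(s), ",
      x$half_length, " bp forward strand",
      if (x$strand_doubled) " (strand-doubled)" else "",
      ", GC ", sprintf("%.3f", x$gc), "\n", sep = "")
  invisible(x)
}

#' Total indexed length of a pool
#'
#' @param pool A `sequence_pool`.
#' @return Number of characters in the concatenated (possibly doubled)
#'   sequence, excluding separators.
#' @export
pool_length <- function(pool) {
  stopifnot(inherits(pool, "sequence_pool"))
  x <- if (pool$strand_doubled) 2L else 1L
  x * pool$half_length
}
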