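#' Shustring lengths of a query against a subject
#'
#' For every position `i` of the (possibly strand-doubled) query, the
#' shortest unique substring (shustring) length is the length of the
#' shortest substring starting at `i` that occurs nowhere in the subject.
#' It equals the matching statistic at `i` (the longest prefix of the query
#' suffix that is a substring of the subject) plus one, capped at the
#' distance to the query end when no unique extension exists. Matching
#' statistics are computed by streaming the query through a suffix
#' automaton of the subject, so total time is linear in the combined
#' sequence length.
#'
#' @param query,subject `sequence_pool` objects (see [sequence_pool()]).
#' @return An object of class `shustring_profile`: a list with integer
#'   vector `lengths` (one per profiled query position), logical `capped`
#'   (positions where the cap at the query end was binding), and `n`
#'   (number of profiled positions). In sentinel mode, separator positions
#'   are excluded from the profile.
#' @export
#' @examples
#' q <- sequence_pool("CCGTT", strand_double = FALSE)
#' s <- sequence_pool("TCGT", strand_double = FALSE)
#' shustring_lengths(q, s)$lengths
shustring_lengths <- function(query, subject) {
  stopifnot(inherits(query, "sequence_pool"), inherits(subject, "sequence_pool"))
  if (nchar(query$sequence) == 0 || nchar(subject$sequence) == 0) {
    stop("query and subject pools must be non-empty")
  }
  ms <- cpp_matching_stats(subject$sequence, query$sequence)
  n <- length(ms)
  remaining <- n - seq_len(n) + 1L

  if (query$sentinel && nzchar(query$sep)) {
    is_sep <- strsplit(query$sequence, "", fixed = TRUE)[[1]] == query$sep
    # the cap is the distance to the query end in indexed characters;
    # separator positions themselves carry no shustring
    keep <- !is_sep
    ms <- ms[keep]
    remaining <- remaining[keep]
    n <- sum(keep)
  }

  lengths <- pmin(ms + 1L, remaining)
  capped <- ms >= remaining
  new_shustring_profile(lengths, capped)
}

new_shustring_profile <- function(lengths, capped) {
  structure(
    list(lengths = as.integer(lengths), capped = as.logical(capped),
         n = length(lengths)),
    class = "shustring_profile"
  )
}

#' @export
print.shustring_profile <- function(x, ...) {
  cat("<shustring_profile> ", x$n, " positions, max length ",
      max(x$lengths), ", ", sum(x$capped), " capped\n", sep = "")
  invisible(x)
}

#' @export
#' @method as.data.frame shustring_profile
as.data.frame.shustring_profile <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(position = seq_len(x$n), length = x$lengths, capped = x$capped)
}

#' Histogram of shustring lengths
#'
#' Tabulates a shustring profile into absolute counts `f(x)` per length
#' `x`, the empirical input to the maximum-likelihood diversity estimator.
#' Capped positions (where the query ended before a unique substring was
#' reached) are retained at their capped value and additionally counted in
#' `n_capped` so they can be excluded downstream if desired.
#'
#' @param profile A `shustring_profile`, or a bare vector of positive
#'   integer lengths.
#' @return A tibble of class `shustring_histogram` with columns `length`,
#'   `count` and `n_capped`, rows sorted by length, restricted to observed
#'   lengths. Attributes `xi` (maximum observed length) and `total`
#'   (number of profiled positions).
#' @export
shustring_histogram <- function(profile) {
  if (inherits(profile, "shustring_profile")) {
    lengths <- profile$lengths
    capped <- profile$capped
  } else {
    lengths <- as.integer(profile)
    capped <- rep(FALSE, length(lengths))
  }
  if (length(lengths) == 0) stop("profile is empty")
  stopifnot(all(lengths >= 1L))
  counts <- tabulate(lengths)
  capped_counts <- if (any(capped)) tabulate(lengths[capped], nbins = length(counts)) else integer(length(counts))
  keep <- counts > 0L
  out <- tibble::tibble(
    length = which(keep),
    count = counts[keep],
    n_capped = capped_counts[keep]
  )
  attr(out, "xi") <- max(lengths)
  attr(out, "total") <- length(lengths)
  class(out) <- c("shustring_histogram", class(out))
  out
}

#' Count shustring peaks in a profile
#'
#' A peak occurs at position `i >= 2` when the shustring length does not
#' decrease from position `i - 1` to `i` (`ties = TRUE`, the default), or
#' strictly increases (`ties = FALSE`); each peak indicates that a new
#' polymorphism (or chance match boundary) is being tracked. The peak count
#' drives the missing-data heuristic of the window scanner: windows with
#' more peaks than `window_length * max_pi` plausibly lack a homolog in the
#' subject.
#'
#' The two variants differ sharply on homologous data: positions just
#' ahead of a polymorphism fall back to the background match floor, where
#' consecutive lengths jitter by 0 or +-1 and ties are common. With
#' `ties = TRUE` these background ties dominate the count (density ~ 0.06
#' per site already at pi = 0.01, right at the conventional threshold
#' `max_pi = 0.06`), so the scanner uses the strict variant, whose density
#' stays proportional to diversity (~ 0.03 at pi = 0.01, ~ 0.14 at
#' pi = 0.08, ~ 0.28 for unrelated sequence) and therefore actually
#' separates usable from missing windows at that threshold.
#'
#' @param profile A `shustring_profile` or a numeric vector of lengths.
#' @param ties If `TRUE` (default), count non-decreasing steps; if `FALSE`,
#'   count strictly increasing steps only.
#' @return Integer peak count (0 for a profile of length 1).
#' @export
#' @examples
#' count_peaks(c(5, 4, 3, 2, 7, 6))  # 1
#' count_peaks(c(3, 3, 3))           # 2
#' count_peaks(c(3, 3, 3), ties = FALSE)  # 0
count_peaks <- function(profile, ties = TRUE) {
  v <- if (inherits(profile, "shustring_profile")) profile$lengths else as.numeric(profile)
  if (length(v) < 1) stop("profile must contain at least one position")
  if (length(v) == 1) return(0L)
  if (ties) sum(v[-1] >= v[-length(v)]) else sum(v[-1] > v[-length(v)])
}
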