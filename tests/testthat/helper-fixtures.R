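# Shared test helpers: brute-force oracles and small utilities.

# Brute-force matching statistic: for each position i of `query`, the
# length of the longest prefix of query[i..] that occurs somewhere in
# `subject`. Quadratic; for oracle tests on short strings only.
oracle_matching_stats <- function(query, subject) {
  n <- nchar(query)
  vapply(seq_len(n), function(i) {
    l <- 0L
    while (i + l <= n &&
           grepl(substr(query, i, i + l), subject, fixed = TRUE)) {
      l <- l + 1L
    }
    l
  }, integer(1))
}

# Brute-force shustring lengths with end-capping, mirroring
# shustring_lengths() semantics on a raw (already pooled) string pair.
oracle_shustring_lengths <- function(query, subject) {
  ms <- oracle_matching_stats(query, subject)
  n <- nchar(query)
  remaining <- n - seq_len(n) + 1L
  list(lengths = pmin(ms + 1L, remaining), capped = ms >= remaining)
}

random_dna <- function(n, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Direct evaluation of the general background-match sum, with the large
# power taken through log1p for accuracy; oracle for background_cdf().
brute_background_cdf <- function(p, ell_s, x) {
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    k <- 0:xx
    word <- p^k * (0.5 - p)^(xx - k)
    sum(2^xx * choose(xx, k) * word * exp(2 * ell_s * log1p(-word)))
  }, numeric(1))
}

# Total variation distance between an empirical count vector (indexed by
# length 1..max) and a pmf evaluated on the same support, with the pmf's
# remaining tail mass counted against zero empirical mass.
tv_distance <- function(counts, pmf_vals) {
  emp <- counts / sum(counts)
  tail_mass <- max(0, 1 - sum(pmf_vals))
  (sum(abs(emp - pmf_vals)) + tail_mass) / 2
}

write_temp_fasta <- function(records, prefix = "pool") {
  path <- tempfile(prefix, fileext = ".fa")
  set <- Biostrings::DNAStringSet(unname(records))
  names(set) <- names(records) %||% paste0("rec", seq_along(records))
  Biostrings::writeXStringSet(set, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
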