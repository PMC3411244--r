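#' Simulate a query/subject pair under a two-lineage coalescent with
#' recombination
#'
#' Generates an aligned pair of DNA sequences whose per-site time to the
#' most recent common ancestor (TMRCA) follows the sequentially Markov
#' approximation of the pairwise coalescent: the TMRCA `T` is exponential
#' with mean one (coalescent units) at any site; moving along the
#' sequence, a recombination breakpoint falls between adjacent sites with
#' probability `1 - exp(-rho * T)`, and at a breakpoint the new TMRCA is
#' redrawn as `U + Exp(1)` with `U ~ Uniform(0, T)` (the detached lineage
#' re-coalesces at rate one above the uniform recombination point). This
#' transition preserves the Exp(1) marginal. Given the local TMRCA, each
#' site is a mismatch independently with probability `pi * T` (clamped at
#' 0.95; clamping events are counted and a warning is raised above 0.1% of
#' sites), so the expected mismatch fraction is `pi`. A Jukes-Cantor
#' finite-sites mode is available via `mutation_model = "jc"`, where the
#' mismatch probability is `3/4 * (1 - exp(-4 pi T / 3))`.
#'
#' `rho` is the per-site population-scaled recombination rate on the same
#' per-site scale as `pi`, so `rho = pi` means mutation and recombination
#' are equally frequent.
#'
#' @param L Sequence length in bp.
#' @param pi Expected mismatches per site, in (0, 1).
#' @param rho Per-site recombination rate, >= 0.
#' @param gc_content GC fraction of the base composition (default 0.5).
#' @param seed Integer seed; all randomness derives from it.
#' @param mutation_model `"linear"` (default, `P(mismatch|T) = pi T`
#'   clamped) or `"jc"` (Jukes-Cantor).
#' @return An object of class `sim_pair`: list with `seq_a`, `seq_b`
#'   (strings of length `L`), `tmrca` (numeric, per site), `mismatch_mask`
#'   (logical, `seq_a[i] != seq_b[i]`), `n_segments`, `n_clamped` and
#'   `params`.
#' @export
simulate_pair <- function(L, pi, rho, gc_content = 0.5, seed,
                          mutation_model = c("linear", "jc")) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(L >= 1, pi > 0, pi < 1, rho >= 0,
            gc_content > 0, gc_content < 1)
  if (missing(seed)) stop("`seed` is required for reproducibility")
  set.seed(as.integer(seed))
  L <- as.integer(L)

  # segment-constant TMRCA along the sequence (SMC for two lineages)
  seg_t <- numeric(64)
  seg_l <- numeric(64)
  k <- 0L
  pos <- 0L
  t <- rexp(1)
  while (pos < L) {
    pr <- if (rho > 0) -expm1(-rho * t) else 0
    d <- if (pr > 0) rgeom(1, pr) + 1 else Inf
    len <- min(d, L - pos)
    k <- k + 1L
    if (k > length(seg_t)) {
      length(seg_t) <- 2L * length(seg_t)
      length(seg_l) <- 2L * length(seg_l)
    }
    seg_t[k] <- t
    seg_l[k] <- len
    pos <- pos + len
    if (pos < L) t <- runif(1, 0, t) + rexp(1)
  }
  seg_t <- seg_t[seq_len(k)]
  seg_l <- seg_l[seq_len(k)]
  tmrca <- rep(seg_t, times = seg_l)

  p_mis <- switch(mutation_model,
                  linear = pmin(pi * tmrca, 0.95),
                  jc = 0.75 * -expm1(-4 / 3 * pi * tmrca))
  n_clamped <- if (mutation_model == "linear") sum(pi * tmrca > 0.95) else 0L
  if (n_clamped > 0.001 * L) {
    warning(sprintf("mismatch probability clamped at %d of %d sites (%.2f%%)",
                    n_clamped, L, 100 * n_clamped / L))
  }
  mask <- runif(L) < p_mis

  base_prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
                 (1 - gc_content) / 2)
  a <- sample.int(4L, L, replace = TRUE, prob = base_prob)
  b <- a
  idx <- which(mask)
  while (length(idx) > 0) {
    b[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = base_prob)
    idx <- idx[b[idx] == a[idx]]
  }

  codes <- utf8ToInt("ACGT")
  structure(
    list(
      seq_a = intToUtf8(codes[a]),
      seq_b = intToUtf8(codes[b]),
      tmrca = tmrca,
      mismatch_mask = mask,
      n_segments = k,
      n_clamped = n_clamped,
      params = list(L = L, pi = pi, rho = rho, gc_content = gc_content,
                    seed = as.integer(seed), mutation_model = mutation_model)
    ),
    class = "sim_pair"
  )
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf(
    "<sim_pair> L = %d, pi = %g, rho = %g, seed = %d: %d segment(s), %d mismatches (%.4f/site)\n",
    x$params$L, x$params$pi, x$params$rho, x$params$seed, x$n_segments,
    sum(x$mismatch_mask), mean(x$mismatch_mask)))
  invisible(x)
}

#' Export a simulated pair as unaligned contig sets
#'
#' Fragments each sequence of a simulated pair into contigs at uniform
#' random internal breakpoints and shuffles the record order, emulating
#' the unordered contigs of a draft assembly; the alignment is discarded.
#' Record names carry the original offset so tests can reassemble them.
#'
#' @param sim_pair A `sim_pair`.
#' @param n_contigs_a,n_contigs_b Number of contigs per sequence (>= 1,
#'   <= sequence length).
#' @return A list with named character vectors `a` and `b`, one element
#'   per contig, ready for [sequence_pool()] or
#'   [Biostrings::writeXStringSet()].
#' @export
export_unaligned <- function(sim_pair, n_contigs_a = 1, n_contigs_b = 1) {
  stopifnot(inherits(sim_pair, "sim_pair"))
  L <- sim_pair$params$L
  if (n_contigs_a > L || n_contigs_b > L) {
    stop("cannot split a sequence of length ", L, " into more contigs than sites")
  }
  split_one <- function(s, n, tag) {
    n <- as.integer(n)
    brk <- if (n > 1) sort(sample.int(L - 1L, n - 1L)) else integer(0)
    start <- c(1L, brk + 1L)
    end <- c(brk, L)
    pieces <- substring(s, start, end)
    names(pieces) <- sprintf("%s_contig%02d offset=%d", tag, seq_len(n), start)
    sample(pieces)
  }
  list(a = split_one(sim_pair$seq_a, n_contigs_a, "a"),
       b = split_one(sim_pair$seq_b, n_contigs_b, "b"))
}

#' Random sequence pool
#'
#' Generates a pool of i.i.d. nucleotides with the requested GC content --
#' the background model against which chance match lengths concentrate
#' near `log4` of the doubled subject length.
#'
#' @param L Sequence length in bp.
#' @param gc_content GC fraction (default 0.5).
#' @param seed Integer seed.
#' @param strand_double Passed to [sequence_pool()].
#' @return A `sequence_pool`.
#' @export
random_pool <- function(L, gc_content = 0.5, seed, strand_double = TRUE) {
  stopifnot(L >= 1, gc_content > 0, gc_content < 1)
  if (missing(seed)) stop("`seed` is required for reproducibility")
  set.seed(as.integer(seed))
  base_prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
                 (1 - gc_content) / 2)
  a <- sample.int(4L, L, replace = TRUE, prob = base_prob)
  sequence_pool(intToUtf8(utf8ToInt("ACGT")[a]), strand_double = strand_double)
}
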