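#' Sliding-window diversity scan
#'
#' Slides a window along the forward strand of the query and, for each
#' window, treats the window's two strands as the query of a shustring
#' computation against the full (doubled) subject. Matching statistics are
#' computed once for the whole query; each window's shustring lengths are
#' then obtained by re-capping them at the window end, which is equivalent
#' to running the window alone as the query. Per window, the
#' maximum-likelihood estimate `pi_d` is computed from the window's
#' length histogram (with `ell_q` equal to the window length), alongside
#' the inverse-mean estimate `pi_m` and the shustring peak count of the
#' forward-strand half.
#'
#' Windows whose peak count exceeds `window * max_pi` are flagged
#' `missing`: an excess of short chance matches indicates the window lacks
#' a full homolog in the subject, which would otherwise masquerade as high
#' diversity. Peaks are counted in the strict sense (see [count_peaks()],
#' `ties = FALSE`): the tie-inclusive count is dominated by background
#' match-floor jitter and already reaches the conventional threshold at
#' pi = 0.01, while the strict count scales with diversity and separates
#' homologous from unrelated windows. Missing windows keep their row
#' (with `pi_d = NA`) so the output is a regular grid.
#'
#' @param query,subject `sequence_pool` objects (sentinel mode not
#'   supported here). Windows are placed on the query's forward strand.
#' @param window Window length in bp (default 1e5).
#' @param step Step between window starts in bp (default 1e4). Windows
#'   start at 0, `step`, `2 * step`, ...; only fully contained windows are
#'   emitted.
#' @param max_pi Peak-density threshold of the missing-data heuristic
#'   (default 0.06, the largest diversity at which the estimator is
#'   usable).
#' @param p Half-GC frequency for the background model; default half the
#'   subject's observed GC fraction.
#' @param min_total Minimum positions per window for estimation.
#' @return A tibble of class `shustring_scan` with columns `window_start`,
#'   `window_end` (1-based, inclusive), `pi_d` (NA when missing or not
#'   converged), `pi_m`, `peaks`, `missing`. Attributes record `window`,
#'   `step`, `max_pi`, `p` and `ell_s`.
#' @export
scan_windows <- function(query, subject, window = 1e5, step = 1e4,
                         max_pi = 0.06, p = NULL, min_total = 100) {
  stopifnot(inherits(query, "sequence_pool"), inherits(subject, "sequence_pool"))
  if (query$sentinel || subject$sentinel) {
    stop("scan_windows() requires pools built without sentinel separators")
  }
  if (nchar(subject$sequence) == 0) stop("subject pool is empty")
  L <- query$half_length
  window <- as.integer(window)
  step <- as.integer(step)
  if (window > L) stop("window (", window, ") exceeds query length (", L, ")")
  if (step < 1) stop("step must be >= 1")
  if (is.null(p)) p <- subject$gc / 2
  ell_s <- subject$half_length

  ms <- cpp_matching_stats(subject$sequence, query$sequence)
  starts <- seq.int(0L, L - window, by = step)

  res <- lapply(starts, function(s) {
    f_idx <- (s + 1L):(s + window)
    rem_f <- (s + window) - f_idx + 1L
    xf <- pmin(ms[f_idx] + 1L, rem_f)
    cap_f <- ms[f_idx] >= rem_f

    if (query$strand_doubled) {
      r_idx <- (2L * L - s - window + 1L):(2L * L - s)
      rem_r <- (2L * L - s) - r_idx + 1L
      xr <- pmin(ms[r_idx] + 1L, rem_r)
      cap_r <- ms[r_idx] >= rem_r
    } else {
      xr <- integer(0)
      cap_r <- logical(0)
    }

    peaks <- count_peaks(xf, ties = FALSE)
    missing <- peaks > window * max_pi
    lens <- c(xf, xr)
    pi_m <- 1 / mean(lens)

    pi_d <- NA_real_
    if (!missing) {
      hist <- shustring_histogram(new_shustring_profile(lens, c(cap_f, cap_r)))
      est <- estimate_pi_d(hist, p = p, ell_s = ell_s, ell_q = window,
                           min_total = min_total)
      if (isTRUE(est$converged)) pi_d <- est$pi_hat
    }
    list(window_start = s + 1L, window_end = s + window, pi_d = pi_d,
         pi_m = pi_m, peaks = as.integer(peaks), missing = missing)
  })

  out <- tibble::tibble(
    window_start = vapply(res, `[[`, integer(1), "window_start"),
    window_end = vapply(res, `[[`, integer(1), "window_end"),
    pi_d = vapply(res, `[[`, numeric(1), "pi_d"),
    pi_m = vapply(res, `[[`, numeric(1), "pi_m"),
    peaks = vapply(res, `[[`, integer(1), "peaks"),
    missing = vapply(res, `[[`, logical(1), "missing")
  )
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "max_pi") <- max_pi
  attr(out, "p") <- p
  attr(out, "ell_s") <- ell_s
  class(out) <- c("shustring_scan", class(out))
  out
}

#' Alignment-based diversity per window of a simulated pair
#'
#' For simulated pairs the alignment is known, so the true per-window
#' mismatch fraction can be computed on the same window grid as
#' [scan_windows()] and used as ground truth.
#'
#' @param sim_pair A `sim_pair` from [simulate_pair()].
#' @param window,step Window grid as in [scan_windows()].
#' @return A tibble with `window_start`, `window_end` (1-based, inclusive)
#'   and `pi_true` (mismatch fraction).
#' @export
per_window_truth <- function(sim_pair, window = 1e5, step = 1e4) {
  stopifnot(inherits(sim_pair, "sim_pair"))
  L <- sim_pair$params$L
  window <- as.integer(window)
  step <- as.integer(step)
  if (window > L) stop("window exceeds sequence length")
  cs <- c(0, cumsum(sim_pair$mismatch_mask))
  starts <- seq.int(0L, L - window, by = step)
  tibble::tibble(
    window_start = starts + 1L,
    window_end = starts + window,
    pi_true = (cs[starts + window + 1L] - cs[starts + 1L]) / window
  )
}

#' Write a window scan as a tab-delimited table
#'
#' Columns `window_start` (1-based), `window_end`, `pi_d` (NA when
#' missing), `pi_m`, `peaks`, `missing` (0/1); the header line is prefixed
#' with `#`. Numbers are printed with 6 significant digits.
#'
#' @param scan A `shustring_scan` tibble.
#' @param path Output file path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  header <- "#window_start\twindow_end\tpi_d\tpi_m\tpeaks\tmissing"
  fmt <- function(v) ifelse(is.na(v), "NA", format(signif(v, 6), trim = TRUE))
  lines <- paste(scan$window_start, scan$window_end, fmt(scan$pi_d),
                 fmt(scan$pi_m), scan$peaks, as.integer(scan$missing),
                 sep = "\t")
  writeLines(c(header, lines), con = path)
  invisible(path)
}

#' Read a window scan written by [write_scan_tsv()]
#'
#' @param path Path to the tab-delimited scan table.
#' @return A tibble with the scan columns.
#' @export
read_scan_tsv <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#")]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  col <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(v) {
    out <- rep(NA_real_, length(v))
    ok <- v != "NA"
    out[ok] <- as.numeric(v[ok])
    out
  }
  tibble::tibble(
    window_start = as.integer(col(1)),
    window_end = as.integer(col(2)),
    pi_d = num(col(3)),
    pi_m = num(col(4)),
    peaks = as.integer(col(5)),
    missing = col(6) == "1"
  )
}

#' Plot a sliding-window diversity scan
#'
#' Draws `pi_d` (and optionally `pi_m`) against the window midpoint;
#' missing windows appear as gaps.
#'
#' @param object A `shustring_scan`.
#' @param show_pi_m Overlay the inverse-mean estimate? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shustring_scan <- function(object, show_pi_m = TRUE, ...) {
  mid <- (object$window_start + object$window_end) / 2
  df <- tibble::tibble(
    position = rep(mid, 2),
    estimate = c(object$pi_d, object$pi_m),
    estimator = rep(c("pi_d", "pi_m"), each = nrow(object))
  )
  if (!show_pi_m) df <- df[df$estimator == "pi_d", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$estimate,
                                   colour = .data$estimator)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "query position (bp)", y = "diversity estimate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
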