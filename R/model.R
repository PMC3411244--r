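#' Coalescent model of the shustring-length distribution
#'
#' Bundles the parameters of the closed-form shustring-length distribution:
#' the per-site pairwise mismatch probability `pi`, the half-GC frequency
#' `p` (so GC-content is `2 * p` and each of G and C has frequency `p`,
#' each of A and T frequency `1/2 - p`), and the single-strand lengths
#' `ell_s` (subject) and `ell_q` (query or window). With strand doubling
#' the indexed sequences have lengths `2 * ell_s` and `2 * ell_q`, which is
#' where the factors of two in the distribution come from.
#'
#' @param pi Mismatches per site, in (0, 1).
#' @param p Half-GC frequency, in (0, 1/2).
#' @param ell_s Subject single-strand length (>= 1/2; non-integer values
#'   are allowed so that the doubled length `2 * ell_s` can be any count).
#' @param ell_q Query single-strand length.
#' @return A list of class `shustring_model`.
#' @export
shustring_model <- function(pi, p = 0.25, ell_s, ell_q = ell_s) {
  stopifnot(pi > 0, pi < 1, p > 0, p < 0.5, ell_s >= 0.5, ell_q >= 0.5)
  structure(list(pi = pi, p = p, ell_s = ell_s, ell_q = ell_q),
            class = "shustring_model")
}

#' @export
print.shustring_model <- function(x, ...) {
  cat(sprintf("<shustring_model> pi = %g, p = %g, ell_s = %g, ell_q = %g\n",
              x$pi, x$p, x$ell_s, x$ell_q))
  invisible(x)
}

#' Survival function of the homologous match length
#'
#' Probability that the match between a query position and its homologous
#' subject position extends beyond `x` sites. Integrating the coalescence
#' time (exponential with mean one in coalescent units) out of the
#' conditional survival `exp(-pi * T * x)` gives `1 / (1 + pi * x)` -- a
#' heavy tail with no finite expectation, which is why the mean-based
#' estimator degrades under fluctuating coalescence times.
#'
#' @param pi Mismatches per site.
#' @param x Non-negative match length (vectorised).
#' @return `P(X > x) = 1 / (1 + pi * x)`.
#' @export
homologous_tail <- function(pi, x) {
  stopifnot(pi > 0, all(x >= 0))
  1 / (1 + pi * x)
}

#' Distribution of the longest background (non-homologous) match
#'
#' Cumulative distribution `w_{p, ell_s}(x)` of the maximum match length
#' between a query position and all *non-homologous* subject positions,
#' modelled as chance matches between random words with GC-content `2p`
#' against a doubled subject of `2 * ell_s` positions:
#' \deqn{w(x) = \sum_{k=0}^{x} 2^x \binom{x}{k} p^k (1/2-p)^{x-k}
#'   \left(1 - p^k (1/2-p)^{x-k}\right)^{2 \ell_S}.}
#' For equiprobable nucleotides (`p = 1/4`) this collapses to
#' `(1 - 4^{-x})^{2 ell_s}`, and that closed form is used. The general sum
#' is evaluated in log space so it remains finite for genome-scale
#' `ell_s`, where small `x` underflow to 0 in linear space.
#'
#' @param p Half-GC frequency in (0, 1/2).
#' @param ell_s Subject single-strand length.
#' @param x Non-negative integer match length (vectorised).
#' @param log Return log probabilities?
#' @return `w_{p, ell_s}(x)` (or its log), with `w(0) = 0`.
#' @export
background_cdf <- function(p, ell_s, x, log = FALSE) {
  stopifnot(p > 0, p < 0.5, ell_s >= 0.5, all(x >= 0))
  lw <- log_background_cdf(p, ell_s, x)
  if (log) lw else exp(lw)
}

log_background_cdf <- function(p, ell_s, x) {
  if (abs(p - 0.25) < 1e-12) {
    out <- rep(-Inf, length(x))
    pos <- x > 0
    out[pos] <- 2 * ell_s * log1p(-4^(-x[pos]))
    return(out)
  }
  q <- 0.5 - p
  # 1 - w(x) <= 2 ell_s (2 p^2 + 2 q^2)^x, so beyond this cutoff w(x) is 1
  # to double precision and the explicit sum can be skipped
  cutoff <- (log(2 * ell_s) - log(1e-18)) / -log(2 * p^2 + 2 * q^2)
  vapply(x, function(xx) {
    if (xx <= 0) return(-Inf)
    if (xx > cutoff) return(0)
    k <- 0:xx
    lword <- k * log(p) + (xx - k) * log(q)
    lt <- xx * log(2) + lchoose(xx, k) + lword + 2 * ell_s * log1p(-exp(lword))
    m <- max(lt)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(lt - m)))
  }, numeric(1))
}

#' Cumulative distribution of the shustring length
#'
#' The shustring at a query position must out-run both the homologous match
#' (heavy-tailed through the fluctuating coalescence time) and the longest
#' chance match against the rest of the subject, so
#' `P(X* <= x) = w_{p, ell_s}(x) * pi * x / (1 + pi * x)`.
#'
#' @param model A `shustring_model`.
#' @param x Non-negative integer lengths (vectorised).
#' @return Cumulative probabilities.
#' @export
shustring_cdf <- function(model, x) {
  stopifnot(inherits(model, "shustring_model"), all(x >= 0))
  background_cdf(model$p, model$ell_s, x) * model$pi * x / (1 + model$pi * x)
}

#' Probability mass function of the shustring length
#'
#' Consecutive difference of [shustring_cdf()]. Internally evaluated as a
#' sum of two positive terms,
#' `[w(x) - w(x-1)] h(x) + w(x-1) [h(x) - h(x-1)]` with
#' `h(x) = pi x / (1 + pi x)`, which avoids the catastrophic cancellation
#' of differencing two numbers near one and keeps log probabilities finite
#' across the whole support. Tiny negative increments of `w` arising from
#' round-off in the general-GC sum are clamped to zero.
#'
#' @inheritParams shustring_cdf
#' @param x Positive integer lengths (vectorised).
#' @param log Return log probabilities?
#' @return `p_pi(x) = P(X* = x)` (or its log).
#' @export
shustring_pmf <- function(model, x, log = FALSE) {
  stopifnot(inherits(model, "shustring_model"), all(x >= 1))
  la <- log_background_cdf(model$p, model$ell_s, x)
  la1 <- log_background_cdf(model$p, model$ell_s, x - 1)
  lp <- log_pmf_terms(model$pi, x, la, la1)
  if (log) lp else exp(lp)
}

# log p_pi(x) from precomputed log w(x), log w(x-1); pi-dependent part only.
log_pmf_terms <- function(pi, x, la, la1) {
  lh <- log(pi) + log(x) - log1p(pi * x)
  d <- pmin(la1 - la, 0)              # log(w(x-1)/w(x)) <= 0; clamp round-off
  lt1 <- ifelse(is.finite(la), la + log(-expm1(d)) + lh, -Inf)
  lt2 <- la1 + log(pi) - log1p(pi * x) - log1p(pi * (x - 1))
  m <- pmax(lt1, lt2)
  ifelse(is.finite(m),
         m + log(exp(lt1 - m) + exp(lt2 - m)),
         -Inf)
}

#' Log-likelihood of a shustring-length histogram
#'
#' Treats each count `f(x)`, `x = 1..xi` (with `xi` the longest observed
#' shustring), as an independent Poisson draw with mean `2 p_pi(x) ell_q`.
#' Up to terms free of `pi`, the Poisson log-likelihood is
#' \deqn{\sum_{x=1}^{\xi} f(x) \log p_\pi(x) \;-\; 2 \ell_Q F_\pi(\xi),}
#' where `F_pi(xi)` is [shustring_cdf()] at `xi` (the sum of the expected
#' counts telescopes to the CDF, so no explicit summation over empty cells
#' is needed). The second term vanishes only in the limit `xi -> Inf`;
#' `objective = "profile"` drops it anyway, giving the reduced form
#' `sum_x f(x) log p_pi(x)`. The full `"poisson"` objective (the default
#' here and in [estimate_pi_d()]) penalises parameter values that expect
#' substantial probability mass beyond the longest observed length, and is
#' what reproduces the reported calibration of the estimator.
#'
#' The value is `-Inf` when any observed length has zero model
#' probability.
#'
#' @param model A `shustring_model`.
#' @param histogram A `shustring_histogram` (or tibble/data.frame with
#'   columns `length` and `count`).
#' @param objective `"poisson"` (full likelihood, default) or `"profile"`
#'   (the reduced `sum f log p` form).
#' @return The log-likelihood value (a scalar, up to a constant in `pi`).
#' @export
shustring_loglik <- function(model, histogram,
                             objective = c("poisson", "profile")) {
  objective <- match.arg(objective)
  stopifnot(nrow(histogram) > 0)
  lp <- shustring_pmf(model, histogram$length, log = TRUE)
  pos <- histogram$count > 0
  if (any(!is.finite(lp[pos]))) return(-Inf)
  ll <- sum(histogram$count[pos] * lp[pos])
  if (objective == "poisson") {
    xi <- attr(histogram, "xi") %||% max(histogram$length[pos])
    ll <- ll - 2 * model$ell_q * shustring_cdf(model, xi)
  }
  ll
}

#' Maximum-likelihood diversity estimate from the shustring-length
#' distribution
#'
#' Maximises the Poisson log-likelihood of the observed length counts
#' (see [shustring_loglik()]) over `pi` by a coarse grid on `log(pi)`
#' followed by golden-section refinement ([stats::optimize()]) in the
#' bracketing interval, to a relative tolerance of `tol` on `pi`.
#' This estimator uses the full length distribution and therefore allows
#' the coalescence time to fluctuate along the sequence, which makes it far
#' more robust to recombination than the inverse-mean estimator
#' [estimate_pi_m()].
#'
#' @param histogram A `shustring_histogram`.
#' @param p Half-GC frequency (default 1/4; in practice half the subject's
#'   GC fraction).
#' @param ell_s Subject single-strand length.
#' @param ell_q Query (or window) single-strand length.
#' @param include_capped Keep positions where the shustring was capped at
#'   the query end? Default `TRUE` (they are retained in the reference
#'   method); requires the histogram's `n_capped` column to exclude them.
#' @param min_total Minimum number of profiled positions required
#'   (default 100).
#' @param bounds Optimisation bounds on `pi`.
#' @param tol Relative tolerance on `pi`.
#' @param objective `"poisson"` (default) keeps the pi-dependent
#'   expected-count term `-2 ell_q F_pi(xi)` of the Poisson likelihood;
#'   `"profile"` maximises the reduced `sum f(x) log p_pi(x)` only (the
#'   two coincide as `xi -> Inf`). See [shustring_loglik()].
#' @return A list of class `pi_estimate` with elements `pi_hat`,
#'   `log_likelihood` (the maximised objective), `converged`,
#'   `n_positions`, `method = "ml"` and the model parameters used. The
#'   `converged` flag is `FALSE` when the optimum sits at a bound, the
#'   objective is non-finite, or the histogram is degenerate (e.g. every
#'   position capped, as for identical sequences).
#' @export
estimate_pi_d <- function(histogram, p = 0.25, ell_s, ell_q,
                          include_capped = TRUE, min_total = 100,
                          bounds = c(1e-8, 0.75), tol = 1e-6,
                          objective = c("poisson", "profile")) {
  objective <- match.arg(objective)
  stopifnot(nrow(histogram) > 0, ell_s >= 0.5, ell_q >= 0.5)
  h <- tibble::tibble(length = histogram$length, count = histogram$count)
  n_capped <- if ("n_capped" %in% names(histogram)) histogram$n_capped else 0L
  if (!include_capped) {
    h$count <- h$count - n_capped
    h <- h[h$count > 0, ]
  }
  total <- sum(h$count)

  diagnostic <- NULL
  if (total < min_total) {
    diagnostic <- sprintf("only %d positions (minimum %d)", total, min_total)
  } else if (all(histogram$count == n_capped)) {
    diagnostic <- "degenerate histogram: all positions capped at the query end"
  }
  if (!is.null(diagnostic)) {
    return(new_pi_estimate(NA_real_, -Inf, FALSE, total, p, ell_s, ell_q,
                           diagnostic))
  }

  x <- h$length
  la <- log_background_cdf(p, ell_s, x)
  la1 <- log_background_cdf(p, ell_s, x - 1)
  xi <- max(x)
  w_xi <- exp(log_background_cdf(p, ell_s, xi))
  obj <- function(lpi) {
    pi <- exp(lpi)
    lp <- log_pmf_terms(pi, x, la, la1)
    if (any(!is.finite(lp))) return(-Inf)
    ll <- sum(h$count * lp)
    if (objective == "poisson") {
      ll <- ll - 2 * ell_q * w_xi * pi * xi / (1 + pi * xi)
    }
    ll
  }

  lb <- log(bounds)
  grid <- seq(lb[1], lb[2], length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  if (all(!is.finite(vals))) {
    return(new_pi_estimate(NA_real_, -Inf, FALSE, total, p, ell_s, ell_q,
                           "log-likelihood not finite anywhere in bounds"))
  }
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = tol)
  pi_hat <- exp(opt$maximum)
  ll <- opt$objective

  converged <- is.finite(ll) &&
    pi_hat > bounds[1] * (1 + 10 * tol) &&
    pi_hat < bounds[2] * (1 - 10 * tol)
  new_pi_estimate(pi_hat, ll, converged, total, p, ell_s, ell_q,
                  if (converged) NULL else "optimum at or beyond bounds")
}

new_pi_estimate <- function(pi_hat, ll, converged, n, p, ell_s, ell_q,
                            diagnostic = NULL) {
  structure(
    list(pi_hat = pi_hat, log_likelihood = ll, converged = converged,
         n_positions = n, p = p, ell_s = ell_s, ell_q = ell_q,
         method = "ml", diagnostic = diagnostic),
    class = "pi_estimate"
  )
}

#' Inverse-mean diversity estimate
#'
#' The legacy estimator: diversity is approximately the inverse of the mean
#' shustring length. Accurate without recombination, but downward biased
#' once recombination clusters polymorphisms, because the heavy upper tail
#' of the length distribution inflates the mean.
#'
#' @param profile A `shustring_profile` (or numeric vector of lengths).
#' @return The scalar estimate `1 / mean(X*)`.
#' @export
estimate_pi_m <- function(profile) {
  v <- if (inherits(profile, "shustring_profile")) profile$lengths else as.numeric(profile)
  if (length(v) == 0) stop("profile is empty")
  1 / mean(v)
}

#' @export
print.pi_estimate <- function(x, ...) {
  cat(sprintf("<pi_estimate> pi_hat = %s, logLik = %.6g, converged = %s, n = %d\n",
              format(signif(x$pi_hat, 6)), x$log_likelihood, x$converged,
              x$n_positions))
  if (!is.null(x$diagnostic)) cat("  note: ", x$diagnostic, "\n", sep = "")
  invisible(x)
}

#' Tidy a diversity estimate
#'
#' @param x A `pi_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `log_likelihood`, `converged`
#'   and `n_positions`.
#' @export
tidy.pi_estimate <- function(x, ...) {
  tibble::tibble(
    term = "pi",
    estimate = x$pi_hat,
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    n_positions = x$n_positions
  )
}

#' Model-level summary of a diversity estimate
#'
#' @inheritParams tidy.pi_estimate
#' @return A one-row tibble with the estimate and the model parameters
#'   (`p`, `ell_s`, `ell_q`) it was computed under.
#' @export
glance.pi_estimate <- function(x, ...) {
  tibble::tibble(
    pi_hat = x$pi_hat,
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    n_positions = x$n_positions,
    p = x$p,
    ell_s = x$ell_s,
    ell_q = x$ell_q
  )
}
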