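test_that("homologous match survival follows 1 / (1 + pi x)", {
  expect_equal(homologous_tail(0.01, 0), 1)
  expect_equal(homologous_tail(0.01, 100), 0.5)
  expect_equal(homologous_tail(0.5, c(2, 6)), c(0.5, 0.25))
})

test_that("background_cdf matches the closed form at p = 1/4", {
  expect_equal(background_cdf(0.25, 0.5, 1), 0.75)
  for (ell_s in c(1, 1e3, 1e7)) {
    x <- 1:64
    # closed form evaluated through log1p: the naive (1 - 4^-x)^(2 ell_s)
    # rounds 1 - 4^-x to 1 beyond x = 26 in double precision
    closed <- exp(2 * ell_s * log1p(-4^(-x)))
    expect_equal(background_cdf(0.25, ell_s, x), closed, tolerance = 1e-12)
  }
})

test_that("general-GC sum equals the equiprobable closed form at p = 1/4", {
  x <- 1:64
  for (ell_s in c(1, 1e3, 1e7)) {
    general <- brute_background_cdf(0.25, ell_s, x)
    closed <- exp(2 * ell_s * log1p(-4^(-x)))
    expect_equal(general, closed, tolerance = 1e-12)
  }
})

test_that("background_cdf matches a direct summation oracle at skewed GC", {
  x <- 0:40
  expect_equal(background_cdf(0.2, 500, x), brute_background_cdf(0.2, 500, x),
               tolerance = 1e-10)
  expect_equal(background_cdf(0.35, 20, x), brute_background_cdf(0.35, 20, x),
               tolerance = 1e-10)
})

test_that("background_cdf is a proper cdf: monotone from 0 to 1", {
  for (p in c(0.1, 0.25, 0.4)) {
    v <- background_cdf(p, 1e6, 0:200)
    expect_equal(v[1], 0)
    expect_true(all(diff(v) >= -1e-14))
    expect_gt(v[201], 1 - 1e-10)
  }
})

test_that("shustring cdf combines background and homologous parts", {
  m <- shustring_model(pi = 0.01, p = 0.25, ell_s = 1e5, ell_q = 1e5)
  x <- c(0, 1, 10, 50, 1e4)
  expect_equal(shustring_cdf(m, x),
               (1 - 4^(-x))^(2e5) * 0.01 * x / (1 + 0.01 * x))
  expect_equal(shustring_cdf(m, 0), 0)
})

test_that("pmf telescopes exactly to the cdf", {
  m <- shustring_model(pi = 0.02, p = 0.25, ell_s = 1e5, ell_q = 1e5)
  x <- 1:3000
  pmf <- shustring_pmf(m, x)
  expect_true(all(pmf >= 0))
  expect_equal(cumsum(pmf), shustring_cdf(m, x), tolerance = 1e-12)

  m2 <- shustring_model(pi = 0.02, p = 0.3, ell_s = 1e5, ell_q = 1e5)
  pmf2 <- shustring_pmf(m2, x)
  expect_true(all(pmf2 >= 0))
  expect_equal(cumsum(pmf2), shustring_cdf(m2, x), tolerance = 1e-10)
})

test_that("log pmf stays finite across the support at genome scale", {
  m <- shustring_model(pi = 0.01, p = 0.25, ell_s = 1e9, ell_q = 1e9)
  lp <- shustring_pmf(m, 1:5000, log = TRUE)
  expect_true(all(is.finite(lp)))
  # linear-space differencing of the cdf underflows at small x here,
  # whereas the decomposed pmf does not
  expect_equal(shustring_cdf(m, 3), 0)
  expect_gt(lp[3], -Inf)
})

test_that("loglik: profile form is linear in counts, poisson form adds the
           expected-count penalty", {
  m <- shustring_model(pi = 0.01, p = 0.25, ell_s = 1e5, ell_q = 1e5)
  h <- shustring_histogram(c(rep(9, 40), rep(12, 30), rep(30, 30), rep(101, 20)))
  ll1 <- shustring_loglik(m, h, objective = "profile")
  h2 <- h
  h2$count <- 2L * h$count
  expect_equal(shustring_loglik(m, h2, objective = "profile"), 2 * ll1)
  expect_equal(shustring_loglik(m, h, objective = "poisson"),
               ll1 - 2 * m$ell_q * shustring_cdf(m, attr(h, "xi")))
})

test_that("estimate_pi_d recovers pi from model-distributed samples", {
  set.seed(42)
  truth <- 0.01
  m <- shustring_model(pi = truth, p = 0.25, ell_s = 1e5, ell_q = 1e5)
  support <- 1:20000
  pmf <- shustring_pmf(m, support)
  lens <- sample(support, size = 2e5, replace = TRUE, prob = pmf)
  est <- estimate_pi_d(shustring_histogram(lens), p = 0.25,
                       ell_s = 1e5, ell_q = 1e5)
  expect_true(est$converged)
  expect_equal(est$pi_hat, truth, tolerance = 0.03)
  # same at skewed GC
  m2 <- shustring_model(pi = 0.02, p = 0.15, ell_s = 1e5, ell_q = 1e5)
  pmf2 <- shustring_pmf(m2, support)
  lens2 <- sample(support, size = 2e5, replace = TRUE, prob = pmf2)
  est2 <- estimate_pi_d(shustring_histogram(lens2), p = 0.15,
                        ell_s = 1e5, ell_q = 1e5)
  expect_equal(est2$pi_hat, 0.02, tolerance = 0.03)
})

test_that("degenerate inputs yield diagnostics instead of estimates", {
  small <- estimate_pi_d(shustring_histogram(c(3, 4, 5)), ell_s = 100,
                         ell_q = 100)
  expect_false(small$converged)
  expect_match(small$diagnostic, "minimum")

  prof <- shustring_lengths(sequence_pool(strrep("ACGT", 60)),
                            sequence_pool(strrep("ACGT", 60)))
  allcap <- estimate_pi_d(shustring_histogram(prof), ell_s = 240, ell_q = 240,
                          min_total = 10)
  expect_false(allcap$converged)
  expect_match(allcap$diagnostic, "capped")
})

test_that("include_capped = FALSE drops capped counts", {
  prof <- shustring_lengths(
    sequence_pool("CCGTT", strand_double = FALSE),
    sequence_pool("TCGT", strand_double = FALSE))
  h <- shustring_histogram(prof)
  est <- estimate_pi_d(h, ell_s = 4, ell_q = 5, min_total = 1,
                       include_capped = FALSE)
  # only the final position (length 1) is capped, leaving 4 of 5
  expect_equal(est$n_positions, 4L)
})

test_that("estimate_pi_m is the inverse mean length", {
  expect_equal(estimate_pi_m(c(2, 4, 3, 2, 1)), 1 / 2.4)
  prof <- shustring_lengths(sequence_pool("CCGTT", strand_double = FALSE),
                            sequence_pool("TCGT", strand_double = FALSE))
  expect_equal(estimate_pi_m(prof), 1 / mean(c(2, 4, 3, 2, 1)))
  expect_error(estimate_pi_m(numeric(0)), "empty")
})

test_that("tidy and glance return one-row tibbles", {
  set.seed(1)
  m <- shustring_model(pi = 0.01, p = 0.25, ell_s = 1e4, ell_q = 1e4)
  lens <- sample(1:5000, 5000, replace = TRUE,
                 prob = shustring_pmf(m, 1:5000))
  est <- estimate_pi_d(shustring_histogram(lens), ell_s = 1e4, ell_q = 1e4)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$estimate, est$pi_hat)
  gl <- glance(est)
  expect_equal(gl$ell_s, 1e4)
  expect_equal(gl$p, 0.25)
})

test_that("model constructor validates parameters", {
  expect_error(shustring_model(pi = 0, ell_s = 10))
  expect_error(shustring_model(pi = 0.01, p = 0.6, ell_s = 10))
  expect_output(print(shustring_model(0.01, ell_s = 10)), "shustring_model")
})
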