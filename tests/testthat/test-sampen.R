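test_that("template-match counts follow the Richman-Moorman convention", {
  # constant series: all C(N - m, 2) pairs match at both lengths
  cnt <- count_template_matches(rep(2, 10), m = 2, tol = 0.1)
  expect_equal(cnt$n_templates, 8)
  expect_equal(cnt$b_pairs, choose(8, 2))
  expect_equal(cnt$a_pairs, choose(8, 2))

  # strictly spaced ramp with sub-step tolerance: no matches at all
  cnt <- count_template_matches(1:10, m = 2, tol = 0.5)
  expect_equal(cnt$b_pairs, 0)
  expect_equal(cnt$a_pairs, 0)

  # frozen values from an independent exhaustive enumeration
  cnt <- count_template_matches(sin(1:30), m = 2, tol = 0.2)
  expect_equal(cnt$b_pairs, 16)
  expect_equal(cnt$a_pairs, 12)
  expect_equal(cnt$n_templates, 28)

  expect_error(count_template_matches(1:3, m = 2, tol = 1), "too short")
  expect_error(count_template_matches(1:10, m = 2, tol = 0), "positive")
})

test_that("sample_entropy matches frozen enumeration values and edges", {
  p_abs <- sampen_params(m = 2, r = 0.2, tolerance_mode = "absolute")
  expect_equal(sample_entropy(sin(1:30), p_abs), -log(12 / 16),
               tolerance = 1e-14)
  p_rel <- sampen_params(m = 2, r = 0.25)
  expect_equal(sample_entropy(sin(1:30), p_rel), -log(12 / 14),
               tolerance = 1e-14)

  # constant series is perfectly regular, even in relative-SD mode
  expect_identical(sample_entropy(rep(3, 50), p_rel), 0)
  # no matches anywhere -> undefined marker
  expect_true(is.na(sample_entropy(1:10,
                                   sampen_params(2, 0.5, "absolute"))))
  expect_error(sample_entropy(1:3, p_rel), "too short")
})

test_that("optimized path agrees with the brute-force oracle", {
  withr::with_seed(4242, {
    for (trial in 1:60) {
      n <- sample(20:300, 1)
      x <- switch(sample(3, 1),
                  rnorm(n),
                  cumsum(rnorm(n)),
                  sin(seq_len(n) / runif(1, 1, 10)) + rnorm(n, sd = 0.2))
      p <- sampen_params(m = sample(1:3, 1), r = runif(1, 0.1, 0.5),
                         tolerance_mode = sample(c("relative_sd",
                                                   "absolute"), 1))
      a <- sample_entropy(x, p)
      b <- sample_entropy_bruteforce(x, p)
      if (is.na(a) || is.na(b)) expect_identical(is.na(a), is.na(b))
      else expect_equal(a, b, tolerance = 1e-12)
    }
  })
  expect_error(sample_entropy_bruteforce(rnorm(2001)), "capped")
})

test_that("match counts are non-decreasing in the tolerance", {
  withr::with_seed(5, {
    x <- rnorm(150)
    tols <- seq(0.05, 2, by = 0.05)
    cnts <- t(vapply(tols, function(tol) {
      cnt <- count_template_matches(x, 2, tol)
      c(cnt$b_pairs, cnt$a_pairs)
    }, numeric(2)))
    expect_true(all(diff(cnts[, 1]) >= 0))
    expect_true(all(diff(cnts[, 2]) >= 0))
    expect_true(all(cnts[, 2] <= cnts[, 1]))  # match at m+1 implies at m
  })
})

test_that("relative-SD mode is invariant to affine amplitude changes", {
  withr::with_seed(9, {
    x <- rnorm(400)
    p <- sampen_params(m = 2, r = 0.2)
    base <- sample_entropy(x, p)
    for (i in 1:10) {
      cc <- runif(1, 0.001, 1000)
      b <- runif(1, -500, 500)
      expect_equal(sample_entropy(cc * x + b, p), base, tolerance = 1e-12)
    }
  })
})

test_that("entropy ranks white noise above AR(1) above a near-sinusoid", {
  p <- sampen_params(m = 2, r = 0.25)
  n <- 4096
  vals <- withr::with_seed(77, {
    replicate(20, {
      wn <- rnorm(n)
      ar <- as.numeric(stats::filter(rnorm(n), 0.95,
                                     method = "recursive"))
      sn <- sin(seq_len(n) / 4) + rnorm(n, sd = 0.01)
      c(wn = sample_entropy(wn, p), ar = sample_entropy(ar, p),
        sn = sample_entropy(sn, p))
    })
  })
  expect_lt(wilcox.test(vals["wn", ], vals["ar", ],
                        alternative = "greater")$p.value, 0.01)
  expect_lt(wilcox.test(vals["ar", ], vals["sn", ],
                        alternative = "greater")$p.value, 0.01)
})
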