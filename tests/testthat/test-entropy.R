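test_that("coarse-graining takes disjoint block means and discards the tail", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  x <- rnorm(37)
  expect_identical(coarse_grain(x, 1), x)
  expect_error(coarse_grain(x, 0), "tau")
  expect_error(coarse_grain(x, 38), "tau")
  # block means conserve the mean of the retained prefix exactly
  for (tau in c(2, 3, 5)) {
    k <- length(x) %/% tau
    expect_equal(mean(coarse_grain(x, tau)), mean(x[seq_len(k * tau)]))
  }
})

test_that("sample entropy handles constant, alternating and degenerate input", {
  expect_equal(sample_entropy(rep(3.7, 100), 2, 0.2), 0)
  # alternating series: every length-2 match extends deterministically
  alt <- rep(c(0, 1), 50)
  expect_equal(sample_entropy(alt, 2, 0.1), 0)
  expect_equal(sample_entropy(alt, 2, 0.1), sampen_bf(alt, 2, 0.1))
  expect_error(sample_entropy(rnorm(3), 2, 0.1), "too short")
  # spread-out series with tiny tolerance: no template pairs at all
  expect_error(sample_entropy(as.numeric(1:20), 2, 0.5), "degenerate")
  # matches at length m but never at m + 1: undefined, reported as NA
  x <- c(0, 0, 10, 0, 0, 20, 0, 0, 30)
  expect_warning(val <- sample_entropy(x, 2, 0.5), "undefined")
  expect_true(is.na(val))
})

test_that("compiled entropies equal brute-force oracles on random series", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(12:60, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1)
    r <- sample(c(0.1, 0.15, 0.3), 1) * sd(x)
    ab <- sampen_bf_counts(x, m, r)
    if (ab["B"] == 0L) {
      expect_error(sample_entropy(x, m, r), "degenerate")
    } else if (ab["A"] == 0L) {
      expect_warning(expect_true(is.na(sample_entropy(x, m, r))))
    } else {
      expect_equal(sample_entropy(x, m, r), sampen_bf(x, m, r),
                   tolerance = 1e-12)
    }
    expect_equal(fuzzy_entropy(x, m, r, 2), fuzzen_bf(x, m, r, 2),
                 tolerance = 1e-12)
  }
})

test_that("fuzzy entropy is zero for constants and decreases in tolerance", {
  expect_equal(fuzzy_entropy(rep(1, 50), 2, 0.3), 0)
  x <- rnorm(200)
  set.seed(7)
  r1 <- 0.1 * sd(x)
  expect_gt(fuzzy_entropy(x, 2, r1), fuzzy_entropy(x, 2, 2 * r1))
  # any 5-point series against the direct double-loop evaluation
  y <- c(0.3, -1.2, 0.8, 0.1, 2.0)
  expect_equal(fuzzy_entropy(y, 2, 0.25, 2), fuzzen_bf(y, 2, 0.25, 2),
               tolerance = 1e-12)
})

test_that("both entropies are invariant under affine maps with scaled tolerance", {
  set.seed(11)
  x <- rnorm(150)
  r <- 0.2 * sd(x)
  for (a in c(2, -1)) {
    y <- a * x + 5
    expect_equal(sample_entropy(y, 2, abs(a) * r), sample_entropy(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(fuzzy_entropy(y, 2, abs(a) * r, 2), fuzzy_entropy(x, 2, r, 2),
                 tolerance = 1e-12)
  }
})

test_that("the complexity area index is the unit-spacing trapezoid integral", {
  expect_equal(cai(rep(2.5, 21)), 20 * 2.5)
  expect_equal(cai(c(1, 0)), 0.5)
  set.seed(3)
  v <- runif(20)
  expect_equal(cai(v), pracma::trapz(seq_along(v), v), tolerance = 1e-12)
  expect_true(is.na(cai(c(1, NA, 2))))
  expect_error(cai(1), "at least 2")
})

test_that("MSE/MFE curves honour their definitional contracts", {
  set.seed(5)
  x <- rnorm(400)
  p <- entropy_params(max_scale = 8)
  cv <- mse_curve(x, p)
  # scale-1 value is the plain entropy with r * SD(x) (population SD)
  sd0 <- sqrt(mean((x - mean(x))^2))
  expect_equal(cv$values[1], sample_entropy(x, 2, 0.15 * sd0))
  expect_equal(cv$cai, cai(cv$values))
  expect_equal(cv$n_effective, 400 %/% (1:8))
  fv <- mfe_curve(x, p)
  expect_equal(fv$values[1], fuzzy_entropy(x, 2, 0.15 * sd0, 2))
  # single-scale curve is just the plain entropy with an undefined CAI
  one <- mse_curve(x, entropy_params(max_scale = 1))
  expect_length(one$values, 1)
  expect_true(is.na(one$cai))
  # max_scale auto-reduction keeps floor(N/tau) >= m + 2 (very short
  # coarse-grained series may additionally have undefined entropies)
  w <- capture_warnings(red <- mse_curve(rnorm(60),
                                         entropy_params(max_scale = 40)))
  expect_true(any(grepl("reduced", w)))
  expect_lte(max(red$scales), 60 %/% 4)
  # per-scale tolerance mode runs and differs from the fixed mode (its
  # shrinking tolerance may leave deep scales undefined, hence warnings)
  ps <- suppressWarnings(
    mse_curve(x, entropy_params(max_scale = 8, r_mode = "per_scale_sd")))
  expect_false(isTRUE(all.equal(ps$values, cv$values)))
})

test_that("entropy parameter validation warns and errors appropriately", {
  expect_warning(entropy_params(r = 0.8), "plausible")
  expect_error(entropy_params(m = 0))
  expect_error(mse_curve(rep(1, 100)), "constant")
})
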