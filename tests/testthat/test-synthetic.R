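test_that("the jitter-free linear archetype lies exactly on a line", {
  pts <- generate_curve("linear", n = 100, seed = 3, jitter = 0)
  fit <- lm(measured_rt ~ library_rt, data = pts)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_true(all(attr(pts, "is_signal")))
})

test_that("every archetype is monotone non-decreasing without jitter", {
  for (ct in c("linear", "distortion_begin", "distortion_end",
               "exponential", "s_type")) {
    pts <- generate_curve(ct, n = 1000, seed = 4, jitter = 0)
    ord <- order(pts$library_rt)
    expect_true(all(diff(pts$measured_rt[ord]) >= -1e-12), label = ct)
  }
})

test_that("curve generation is deterministic under a fixed seed", {
  a <- generate_curve("s_type", n = 500, seed = 11)
  b <- generate_curve("s_type", n = 500, seed = 11)
  expect_identical(a, b)
  c <- generate_curve("s_type", n = 500, seed = 12)
  expect_false(identical(a$library_rt, c$library_rt))
})

test_that("library-RT sampling is center-dense", {
  pts <- generate_curve("linear", n = 5000, seed = 5)
  x <- pts$library_rt
  mid <- mean(x > 25 & x < 75)
  # truncated normal (sd = range/4) puts ~71.6% of mass in the middle half;
  # a uniform draw would put 50%
  expect_equal(mid, 0.716, tolerance = 0.05)
  expect_gt(mid, 0.65)
})

test_that("subsampling and noise injection hit the requested fractions", {
  truth <- generate_curve("linear", n = 1000, seed = 6)
  clean <- subsample_and_add_noise(truth, 0.5, 0, seed = 7)
  expect_equal(nrow(clean), 500L)
  expect_true(all(attr(clean, "is_signal")))

  # 25 signal at 75% noise -> 75 noise points, 100 total
  truth2 <- generate_curve("s_type", n = 2500, seed = 8)
  scen <- subsample_and_add_noise(truth2, 0.01, 0.75, seed = 9)
  sig <- attr(scen, "is_signal")
  expect_equal(sum(sig), 25L)
  expect_equal(sum(!sig), 75L)

  # the achieved noise fraction is within one point of the request
  set.seed(10)
  for (nf in c(0.01, 0.05, 0.35, 0.75)) {
    s <- subsample_and_add_noise(truth, 0.3, nf, seed = sample.int(1e6, 1))
    n_noise <- sum(!attr(s, "is_signal"))
    expect_lte(abs(n_noise - nf * nrow(s)), 1, label = sprintf("nf=%g", nf))
  }
})

test_that("in-range noise stays inside the sampled-signal bounding box", {
  truth <- generate_curve("exponential", n = 2000, seed = 13)
  scen <- subsample_and_add_noise(truth, 0.1, 0.5, seed = 14)
  sig <- attr(scen, "is_signal")
  expect_gte(min(scen$library_rt[!sig]), min(scen$library_rt[sig]))
  expect_lte(max(scen$library_rt[!sig]), max(scen$library_rt[sig]))
  expect_gte(min(scen$measured_rt[!sig]), min(scen$measured_rt[sig]))
  expect_lte(max(scen$measured_rt[!sig]), max(scen$measured_rt[sig]))
})

test_that("the out-of-range factor extends only the upper noise x limit", {
  truth <- generate_curve("linear", n = 2000, seed = 15)
  scen <- subsample_and_add_noise(truth, 0.1, 0.5,
                                  noise_x_limit_factor = 1.2, seed = 16)
  sig <- attr(scen, "is_signal")
  max_sig <- max(scen$library_rt[sig])
  expect_lte(max(scen$library_rt[!sig]), 1.2 * max_sig)
  expect_gt(max(scen$library_rt[!sig]), max_sig)  # some noise beyond range
  expect_gte(min(scen$library_rt[!sig]), min(scen$library_rt[sig]))
})

test_that("MRD is range-normalized and blind to noise points", {
  expect_equal(mrd(c(1, 2, 3), c(1, 2, 3), rep(TRUE, 3)), 0)
  # hand example: signal measured (0, 10), predicted (1, 10)
  expect_equal(mrd(c(1, 10), c(0, 10), c(TRUE, TRUE)), 0.05)
  # perturbing noise predictions arbitrarily changes nothing
  base <- mrd(c(1, 10, 99), c(0, 10, 5), c(TRUE, TRUE, FALSE))
  pert <- mrd(c(1, 10, -1e6), c(0, 10, 5), c(TRUE, TRUE, FALSE))
  expect_equal(base, pert)
  expect_equal(base, 0.05)
  expect_error(mrd(1, 1, TRUE), "range")
  expect_error(mrd(c(1, 2), c(1, 2), c(FALSE, FALSE)), "signal")
})
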