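# Circular summaries and surrogate machinery.

test_that("circular mean and resultant length match hand-computed vectors", {
  m <- circ_mean_r(rep(pi / 3, 5))
  expect_equal(m$mu, pi / 3)
  expect_equal(m$r, 1)
  expect_equal(circ_mean_r(c(0, pi))$r, 0, tolerance = 1e-12)
  m2 <- circ_mean_r(c(0, pi / 2))
  expect_equal(m2$mu, pi / 4)
  expect_equal(m2$r, cos(pi / 4), tolerance = 1e-12)
  expect_error(circ_mean_r(numeric(0)), "non-empty")
})

test_that("PPC closed form matches enumerated pair averages", {
  expect_equal(ppc(rep(1.2, 7)), 1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi)), -1, tolerance = 1e-12)
  # 4 equally spaced phases: 6 pairs, mean cos = -1/3
  expect_equal(ppc(c(0, pi / 2, pi, 3 * pi / 2)), -1 / 3, tolerance = 1e-12)
  expect_error(ppc(0.3), "at least 2")
})

test_that("PPC closed form equals the O(n^2) definition on random draws", {
  brute <- function(ph) {
    n <- length(ph)
    s <- 0
    for (i in 1:(n - 1)) s <- s + sum(cos(ph[i] - ph[(i + 1):n]))
    s / (n * (n - 1) / 2)
  }
  set.seed(11)
  for (rep in 1:25) {
    ph <- stats::runif(sample(5:200, 1), -pi, pi)
    expect_equal(ppc(ph), brute(ph), tolerance = 1e-12)
  }
})

test_that("Rayleigh z follows z = n r^2", {
  r10 <- rayleigh(rep(0.7, 10))
  expect_equal(r10$z, 10)
  ph <- c(rep(0, 75), rep(pi, 25)) # r = 0.5 by construction
  r100 <- rayleigh(ph)
  expect_equal(r100$r, 0.5, tolerance = 1e-12)
  expect_equal(r100$z, 25, tolerance = 1e-9)
})

test_that("rotation invariance: mu rotates, ppc/r/z/F unchanged", {
  set.seed(21)
  a <- stats::rnorm(200, 1, 0.6)
  b <- stats::rnorm(150, -0.5, 0.8)
  rot <- 1.234
  expect_equal(ppc(a), ppc(a + rot), tolerance = 1e-12)
  expect_equal(circ_mean_r(a)$r, circ_mean_r(a + rot)$r, tolerance = 1e-12)
  expect_angle_equal(circ_mean_r(a + rot)$mu, circ_mean_r(a)$mu + rot, 1e-9)
  expect_equal(watson_williams(a, b), watson_williams(a + rot, b + rot),
               tolerance = 1e-9)
})

test_that("Watson-Williams is near zero for identical samples, large for shifted", {
  set.seed(31)
  a <- stats::rnorm(500, 0, 0.5)
  expect_lt(watson_williams(a, a), 1e-9)
  b <- a + pi / 2
  expect_gt(watson_williams(a, b), 100)
})

test_that("circular-shift locking test recovers locking and excludes lag 0", {
  # aperiodic phase series (drifting instantaneous frequency) so that
  # rotation genuinely destroys spike-phase alignment
  set.seed(41)
  fs <- 200
  ifreq <- 4 + cumsum(stats::rnorm(400 * fs, 0, 0.01))
  ifreq <- pmin(8, pmax(2, ifreq))
  ph <- thetalock:::wrap_pi(cumsum(2 * pi * ifreq / fs))
  samp <- sort(sample(which(abs(ph - 1) < 0.3), 300))
  res <- circshift_locking_test(samp, ph, n_surr = 201, seed = 5)
  expect_true(res$significant)
  expect_lte(res$p, 0.01)
  expect_angle_equal(res$mu, 1, 0.2)
  expect_error(circshift_locking_test(samp, rep(0.5, length(ph))),
               "degenerate")
})

test_that("condition-swap test: zero differences give t = 0, sign flip negates t", {
  set.seed(51)
  x <- stats::runif(20, 0, 0.3)
  eps <- stats::rnorm(20, 0, 1e-3)
  res0 <- ppc_condition_swap_test(x, x + eps, n_surr = 501, seed = 1)
  res_sw <- ppc_condition_swap_test(x + eps, x, n_surr = 501, seed = 1)
  expect_equal(res0$empirical, -res_sw$empirical, tolerance = 1e-12)
  expect_gt(res0$p, 0.05) # null-like
  # clear difference detected
  res1 <- ppc_condition_swap_test(x + 0.2, x, n_surr = 1001, seed = 2)
  expect_lt(res1$p, 0.01)
})

test_that("ww surrogate test keeps segments together and attains significance", {
  set.seed(61)
  n_seg <- 40
  seg_id <- rep(1:n_seg, each = 12)
  lab <- ifelse(seg_id <= n_seg / 2, "enc", "ret")
  mu <- ifelse(lab == "enc", 0, pi / 2)
  ph <- mu + stats::rnorm(length(seg_id), 0, 0.5)
  res <- ww_surrogate_test(ph, lab, mode = "segment-shuffle", n_surr = 501,
                           segment_id = seg_id, seed = 3)
  expect_true(res$significant)
  expect_lt(res$p, 0.01)
  # no shift: null behaviour
  ph0 <- stats::rnorm(length(seg_id), 0, 0.5)
  res0 <- ww_surrogate_test(ph0, lab, mode = "segment-shuffle", n_surr = 501,
                            segment_id = seg_id, seed = 4)
  expect_gt(res0$p, 0.02)
})

test_that("rayleigh z-difference shuffle detects a locked-vs-uniform contrast", {
  set.seed(71)
  a <- stats::rnorm(500, 0, 0.4) # concentrated
  b <- stats::runif(500, -pi, pi)
  res <- rayleigh_diff_shuffle_test(a, b, n_surr = 501, seed = 9)
  expect_lt(res$p, 0.01)
  res_null <- rayleigh_diff_shuffle_test(b[1:250], b[251:500], n_surr = 501,
                                         seed = 10)
  expect_gt(res_null$p, 0.02)
})

test_that("binomial exceedance matches closed forms and the cohort example", {
  expect_equal(binomial_exceedance(0, 10), 1)
  expect_equal(binomial_exceedance(10, 10), 0.05^10, tolerance = 1e-12)
  expect_lt(binomial_exceedance(62, 666), 0.001)
})

test_that("median split applies the ties-to-low rule", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  expect_error(median_split(rep(2, 5)), "identical")
  set.seed(81)
  v <- stats::rnorm(1001)
  tab <- table(median_split(v))
  expect_lte(abs(tab[["high"]] - tab[["low"]]), 1)
})
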