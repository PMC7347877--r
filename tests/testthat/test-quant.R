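test_that("window signal is a length-weighted mean with replicate averaging", {
  const2 <- signal_track(iv_val("chr1", 0, 10000, 2))
  w <- iv("chr1", 2000, 3000)
  expect_equal(window_signal(const2, w), 2)

  half <- signal_track(data.frame(chrom = "chr1", start = c(0, 500),
                                  end = c(500, 1000), value = c(1, 3)))
  expect_equal(window_signal(half, iv("chr1", 0, 1000)), 2)

  # uncovered bases count 0
  gap <- signal_track(iv_val("chr1", 0, 500, 4))
  expect_equal(window_signal(gap, iv("chr1", 0, 1000)), 2)

  reps <- list(signal_track(iv_val("chr1", 0, 1000, 1)),
               signal_track(iv_val("chr1", 0, 1000, 3)))
  expect_equal(window_signal(reps, iv("chr1", 0, 1000)), 2)

  expect_error(window_signal(const2, iv("chrX", 0, 100)),
               "chromosome absent")
})

test_that("log2 fold-change uses a symmetric pseudocount", {
  expect_equal(log2_change(5, 5), 0)
  expect_equal(log2_change(2, 1, pseudocount = 1e-9), 1, tolerance = 1e-6)
  expect_equal(log2_change(0, 0), 0)
  expect_error(log2_change(-1, 2), ">= 0")
})

test_that("domain signal averages DHS windows by midpoint containment", {
  trk <- signal_track(data.frame(
    chrom = "chr1", start = c(0, 10000, 20000),
    end = c(10000, 20000, 30000), value = c(5, 1, 3)))
  doms <- iv("chr1", c(0, 40000), c(30000, 50000))
  # one DHS window inside the first domain, constant value 5
  w1 <- iv("chr1", 2000, 3000)
  expect_equal(domain_signal(doms, w1, trk), c(5, NA_real_))
  # two DHS windows with means 1 and 3 -> unweighted mean 2
  w2 <- iv("chr1", c(12000, 22000), c(13000, 23000))
  expect_equal(domain_signal(doms, w2, trk)[1], 2)
  # invariant to DHS ordering
  expect_equal(domain_signal(doms, w2[2:1, ], trk),
               domain_signal(doms, w2, trk))
})

test_that("accessibility classes use strict inequalities at +/-0.585", {
  expect_equal(classify_accessibility(c(1, 0, -1)),
               c("increased", "unchanged", "decreased"))
  expect_equal(classify_accessibility(0.585), "unchanged")
  expect_equal(classify_accessibility(-0.585), "unchanged")
  expect_equal(classify_accessibility(0.5851), "increased")
  expect_true(is.na(classify_accessibility(NA_real_)))
  expect_error(classify_accessibility(Inf), "non-finite")
})

test_that("correlation matches the closed-form coefficient and handles degenerate input", {
  # r = S_xy / sqrt(S_xx S_yy) computed by hand: 5 / sqrt(2 * 114/9)
  r <- correlate(c(1, 2, 3), c(2, 4, 7), "pearson")
  expect_equal(r$estimate, 5 / sqrt(2 * 114 / 9), tolerance = 1e-12)

  x <- rnorm(20)
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  expect_equal(correlate(x, -x, "pearson")$estimate, -1)
  expect_equal(correlate(x, 2 * x + 3, "pearson")$estimate, 1)
  expect_equal(correlate(x, x^3, "spearman")$estimate, 1)
  expect_error(correlate(x, rep(1, 20), "pearson"), "constant")
  expect_error(correlate(x[1:2], x[1:2], "pearson"), "fewer than 3")
})
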