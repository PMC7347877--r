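test_that("candidate enumeration pairs DHS within, never across, domains", {
  doms <- iv("chr1", c(0, 1e6), c(5e5, 1.5e6))
  one <- iv("chr1", 100000, 100600)
  expect_equal(nrow(enumerate_candidate_pairs(doms[1, ], one)), 0)

  four <- iv("chr1", seq(1e5, 4e5, by = 1e5), seq(1e5, 4e5, by = 1e5) + 600)
  expect_equal(nrow(enumerate_candidate_pairs(doms[1, ], four)), 6)  # C(4,2)

  six <- iv("chr1", c(1e5, 2e5, 3e5, 1.1e6, 1.2e6, 1.3e6),
            c(1e5, 2e5, 3e5, 1.1e6, 1.2e6, 1.3e6) + 600)
  pairs <- enumerate_candidate_pairs(doms, six)
  expect_equal(nrow(pairs), 6)  # 3 per domain, none cross-domain
  expect_true(all(pairs$distance > 0))
  expect_equal(length(unique(pairs$domain_id)), 2)
})

test_that("pair pixel fold-changes recover planted domain changes", {
  D <- matrix(1, 40, 40)
  cm_ctrl <- cm_from_dense(D, chrom = "chr1")
  cm_cko <- cm_from_dense(2 * D, chrom = "chr1")
  pairs <- data.frame(chrom = "chr1", pos_a = c(15000, 55000),
                      pos_b = c(95000, 255000))
  v <- pair_contact_log2fc(pairs, cm_ctrl, cm_cko)
  expect_equal(v$value, c(1, 1), tolerance = 1e-3)

  # same-bin pairs are diagonal pixels and get dropped
  deg <- data.frame(chrom = "chr1", pos_a = 12000, pos_b = 13000)
  v2 <- pair_contact_log2fc(deg, cm_ctrl, cm_cko)
  expect_equal(nrow(v2), 0)
  expect_equal(attr(v2, "n_dropped"), 1L)
})

test_that("every resample matches the test set's log2 distance histogram", {
  set.seed(8)
  cand <- data.frame(chrom = "chr1",
                     distance = round(2^runif(500, 13, 20)),
                     value = rnorm(500))
  test_d <- sample(cand$distance, 40)
  for (seed in c(1, 99)) {
    res <- distance_matched_resample(cand, test_d, n = 5, seed = seed)
    for (r in res) {
      expect_equal(nrow(r), 40)
      expect_equal(table(floor(log2(r$distance))),
                   table(floor(log2(test_d))))
    }
  }
  # determinism under the seed
  r1 <- distance_matched_resample(cand, test_d, n = 3, seed = 42)
  r2 <- distance_matched_resample(cand, test_d, n = 3, seed = 42)
  expect_identical(r1, r2)

  # a test distance with no candidates in its bin is an error
  expect_error(distance_matched_resample(cand, 2^25, n = 1, seed = 1),
               "distance bin")
})

test_that("the empirical p-value counts resampled medians below the test median", {
  meds <- c(seq_len(99) / 100)
  expect_equal(empirical_pvalue(0.015, meds[1:99]), 1 / 99)
  # the published convention: 1 of 100 resamples below -> p = 0.01
  expect_equal(empirical_pvalue(0.015, seq(0.01, 1, by = 0.01)), 0.01)
  expect_equal(empirical_pvalue(0.505, seq(0.01, 1, by = 0.01)), 0.5)
  expect_equal(empirical_pvalue(-1, seq(0.01, 1, by = 0.01)), 0)
  expect_equal(empirical_pvalue(-1, seq(0.01, 1, by = 0.01), plus_one = TRUE),
               1 / 101)
  # monotone: lowering resampled medians weakly increases p
  expect_gte(empirical_pvalue(0.5, meds - 0.2), empirical_pvalue(0.5, meds))
})

test_that("resampling_test assembles medians, p, and the middle resample deterministically", {
  set.seed(13)
  cand <- data.frame(chrom = "chr1", distance = round(2^runif(400, 14, 19)),
                     value = rnorm(400, 0.3, 0.5))
  ti <- sample(400, 30)
  rt <- resampling_test(cand$value[ti], cand$distance[ti], cand,
                        n = 50, seed = 5)
  expect_length(rt$resampled_medians, 50)
  expect_equal(rt$empirical_p,
               mean(rt$resampled_medians < rt$test_median))
  expect_equal(stats::median(rt$median_resample$value),
               sort(rt$resampled_medians)[25])
  rt2 <- resampling_test(cand$value[ti], cand$distance[ti], cand,
                         n = 50, seed = 5)
  expect_identical(rt$resampled_medians, rt2$resampled_medians)
})
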