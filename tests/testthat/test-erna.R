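test_that("eRNA windows flank the DHS center and gene exclusion removes features", {
  dhs <- iv("chr1", 9700, 10300)     # center 10,000
  enh <- iv("chr1", 9700, 10300)
  no_genes <- data.frame(chrom = character(), start = integer(),
                         end = integer(), gene_biotype = character())
  f <- build_erna_features(dhs, enh, no_genes)
  expect_equal(nrow(f), 1)
  expect_equal(c(f$minus_start, f$minus_end), c(8000, 10000))
  expect_equal(c(f$plus_start, f$plus_end), c(10000, 12000))

  # coding gene [11000, 20000) extends to [10000, 21000): hits the plus window
  gene <- data.frame(chrom = "chr1", start = 11000L, end = 20000L,
                     gene_biotype = "protein_coding")
  f2 <- build_erna_features(dhs, enh, gene)
  expect_equal(nrow(f2), 0)
  expect_equal(attr(f2, "n_dropped"), 1L)

  # a gene further away (extension stops 1 bp short of the window) is kept
  gene2 <- data.frame(chrom = "chr1", start = 13000L, end = 20000L,
                      gene_biotype = "protein_coding")
  expect_equal(nrow(build_erna_features(dhs, enh, gene2)), 1)

  # non-excluded biotypes do not drop features
  sno <- data.frame(chrom = "chr1", start = 11000L, end = 20000L,
                    gene_biotype = "snoRNA")
  expect_equal(nrow(build_erna_features(dhs, enh, sno)), 1)

  # upstream window past the chromosome start -> dropped
  near0 <- iv("chr1", 500, 1100)
  f3 <- build_erna_features(near0, near0, no_genes)
  expect_equal(nrow(f3), 0)
})

test_that("fragment counting is strand- and window-specific at the 5' end", {
  f <- build_erna_features(iv("chr1", 9700, 10300), iv("chr1", 9700, 10300),
                           data.frame(chrom = character(), start = integer(),
                                      end = integer(),
                                      gene_biotype = character()))
  frags <- data.frame(
    chrom = "chr1",
    start = c(8851, 11000, 8900, 11990),
    end = c(9001, 11150, 9050, 12140),
    strand = c("-", "+", "+", "+"),
    stringsAsFactors = FALSE)
  # "-" with 5' end 9000 in the minus window: counted
  # "+" at 11000 in the plus window: counted
  # "+" with 5' end 8900 (wrong strand for the upstream window): not counted
  # "+" with 5' end 11990 inside the plus window: counted
  counts <- count_fragments(f, frags)
  expect_equal(unname(counts[1, 1]), 3L)

  expect_equal(sum(count_fragments(f, frags[0, , drop = FALSE])), 0)
  bad <- frags; bad$strand[1] <- "*"
  expect_error(count_fragments(f, bad), "strand")
})

test_that("the low-count filter removes features with fewer than ten total counts", {
  ctrl <- matrix(c(4L, 5L, 0L), ncol = 1)
  cko <- matrix(c(5L, 5L, 4L), ncol = 1)
  keep <- filter_low(list(ctrl = ctrl, cko = cko), 10)
  expect_equal(keep, c(FALSE, TRUE, FALSE))  # totals 9, 10, 4
  expect_length(filter_low(list(matrix(integer(), ncol = 1)), 10), 0)
  # monotone: raising the threshold never adds features
  keep15 <- filter_low(list(ctrl = ctrl, cko = cko), 15)
  expect_true(all(keep15 <= keep))
})

test_that("size factors absorb global scaling and preserve single-feature changes", {
  set.seed(21)
  n <- 50
  base <- matrix(rnbinom(2 * n, size = 20, mu = 100), ncol = 2)
  rownames(base) <- sprintf("f%02d", seq_len(n))

  # knockout counts exactly double: size factors absorb the doubling
  fc <- erna_log2fc(base, 2L * base)
  expect_true(all(abs(fc$log2fc) < 0.1))

  # one feature genuinely doubled against a stable background
  cko <- base
  cko[1, ] <- 2L * cko[1, ]
  fc2 <- erna_log2fc(base, cko)
  expect_equal(fc2$log2fc[1], 1, tolerance = 0.15)
  expect_lt(max(abs(fc2$log2fc[-1])), 0.2)

  expect_equal(fc2$log2fc, erna_log2fc(base, cko)$log2fc)  # deterministic
})

test_that("planted eRNA fold-changes are recovered from overdispersed counts", {
  set.seed(31)
  n <- 240
  planted <- runif(n, -2, 2)
  mu0 <- 60; size <- 15
  ctrl <- cbind(rnbinom(n, size = size, mu = mu0),
                rnbinom(n, size = size, mu = mu0))
  cko <- cbind(rnbinom(n, size = size, mu = mu0 * 2^planted),
               rnbinom(n, size = size, mu = mu0 * 2^planted))
  rownames(ctrl) <- rownames(cko) <- sprintf("f%03d", seq_len(n))
  keep <- filter_low(list(ctrl, cko), 10)
  fc <- erna_log2fc(ctrl[keep, ], cko[keep, ])
  rho <- cor(planted[keep], fc$log2fc, method = "spearman")
  expect_gte(rho, 0.9)
})
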