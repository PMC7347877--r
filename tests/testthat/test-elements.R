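test_that("reciprocal overlap applies the fraction to both intervals", {
  a <- iv("chr1", 0, 100)
  expect_true(reciprocal_overlap(a, a, 0.25))
  # overlap 20 of a 100-bp interval: 0.20 < 0.25
  expect_false(reciprocal_overlap(a, iv("chr1", 80, 180), 0.25))
  # overlap 50 >= 25 on both sides
  expect_true(reciprocal_overlap(a, iv("chr1", 50, 150), 0.25))
  expect_false(reciprocal_overlap(a, iv("chr2", 0, 100), 0.25))
})

test_that("reciprocal overlap is symmetric over random interval pairs", {
  set.seed(3)
  for (k in 1:50) {
    s1 <- sample(1000, 1); s2 <- sample(1000, 1)
    a <- iv("chr1", s1, s1 + sample(500, 1))
    b <- iv("chr1", s2, s2 + sample(500, 1))
    expect_equal(reciprocal_overlap(a, b, 0.25), reciprocal_overlap(b, a, 0.25))
  }
})

test_that("element classification finds enhancers and promoters with centered windows", {
  dhs <- iv("chr1", c(1000, 4900), c(1600, 5200))
  k27 <- iv("chr1", c(900, 4800), c(1700, 5300))
  k4 <- iv("chr1", 800, 1800)
  tss <- data.frame(chrom = "chr1", pos = 5000L)

  el <- classify_elements(dhs, k27, k4, tss)
  enh <- el[el$kind == "enhancer", ]
  prom <- el[el$kind == "promoter", ]
  # enhancer window centered on the DHS midpoint 1300
  expect_equal(nrow(enh), 1)
  expect_equal(c(enh$window_start, enh$window_end), c(800, 1800))
  # promoter window centered on the TSS
  expect_equal(nrow(prom), 1)
  expect_equal(c(prom$window_start, prom$window_end), c(4500, 5500))

  # no H3K27ac -> nothing is active
  none <- classify_elements(dhs, iv("chr1", integer(), integer()), k4, tss)
  expect_equal(nrow(none), 0)
})

test_that("loop merging uses inclusive 10 kb midpoint tolerance and counts matches", {
  a <- lp("chr1", 0, 10000, 500000, 510000)
  expect_equal(nrow(merge_loops(a, a)), 1)

  # both anchor midpoints offset by 10,001 bp: outside "within 10 kb"
  b <- lp("chr1", 10001, 20001, 510001, 520001)
  expect_equal(nrow(merge_loops(a, b)), 2)
  # at exactly 10,000 they merge
  b2 <- lp("chr1", 10000, 20000, 510000, 520000)
  expect_equal(nrow(merge_loops(a, b2)), 1)

  # 3 + 2 loops with one cross-match -> 4 merged loops
  a3 <- lp("chr1", c(0, 1e6, 2e6), c(10000, 1e6 + 10000, 2e6 + 10000),
           c(5e5, 1.5e6, 2.5e6), c(5e5 + 10000, 1.5e6 + 10000, 2.5e6 + 10000))
  b2 <- lp("chr1", c(1e6 + 5000, 8e6), c(1e6 + 15000, 8e6 + 10000),
           c(1.5e6 + 5000, 8.5e6), c(1.5e6 + 15000, 8.5e6 + 10000))
  m <- merge_loops(a3, b2)
  expect_equal(nrow(m), 4)
  expect_equal(sum(m$source == "merged"), 1)
})

test_that("domain merging requires both borders within 20 kb", {
  a <- iv("chr1", 0, 500000)
  expect_equal(nrow(merge_domains(a, a)), 1)
  # starts differ 15 kb (ok) but ends differ 25 kb (not ok)
  b <- iv("chr1", 15000, 525000)
  expect_equal(nrow(merge_domains(a, b)), 2)
  # disjoint sets pass through
  d <- merge_domains(a, iv("chr1", 2e6, 2.5e6))
  expect_equal(nrow(d), 2)
})

test_that("merge operations are idempotent", {
  a <- iv("chr1", c(0, 1e6), c(5e5, 1.4e6))
  empty_d <- iv("chr1", integer(), integer())
  expect_equal(merge_domains(a, empty_d)[, 1:3], a)
  expect_equal(nrow(merge_domains(a, a)), nrow(a))

  l <- lp("chr1", c(0, 1e6), c(1e4, 1.01e6), c(4e5, 1.39e6), c(4.1e5, 1.4e6))
  empty_l <- lp("chr1", integer(), integer(), integer(), integer())
  expect_equal(merge_loops(l, empty_l)[, 1:5], l)
  expect_equal(nrow(merge_loops(l, l)), nrow(l))
})

test_that("domain classification against loop anchors respects the 25 kb rule", {
  doms <- iv("chr1", 0, 500000)
  expect_equal(classify_domains(doms, lp("chr1", integer(), integer(),
                                         integer(), integer()))$klass,
               "compartmental")
  near <- lp("chr1", 0, 10000, 490000, 500000)
  expect_equal(classify_domains(doms, near)$klass, "loop")
  far <- lp("chr1", 30000, 40000, 450000, 460000)  # 30 kb from each border
  expect_equal(classify_domains(doms, far)$klass, "compartmental")
})

test_that("loop classification distinguishes boundary, intra-domain, and other", {
  doms <- iv("chr1", c(0, 6e5), c(5e5, 1.2e6))
  boundary <- lp("chr1", 0, 10000, 490000, 500000)
  intra <- lp("chr1", 100000, 110000, 300000, 310000)  # >= 25 kb inside
  spanning <- lp("chr1", 100000, 110000, 700000, 710000)  # crosses domains
  cl <- classify_loops(rbind(boundary, intra, spanning), doms)
  expect_equal(cl$klass, c("boundary", "intra_domain", "other"))
})

test_that("domain classification partitions every input set", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(1:15, 1)
    starts <- sort(sample(seq(0, 5e6, by = 1e5), n))
    doms <- iv("chr1", starts, starts + 8e4)
    nl <- sample(0:6, 1)
    ls <- sort(sample(seq(0, 5e6, by = 1e4), nl))
    loops <- lp("chr1", ls, ls + 1e4, ls + 3e5, ls + 3.1e5)
    cl <- classify_domains(doms, loops)
    expect_equal(sum(cl$klass == "loop") + sum(cl$klass == "compartmental"),
                 nrow(doms))
  }
})
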