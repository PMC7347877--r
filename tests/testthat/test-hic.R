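test_that("domain contacts average off-diagonal pairs inside the domain", {
  D <- matrix(1, 6, 6)
  cm <- cm_from_dense(D)
  expect_equal(domain_contacts(cm, 0, 60000), 1)

  # 3-bin domain with v(1,2)=2, v(1,3)=1, v(2,3)=3 -> mean 2
  D <- diag(6)
  D[1, 2] <- D[2, 1] <- 2; D[1, 3] <- D[3, 1] <- 1; D[2, 3] <- D[3, 2] <- 3
  cm <- cm_from_dense(D)
  expect_equal(domain_contacts(cm, 0, 30000), 2)

  expect_error(domain_contacts(cm, 0, 10000), "fewer than 2 bins")
})

test_that("loop contacts average the anchor rectangle", {
  D <- matrix(0, 8, 8)
  D[2, 6] <- D[6, 2] <- 4.2
  cm <- cm_from_dense(D)
  expect_equal(loop_contacts(cm, 10000, 20000, 50000, 60000), 4.2)

  D[2, 6] <- D[6, 2] <- 1; D[2, 7] <- D[7, 2] <- 2
  D[3, 6] <- D[6, 3] <- 3; D[3, 7] <- D[7, 3] <- 4
  cm <- cm_from_dense(D)
  expect_equal(loop_contacts(cm, 10000, 30000, 50000, 70000), 2.5)

  expect_error(loop_contacts(cm, 10000, 30000, 20000, 40000), "overlap")
})

test_that("insulation matches enumeration and its uniform closed form", {
  # uniform matrix, ell = 2: 4 crossing pairs of 6 -> -log2(4/6)
  D <- matrix(1, 10, 10)
  cm <- cm_from_dense(D)
  expect_equal(insulation_score(cm, 5, 2), -log2((4 + 1e-6) / (6 + 1e-6)))

  # closed form on uniform matrices: -log2(ell^2 / (ell * (2*ell - 1)))
  D <- matrix(1, 42, 42)
  cm <- cm_from_dense(D)
  for (ell in 1:10) {
    expected <- -log2((ell^2 + 1e-6) / (ell * (2 * ell - 1) + 1e-6))
    expect_equal(insulation_score(cm, 21, ell), expected, tolerance = 1e-12)
  }

  # zero crossing entries -> strongly positive score
  D <- matrix(0, 10, 10)
  D[1:5, 1:5] <- 1; D[6:10, 6:10] <- 1
  cm <- cm_from_dense(D)
  expect_gt(insulation_score(cm, 6, 5), 10)

  # degenerate 2-bin window: the only pair crosses -> score 0
  D <- matrix(1, 4, 4)
  expect_equal(insulation_score(cm_from_dense(D), 2, 1), 0)

  expect_error(insulation_score(cm_from_dense(D), 1, 2), "outside")
})

test_that("APA recovers a planted center enrichment and is flat on uniform input", {
  n <- 60
  D <- matrix(1, n, n)
  cm <- cm_from_dense(D)
  loops <- lp("chrT", 140000, 150000, 440000, 450000)
  r <- apa(cm, loops, w = 10)
  expect_equal(r$p2ll, 1)
  expect_true(all(abs(r$aggregate - 1) < 1e-12))

  D[15, 45] <- D[45, 15] <- 5
  r <- apa(cm_from_dense(D), loops, w = 10)
  expect_equal(r$p2ll, 5)
  expect_equal(r$n_loops_used, 1)

  # loops too close to the diagonal are skipped; none usable -> error
  near <- lp("chrT", 140000, 150000, 190000, 200000)
  expect_error(apa(cm_from_dense(D), near, w = 10), "no loops usable")
})

test_that("contact statistics scale linearly with the matrix", {
  set.seed(9)
  D <- random_dense(30)
  cm1 <- cm_from_dense(D)
  cm3 <- cm_from_dense(3 * D)
  expect_equal(domain_contacts(cm3, 0, 100000), 3 * domain_contacts(cm1, 0, 100000))
  expect_equal(loop_contacts(cm3, 0, 10000, 50000, 60000),
               3 * loop_contacts(cm1, 0, 10000, 50000, 60000))
})

test_that("compartment eigenvector separates a two-block checkerboard and respects sign symmetry", {
  set.seed(4)
  n <- 24
  lab <- rep(c(1, -1), each = n / 2)
  D <- outer(lab, lab) * 0.4 + 1 + matrix(runif(n * n, -0.02, 0.02), n, n)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  cm <- cm_from_dense(D, resolution = 150000)
  k27 <- ifelse(lab > 0, 2, 0.5)
  tr <- compartment_eigenvector(cm, k27)
  expect_equal(sign(tr$eigenvalue), lab)
  expect_true(tr$oriented)

  # negating the H3K27ac orientation vector negates the eigenvalues
  tr2 <- compartment_eigenvector(cm, -k27 + 3)  # reversed ordering
  expect_equal(tr2$eigenvalue, -tr$eigenvalue)

  # invariant to uniform scaling of the matrix
  tr3 <- compartment_eigenvector(cm_from_dense(5 * D, resolution = 150000), k27)
  expect_equal(tr3$eigenvalue, tr$eigenvalue, tolerance = 1e-8)

  expect_error(compartment_eigenvector(cm, rep(1, n)), "zero-variance")
})

test_that("domain eigenvalue averages overlapped 150 kb bins", {
  tr <- structure(list(chrom = "chrT", bin_size = 150000,
                       eigenvalue = c(0.4, 0.2, -0.2, 0.1, 0.2, 0.6),
                       oriented = TRUE), class = "compartment_track")
  expect_equal(domain_eigenvalue(tr, 10000, 100000), 0.4)
  expect_equal(domain_eigenvalue(tr, 150000, 450000), 0)
  expect_equal(domain_eigenvalue(tr, 450000, 900000), 0.3)
  tr$eigenvalue[1] <- NA
  expect_true(is.na(domain_eigenvalue(tr, 0, 150000)))
})
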