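test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- tiny_cfg()
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$truth$domains, b$truth$domains)
  expect_identical(a$control$fragments, b$control$fragments)
  expect_identical(as.matrix(a$knockout$matrices[[1]]$mat),
                   as.matrix(b$knockout$matrices[[1]]$mat))
  c <- generate_dataset(tiny_cfg(rng_seed = 12))
  expect_false(identical(a$truth$domains$acc_lfc, c$truth$domains$acc_lfc))
})

test_that("zero coupling and zero noise plant no contact change", {
  ds <- generate_dataset(tiny_cfg(contact_log2fc_slope = 0,
                                  target_correlation = NA,
                                  matrix_noise_sd = 0))
  expect_true(all(ds$truth$domains$contact_lfc == 0))
})

test_that("unit loop enrichment with zero coupling leaves loop pixels equal across conditions up to noise", {
  ds <- generate_dataset(tiny_cfg(loop_enrichment = 1,
                                  contact_log2fc_slope = 0,
                                  target_correlation = NA,
                                  matrix_noise_sd = 0))
  tl <- ds$truth$loops
  res <- ds$truth$config$resolution_bp
  for (k in seq_len(nrow(tl))) {
    i <- tl$start1[k] %/% res + 1L
    j <- tl$start2[k] %/% res + 1L
    vc <- as.numeric(ds$control$matrices[[tl$chrom[k]]]$mat[i, j])
    vk <- as.numeric(ds$knockout$matrices[[tl$chrom[k]]]$mat[i, j])
    expect_equal(vk, vc)
  }
})

test_that("planted truth correlation hits the configured target at study scale", {
  tr <- default_ds()$truth$domains  # 60 domains, target r 0.6, seed 7
  r <- cor(tr$acc_lfc, tr$contact_lfc)
  expect_true(abs(r - 0.6) <= 0.15)
})

test_that("planted accessibility classes are consistent with the 0.585 thresholds", {
  tr <- tiny_ds()$truth$domains
  expect_true(all(tr$acc_lfc[tr$acc_class == "increased"] > 0.585))
  expect_true(all(tr$acc_lfc[tr$acc_class == "decreased"] < -0.585))
  expect_true(all(abs(tr$acc_lfc[tr$acc_class == "unchanged"]) < 0.585))
  expect_true(all(table(tr$acc_class) >= 1))
})

test_that("the O/E background calibrates to 1 without domains or loops", {
  ds <- generate_dataset(sim_config(
    genome = data.frame(chrom = "chrS", length = 2.4e6),
    n_domains_per_chrom = 1, domain_length_range = c(250e3, 300e3),
    frac_loop_domains = 0, frac_intra_loops = 0, domain_boost = 1,
    contact_log2fc_slope = 0, target_correlation = NA, rng_seed = 2))
  m <- ds$control$matrices[[1]]$mat
  expect_equal(mean(m@x), 1, tolerance = 0.01)
})

test_that("impossible domain placement raises an explicit error", {
  expect_error(generate_dataset(sim_config(
    genome = data.frame(chrom = "chrS", length = 1e6),
    n_domains_per_chrom = 5, domain_length_range = c(3e5, 4e5),
    rng_seed = 1)), "cannot fit")
})

test_that("written bundles round-trip through the package readers", {
  ds <- tiny_ds()
  tmp <- withr::local_tempdir()
  write_dataset(ds, tmp)

  dhs <- read_bed(file.path(tmp, "control", "dhs_peaks.bed"))
  expect_equal(dhs[, 1:3], ds$control$peaks$dhs)

  loops <- read_bedpe(file.path(tmp, "control", "loops.bedpe"))
  expect_equal(loops, ds$control$loops)

  doms <- read_bed(file.path(tmp, "knockout", "domains.bed"))
  expect_equal(doms[, 1:3], ds$knockout$domains)

  trk <- read_bedgraph(file.path(tmp, "control", "accessibility.bedGraph"))
  expect_equal(trk$segments, ds$control$tracks$accessibility$segments,
               tolerance = 1e-9)

  cm0 <- ds$control$matrices[[1]]
  cm <- read_contact_triples(file.path(tmp, "control", "chrS.oe.txt"),
                             cm0$resolution, cm0$chrom,
                             cm0$n_bins * cm0$resolution)
  expect_equal(as.matrix(cm$mat), as.matrix(cm0$mat), tolerance = 1e-9)

  genes <- read_gtf(file.path(tmp, "annotation.gtf"))
  expect_equal(genes, ds$annotation)
})

test_that("simulation config rejects inconsistent settings", {
  expect_error(sim_config(loop_enrichment = 0.5))
  expect_error(sim_config(target_correlation = 1.5))
  expect_error(sim_config(target_correlation = 0.6, contact_log2fc_slope = 0),
               "non-zero")
  expect_error(sim_config(compartment_period_bp = 1.25e6), "resolution")
})
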