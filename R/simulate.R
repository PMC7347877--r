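# Two-condition synthetic dataset with planted effect sizes: non-
# overlapping contact domains carrying per-domain accessibility log2
# fold-changes coupled to contact fold-changes, boundary and intra-domain
# loops with planted pixel enrichment, a checkerboard compartment structure
# at 150 kb, DHS-centered signal tracks, and negative-binomial stranded
# eRNA fragments.  Identical config (including seed) reproduces the dataset
# bit for bit.

#' Simulation configuration
#'
#' Defines the synthetic study conditions.  Defaults emulate a desk-scale
#' two-condition chromatin study: three 9 Mb chromosomes at 10 kb matrix
#' resolution, 60 domains (250-450 kb) of which half are loop domains, a
#' 20/70/10 increased/unchanged/decreased accessibility class mix with
#' class-consistent planted log2 fold-changes, contact changes coupled to
#' accessibility at a target Pearson correlation of 0.6, 3-fold loop-pixel
#' enrichment, a 1.2 Mb compartment checkerboard, five DHS per domain, and
#' overdispersed eRNA counts (negative binomial, mean 60, size 15, two
#' replicates per condition).
#'
#' @param genome data.frame with `chrom`, `length` (bp).
#' @param resolution_bp Contact-matrix bin size (bp).
#' @param eigen_resolution_bp Compartment-matrix bin size (bp).
#' @param n_domains_per_chrom Domains placed on each chromosome.
#' @param domain_length_range Length range in bp, `c(min, max)`.
#' @param frac_loop_domains Fraction of domains given a boundary loop.
#' @param frac_intra_loops Fraction of domains given one intra-domain loop.
#' @param class_probs Named probabilities for
#'   increased/unchanged/decreased accessibility classes.
#' @param class_means,class_sds Named per-class means/sds of planted
#'   accessibility log2FC (draws are rejected until class-consistent:
#'   increased >= 0.75, |unchanged| <= 0.45, decreased <= -0.75).
#' @param contact_log2fc_slope Linear coupling of planted contact log2FC to
#'   accessibility log2FC.
#' @param target_correlation Intended Pearson r between planted
#'   accessibility and contact log2FCs (in [-1, 1]); the contact-noise sd is
#'   derived from it.  `NA` means no contact noise (r = 1 when slope != 0).
#' @param loop_enrichment Multiplicative loop-pixel enrichment (>= 1).
#' @param domain_boost Multiplicative within-domain O/E elevation.
#' @param matrix_noise_sd sdlog of mean-one log-normal pixel noise.
#' @param compartment_period_bp Checkerboard block period (bp); must be a
#'   multiple of both resolutions.
#' @param compartment_amp O/E amplitude of the checkerboard (+/- around 1).
#' @param dhs_per_domain DHS placed per domain (first is promoter-like).
#' @param base_rpm DHS signal height in control (rpm).
#' @param background_rpm Track background (rpm).
#' @param signal_noise_sd sd (log2 units) of per-DHS, per-condition signal
#'   noise.
#' @param h3k27ac_slope,smc1_slope Coupling of H3K27ac / Smc1 log2FC to the
#'   planted accessibility log2FC.
#' @param erna_mean Control negative-binomial mean count per feature per
#'   replicate.
#' @param erna_dispersion Negative-binomial size parameter.
#' @param call_jitter_bp Border jitter applied to knockout-condition
#'   domain/loop calls (exercises merging).
#' @param rng_seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    genome = data.frame(chrom = c("chr1", "chr2", "chr3"),
                        length = rep(9e6, 3), stringsAsFactors = FALSE),
    resolution_bp = 10000,
    eigen_resolution_bp = 150000,
    n_domains_per_chrom = 20,
    domain_length_range = c(250e3, 450e3),
    frac_loop_domains = 0.5,
    frac_intra_loops = 0.5,
    class_probs = c(increased = 0.2, unchanged = 0.7, decreased = 0.1),
    class_means = c(increased = 1.1, unchanged = 0, decreased = -1.1),
    class_sds = c(increased = 0.25, unchanged = 0.18, decreased = 0.25),
    contact_log2fc_slope = 0.5,
    target_correlation = 0.6,
    loop_enrichment = 3,
    domain_boost = 1.6,
    matrix_noise_sd = 0.1,
    compartment_period_bp = 1.2e6,
    compartment_amp = 0.4,
    dhs_per_domain = 5,
    base_rpm = 10,
    background_rpm = 0.5,
    signal_noise_sd = 0.15,
    h3k27ac_slope = 0.8,
    smc1_slope = 0.7,
    erna_mean = 60,
    erna_dispersion = 15,
    call_jitter_bp = 5000,
    rng_seed = 7) {
  cfg <- list(genome = genome, resolution_bp = resolution_bp,
              eigen_resolution_bp = eigen_resolution_bp,
              n_domains_per_chrom = n_domains_per_chrom,
              domain_length_range = domain_length_range,
              frac_loop_domains = frac_loop_domains,
              frac_intra_loops = frac_intra_loops,
              class_probs = class_probs, class_means = class_means,
              class_sds = class_sds,
              contact_log2fc_slope = contact_log2fc_slope,
              target_correlation = target_correlation,
              loop_enrichment = loop_enrichment, domain_boost = domain_boost,
              matrix_noise_sd = matrix_noise_sd,
              compartment_period_bp = compartment_period_bp,
              compartment_amp = compartment_amp,
              dhs_per_domain = dhs_per_domain, base_rpm = base_rpm,
              background_rpm = background_rpm,
              signal_noise_sd = signal_noise_sd,
              h3k27ac_slope = h3k27ac_slope, smc1_slope = smc1_slope,
              erna_mean = erna_mean, erna_dispersion = erna_dispersion,
              call_jitter_bp = call_jitter_bp,
              rng_seed = as.integer(rng_seed))
  stopifnot(all(genome$length > 0), resolution_bp > 0,
            compartment_period_bp %% resolution_bp == 0,
            compartment_period_bp %% eigen_resolution_bp == 0,
            loop_enrichment >= 1,
            is.na(target_correlation) ||
              (target_correlation >= -1 && target_correlation <= 1),
            domain_length_range[1] > 0,
            domain_length_range[2] >= domain_length_range[1],
            abs(sum(class_probs) - 1) < 1e-8,
            dhs_per_domain >= 1)
  if (!is.na(target_correlation) && target_correlation != 0 &&
      contact_log2fc_slope == 0)
    stop("target_correlation != 0 requires a non-zero contact_log2fc_slope",
         call. = FALSE)
  if (!is.na(target_correlation) && target_correlation == 0 &&
      contact_log2fc_slope != 0)
    stop("target_correlation == 0 requires contact_log2fc_slope == 0",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Class-consistent planted accessibility log2FC: rejection-sample until the
# draw lands in the class band (keeps downstream +/-0.585 classification
# exact even in the zero-noise limit).
.draw_class_lfc <- function(klass, means, sds) {
  lo <- c(increased = 0.75, unchanged = -0.45, decreased = -Inf)[klass]
  hi <- c(increased = Inf, unchanged = 0.45, decreased = -0.75)[klass]
  x <- stats::rnorm(length(klass), means[klass], sds[klass])
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), means[klass[bad]], sds[klass[bad]])
    bad <- bad[x[bad] < lo[bad] | x[bad] > hi[bad]]
  }
  x
}

# Safe single draw from a vector (sample() treats a scalar as 1:n).
.pick1 <- function(x) x[sample.int(length(x), 1)]

# Mean-one multiplicative log-normal noise.
.mnoise <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# Place n non-overlapping domains on [margin, len - margin] with >= gap bp
# between them, borders snapped to the bin grid.
.place_domains <- function(len, n, len_range, res, gap, margin) {
  lens <- round(stats::runif(n, len_range[1], len_range[2]) / res) * res
  slack <- len - 2 * margin - sum(lens) - (n - 1) * gap
  if (slack < 0)
    stop("domains cannot fit on a chromosome of ", len,
         " bp without overlap; reduce n_domains_per_chrom or lengths",
         call. = FALSE)
  cuts <- sort(stats::runif(n))
  extra <- round(diff(c(0, cuts)) / max(cuts, 1e-12) * slack / res) * res
  starts <- margin + cumsum(extra) + c(0, cumsum(lens[-n] + gap))
  data.frame(start = as.integer(starts), end = as.integer(starts + lens))
}

#' Generate a two-condition synthetic dataset
#'
#' Builds, for control and knockout conditions, peak sets (DHS, H3K27ac,
#' H3K4me1), signal tracks (accessibility, H3K27ac, Smc1), stranded eRNA
#' fragments, domain/loop call sets, and O/E KR-style contact matrices (at
#' quantification and compartment resolutions), together with the truth
#' set of planted effects.  Knockout matrices are the shared clean
#' structure times per-domain multiplicative fold-changes, with independent
#' mean-one multiplicative noise per condition.
#'
#' @param cfg A [sim_config()].
#' @return List with `control` and `knockout` bundles (each: `peaks`,
#'   `tracks`, `fragments`, `domains`, `loops`, `matrices`,
#'   `matrices_eigen`), shared `annotation` (genes), and `truth`
#'   (per-domain planted classes and log2FCs, loops with enrichment and
#'   class, per-bin compartment labels).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$rng_seed)
  res <- cfg$resolution_bp

  ## ---- truth: domains, classes, planted effects ----
  dom <- do.call(rbind, lapply(seq_len(nrow(cfg$genome)), function(g) {
    d <- .place_domains(cfg$genome$length[g], cfg$n_domains_per_chrom,
                        cfg$domain_length_range, res,
                        gap = 3 * res, margin = 15 * res)
    d$chrom <- cfg$genome$chrom[g]
    d
  }))
  dom <- dom[, c("chrom", "start", "end")]
  n_dom <- nrow(dom)
  # deterministic class counts (round n * p, remainder to the largest
  # class), then a random permutation: keeps class sizes stable across
  # seeds so every downstream stage has members of each planted class
  klass_names <- c("increased", "unchanged", "decreased")
  cnt <- floor(n_dom * cfg$class_probs[klass_names])
  cnt[which.max(cnt)] <- cnt[which.max(cnt)] + n_dom - sum(cnt)
  acc_class <- sample(rep(klass_names, cnt))
  acc_lfc <- .draw_class_lfc(acc_class, cfg$class_means, cfg$class_sds)
  slope <- cfg$contact_log2fc_slope
  contact_lfc <- slope * acc_lfc
  if (!is.na(cfg$target_correlation) && cfg$target_correlation != 0 &&
      abs(cfg$target_correlation) < 1 && slope != 0) {
    # noise orthogonalized against acc_lfc in-sample and scaled so the
    # sample Pearson r of the planted vectors equals the target exactly
    z <- stats::rnorm(n_dom)
    z <- stats::residuals(stats::lm(z ~ acc_lfc))
    eps_sd <- abs(slope) * stats::sd(acc_lfc) *
      sqrt(1 / cfg$target_correlation^2 - 1)
    contact_lfc <- contact_lfc + z / stats::sd(z) * eps_sd
  }
  n_ld <- round(n_dom * cfg$frac_loop_domains)
  is_loop_dom <- sample(rep(c(TRUE, FALSE), c(n_ld, n_dom - n_ld)))
  n_il <- round(n_dom * cfg$frac_intra_loops)
  has_intra <- sample(rep(c(TRUE, FALSE), c(n_il, n_dom - n_il)))

  dom$domain_id <- sprintf("dom_%03d", seq_len(n_dom))
  dom$klass <- ifelse(is_loop_dom, "loop", "compartmental")
  dom$acc_class <- acc_class
  dom$acc_lfc <- acc_lfc
  dom$contact_lfc <- contact_lfc

  ## ---- loops (bin-snapped anchors) ----
  loops <- list()
  for (k in seq_len(n_dom)) {
    a <- dom$start[k]; b <- dom$end[k]
    if (is_loop_dom[k]) {
      loops[[length(loops) + 1]] <- data.frame(
        chrom = dom$chrom[k], start1 = a, end1 = a + res,
        start2 = b - res, end2 = b,
        klass = "boundary", domain_id = dom$domain_id[k],
        stringsAsFactors = FALSE)
    }
    if (has_intra[k]) {
      nb <- (b - a) %/% res
      # anchors > 25 kb (3 bins) inside each boundary; >= 3 bins apart so
      # that jittered-and-merged anchors can never touch on the bin grid
      lo <- 4; hi <- nb - 4
      if (hi - lo >= 3) {
        i <- .pick1(lo:(hi - 3))
        j <- .pick1((i + 3):hi)
        loops[[length(loops) + 1]] <- data.frame(
          chrom = dom$chrom[k], start1 = a + (i - 1) * res, end1 = a + i * res,
          start2 = a + (j - 1) * res, end2 = a + j * res,
          klass = "intra_domain", domain_id = dom$domain_id[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  loops <- do.call(rbind, loops)
  if (is.null(loops))
    loops <- data.frame(chrom = character(), start1 = integer(),
                        end1 = integer(), start2 = integer(),
                        end2 = integer(), klass = character(),
                        domain_id = character(), stringsAsFactors = FALSE)
  loops$enrichment <- rep(cfg$loop_enrichment, nrow(loops))

  ## ---- DHS and derived peaks ----
  dhs <- do.call(rbind, lapply(seq_len(n_dom), function(k) {
    n <- cfg$dhs_per_domain
    span <- dom$end[k] - dom$start[k] - 4e4
    pos <- dom$start[k] + 2e4 +
      round(span * (seq_len(n) - 0.5) / n + stats::runif(n, -3e3, 3e3))
    data.frame(chrom = dom$chrom[k], center = as.integer(pos),
               domain_id = dom$domain_id[k],
               role = c("promoter", rep("enhancer", n - 1)),
               stringsAsFactors = FALSE)
  }))
  peak <- function(half) data.frame(chrom = dhs$chrom,
                                    start = dhs$center - half,
                                    end = dhs$center + half,
                                    stringsAsFactors = FALSE)
  dhs_peaks <- peak(300)
  k27_peaks <- peak(400)
  k4me1_peaks <- peak(500)[dhs$role == "enhancer", , drop = FALSE]

  ## ---- gene annotation ----
  # Promoter genes: TSS at the promoter DHS center, 8 kb body on "+".
  prom <- dhs[dhs$role == "promoter", , drop = FALSE]
  genes <- data.frame(
    chrom = prom$chrom, start = prom$center, end = prom$center + 8000L,
    strand = "+",
    gene_id = sprintf("gene_%s", prom$domain_id),
    gene_biotype = "protein_coding", stringsAsFactors = FALSE)
  # Intergenic genes in the gaps between consecutive domains (alternating
  # biotype) exercise the eRNA exclusion rule without touching DHS windows.
  gaps <- list()
  for (g in seq_len(nrow(cfg$genome))) {
    d <- dom[dom$chrom == cfg$genome$chrom[g], , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) next
    gs <- d$end[-nrow(d)]; ge <- d$start[-1]
    wide <- which(ge - gs >= 20000)
    if (!length(wide)) next
    mid <- (gs[wide] + ge[wide]) %/% 2
    gaps[[g]] <- data.frame(
      chrom = cfg$genome$chrom[g], start = mid - 4000L, end = mid + 4000L,
      strand = rep(c("+", "-"), length.out = length(wide)),
      gene_id = sprintf("inter_%s_%d", cfg$genome$chrom[g], wide),
      gene_biotype = rep(c("protein_coding", "lncRNA"),
                         length.out = length(wide)),
      stringsAsFactors = FALSE)
  }
  genes <- rbind(genes, do.call(rbind, gaps))
  rownames(genes) <- NULL

  ## ---- signal tracks ----
  lfc_assay <- list(accessibility = dom$acc_lfc,
                    h3k27ac = cfg$h3k27ac_slope * dom$acc_lfc,
                    smc1 = cfg$smc1_slope * dom$acc_lfc)
  comp_label <- .compartment_labels(cfg)
  build_tracks <- function(condition) {
    lapply(names(lfc_assay), function(assay) {
      height <- cfg$base_rpm *
        (if (condition == "knockout")
           2^(lfc_assay[[assay]][match(dhs$domain_id, dom$domain_id)]) else 1) *
        2^stats::rnorm(nrow(dhs), 0, cfg$signal_noise_sd)
      segs <- lapply(seq_len(nrow(cfg$genome)), function(g) {
        ch <- cfg$genome$chrom[g]
        sel <- which(dhs$chrom == ch)
        sel <- sel[order(dhs$center[sel])]
        bg <- cfg$background_rpm
        # A-block H3K27ac elevation carries the compartment signal
        base_segs <- if (assay == "h3k27ac") {
          lab <- comp_label[comp_label$chrom == ch, , drop = FALSE]
          data.frame(chrom = ch, start = lab$start, end = lab$end,
                     value = bg + ifelse(lab$label == "A", 0.4, 0))
        } else {
          data.frame(chrom = ch, start = 0L, end = cfg$genome$length[g],
                     value = bg)
        }
        pk <- data.frame(chrom = ch, start = dhs$center[sel] - 500L,
                         end = dhs$center[sel] + 500L, value = height[sel])
        .overlay_segments(base_segs, pk)
      })
      signal_track(do.call(rbind, segs))
    }) -> tracks
    names(tracks) <- names(lfc_assay)
    tracks
  }
  tracks_ctrl <- build_tracks("control")
  tracks_ko <- build_tracks("knockout")

  ## ---- contact matrices ----
  mats <- .build_matrices(cfg, dom, loops)
  emats <- .build_eigen_matrices(cfg, comp_label)

  ## ---- eRNA fragments ----
  frag <- function(condition) {
    enh <- dhs[dhs$role == "enhancer", , drop = FALSE]
    lfc <- if (condition == "knockout")
      dom$acc_lfc[match(enh$domain_id, dom$domain_id)] else 0
    out <- list()
    for (r in 1:2) {
      mu <- cfg$erna_mean * 2^lfc
      counts <- stats::rnbinom(nrow(enh), size = cfg$erna_dispersion, mu = mu)
      minus <- stats::rbinom(nrow(enh), counts, 0.5)
      plus <- counts - minus
      pm <- rep(seq_len(nrow(enh)), minus)
      pp <- rep(seq_len(nrow(enh)), plus)
      p5m <- enh$center[pm] - sample.int(2000, length(pm), replace = TRUE)
      p5p <- enh$center[pp] + sample.int(2000, length(pp), replace = TRUE) - 1L
      out[[r]] <- rbind(
        data.frame(chrom = enh$chrom[pm], start = pmax(p5m - 149L, 0L),
                   end = p5m + 1L, strand = "-",
                   rep = sprintf("rep%d", r), stringsAsFactors = FALSE),
        data.frame(chrom = enh$chrom[pp], start = p5p, end = p5p + 150L,
                   strand = "+", rep = sprintf("rep%d", r),
                   stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, out)
    out[order(out$chrom, out$start, out$rep, out$strand), , drop = FALSE]
  }
  frags_ctrl <- frag("control")
  frags_ko <- frag("knockout")

  ## ---- per-condition call sets (knockout borders jittered) ----
  jit <- function(x, n) as.integer(x + sample(seq(-cfg$call_jitter_bp,
                                                  cfg$call_jitter_bp, by = 1000),
                                              n, replace = TRUE))
  dom_ctrl <- dom[, c("chrom", "start", "end")]
  dom_ko <- dom_ctrl
  loops_ctrl <- loops[, c("chrom", "start1", "end1", "start2", "end2")]
  loops_ko <- loops_ctrl
  if (cfg$call_jitter_bp > 0) {
    dom_ko$start <- jit(dom_ko$start, nrow(dom_ko))
    dom_ko$end <- jit(dom_ko$end, nrow(dom_ko))
    half <- cfg$call_jitter_bp %/% 2
    jl <- function(x, n) as.integer(x + sample(seq(-half, half, by = 500),
                                               n, replace = TRUE))
    loops_ko$start1 <- jl(loops_ko$start1, nrow(loops_ko))
    loops_ko$end1 <- loops_ko$start1 + res
    loops_ko$start2 <- jl(loops_ko$start2, nrow(loops_ko))
    loops_ko$end2 <- loops_ko$start2 + res
  }

  bundle <- function(condition) {
    list(
      peaks = list(dhs = dhs_peaks, h3k27ac = k27_peaks, h3k4me1 = k4me1_peaks),
      tracks = if (condition == "control") tracks_ctrl else tracks_ko,
      fragments = if (condition == "control") frags_ctrl else frags_ko,
      domains = if (condition == "control") dom_ctrl else dom_ko,
      loops = if (condition == "control") loops_ctrl else loops_ko,
      matrices = if (condition == "control") mats$ctrl else mats$ko,
      matrices_eigen = if (condition == "control") emats$ctrl else emats$ko
    )
  }
  list(control = bundle("control"), knockout = bundle("knockout"),
       annotation = genes,
       truth = list(domains = dom, loops = loops,
                    compartments = comp_label,
                    dhs = dhs,
                    config = cfg))
}

# Per-150kb-bin compartment labels from the checkerboard period.
.compartment_labels <- function(cfg) {
  do.call(rbind, lapply(seq_len(nrow(cfg$genome)), function(g) {
    bs <- cfg$eigen_resolution_bp
    n <- cfg$genome$length[g] %/% bs
    start <- (seq_len(n) - 1L) * bs
    block <- start %/% cfg$compartment_period_bp
    data.frame(chrom = cfg$genome$chrom[g], start = as.integer(start),
               end = as.integer(start + bs),
               label = ifelse(block %% 2 == 0, "A", "B"),
               stringsAsFactors = FALSE)
  }))
}

# Overlay peak segments on a base piecewise-constant track (peaks replace
# the base value; peaks are non-overlapping and sorted).
.overlay_segments <- function(base, peaks) {
  brk <- sort(unique(c(base$start, base$end, peaks$start, peaks$end)))
  brk <- brk[brk >= min(base$start) & brk <= max(base$end)]
  s <- brk[-length(brk)]; e <- brk[-1]
  val <- base$value[findInterval(s, base$start)]
  pi <- findInterval(s, peaks$start)
  inpk <- pi >= 1 & s < peaks$end[pmax(pi, 1)]
  val[inpk] <- peaks$value[pi[inpk]]
  out <- data.frame(chrom = base$chrom[1], start = s, end = e, value = val)
  # merge equal-valued neighbours to keep files small
  grp <- cumsum(c(TRUE, val[-1] != val[-length(val)]))
  data.frame(chrom = base$chrom[1],
             start = tapply(out$start, grp, min),
             end = tapply(out$end, grp, max),
             value = tapply(out$value, grp, function(v) v[1]),
             row.names = NULL)
}

# Quantification-resolution matrices: clean structure (background 1, domain
# blocks boosted, loop pixels enriched) with per-domain knockout fold-
# changes and independent mean-one log-normal noise per condition.
.build_matrices <- function(cfg, dom, loops) {
  res <- cfg$resolution_bp
  ctrl <- list(); ko <- list()
  for (g in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[g]
    n <- as.integer(cfg$genome$length[g] %/% res)
    clean <- matrix(1, n, n)
    fold <- matrix(1, n, n)
    dd <- dom[dom$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(dd))) {
      bins <- (dd$start[k] %/% res + 1):(dd$end[k] %/% res)
      clean[bins, bins] <- clean[bins, bins] * cfg$domain_boost
      fold[bins, bins] <- fold[bins, bins] * 2^dd$contact_lfc[k]
    }
    ll <- loops[loops$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(ll))) {
      bi <- ll$start1[k] %/% res + 1L
      bj <- ll$start2[k] %/% res + 1L
      clean[bi, bj] <- clean[bi, bj] * ll$enrichment[k]
      clean[bj, bi] <- clean[bi, bj]
    }
    up <- which(upper.tri(clean, diag = TRUE), arr.ind = TRUE)
    v <- clean[up]
    vc <- v * .mnoise(nrow(up), cfg$matrix_noise_sd)
    vk <- v * fold[up] * .mnoise(nrow(up), cfg$matrix_noise_sd)
    ctrl[[ch]] <- contact_matrix(up[, 1], up[, 2], vc, ch, res, n)
    ko[[ch]] <- contact_matrix(up[, 1], up[, 2], vk, ch, res, n)
  }
  list(ctrl = ctrl, ko = ko)
}

# Compartment-resolution matrices: checkerboard O/E (1 +/- amp for same/
# different block labels) with independent noise per condition.
.build_eigen_matrices <- function(cfg, comp_label) {
  bs <- cfg$eigen_resolution_bp
  ctrl <- list(); ko <- list()
  for (g in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[g]
    lab <- comp_label$label[comp_label$chrom == ch]
    n <- length(lab)
    same <- outer(lab, lab, "==")
    clean <- ifelse(same, 1 + cfg$compartment_amp, 1 - cfg$compartment_amp)
    up <- which(upper.tri(clean, diag = TRUE), arr.ind = TRUE)
    v <- clean[up]
    ctrl[[ch]] <- contact_matrix(up[, 1], up[, 2],
                                 v * .mnoise(nrow(up), cfg$matrix_noise_sd),
                                 ch, bs, n)
    ko[[ch]] <- contact_matrix(up[, 1], up[, 2],
                               v * .mnoise(nrow(up), cfg$matrix_noise_sd),
                               ch, bs, n)
  }
  list(ctrl = ctrl, ko = ko)
}

#' Write a condition bundle to disk
#'
#' Writes the file set one condition contributes to a run: BED peaks,
#' bedGraph tracks, BED6 stranded fragments, domain BED, loop BEDPE, and
#' per-chromosome contact-triple files at both resolutions.  Every file
#' round-trips through the package's readers.
#'
#' @param bundle A `control` or `knockout` bundle from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- list()
  for (p in names(bundle$peaks)) {
    paths[[paste0("peaks_", p)]] <-
      write_bed(bundle$peaks[[p]], file.path(dir, paste0(p, "_peaks.bed")))
  }
  for (a in names(bundle$tracks)) {
    paths[[paste0("track_", a)]] <-
      write_bedgraph(bundle$tracks[[a]], file.path(dir, paste0(a, ".bedGraph")))
  }
  frag <- bundle$fragments
  frag$name <- frag$rep
  frag$score <- 0L
  paths$fragments <- write_bed(
    frag[, c("chrom", "start", "end", "name", "score", "strand")],
    file.path(dir, "fragments.bed"))
  paths$domains <- write_bed(bundle$domains, file.path(dir, "domains.bed"))
  paths$loops <- write_bedpe(bundle$loops, file.path(dir, "loops.bedpe"))
  for (ch in names(bundle$matrices)) {
    paths[[paste0("matrix_", ch)]] <- write_contact_triples(
      bundle$matrices[[ch]], file.path(dir, paste0(ch, ".oe.txt")))
  }
  for (ch in names(bundle$matrices_eigen)) {
    paths[[paste0("matrix_eigen_", ch)]] <- write_contact_triples(
      bundle$matrices_eigen[[ch]], file.path(dir, paste0(ch, ".oe150k.txt")))
  }
  invisible(paths)
}

#' Write a full synthetic dataset
#'
#' Convenience wrapper: writes `control/` and `knockout/` bundles, the
#' shared gene annotation (GTF), and the truth tables (TSV) under `dir`.
#'
#' @param ds Dataset from [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bundle(ds$control, file.path(dir, "control"))
  write_bundle(ds$knockout, file.path(dir, "knockout"))
  write_gtf(ds$annotation, file.path(dir, "annotation.gtf"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  data.table::fwrite(ds$truth$domains, file.path(tdir, "domains.tsv"), sep = "\t")
  data.table::fwrite(ds$truth$loops, file.path(tdir, "loops.tsv"), sep = "\t")
  data.table::fwrite(ds$truth$compartments,
                     file.path(tdir, "compartments.tsv"), sep = "\t")
  invisible(dir)
}
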