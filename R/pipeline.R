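# End-to-end orchestration: merge and classify architecture calls, quantify
# signal and contacts per domain and loop, build and count eRNA features,
# run the distance-controlled resampling test, and emit summary tables with
# a filter-accounting log.

#' Default run configuration
#'
#' Every pipeline constant in one place: 25% reciprocal overlap; 10 kb loop
#' merge, 20 kb domain merge, and 25 kb classification tolerances; the
#' 0.585 accessibility class threshold; 1 kb element windows; 2 kb eRNA
#' windows with 1 kb gene exclusion extension and the 10-count filter;
#' 150 kb compartment bins; 10 kb quantification resolution; 100 resamples.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    reciprocal_frac = 0.25,
    loop_merge_tol = 10000,
    domain_merge_tol = 20000,
    class_tol = 25000,
    acc_threshold = 0.585,
    element_window = 1000,
    erna_window = 2000,
    erna_exclusion_extension = 1000,
    erna_min_count = 10,
    eigen_bin = 150000,
    resolution = 10000,
    n_resamples = 100,
    pseudocount_rpm = 0.1,
    pair_pseudocount = 1e-3,
    apa_w = 10,
    seed = 7
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config key: ", bad[1], call. = FALSE)
  cfg[names(over)] <- over
  num <- setdiff(names(cfg), character(0))
  if (any(vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all run_config values must be positive numbers", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration file
#'
#' Flat `key = value` text (one pair per line, `#` comments); keys must
#' match [default_run_config()] names, values numeric.
#'
#' @param path Path to the config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(default_run_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed config line: ", lines[lengths(kv) != 2][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (any(is.na(vals)))
    stop("non-numeric config value for key ", keys[is.na(vals)][1], call. = FALSE)
  do.call(default_run_config, as.list(stats::setNames(vals, keys)))
}

# Read one condition's bundle from a directory written by write_bundle().
.read_bundle <- function(dir, genome, cfg) {
  tracks <- list()
  for (a in c("accessibility", "h3k27ac", "smc1")) {
    f <- file.path(dir, paste0(a, ".bedGraph"))
    if (file.exists(f)) tracks[[a]] <- read_bedgraph(f)
  }
  frag <- read_bed(file.path(dir, "fragments.bed"))
  names(frag)[names(frag) == "name"] <- "rep"
  mats <- list(); emats <- list()
  for (g in seq_len(nrow(genome))) {
    ch <- genome$chrom[g]
    mats[[ch]] <- read_contact_triples(file.path(dir, paste0(ch, ".oe.txt")),
                                       cfg$resolution, ch, genome$length[g])
    f150 <- file.path(dir, paste0(ch, ".oe150k.txt"))
    if (file.exists(f150))
      emats[[ch]] <- read_contact_triples(f150, cfg$eigen_bin, ch,
                                          genome$length[g])
  }
  list(
    peaks = list(dhs = read_bed(file.path(dir, "dhs_peaks.bed")),
                 h3k27ac = read_bed(file.path(dir, "h3k27ac_peaks.bed")),
                 h3k4me1 = read_bed(file.path(dir, "h3k4me1_peaks.bed"))),
    tracks = tracks, fragments = frag,
    domains = read_bed(file.path(dir, "domains.bed")),
    loops = read_bedpe(file.path(dir, "loops.bedpe")),
    matrices = mats, matrices_eigen = emats
  )
}

# Union of two peak sets, overlapping intervals collapsed.
.pool_peaks <- function(a, b) {
  gr <- GenomicRanges::reduce(c(.as_granges(a), .as_granges(b)))
  out <- .from_granges(gr)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Mean per-eigen-bin signal of a track, for eigenvector orientation.
.binned_track <- function(track, chrom, chrom_length, bin) {
  n <- chrom_length %/% bin
  wins <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
                     end = seq_len(n) * bin)
  window_signal(track, wins)
}

#' Run the full two-condition analysis
#'
#' Stages: pool peaks and classify regulatory elements; merge per-condition
#' domain and loop calls and classify both; quantify per-domain
#' accessibility/H3K27ac/Smc1 at DHS windows and per-domain and per-loop
#' O/E contacts in both conditions; compute boundary insulation, the 150 kb
#' compartment eigenvector (H3K27ac-oriented) and per-domain eigenvalues;
#' build, count, filter and normalize eRNA features; run the
#' distance-controlled resampling test of boundary-loop versus intra-domain
#' DHS-pair contact changes in domains with increased accessibility; and
#' assemble the correlation panel.  Deterministic under a fixed seed.
#'
#' @param input Either a dataset list from [generate_dataset()] or a
#'   directory written by [write_dataset()].
#' @param config A `run_config` from [default_run_config()].
#' @param outdir Optional output directory; when given, per-domain,
#'   per-loop, and eRNA tables (TSV), the resampling result (JSON), the
#'   correlation panel (TSV), and a run log are written there.
#' @param genome Required when `input` is a directory: data.frame with
#'   `chrom`, `length`.
#' @return List with `domains`, `loops`, `erna`, `resampling`,
#'   `correlations`, `apa`, `log`.
#' @export
run_pipeline <- function(input, config = default_run_config(), outdir = NULL,
                         genome = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list(seed = config$seed,
              thresholds = unclass(config))
  if (is.character(input)) {
    if (is.null(genome)) stop("genome required when reading from a directory",
                              call. = FALSE)
    annotation <- read_gtf(file.path(input, "annotation.gtf"))
    ctrl <- .read_bundle(file.path(input, "control"), genome, config)
    cko <- .read_bundle(file.path(input, "knockout"), genome, config)
  } else {
    ctrl <- input$control; cko <- input$knockout
    annotation <- input$annotation
    genome <- data.frame(
      chrom = names(ctrl$matrices),
      length = vapply(ctrl$matrices, function(m) m$n_bins * m$resolution, 0))
  }

  ## ---- architecture: merge + classify ----
  domains <- merge_domains(ctrl$domains, cko$domains, config$domain_merge_tol)
  loops <- merge_loops(ctrl$loops, cko$loops, config$loop_merge_tol)
  log$n_domains <- c(control = nrow(ctrl$domains), knockout = nrow(cko$domains),
                     merged = nrow(domains))
  log$n_loops <- c(control = nrow(ctrl$loops), knockout = nrow(cko$loops),
                   merged = nrow(loops))
  domains <- classify_domains(domains, loops, config$class_tol)
  loops <- classify_loops(loops, domains, config$class_tol)

  ## ---- regulatory elements ----
  dhs <- .pool_peaks(ctrl$peaks$dhs, cko$peaks$dhs)
  k27 <- .pool_peaks(ctrl$peaks$h3k27ac, cko$peaks$h3k27ac)
  k4 <- .pool_peaks(ctrl$peaks$h3k4me1, cko$peaks$h3k4me1)
  tss <- gene_tss(annotation)
  elements <- classify_elements(dhs, k27, k4, tss,
                                frac = config$reciprocal_frac,
                                window_bp = config$element_window)
  log$n_elements <- table(elements$kind)

  # 1 kb DHS quantification windows (all DHS, for per-domain aggregation)
  half <- config$element_window %/% 2
  mid <- (dhs$start + dhs$end) %/% 2
  dhs_windows <- data.frame(chrom = dhs$chrom, start = mid - half,
                            end = mid - half + config$element_window)

  ## ---- per-domain signal + contacts ----
  dt <- domains
  dt$domain_id <- sprintf("mdom_%03d", seq_len(nrow(dt)))
  for (assay in names(ctrl$tracks)) {
    c0 <- domain_signal(dt, dhs_windows, ctrl$tracks[[assay]])
    c1 <- domain_signal(dt, dhs_windows, cko$tracks[[assay]])
    dt[[paste0(assay, "_ctrl")]] <- c0
    dt[[paste0(assay, "_cko")]] <- c1
    dt[[paste0(assay, "_log2fc")]] <-
      log2_change(c1, c0, config$pseudocount_rpm)
  }
  dt$accessibility_class <- classify_accessibility(dt$accessibility_log2fc,
                                                   config$acc_threshold)
  dt$contacts_ctrl <- NA_real_; dt$contacts_cko <- NA_real_
  dt$insulation_ctrl <- NA_real_; dt$insulation_cko <- NA_real_
  for (k in seq_len(nrow(dt))) {
    mc <- ctrl$matrices[[dt$chrom[k]]]; mk <- cko$matrices[[dt$chrom[k]]]
    dt$contacts_ctrl[k] <- domain_contacts(mc, dt$start[k], dt$end[k])
    dt$contacts_cko[k] <- domain_contacts(mk, dt$start[k], dt$end[k])
    ell <- max(1, (dt$end[k] - dt$start[k]) %/% mc$resolution)
    bb <- dt$start[k] %/% mc$resolution + 1L
    if (bb - ell >= 1 && bb + ell - 1 <= mc$n_bins) {
      dt$insulation_ctrl[k] <- insulation_score(mc, bb, ell)
      dt$insulation_cko[k] <- insulation_score(mk, bb, ell)
    }
  }
  dt$contacts_log2fc <- log2_change(dt$contacts_cko, dt$contacts_ctrl,
                                    config$pair_pseudocount)

  ## ---- compartments ----
  ev_ctrl <- list(); ev_cko <- list()
  if (length(ctrl$matrices_eigen)) {
    for (g in seq_len(nrow(genome))) {
      ch <- genome$chrom[g]
      k27c <- .binned_track(ctrl$tracks$h3k27ac, ch, genome$length[g],
                            config$eigen_bin)
      k27k <- .binned_track(cko$tracks$h3k27ac, ch, genome$length[g],
                            config$eigen_bin)
      ev_ctrl[[ch]] <- compartment_eigenvector(ctrl$matrices_eigen[[ch]], k27c)
      ev_cko[[ch]] <- compartment_eigenvector(cko$matrices_eigen[[ch]], k27k)
    }
    dt$eigen_ctrl <- NA_real_; dt$eigen_cko <- NA_real_
    for (k in seq_len(nrow(dt))) {
      dt$eigen_ctrl[k] <- domain_eigenvalue(ev_ctrl[[dt$chrom[k]]],
                                            dt$start[k], dt$end[k])
      dt$eigen_cko[k] <- domain_eigenvalue(ev_cko[[dt$chrom[k]]],
                                           dt$start[k], dt$end[k])
    }
    dt$eigen_delta <- dt$eigen_cko - dt$eigen_ctrl
  }

  ## ---- per-loop contacts ----
  lt <- loops
  lt$loop_id <- sprintf("mloop_%03d", seq_len(nrow(lt)))
  lt$contacts_ctrl <- NA_real_; lt$contacts_cko <- NA_real_
  for (k in seq_len(nrow(lt))) {
    mc <- ctrl$matrices[[lt$chrom[k]]]; mk <- cko$matrices[[lt$chrom[k]]]
    lt$contacts_ctrl[k] <- loop_contacts(mc, lt$start1[k], lt$end1[k],
                                         lt$start2[k], lt$end2[k])
    lt$contacts_cko[k] <- loop_contacts(mk, lt$start1[k], lt$end1[k],
                                        lt$start2[k], lt$end2[k])
  }
  lt$contacts_log2fc <- log2_change(lt$contacts_cko, lt$contacts_ctrl,
                                    config$pair_pseudocount)
  # domain accessibility class at each loop (midpoint containment)
  lmid <- (lt$start1 + lt$end2) %/% 2
  lt$domain_class <- NA_character_
  for (k in seq_len(nrow(lt))) {
    hit <- which(dt$chrom == lt$chrom[k] & dt$start <= lmid[k] &
                   dt$end > lmid[k])
    if (length(hit)) lt$domain_class[k] <- dt$accessibility_class[hit[1]]
  }

  ## ---- APA ----
  apa_res <- list()
  usable <- lt
  apa_try <- function(mats) {
    aggs <- NULL; used <- 0; skipped <- 0
    for (ch in unique(usable$chrom)) {
      r <- tryCatch(apa(mats[[ch]], usable[usable$chrom == ch, , drop = FALSE],
                        w = config$apa_w), error = function(e) NULL)
      if (is.null(r)) next
      aggs <- if (is.null(aggs)) r$aggregate * r$n_loops_used
              else aggs + r$aggregate * r$n_loops_used
      used <- used + r$n_loops_used; skipped <- skipped + r$n_skipped
    }
    if (used == 0) return(NULL)
    agg <- aggs / used
    w <- config$apa_w; size <- 2 * w + 1; cw <- ceiling(w / 2)
    ll <- agg[(size - cw + 1):size, 1:cw, drop = FALSE]
    structure(list(aggregate = agg, p2ll = agg[w + 1, w + 1] / mean(ll),
                   n_loops_used = used, n_skipped = skipped),
              class = "apa_result")
  }
  apa_res$control <- apa_try(ctrl$matrices)
  apa_res$knockout <- apa_try(cko$matrices)

  ## ---- eRNA ----
  erna_feat <- build_erna_features(dhs, elements, annotation,
                                   window_bp = config$erna_window,
                                   extension_bp = config$erna_exclusion_extension)
  counts_ctrl <- count_fragments(erna_feat, ctrl$fragments)
  counts_cko <- count_fragments(erna_feat, cko$fragments)
  keep <- filter_low(list(ctrl = counts_ctrl, cko = counts_cko),
                     config$erna_min_count)
  log$n_erna <- c(built = nrow(erna_feat),
                  dropped_in_build = attr(erna_feat, "n_dropped") %||% 0L,
                  low_count = sum(!keep), kept = sum(keep))
  erna <- if (any(keep)) {
    fc <- erna_log2fc(counts_ctrl[keep, , drop = FALSE],
                      counts_cko[keep, , drop = FALSE])
    cbind(erna_feat[keep, , drop = FALSE], fc[, -1, drop = FALSE])
  } else NULL

  ## ---- resampling ----
  inc <- dt[!is.na(dt$accessibility_class) &
              dt$accessibility_class == "increased", , drop = FALSE]
  test_loops <- lt[lt$klass == "boundary" & !is.na(lt$domain_class) &
                     lt$domain_class == "increased", , drop = FALSE]
  resamp <- NULL
  if (nrow(inc) >= 1 && nrow(test_loops) >= 3) {
    cand <- enumerate_candidate_pairs(inc, dhs)
    if (nrow(cand)) {
      cand <- pair_contact_log2fc(cand, ctrl$matrices, cko$matrices,
                                  config$pair_pseudocount)
      tmid1 <- (test_loops$start1 + test_loops$end1) %/% 2
      tmid2 <- (test_loops$start2 + test_loops$end2) %/% 2
      tpairs <- data.frame(chrom = test_loops$chrom, pos_a = tmid1,
                           pos_b = tmid2)
      tpairs <- pair_contact_log2fc(tpairs, ctrl$matrices, cko$matrices,
                                    config$pair_pseudocount)
      resamp <- tryCatch(
        resampling_test(tpairs$value, tpairs$pos_b - tpairs$pos_a, cand,
                        n = config$n_resamples, seed = config$seed),
        error = function(e) {
          log$resampling_error <<- conditionMessage(e); NULL
        })
    }
  }

  ## ---- correlation panel ----
  corr <- list()
  add_cor <- function(name, x, y, method) {
    r <- tryCatch(correlate(x, y, method), error = function(e) NULL)
    if (!is.null(r))
      corr[[length(corr) + 1]] <<- data.frame(
        comparison = name, method = method,
        estimate = r$estimate, p.value = r$p.value, n = sum(is.finite(x) & is.finite(y)),
        stringsAsFactors = FALSE)
  }
  add_cor("accessibility_vs_contacts", dt$accessibility_log2fc,
          dt$contacts_log2fc, "pearson")
  add_cor("h3k27ac_vs_contacts", dt$h3k27ac_log2fc, dt$contacts_log2fc,
          "pearson")
  add_cor("smc1_vs_contacts", dt$smc1_log2fc, dt$contacts_log2fc, "pearson")
  if (!is.null(dt$eigen_delta)) {
    add_cor("eigen_delta_vs_contacts", dt$eigen_delta, dt$contacts_log2fc,
            "spearman")
    add_cor("eigen_delta_vs_accessibility", dt$eigen_delta,
            dt$accessibility_log2fc, "spearman")
  }
  corr <- do.call(rbind, corr)

  out <- list(domains = dt, loops = lt, erna = erna, resampling = resamp,
              correlations = corr, apa = apa_res,
              eigenvectors = list(control = ev_ctrl, knockout = ev_cko),
              elements = elements, log = log)

  if (!is.null(outdir)) .write_report(out, outdir)
  out
}

.write_report <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out$domains, file.path(outdir, "domains.tsv"), sep = "\t")
  data.table::fwrite(out$loops, file.path(outdir, "loops.tsv"), sep = "\t")
  if (!is.null(out$erna))
    data.table::fwrite(out$erna, file.path(outdir, "erna.tsv"), sep = "\t")
  if (!is.null(out$correlations))
    data.table::fwrite(out$correlations, file.path(outdir, "correlations.tsv"),
                       sep = "\t")
  if (!is.null(out$resampling)) {
    r <- out$resampling
    jsonlite::write_json(
      list(test_median = r$test_median,
           resampled_medians = r$resampled_medians,
           empirical_p = r$empirical_p,
           empirical_p_text = if (r$empirical_p == 0)
             sprintf("< %g", 1 / r$n_resamples) else
               as.character(r$empirical_p),
           n_resamples = r$n_resamples, seed = r$seed,
           bin_scheme = sprintf("log2 bins of width %g", r$bin_width)),
      file.path(outdir, "resampling.json"), auto_unbox = TRUE, digits = NA)
  }
  logtxt <- utils::capture.output(utils::str(out$log, give.head = FALSE))
  writeLines(c(sprintf("domainweaver %s",
                       as.character(utils::packageVersion("domainweaver"))),
               logtxt), file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Per-class summary of a domain-table column
#'
#' n, median, and quartiles of `value_col` within each level of
#' `class_col`; classes absent from the table get an `n = 0` row with
#' missing summaries.
#'
#' @param table data.frame (usually the pipeline's domain table).
#' @param value_col Name of the numeric column to summarize.
#' @param class_col Name of the class column (default
#'   "accessibility_class").
#' @param levels Class levels to report (default: those present).
#' @return data.frame with `class`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_by_class <- function(table, value_col,
                               class_col = "accessibility_class",
                               levels = NULL) {
  stopifnot(value_col %in% names(table), class_col %in% names(table))
  cls <- table[[class_col]]
  if (is.null(levels)) levels <- unique(cls[!is.na(cls)])
  rows <- lapply(levels, function(l) {
    v <- table[[value_col]][!is.na(cls) & cls == l]
    v <- v[is.finite(v)]
    if (!length(v))
      data.frame(class = l, n = 0L, median = NA_real_, q25 = NA_real_,
                 q75 = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(class = l, n = length(v), median = stats::median(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 q75 = unname(stats::quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
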