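# Distance-controlled resampling null: compares the median contact
# log2 fold-change of a test pair set (loop-domain boundary loops) against
# resampled sets of intra-domain DHS pairs matched in number and pairwise
# distance, yielding a one-sided empirical p-value.

#' Enumerate candidate DHS pairs within domains
#'
#' All unordered pairs of DHS centers lying within the same domain; pairs
#' never cross domains.
#'
#' @param domains Domain data.frame (`chrom`, `start`, `end`), typically
#'   restricted to domains with increased accessibility.
#' @param dhs DNaseI peak data.frame (`chrom`, `start`, `end`).
#' @return data.frame with `chrom`, `pos_a`, `pos_b` (centers, pos_a <
#'   pos_b), `distance` (bp), `domain_id`.
#' @export
enumerate_candidate_pairs <- function(domains, dhs) {
  .check_intervals(domains, "domains"); .check_intervals(dhs, "dhs")
  center <- (dhs$start + dhs$end) %/% 2
  out <- vector("list", nrow(domains))
  for (k in seq_len(nrow(domains))) {
    inside <- which(dhs$chrom == domains$chrom[k] &
                      center >= domains$start[k] & center < domains$end[k])
    if (length(inside) < 2) next
    cc <- sort(center[inside])
    idx <- utils::combn(length(cc), 2)
    out[[k]] <- data.frame(
      chrom = domains$chrom[k],
      pos_a = cc[idx[1, ]], pos_b = cc[idx[2, ]],
      distance = cc[idx[2, ]] - cc[idx[1, ]],
      domain_id = k, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), pos_a = integer(), pos_b = integer(),
                      distance = integer(), domain_id = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contact log2 fold-change at position pairs
#'
#' For each pair, the log2 ratio of the knockout to control O/E value at the
#' single matrix pixel containing the two positions.  Pairs whose positions
#' fall in the same bin (a diagonal pixel) are dropped with a count in
#' attribute `n_dropped`.
#'
#' @param pairs Pair data.frame (`chrom`, `pos_a`, `pos_b`).
#' @param cm_ctrl,cm_cko Named lists of [contact_matrix()] per chromosome
#'   (or single matrices when all pairs share one chromosome).
#' @param pseudocount Pseudocount in O/E units (default 1e-3).
#' @return `pairs` with a `value` column of pixel log2 fold-changes.
#' @export
pair_contact_log2fc <- function(pairs, cm_ctrl, cm_cko, pseudocount = 1e-3) {
  if (inherits(cm_ctrl, "contact_matrix")) cm_ctrl <- stats::setNames(
    list(cm_ctrl), cm_ctrl$chrom)
  if (inherits(cm_cko, "contact_matrix")) cm_cko <- stats::setNames(
    list(cm_cko), cm_cko$chrom)
  value <- rep(NA_real_, nrow(pairs))
  same_bin <- logical(nrow(pairs))
  for (ch in unique(pairs$chrom)) {
    mc <- cm_ctrl[[ch]]; mk <- cm_cko[[ch]]
    if (is.null(mc) || is.null(mk))
      stop("no contact matrix for chromosome ", ch, call. = FALSE)
    sel <- pairs$chrom == ch
    bi <- pairs$pos_a[sel] %/% mc$resolution + 1L
    bj <- pairs$pos_b[sel] %/% mc$resolution + 1L
    diag_px <- bi == bj
    v <- rep(NA_real_, sum(sel))
    if (any(!diag_px)) {
      vc <- .cm_pixels(mc, bi[!diag_px], bj[!diag_px])
      vk <- .cm_pixels(mk, bi[!diag_px], bj[!diag_px])
      v[!diag_px] <- log2((vk + pseudocount) / (vc + pseudocount))
    }
    value[sel] <- v
    same_bin[sel] <- diag_px
  }
  out <- pairs[!same_bin, , drop = FALSE]
  out$value <- value[!same_bin]
  attr(out, "n_dropped") <- sum(same_bin)
  rownames(out) <- NULL
  out
}

.distance_bin <- function(d, bin_width = 1) {
  floor(log2(as.numeric(d)) / bin_width)
}

#' Distance-matched resampling
#'
#' Draws `n` resampled pair sets from `candidates`, each matching the test
#' set in size and in per-bin distance histogram.  Distances are binned in
#' log2-width bins (bin k covers [2^k, 2^(k+1)) bp); within one resample
#' candidates are drawn without replacement, falling back to replacement
#' when a bin is exhausted (counted in attribute `n_with_replacement`).
#'
#' @param candidates Pair data.frame with a `distance` column (and usually a
#'   `value` column).
#' @param test_distances Numeric vector of test-set pair distances (bp).
#' @param n Number of resamples (default 100).
#' @param seed Integer seed; the draw is fully determined by it.
#' @param bin_width Width of the log2 distance bins (default 1).
#' @return List of `n` data.frames, each a row subset of `candidates` with
#'   `length(test_distances)` rows.
#' @export
distance_matched_resample <- function(candidates, test_distances, n = 100,
                                      seed = 1, bin_width = 1) {
  stopifnot(n >= 1, length(test_distances) >= 1, all(test_distances > 0))
  cand_bin <- .distance_bin(candidates$distance, bin_width)
  need <- table(.distance_bin(test_distances, bin_width))
  bins <- as.integer(names(need))
  by_bin <- lapply(bins, function(b) which(cand_bin == b))
  empty <- lengths(by_bin) == 0
  if (any(empty))
    stop("no candidate pairs in distance bin [2^", bins[empty][1], ", 2^",
         bins[empty][1] + 1, ") bp", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n_wr <- 0L
  out <- vector("list", n)
  for (r in seq_len(n)) {
    take <- integer(0)
    for (k in seq_along(bins)) {
      pool <- by_bin[[k]]
      m <- as.integer(need[k])
      if (length(pool) >= m) {
        take <- c(take, pool[sample.int(length(pool), m)])
      } else {
        extra <- m - length(pool)
        take <- c(take, pool, pool[sample.int(length(pool), extra, replace = TRUE)])
        n_wr <- n_wr + extra
      }
    }
    out[[r]] <- candidates[take, , drop = FALSE]
  }
  attr(out, "n_with_replacement") <- n_wr
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Empirical p-value from resampled medians
#'
#' One-sided probability that the null produces a median below the test
#' set's: `(# resampled medians < test_median) / N`.  The conservative
#' `(k + 1) / (N + 1)` variant is available with `plus_one = TRUE`.
#'
#' @param test_median Median of the test pair set's values.
#' @param resampled_medians Numeric vector of resampled medians.
#' @param plus_one Use the (k+1)/(N+1) estimator (default FALSE).
#' @return Empirical p-value in [0, 1].
#' @export
empirical_pvalue <- function(test_median, resampled_medians, plus_one = FALSE) {
  stopifnot(length(resampled_medians) >= 1)
  k <- sum(resampled_medians < test_median)
  n <- length(resampled_medians)
  if (plus_one) (k + 1) / (n + 1) else k / n
}

#' Full distance-controlled resampling test
#'
#' Computes the test median, `n` distance-matched resampled medians, and the
#' one-sided empirical p-value.
#'
#' @param test_values Per-pair contact log2 fold-changes of the test set.
#' @param test_distances Matching pair distances (bp).
#' @param candidates Candidate pair data.frame with `distance` and `value`.
#' @param n Number of resamples (default 100).
#' @param seed Integer seed.
#' @param bin_width Log2 bin width (default 1).
#' @return List of class `resampling_result`: `test_median`,
#'   `resampled_medians`, `empirical_p`, `median_resample` (the resample at
#'   the floor(N/2)-th order statistic of the medians), `n_resamples`,
#'   `seed`, `bin_width`.
#' @export
resampling_test <- function(test_values, test_distances, candidates,
                            n = 100, seed = 1, bin_width = 1) {
  stopifnot(length(test_values) == length(test_distances))
  ok <- is.finite(test_values)
  test_values <- test_values[ok]; test_distances <- test_distances[ok]
  if (!length(test_values)) stop("empty test set", call. = FALSE)
  res <- distance_matched_resample(candidates, test_distances, n = n,
                                   seed = seed, bin_width = bin_width)
  meds <- vapply(res, function(d) stats::median(d$value), numeric(1))
  test_median <- stats::median(test_values)
  mid <- order(meds)[max(1L, floor(n / 2))]
  structure(list(
    test_median = test_median,
    resampled_medians = meds,
    empirical_p = empirical_pvalue(test_median, meds),
    median_resample = res[[mid]],
    n_resamples = n, seed = as.integer(seed), bin_width = bin_width
  ), class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  ptxt <- if (x$empirical_p == 0) sprintf("< %.3g", 1 / x$n_resamples)
          else sprintf("= %.3g", x$empirical_p)
  cat(sprintf(
    "<resampling_result> test median %.4f vs %d resamples (median of medians %.4f), empirical p %s\n",
    x$test_median, x$n_resamples, stats::median(x$resampled_medians), ptxt))
  invisible(x)
}
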