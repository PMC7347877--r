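# Signal quantification: piecewise-constant rpm coverage tracks, 1 kb
# element windows, per-domain aggregation over DHS, log2 fold-changes and
# the +/-0.585 accessibility classes.

#' Construct a signal track
#'
#' Piecewise-constant coverage in bedGraph semantics; uncovered positions
#' have value 0.  Segments must be non-overlapping per chromosome and
#' values non-negative (units: reads per million, rpm).
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `value`.
#' @return A `signal_track` object.
#' @export
signal_track <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  .check_intervals(segments, "signal track")
  if (nrow(segments) && any(segments$value < 0))
    stop("signal values must be >= 0", call. = FALSE)
  dt <- data.table::as.data.table(segments[, c("chrom", "start", "end", "value")])
  data.table::setkey(dt, chrom, start, end)
  if (nrow(dt) > 1) {
    ov <- dt[, any(start[-1] < end[-.N]), by = "chrom"]$V1
    if (any(ov)) stop("signal track segments overlap", call. = FALSE)
  }
  structure(list(segments = as.data.frame(dt)), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d segments on %d chromosome(s)\n",
              nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Mean signal over windows
#'
#' Length-weighted mean of the track over each window, with uncovered bases
#' counting 0.  When `track` is a list of replicate tracks they are averaged
#' with equal weight.
#'
#' @param track A `signal_track` or list of replicate `signal_track`s.
#' @param windows Interval data.frame (`chrom`, `start`, `end`).
#' @return Numeric vector of rpm means, one per window.
#' @export
window_signal <- function(track, windows) {
  if (!inherits(track, "signal_track")) {
    stopifnot(is.list(track), length(track) >= 1)
    reps <- vapply(track, window_signal, numeric(nrow(windows)), windows = windows)
    if (nrow(windows) == 1) return(mean(reps))
    return(rowMeans(matrix(reps, nrow = nrow(windows))))
  }
  .check_intervals(windows, "windows")
  seg <- track$segments
  if (nrow(windows) && !all(windows$chrom %in% unique(seg$chrom)))
    stop("window chromosome absent from signal track", call. = FALSE)
  if (!nrow(windows)) return(numeric(0))
  wg <- .as_granges(windows)
  sg <- .as_granges(seg)
  hits <- GenomicRanges::findOverlaps(wg, sg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(wg[qi], sg[si]))
  wsum <- rep(0, nrow(windows))
  if (length(qi)) {
    agg <- tapply(ov * seg$value[si], qi, sum)
    wsum[as.integer(names(agg))] <- agg
  }
  wsum / (windows$end - windows$start)
}

#' Log2 fold-change with pseudocount
#'
#' `log2((cko + pseudocount) / (ctrl + pseudocount))`.
#'
#' @param cko,ctrl Non-negative signal values (rpm or normalized counts).
#' @param pseudocount Positive stabilizer (default 0.1 rpm).
#' @return Numeric vector of log2 fold-changes.
#' @export
log2_change <- function(cko, ctrl, pseudocount = 0.1) {
  stopifnot(pseudocount > 0)
  if (any(cko < 0, na.rm = TRUE) || any(ctrl < 0, na.rm = TRUE))
    stop("signal values must be >= 0", call. = FALSE)
  log2((cko + pseudocount) / (ctrl + pseudocount))
}

#' Per-domain signal over DHS windows
#'
#' Unweighted mean of [window_signal()] over all DHS quantification windows
#' whose midpoint lies within each domain; NA for domains containing no
#' DHS window.
#'
#' @param domains Domain data.frame (`chrom`, `start`, `end`).
#' @param windows DHS window data.frame (`chrom`, `window_start`,
#'   `window_end`; or `start`/`end`).
#' @param track A `signal_track` or replicate list.
#' @return Numeric vector, one mean rpm per domain (NA when empty).
#' @export
domain_signal <- function(domains, windows, track) {
  .check_intervals(domains, "domains")
  if (all(c("window_start", "window_end") %in% names(windows))) {
    windows <- data.frame(chrom = windows$chrom, start = windows$window_start,
                          end = windows$window_end, stringsAsFactors = FALSE)
  }
  if (!nrow(windows)) return(rep(NA_real_, nrow(domains)))
  vals <- window_signal(track, windows)
  mid <- (windows$start + windows$end) %/% 2
  out <- rep(NA_real_, nrow(domains))
  for (k in seq_len(nrow(domains))) {
    inside <- windows$chrom == domains$chrom[k] &
      mid >= domains$start[k] & mid < domains$end[k]
    if (any(inside)) out[k] <- mean(vals[inside])
  }
  out
}

#' Accessibility change classes
#'
#' Classifies log2 fold-changes as increased (> threshold), decreased
#' (< -threshold), or unchanged (strictly between); values exactly at the
#' threshold are unchanged.
#'
#' @param log2fc Numeric vector of log2 fold-changes (NA allowed,
#'   propagated).
#' @param threshold Positive class threshold (default 0.585, i.e. 1.5-fold).
#' @return Character vector: increased|unchanged|decreased (NA preserved).
#' @export
classify_accessibility <- function(log2fc, threshold = 0.585) {
  stopifnot(threshold > 0)
  if (any(!is.finite(log2fc) & !is.na(log2fc)))
    stop("non-finite log2 fold-change", call. = FALSE)
  out <- rep("unchanged", length(log2fc))
  out[log2fc > threshold] <- "increased"
  out[log2fc < -threshold] <- "decreased"
  out[is.na(log2fc)] <- NA_character_
  out
}

#' Correlation with two-sided p-value
#'
#' Pearson or Spearman correlation via [stats::cor.test()], after dropping
#' incomplete pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method "pearson" or "spearman".
#' @return List with `estimate` and `p.value`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
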