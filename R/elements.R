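# Regulatory-element classification and merging/classification of contact
# domains and loops.  "Within N kb" is inclusive (<= N) throughout, and
# anchor-boundary distances are measured from the boundary point to the
# nearest point of the anchor interval (0 when the point lies inside).

#' Reciprocal overlap test
#'
#' TRUE iff the overlap between two intervals covers at least `frac` of each
#' interval's length (bedtools `-f frac -r` semantics).  Vectorized;
#' intervals on different chromosomes never overlap.
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`), recycled to a
#'   common length.
#' @param frac Required fraction in (0, 1].
#' @return Logical vector.
#' @export
reciprocal_overlap <- function(a, b, frac = 0.25) {
  stopifnot(frac > 0, frac <= 1)
  .check_intervals(a, "a"); .check_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  ov <- pmax(ov, 0)
  ov[a$chrom[ia] != b$chrom[ib]] <- 0
  ov >= frac * (a$end[ia] - a$start[ia]) & ov >= frac * (b$end[ib] - b$start[ib])
}

# Indices of `query` rows having >= frac reciprocal overlap with any
# `subject` row (GRanges-backed for large peak sets).
.reciprocal_any <- function(query, subject, frac) {
  if (!nrow(query) || !nrow(subject)) return(logical(nrow(query)))
  qg <- .as_granges(query); sg <- .as_granges(subject)
  hits <- GenomicRanges::findOverlaps(qg, sg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(qg[qi], sg[si]))
  ok <- ov >= frac * GenomicRanges::width(qg[qi]) &
        ov >= frac * GenomicRanges::width(sg[si])
  out <- logical(nrow(query))
  out[unique(qi[ok])] <- TRUE
  out
}

# TRUE for each point (chrom, pos) contained in some interval of `set`.
.point_in <- function(chrom, pos, set) {
  if (!length(pos) || !nrow(set)) return(logical(length(pos)))
  pg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  IRanges::overlapsAny(pg, .as_granges(set))
}

#' Classify active promoters and enhancers
#'
#' Promoters are transcription start sites whose 1-bp position lies within
#' both a DNaseI peak and an H3K27ac peak.  Enhancers are DNaseI peaks with
#' at least `frac` reciprocal overlap with an H3K27ac peak and with an
#' H3K4me1 peak, excluding DNaseI peaks that contain a promoter TSS.  Each
#' element carries a quantification window of `window_bp` centered on the
#' TSS (promoters) or the DHS midpoint (enhancers; floor division for odd
#' lengths).
#'
#' @param dhs,h3k27ac,h3k4me1 Peak interval data.frames.
#' @param tss data.frame with `chrom`, `pos` (0-based TSS positions); may be
#'   empty.
#' @param frac Reciprocal-overlap fraction (default 0.25).
#' @param window_bp Quantification window length in bp (default 1000).
#' @return data.frame with `kind` (promoter|enhancer), `chrom`,
#'   `anchor_start`, `anchor_end`, `window_start`, `window_end`.
#' @export
classify_elements <- function(dhs, h3k27ac, h3k4me1, tss,
                              frac = 0.25, window_bp = 1000) {
  .check_intervals(dhs, "dhs"); .check_intervals(h3k27ac, "h3k27ac")
  .check_intervals(h3k4me1, "h3k4me1")
  half <- window_bp %/% 2
  empty <- data.frame(kind = character(), chrom = character(),
                      anchor_start = integer(), anchor_end = integer(),
                      window_start = integer(), window_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(dhs)) return(empty)

  prom_ok <- if (nrow(tss)) {
    .point_in(tss$chrom, tss$pos, dhs) & .point_in(tss$chrom, tss$pos, h3k27ac)
  } else logical(0)
  promoters <- if (any(prom_ok)) {
    p <- tss[prom_ok, , drop = FALSE]
    data.frame(kind = "promoter", chrom = p$chrom,
               anchor_start = p$pos, anchor_end = p$pos + 1L,
               window_start = p$pos - half, window_end = p$pos - half + window_bp,
               stringsAsFactors = FALSE)
  } else empty

  enh_ok <- .reciprocal_any(dhs, h3k27ac, frac) &
            .reciprocal_any(dhs, h3k4me1, frac)
  if (any(prom_ok)) {
    # DHS peaks harboring a promoter TSS are promoter-associated, not enhancers
    ptss <- tss[prom_ok, , drop = FALSE]
    has_tss <- IRanges::overlapsAny(
      .as_granges(dhs),
      GenomicRanges::GRanges(ptss$chrom, IRanges::IRanges(ptss$pos + 1L, ptss$pos + 1L)))
    enh_ok <- enh_ok & !has_tss
  }
  enhancers <- if (any(enh_ok)) {
    e <- dhs[enh_ok, , drop = FALSE]
    mid <- (e$start + e$end) %/% 2
    data.frame(kind = "enhancer", chrom = e$chrom,
               anchor_start = e$start, anchor_end = e$end,
               window_start = mid - half, window_end = mid - half + window_bp,
               stringsAsFactors = FALSE)
  } else empty

  out <- rbind(promoters, enhancers)
  rownames(out) <- NULL
  out
}

# Greedy one-to-one matching of candidate pairs (ai, bi, dist), nearest
# first, ties broken by the smaller a-index.
.greedy_match <- function(ai, bi, dist) {
  o <- order(dist, ai, bi)
  used_a <- logical(0); used_b <- logical(0)
  keep <- logical(length(o))
  seen_a <- integer(0); seen_b <- integer(0)
  for (k in o) {
    if (!(ai[k] %in% seen_a) && !(bi[k] %in% seen_b)) {
      keep[k] <- TRUE
      seen_a <- c(seen_a, ai[k]); seen_b <- c(seen_b, bi[k])
    }
  }
  which(keep)
}

#' Merge two loop call sets
#'
#' Loops from the two sets are collapsed into one merged loop when both
#' anchor midpoints lie within `tol` bp of one another (inclusive); the
#' merged loop takes the union of each anchor pair.  Matching is greedy
#' one-to-one, nearest first.  Unmatched loops pass through.
#'
#' @param a,b Loop data.frames (`chrom`, `start1`, `end1`, `start2`,
#'   `end2`).
#' @param tol Midpoint tolerance in bp (default 10000).
#' @return Merged loop data.frame with a `source` column
#'   (a|b|merged).
#' @export
merge_loops <- function(a, b, tol = 10000) {
  .check_loops(a); .check_loops(b)
  a$source <- if (nrow(a)) "a" else character(0)
  b$source <- if (nrow(b)) "b" else character(0)
  cols <- c("chrom", "start1", "end1", "start2", "end2", "source")
  a <- a[, cols, drop = FALSE]; b <- b[, cols, drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    out <- rbind(a, b)
    return(out[order(out$chrom, out$start1, out$start2), , drop = FALSE])
  }
  am1 <- (a$start1 + a$end1) / 2; am2 <- (a$start2 + a$end2) / 2
  bm1 <- (b$start1 + b$end1) / 2; bm2 <- (b$start2 + b$end2) / 2
  cand <- data.table::CJ(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  cand <- cand[a$chrom[cand$ai] == b$chrom[cand$bi]]
  d1 <- abs(am1[cand$ai] - bm1[cand$bi]); d2 <- abs(am2[cand$ai] - bm2[cand$bi])
  cand <- cand[d1 <= tol & d2 <= tol]
  d <- abs(am1[cand$ai] - bm1[cand$bi]) + abs(am2[cand$ai] - bm2[cand$bi])
  sel <- .greedy_match(cand$ai, cand$bi, d)
  mi <- cand$ai[sel]; mj <- cand$bi[sel]
  merged <- if (length(mi)) data.frame(
    chrom = a$chrom[mi],
    start1 = pmin(a$start1[mi], b$start1[mj]),
    end1 = pmax(a$end1[mi], b$end1[mj]),
    start2 = pmin(a$start2[mi], b$start2[mj]),
    end2 = pmax(a$end2[mi], b$end2[mj]),
    source = "merged", stringsAsFactors = FALSE
  ) else a[0, , drop = FALSE]
  out <- rbind(merged,
               a[setdiff(seq_len(nrow(a)), mi), , drop = FALSE],
               b[setdiff(seq_len(nrow(b)), mj), , drop = FALSE])
  out <- out[order(out$chrom, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two domain call sets
#'
#' Domains collapse when both borders lie within `tol` bp of one another
#' (inclusive); the merged domain is the union interval.  Greedy nearest
#' one-to-one matching, ties broken toward the smaller start.
#'
#' @param a,b Domain interval data.frames (`chrom`, `start`, `end`).
#' @param tol Border tolerance in bp (default 20000).
#' @return Merged domain data.frame with a `source` column.
#' @export
merge_domains <- function(a, b, tol = 20000) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  a$source <- if (nrow(a)) "a" else character(0)
  b$source <- if (nrow(b)) "b" else character(0)
  cols <- c("chrom", "start", "end", "source")
  a <- a[, cols, drop = FALSE]; b <- b[, cols, drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    out <- rbind(a, b)
    return(out[order(out$chrom, out$start), , drop = FALSE])
  }
  cand <- data.table::CJ(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  cand <- cand[a$chrom[cand$ai] == b$chrom[cand$bi]]
  ds <- abs(a$start[cand$ai] - b$start[cand$bi])
  de <- abs(a$end[cand$ai] - b$end[cand$bi])
  keep <- ds <= tol & de <= tol
  cand <- cand[keep]
  d <- (ds + de)[keep]
  sel <- .greedy_match(cand$ai, cand$bi, d)
  mi <- cand$ai[sel]; mj <- cand$bi[sel]
  merged <- if (length(mi)) data.frame(
    chrom = a$chrom[mi],
    start = pmin(a$start[mi], b$start[mj]),
    end = pmax(a$end[mi], b$end[mj]),
    source = "merged", stringsAsFactors = FALSE
  ) else a[0, , drop = FALSE]
  out <- rbind(merged,
               a[setdiff(seq_len(nrow(a)), mi), , drop = FALSE],
               b[setdiff(seq_len(nrow(b)), mj), , drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Distance from a boundary point to an interval [s, e): 0 inside, else the
# gap to the nearest edge.
.point_interval_dist <- function(p, s, e) {
  pmax(s - p, p - e, 0)
}

#' Classify domains as loop or compartmental
#'
#' A domain is a loop domain iff some loop has anchor1 within `tol` of the
#' domain start and anchor2 within `tol` of the domain end (same
#' chromosome); otherwise it is compartmental (ordinary).
#'
#' @param domains Domain data.frame (`chrom`, `start`, `end`).
#' @param loops Loop data.frame.
#' @param tol Boundary-anchor tolerance in bp (default 25000).
#' @return `domains` with a `klass` column (loop|compartmental).
#' @export
classify_domains <- function(domains, loops, tol = 25000) {
  .check_intervals(domains, "domains")
  klass <- rep("compartmental", nrow(domains))
  if (nrow(loops)) {
    for (k in seq_len(nrow(domains))) {
      same <- loops$chrom == domains$chrom[k]
      if (!any(same)) next
      l <- loops[same, , drop = FALSE]
      d1 <- .point_interval_dist(domains$start[k], l$start1, l$end1)
      d2 <- .point_interval_dist(domains$end[k], l$start2, l$end2)
      if (any(d1 <= tol & d2 <= tol)) klass[k] <- "loop"
    }
  }
  domains$klass <- klass
  domains
}

#' Classify loops as boundary, intra-domain, or other
#'
#' A loop is a boundary (domain) loop iff its anchors lie within `tol` of
#' the two boundaries of one domain; an intra-domain loop iff both anchors
#' fall strictly inside a single domain and it is not a boundary loop;
#' otherwise other (ordinary).
#'
#' @param loops Loop data.frame.
#' @param domains Domain data.frame.
#' @param tol Boundary-anchor tolerance in bp (default 25000).
#' @return `loops` with a `klass` column (boundary|intra_domain|other).
#' @export
classify_loops <- function(loops, domains, tol = 25000) {
  .check_loops(loops)
  klass <- rep("other", nrow(loops))
  for (k in seq_len(nrow(loops))) {
    same <- domains$chrom == loops$chrom[k]
    if (!any(same)) next
    d <- domains[same, , drop = FALSE]
    b1 <- .point_interval_dist(d$start, loops$start1[k], loops$end1[k])
    b2 <- .point_interval_dist(d$end, loops$start2[k], loops$end2[k])
    if (any(b1 <= tol & b2 <= tol)) {
      klass[k] <- "boundary"
    } else if (any(loops$start1[k] > d$start & loops$end2[k] < d$end)) {
      klass[k] <- "intra_domain"
    }
  }
  loops$klass <- klass
  loops
}
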