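# Enhancer-RNA quantification: bidirectional 2 kb stranded windows at
# enhancer DHS centers, gene/lncRNA exclusion with 1 kb extension,
# strand-specific 5'-end fragment counting, the <10-count filter, and
# size-factor-normalized log2 fold-changes.

#' Build eRNA features at enhancer DHS
#'
#' One bidirectional feature per DNaseI peak overlapping an enhancer
#' element: a `window_bp` window upstream of the peak center counted on the
#' Crick (-) strand and a `window_bp` window downstream counted on the
#' Watson (+) strand.  Features are dropped when either window overlaps a
#' protein-coding gene or lncRNA body extended by `extension_bp` beyond TSS
#' and TES, or when the upstream window would extend past the chromosome
#' start.
#'
#' @param dhs DNaseI peak data.frame (`chrom`, `start`, `end`).
#' @param enhancers Element data.frame from [classify_elements()] (only
#'   rows with `kind == "enhancer"` are used), or any interval set defining
#'   enhancer locations.
#' @param genes Gene data.frame (`chrom`, `start`, `end`, `gene_biotype`);
#'   protein_coding and lncRNA biotypes define exclusion zones.
#' @param window_bp Window length in bp (default 2000).
#' @param extension_bp Exclusion extension beyond gene ends (default 1000).
#' @return data.frame with `feature_id`, `chrom`, `center`, `minus_start`,
#'   `minus_end`, `plus_start`, `plus_end`, plus attribute
#'   `n_dropped` (features removed by exclusion or truncation).
#' @export
build_erna_features <- function(dhs, enhancers, genes,
                                window_bp = 2000, extension_bp = 1000) {
  .check_intervals(dhs, "dhs")
  if (all(c("anchor_start", "anchor_end") %in% names(enhancers))) {
    enhancers <- enhancers[enhancers$kind == "enhancer", , drop = FALSE]
    enhancers <- data.frame(chrom = enhancers$chrom,
                            start = enhancers$anchor_start,
                            end = enhancers$anchor_end, stringsAsFactors = FALSE)
  }
  empty <- data.frame(feature_id = character(), chrom = character(),
                      center = integer(), minus_start = integer(),
                      minus_end = integer(), plus_start = integer(),
                      plus_end = integer(), stringsAsFactors = FALSE)
  if (!nrow(dhs) || !nrow(enhancers)) return(empty)
  is_enh <- IRanges::overlapsAny(.as_granges(dhs), .as_granges(enhancers))
  d <- dhs[is_enh, , drop = FALSE]
  if (!nrow(d)) return(empty)
  center <- (d$start + d$end) %/% 2
  feat <- data.frame(
    feature_id = sprintf("erna_%s_%d", d$chrom, center),
    chrom = d$chrom, center = as.integer(center),
    minus_start = as.integer(center - window_bp), minus_end = as.integer(center),
    plus_start = as.integer(center), plus_end = as.integer(center + window_bp),
    stringsAsFactors = FALSE
  )
  truncated <- feat$minus_start < 0
  feat <- feat[!truncated, , drop = FALSE]

  excl <- genes[genes$gene_biotype %in% c("protein_coding", "lncRNA"), , drop = FALSE]
  dropped_excl <- 0L
  if (nrow(excl) && nrow(feat)) {
    zones <- data.frame(chrom = excl$chrom,
                        start = pmax(excl$start - extension_bp, 0),
                        end = excl$end + extension_bp, stringsAsFactors = FALSE)
    zg <- .as_granges(zones)
    span <- data.frame(chrom = feat$chrom, start = feat$minus_start,
                       end = feat$plus_end, stringsAsFactors = FALSE)
    hit <- IRanges::overlapsAny(.as_granges(span), zg)
    dropped_excl <- sum(hit)
    feat <- feat[!hit, , drop = FALSE]
  }
  rownames(feat) <- NULL
  attr(feat, "n_dropped") <- as.integer(sum(truncated) + dropped_excl)
  feat
}

# 0-based 5'-end position of stranded fragments.
.five_prime <- function(fragments) {
  ifelse(fragments$strand == "+", fragments$start, fragments$end - 1L)
}

#' Count stranded fragments in eRNA windows
#'
#' A fragment is counted for a feature when its 5' end lies in the upstream
#' window with strand "-" or in the downstream window with strand "+"; the
#' feature count is the sum of both windows, per replicate.
#'
#' @param features Feature data.frame from [build_erna_features()].
#' @param fragments Stranded fragment data.frame (`chrom`, `start`, `end`,
#'   `strand`, optional `rep`); strand must be "+" or "-".
#' @return Integer matrix: features x replicates (replicate labels from the
#'   `rep` column, or a single column "rep1").
#' @export
count_fragments <- function(features, fragments) {
  if (nrow(fragments) && !all(fragments$strand %in% c("+", "-")))
    stop("fragments must carry strand '+' or '-'", call. = FALSE)
  reps <- if ("rep" %in% names(fragments) && nrow(fragments))
    sort(unique(fragments$rep)) else "rep1"
  counts <- matrix(0L, nrow = nrow(features), ncol = length(reps),
                   dimnames = list(features$feature_id, reps))
  if (!nrow(fragments) || !nrow(features)) return(counts)
  p5 <- .five_prime(fragments)
  frep <- if ("rep" %in% names(fragments)) fragments$rep else "rep1"
  for (r in seq_along(reps)) {
    sel <- frep == reps[r]
    for (s in c("-", "+")) {
      f <- sel & fragments$strand == s
      if (!any(f)) next
      pg <- GenomicRanges::GRanges(fragments$chrom[f],
                                   IRanges::IRanges(p5[f] + 1L, p5[f] + 1L))
      win <- if (s == "-") {
        data.frame(chrom = features$chrom, start = features$minus_start,
                   end = features$minus_end)
      } else {
        data.frame(chrom = features$chrom, start = features$plus_start,
                   end = features$plus_end)
      }
      hits <- IRanges::countOverlaps(.as_granges(win), pg)
      counts[, r] <- counts[, r] + as.integer(hits)
    }
  }
  counts
}

#' Remove low-count features
#'
#' Keeps features whose summed count across every replicate and condition is
#' at least `min_total` (strict "fewer than" removal).
#'
#' @param counts List of per-condition count matrices (features x
#'   replicates) with identical row order, e.g. `list(ctrl = , cko = )`.
#' @param min_total Minimum total count (default 10).
#' @return Logical keep vector over features.
#' @export
filter_low <- function(counts, min_total = 10) {
  stopifnot(is.list(counts), length(counts) >= 1)
  total <- Reduce(`+`, lapply(counts, rowSums))
  total >= min_total
}

# Median-of-ratios size factors over a pooled count matrix (features x
# samples); the reference is the per-feature geometric mean over samples,
# restricted to features positive in every sample.
.size_factors <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos))
    stop("no feature has positive counts in every sample; cannot normalize",
         call. = FALSE)
  lg <- log(mat[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - ref)))
}

#' eRNA log2 fold-change (knockout vs control)
#'
#' Counts are scaled by median-of-ratios size factors computed jointly over
#' all replicates of both conditions, averaged across replicates per
#' condition, and compared as `log2((cko + 0.5) / (ctrl + 0.5))`.
#'
#' @param counts_ctrl,counts_cko Count matrices (features x replicates) with
#'   identical row order, already filtered with [filter_low()].
#' @return data.frame with `feature_id`, normalized per-condition means
#'   (`ctrl_mean`, `cko_mean`), and `log2fc`; size factors attached as
#'   attribute `size_factors`.
#' @export
erna_log2fc <- function(counts_ctrl, counts_cko) {
  stopifnot(nrow(counts_ctrl) == nrow(counts_cko))
  if (!nrow(counts_ctrl)) stop("no retained eRNA features", call. = FALSE)
  pooled <- cbind(counts_ctrl, counts_cko)
  colnames(pooled) <- c(paste0("ctrl_", seq_len(ncol(counts_ctrl))),
                        paste0("cko_", seq_len(ncol(counts_cko))))
  sf <- .size_factors(pooled)
  norm <- sweep(pooled, 2, sf, "/")
  ctrl <- rowMeans(norm[, seq_len(ncol(counts_ctrl)), drop = FALSE])
  cko <- rowMeans(norm[, ncol(counts_ctrl) + seq_len(ncol(counts_cko)),
                       drop = FALSE])
  out <- data.frame(
    feature_id = rownames(counts_ctrl) %||% as.character(seq_len(nrow(counts_ctrl))),
    ctrl_mean = ctrl, cko_mean = cko,
    log2fc = log2((cko + 0.5) / (ctrl + 0.5)),
    stringsAsFactors = FALSE
  )
  attr(out, "size_factors") <- sf
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
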