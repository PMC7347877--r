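# Sparse O/E KR-normalized contact matrices and the matrix statistics
# computed on them: domain/loop contact means, boundary insulation,
# aggregate peak analysis (P2LL), compartment eigenvector, per-domain
# eigenvalue.

#' Construct a contact matrix
#'
#' Per-chromosome sparse upper-triangle map of observed-over-expected (O/E)
#' KR-normalized contact values at a fixed resolution.  Bin indices are
#' 1-based in R; bin `k` covers bp `[(k-1)*resolution, k*resolution)`.
#' Absent entries are zeros to every consumer.
#'
#' @param i,j Integer bin indices (any order; stored with i <= j).
#' @param x Non-negative O/E values.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins on the chromosome.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(i, j, x, chrom, resolution, n_bins) {
  stopifnot(length(i) == length(j), length(j) == length(x),
            resolution > 0, n_bins >= 1)
  if (length(x) && any(x < 0)) stop("O/E values must be >= 0", call. = FALSE)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo) && (any(lo < 1) || any(hi > n_bins)))
    stop("bin indices outside chromosome", call. = FALSE)
  if (anyDuplicated(cbind(lo, hi)))
    stop("duplicate (i, j) contact records", call. = FALSE)
  mat <- Matrix::sparseMatrix(i = lo, j = hi, x = as.numeric(x),
                              dims = c(n_bins, n_bins))
  structure(list(chrom = chrom, resolution = as.integer(resolution),
                 n_bins = as.integer(n_bins), mat = mat),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, %d non-zero entries\n",
              x$chrom, x$n_bins, x$resolution, length(x$mat@x)))
  invisible(x)
}

# Dense symmetric block M[rows, cols]; absent entries are 0.
.cm_block <- function(cm, rows, cols) {
  sub <- cm$mat[rows, cols, drop = FALSE] + Matrix::t(cm$mat)[rows, cols, drop = FALSE]
  sub <- as.matrix(sub)
  # the diagonal is stored once in the upper triangle but added twice above
  di <- match(intersect(rows, cols), rows)
  dj <- match(intersect(rows, cols), cols)
  if (length(di)) sub[cbind(di, dj)] <- sub[cbind(di, dj)] / 2
  sub
}

# Values at specific pixel pairs (vectors of bin indices), symmetric lookup.
.cm_pixels <- function(cm, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.numeric(cm$mat[cbind(lo, hi)])
}

#' Read a contact-triple text file
#'
#' Tab-separated `pos_i<TAB>pos_j<TAB>value` records, one per contact, with
#' positions the left bp coordinate of each bin (juicer-dump style).
#' Records with `pos_i > pos_j` are mirrored into the upper triangle.
#'
#' @param path Path to the triple file.
#' @param resolution Bin size in bp; all positions must be multiples.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp (defines the bin count).
#' @return A [contact_matrix()].
#' @export
read_contact_triples <- function(path, resolution, chrom, chrom_length) {
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw))
    return(contact_matrix(integer(), integer(), numeric(),
                          chrom, resolution, n_bins))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed contact record at line ", bad[1], " of ", path, call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stop("non-numeric contact record at line ", bad[1], " of ", path, call. = FALSE)
  bad <- which(m[, 1] %% resolution != 0 | m[, 2] %% resolution != 0)
  if (length(bad))
    stop("position not a multiple of resolution at line ", bad[1], " of ", path,
         call. = FALSE)
  i <- as.integer(m[, 1] %/% resolution) + 1L
  j <- as.integer(m[, 2] %/% resolution) + 1L
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- which(duplicated(cbind(lo, hi)))
  if (length(dup))
    stop("duplicate contact record at line ", dup[1], " of ", path, call. = FALSE)
  contact_matrix(i, j, m[, 3], chrom, resolution, n_bins)
}

#' Write a contact matrix as contact triples
#'
#' Inverse of [read_contact_triples()]: emits upper-triangle records
#' (including stored diagonal entries) as tab-separated
#' `pos_i	pos_j	value`.
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_triples <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  tm <- as(cm$mat, "TsparseMatrix")
  o <- order(tm@i, tm@j)
  dt <- data.table::data.table(
    pos_i = as.numeric(tm@i[o]) * cm$resolution,
    pos_j = as.numeric(tm@j[o]) * cm$resolution,
    value = tm@x[o]
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Bins fully inside [start, end): first bin whose left edge >= start through
# last bin whose right edge <= end (1-based indices).
.bins_inside <- function(start, end, resolution) {
  a <- ceiling(start / resolution) + 1
  b <- floor(end / resolution)
  if (b < a) integer() else as.integer(a:b)
}

# Bins overlapping [start, end)
.bins_overlapping <- function(start, end, resolution) {
  as.integer((start %/% resolution + 1):((end - 1) %/% resolution + 1))
}

#' Mean O/E contact within a domain
#'
#' Mean of the matrix over all bin pairs (i, j), i < j, with both bins fully
#' inside the domain.  Absent sparse entries count as zero; the diagonal is
#' excluded (self-bin signal is not an interaction).
#'
#' @param cm A [contact_matrix()].
#' @param start,end Domain interval in bp (0-based half-open).
#' @return Mean O/E value (numeric scalar).
#' @export
domain_contacts <- function(cm, start, end) {
  stopifnot(inherits(cm, "contact_matrix"))
  bins <- .bins_inside(start, end, cm$resolution)
  if (length(bins) < 2)
    stop("domain [", start, ", ", end, ") spans fewer than 2 bins", call. = FALSE)
  block <- cm$mat[bins, bins, drop = FALSE]  # upper triangle holds all i<j pairs
  n <- length(bins)
  (sum(block) - sum(Matrix::diag(block))) / (n * (n - 1) / 2)
}

#' Mean O/E contact at a loop
#'
#' Mean of the matrix over the rectangle (bins of anchor1) x (bins of
#' anchor2); anchors are converted to the bins they overlap.
#'
#' @param cm A [contact_matrix()].
#' @param start1,end1 Anchor 1 interval in bp (upstream anchor).
#' @param start2,end2 Anchor 2 interval in bp.
#' @return Mean O/E value over the anchor rectangle.
#' @export
loop_contacts <- function(cm, start1, end1, start2, end2) {
  stopifnot(inherits(cm, "contact_matrix"))
  b1 <- .bins_overlapping(start1, end1, cm$resolution)
  b2 <- .bins_overlapping(start2, end2, cm$resolution)
  if (max(b1) >= min(b2))
    stop("loop anchors overlap on the bin grid", call. = FALSE)
  mean(.cm_block(cm, b1, b2))
}

#' Boundary insulation score
#'
#' In a window of `ell` bins on each side of a boundary, the negative log2
#' ratio of contacts that cross the boundary to all contacts in the window:
#' `-log2((crossing + eps) / (total + eps))`.  Higher scores mean stronger
#' insulation; a uniform matrix gives `-log2(ell / (2*ell - 1))`.
#'
#' @param cm A [contact_matrix()].
#' @param boundary_bin 1-based index of the first bin to the right of the
#'   boundary.
#' @param ell Window half-width in bins (the domain length, in bins, when
#'   scoring a domain boundary).
#' @param eps Stabilizer added to numerator and denominator (default 1e-6).
#' @return Insulation score (numeric scalar).
#' @export
insulation_score <- function(cm, boundary_bin, ell, eps = 1e-6) {
  stopifnot(inherits(cm, "contact_matrix"), ell >= 1)
  lo <- boundary_bin - ell
  hi <- boundary_bin + ell - 1
  if (lo < 1 || hi > cm$n_bins)
    stop("insulation window [", lo, ", ", hi, "] outside chromosome", call. = FALSE)
  bins <- lo:hi
  block <- cm$mat[bins, bins, drop = FALSE]
  total <- sum(block) - sum(Matrix::diag(block))
  left <- lo:(boundary_bin - 1)
  right <- boundary_bin:hi
  crossing <- sum(cm$mat[left, right, drop = FALSE])
  if (eps == 0 && total == 0)
    stop("no contacts in insulation window and eps = 0", call. = FALSE)
  -log2((crossing + eps) / (total + eps))
}

#' Aggregate peak analysis
#'
#' Element-wise mean of the (2w+1) x (2w+1) O/E submatrices centered on each
#' loop's central pixel, with the peak-to-lower-left score: center value
#' divided by the mean of the corner box of size `ceiling(w/2)` at larger
#' anchor-1 coordinates and smaller anchor-2 coordinates.  Loops whose
#' window would cross the diagonal or the chromosome edge are skipped and
#' counted.
#'
#' @param cm A [contact_matrix()].
#' @param loops Loop data.frame (`chrom`, `start1`, `end1`, `start2`, `end2`)
#'   on `cm`'s chromosome.
#' @param w Window half-width in bins (default 10).
#' @return List of class `apa_result`: `aggregate` matrix, `p2ll`,
#'   `n_loops_used`, `n_skipped`.
#' @export
apa <- function(cm, loops, w = 10) {
  stopifnot(inherits(cm, "contact_matrix"), w >= 1)
  loops <- loops[loops$chrom == cm$chrom, , drop = FALSE]
  res <- cm$resolution
  ci <- as.integer(((loops$start1 + loops$end1) / 2) %/% res) + 1L
  cj <- as.integer(((loops$start2 + loops$end2) / 2) %/% res) + 1L
  ok <- ci - w >= 1 & cj + w <= cm$n_bins & (ci + w) < (cj - w)
  if (!any(ok)) stop("no loops usable for APA at w = ", w, call. = FALSE)
  size <- 2L * w + 1L
  agg <- matrix(0, size, size)
  for (k in which(ok)) {
    agg <- agg + .cm_block(cm, (ci[k] - w):(ci[k] + w), (cj[k] - w):(cj[k] + w))
  }
  agg <- agg / sum(ok)
  cw <- ceiling(w / 2)
  ll <- agg[(size - cw + 1):size, 1:cw, drop = FALSE]
  structure(list(aggregate = agg,
                 p2ll = agg[w + 1, w + 1] / mean(ll),
                 n_loops_used = sum(ok),
                 n_skipped = sum(!ok)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %d loops (%d skipped), P2LL = %.3f\n",
              x$n_loops_used, x$n_skipped, x$p2ll))
  invisible(x)
}

#' A/B compartment eigenvector
#'
#' Leading eigenvector (largest eigenvalue by magnitude) of the Pearson
#' correlation matrix of O/E rows, computed on bins with non-zero marginals.
#' The sign is oriented so that the eigenvector correlates positively with
#' per-bin H3K27ac signal; positive bins are called A, negative B.
#'
#' @param cm A [contact_matrix()] at compartment resolution (150 kb in the
#'   default pipeline).
#' @param h3k27ac_bins Numeric vector of per-bin H3K27ac signal, length
#'   `cm$n_bins`.
#' @return List of class `compartment_track`: `chrom`, `bin_size`,
#'   `eigenvalue` (length `n_bins`, NA at dropped bins), `oriented`.
#' @export
compartment_eigenvector <- function(cm, h3k27ac_bins) {
  stopifnot(inherits(cm, "contact_matrix"),
            length(h3k27ac_bins) == cm$n_bins)
  dense <- .cm_block(cm, seq_len(cm$n_bins), seq_len(cm$n_bins))
  keep <- rowSums(dense) > 0
  if (sum(keep) < 3)
    stop("fewer than 3 bins with contacts; cannot compute eigenvector",
         call. = FALSE)
  corr <- stats::cor(dense[keep, keep, drop = FALSE])
  corr[!is.finite(corr)] <- 0
  eg <- eigen(corr, symmetric = TRUE)
  lead <- which.max(abs(eg$values))
  v <- eg$vectors[, lead]
  k27 <- h3k27ac_bins[keep]
  if (stats::sd(k27) == 0)
    stop("zero-variance H3K27ac signal; cannot orient eigenvector", call. = FALSE)
  r <- suppressWarnings(stats::cor(v, k27))
  if (!is.finite(r))
    stop("cannot orient eigenvector against H3K27ac", call. = FALSE)
  if (r < 0) v <- -v
  ev <- rep(NA_real_, cm$n_bins)
  ev[keep] <- v
  structure(list(chrom = cm$chrom, bin_size = cm$resolution,
                 eigenvalue = ev, oriented = TRUE),
            class = "compartment_track")
}

#' Per-domain eigenvalue
#'
#' Mean eigenvalue of the compartment-track bins that the domain spans
#' (any overlap counts); bins dropped from the eigenvector are excluded.
#'
#' @param track A `compartment_track` from [compartment_eigenvector()].
#' @param start,end Domain interval in bp.
#' @return Mean eigenvalue, or NA when every spanned bin is missing.
#' @export
domain_eigenvalue <- function(track, start, end) {
  stopifnot(inherits(track, "compartment_track"))
  bins <- .bins_overlapping(start, end, track$bin_size)
  bins <- bins[bins >= 1 & bins <= length(track$eigenvalue)]
  vals <- track$eigenvalue[bins]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}
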