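#' @import data.table
#' @importFrom methods as is
NULL

# Interval tables throughout the package are plain data.frames in BED
# semantics: `chrom`, `start` (0-based), `end` (half-open), optionally
# `name`, `score`, `strand`.  Conversion to GRanges happens at overlap time.

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.check_intervals <- function(df, what = "interval set") {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (nrow(df) && any(df$start < 0 | df$start >= df$end))
    stop(what, " violates 0 <= start < end", call. = FALSE)
  invisible(df)
}

#' Read a BED file
#'
#' Reads 0-based half-open intervals.  Columns beyond the first three
#' (name, score, strand) are kept when present.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- .from_granges(gr)
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) df$name <- as.character(md$name)
  if ("score" %in% names(md) && !all(is.na(md$score))) df$score <- md$score
  str <- as.character(GenomicRanges::strand(gr))
  if (any(str != "*")) df$strand <- str
  df
}

#' Write a BED file
#'
#' @param df Interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  .check_intervals(df, "BED input")
  gr <- .as_granges(df)
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BEDPE loop file
#'
#' Plain 6+ column BEDPE: chrom1 start1 end1 chrom2 start2 end2
#' (optional name, score, strand1, strand2).  Only intra-chromosomal
#' records are supported; anchor1 must lie upstream of anchor2.
#'
#' @param path Path to a BEDPE file.
#' @return data.frame with `chrom`, `start1`, `end1`, `start2`, `end2`.
#' @export
read_bedpe <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0)
    return(data.frame(chrom = character(), start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer()))
  if (ncol(dt) < 6) stop("BEDPE needs at least 6 columns: ", path, call. = FALSE)
  out <- data.frame(
    chrom = as.character(dt[[1]]),
    start1 = as.integer(dt[[2]]), end1 = as.integer(dt[[3]]),
    start2 = as.integer(dt[[5]]), end2 = as.integer(dt[[6]]),
    stringsAsFactors = FALSE
  )
  if (any(as.character(dt[[4]]) != out$chrom))
    stop("inter-chromosomal BEDPE records are not supported: ", path, call. = FALSE)
  .check_loops(out)
  out
}

#' Write a BEDPE loop file
#'
#' @param loops Loop data.frame (`chrom`, `start1`, `end1`, `start2`, `end2`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  .check_loops(loops)
  dt <- data.table::data.table(
    loops$chrom, loops$start1, loops$end1,
    loops$chrom, loops$start2, loops$end2,
    if ("name" %in% names(loops)) loops$name else
      sprintf("loop_%d", seq_len(nrow(loops))),
    ".", ".", "."
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_loops <- function(loops) {
  req <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(req %in% names(loops)))
    stop("loops must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(loops) && any(loops$end1 > loops$start2))
    stop("loop anchor1 must end at or before anchor2 starts", call. = FALSE)
  invisible(loops)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph (values in rpm).
#' @return A `signal_track` object.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE
  ))
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  seg <- track$segments
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1L, seg$end),
                               score = seg$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read gene annotation from GTF
#'
#' Keeps `gene` features (or, when a file carries no gene features, all
#' records), converting 1-based inclusive GTF coordinates to 0-based
#' half-open.
#'
#' @param path Path to a GTF file with `gene_id` and `gene_biotype`
#'   attributes.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `gene_biotype`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    gene_biotype = as.character(gr$gene_biotype),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotation as GTF
#'
#' @param genes data.frame with `chrom`, `start` (0-based), `end`, `strand`,
#'   `gene_id`, `gene_biotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  req <- c("chrom", "start", "end", "strand", "gene_id", "gene_biotype")
  stopifnot(all(req %in% names(genes)))
  lines <- sprintf(
    "%s\tdomainweaver\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_biotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table
#'
#' Derives transcription start sites from gene annotation: start of
#' plus-strand genes, end of minus-strand genes, as 0-based positions.
#'
#' @param genes Gene data.frame as returned by [read_gtf()].
#' @return data.frame with `chrom`, `pos` (0-based bp), `gene_id`.
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  data.frame(chrom = genes$chrom, pos = as.integer(pos),
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}
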