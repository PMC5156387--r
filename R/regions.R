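#' Genomic regions (0-based, half-open)
#'
#' Internally all region arithmetic uses 0-based half-open intervals, the
#' BED convention; VCF positions and site tables are 1-based and are
#' converted only at I/O boundaries.
#'
#' @param chrom chromosome names.
#' @param start 0-based start (inclusive).
#' @param end 0-based end (exclusive); must exceed \code{start}.
#' @param label free-text labels.
#' @return data.frame of class \code{region_set}, sorted by (chrom, start).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = NULL) {
  n <- length(chrom)
  if (is.null(label)) label <- rep("", n)
  stopifnot(length(start) == n, length(end) == n, length(label) == n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("region start must be >= 0")
  if (any(end <= start)) stop("region end must be > start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Locus window around an index variant
#'
#' A priority locus spans a fixed flank on each side of the index SNP
#' position (default 100 kb up- and downstream, 200 kb total), clipped at
#' the chromosome start.
#'
#' @param chrom chromosome of the index variant.
#' @param index_pos 1-based index SNP position.
#' @param flank_bp flank size in bp on each side.
#' @param label region label (defaults to the position).
#' @return single-row \code{region_set} covering all 1-based positions
#'   \code{p} with \code{|p - index_pos| <= flank_bp}.
#' @export
locus_window <- function(chrom, index_pos, flank_bp = 100000L, label = NULL) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  if (index_pos < 1) stop("index_pos must be >= 1")
  if (is.null(label)) label <- paste0(chrom, ":", index_pos)
  start0 <- max(0, index_pos - 1 - flank_bp)
  end0 <- index_pos + flank_bp           # half-open: covers pos+flank (1-based)
  region_set(chrom, start0, end0, label)
}

#' Gene region from transcript coordinates
#'
#' The gene interval is the span of the union of its reported transcripts
#' (min start to max end), extended by a flank (default 50 kb) on each
#' side and clipped at 0.
#'
#' @param chrom chromosome.
#' @param starts,ends 0-based half-open transcript coordinates (equal
#'   length, at least one transcript).
#' @param flank_bp flank in bp.
#' @param label gene name.
#' @return single-row \code{region_set}.
#' @export
gene_region <- function(chrom, starts, ends, flank_bp = 50000L,
                        label = "gene") {
  if (length(starts) == 0) stop("at least one transcript required")
  stopifnot(length(starts) == length(ends), flank_bp >= 0)
  region_set(chrom, max(0, min(starts) - flank_bp), max(ends) + flank_bp,
             label)
}

#' Merge overlapping and touching regions
#'
#' Returns the minimal sorted set of disjoint intervals with the same
#' union; touching intervals (\code{[a,b)}, \code{[b,c)}) are merged.
#' Labels of merged members are joined with ",".
#'
#' @param regions a \code{region_set} (or data.frame with chrom/start/end).
#' @return merged \code{region_set} with attribute \code{covered_bp}, the
#'   total number of covered bases.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) {
    out <- region_set()
    attr(out, "covered_bp") <- 0
    return(out)
  }
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1, end = regions$end))
  red <- GenomicRanges::reduce(gr)   # merges overlapping + adjacent
  ov <- GenomicRanges::findOverlaps(red, gr)
  lab <- if (!is.null(regions$label)) {
    vapply(split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov)),
           function(i) paste(unique(regions$label[i]), collapse = ","),
           character(1))
  } else rep("", length(red))
  out <- region_set(as.character(GenomicRanges::seqnames(red)),
                    GenomicRanges::start(red) - 1,
                    GenomicRanges::end(red),
                    lab)
  attr(out, "covered_bp") <- sum(out$end - out$start)
  out
}

#' Clip regions at chromosome ends
#'
#' Left clipping (at 0) is always applied by the constructors; right
#' clipping needs to know the chromosome sizes, so it is applied only
#' when a sizes table is supplied.  Regions on chromosomes absent from
#' the table are left untouched; regions entirely beyond the end are
#' dropped.
#'
#' @param regions a \code{\link{region_set}}.
#' @param chrom_sizes data.frame with columns \code{chrom}, \code{size}.
#' @return clipped \code{region_set}.
#' @export
clip_regions <- function(regions, chrom_sizes) {
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  sz <- chrom_sizes$size[match(regions$chrom, chrom_sizes$chrom)]
  lim <- ifelse(is.na(sz), regions$end, sz)
  keep <- regions$start < lim
  regions <- regions[keep, , drop = FALSE]
  regions$end <- pmin(regions$end, lim[keep])
  class(regions) <- c("region_set", "data.frame")
  regions
}

#' Which 1-based positions fall inside a region set
#'
#' @param regions a \code{region_set}.
#' @param chrom,pos vectors of chromosome and 1-based position.
#' @return logical vector.
#' @export
in_regions <- function(regions, chrom, pos) {
  if (nrow(regions) == 0) return(rep(FALSE, length(pos)))
  res <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    res <- res | (chrom == regions$chrom[i] &
                    pos - 1 >= regions$start[i] & pos - 1 < regions$end[i])
  }
  res
}
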