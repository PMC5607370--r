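#' 5'-end coverage container
#'
#' Per-position, per-strand counts of read 5' ends for one sequencing
#' library. Both strand vectors have length equal to the genome length.
#'
#' @param plus,minus Non-negative integer count vectors of equal length.
#' @param label Library label (e.g. `"deplete_12h_enriched"`).
#' @param condition `"replete"` or `"deplete"` (optional).
#' @param timepoint_h Time point in hours (optional).
#' @return An object of class `five_prime_coverage`.
#' @export
five_prime_coverage <- function(plus, minus, label = "library",
                                condition = NA_character_,
                                timepoint_h = NA_real_) {
  plus <- as.integer(plus)
  minus <- as.integer(minus)
  if (length(plus) != length(minus)) {
    stop("plus and minus strand vectors must have equal length")
  }
  if (any(plus < 0L) || any(minus < 0L)) stop("counts must be non-negative")
  structure(list(plus = plus, minus = minus, label = label,
                 condition = condition, timepoint_h = timepoint_h),
            class = "five_prime_coverage")
}

#' @export
print.five_prime_coverage <- function(x, ...) {
  cat("<five_prime_coverage>", x$label, ":", length(x$plus), "bp,",
      sum(x$plus) + sum(x$minus), "5' ends\n")
  invisible(x)
}

#' Total 5'-end count of a library (both strands)
#' @param coverage A `five_prime_coverage`.
#' @return Integer total.
#' @export
library_depth <- function(coverage) {
  sum(as.numeric(coverage$plus)) + sum(as.numeric(coverage$minus))
}

strand_counts <- function(coverage, strand) {
  if (strand == "+") coverage$plus else coverage$minus
}

#' Write one strand of a coverage track as bedGraph
#'
#' Intervals are maximal runs of equal nonzero count (zero-count runs are
#' omitted, per common bedGraph practice), 0-based half-open.
#'
#' @param counts Integer vector of per-position counts.
#' @param path Output path.
#' @param chrom Chromosome name used in the track (default `"genome"`).
#' @export
write_bedgraph <- function(counts, path, chrom = "genome") {
  r <- rle(as.integer(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

read_bedgraph_counts <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  counts <- integer(genome_length)
  if (length(gr) > 0L) {
    st <- GenomicRanges::start(gr)
    en <- GenomicRanges::end(gr)
    sc <- as.integer(gr$score)
    for (i in seq_along(gr)) counts[st[i]:en[i]] <- sc[i]
  }
  counts
}

#' Load a 5'-end coverage library from a pair of bedGraph files
#'
#' @param plus_path,minus_path bedGraph paths for the two strands.
#' @param genome_length Genome length (positions absent from the bedGraph get
#'   count 0).
#' @param label,condition,timepoint_h Library metadata.
#' @return A `five_prime_coverage`.
#' @export
load_coverage <- function(plus_path, minus_path, genome_length,
                          label = "library", condition = NA_character_,
                          timepoint_h = NA_real_) {
  for (p in c(plus_path, minus_path)) {
    if (!file.exists(p)) stop("bedGraph not found: ", p)
  }
  five_prime_coverage(
    plus = read_bedgraph_counts(plus_path, genome_length),
    minus = read_bedgraph_counts(minus_path, genome_length),
    label = label, condition = condition, timepoint_h = timepoint_h
  )
}

#' Write a coverage library as a bedGraph pair
#'
#' @param coverage A `five_prime_coverage`.
#' @param dir Output directory.
#' @param prefix File prefix; files are `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @return Named character vector of the two paths.
#' @export
write_coverage <- function(coverage, dir, prefix = coverage$label) {
  pp <- file.path(dir, paste0(prefix, ".plus.bedgraph"))
  mp <- file.path(dir, paste0(prefix, ".minus.bedgraph"))
  write_bedgraph(coverage$plus, pp)
  write_bedgraph(coverage$minus, mp)
  c(plus = pp, minus = mp)
}
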