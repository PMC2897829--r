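# Internal coordinate convention: 0-based half-open [start, end).
# External tab-delimited formats (SEG, DGV dumps) are 1-based inclusive;
# BED is already 0-based half-open.

#' Convert 1-based inclusive coordinates to the internal convention
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return list with components `start`, `end` in 0-based half-open form.
#' @keywords internal
to_internal <- function(start, end) {
  list(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#' @keywords internal
to_external <- function(start, end) {
  list(start = as.numeric(start) + 1, end = as.numeric(end))
}

#' Normalize chromosome names
#'
#' Strips any leading "chr" prefix and upper-cases X/Y so that "chrX", "x"
#' and "X" refer to the same chromosome.
#' @param chrom character vector.
#' @return normalized character vector.
#' @keywords internal
norm_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x[x %in% c("x", "y")] <- toupper(x[x %in% c("x", "y")])
  x
}

is_sex_chrom <- function(chrom) norm_chrom(chrom) %in% c("X", "Y")

#' Overlap hits between two sets of half-open intervals
#'
#' Thin wrapper over [IRanges::findOverlaps()] taking internal 0-based
#' half-open intervals. Zero-width intervals never overlap anything.
#'
#' @param q_start,q_end,s_start,s_end numeric vectors (query and subject).
#' @return two-column integer matrix of (query index, subject index) hits.
#' @keywords internal
interval_hits <- function(q_start, q_end, s_start, s_end) {
  if (length(q_start) == 0L || length(s_start) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("query", "subject"))))
  }
  q <- IRanges::IRanges(start = as.integer(q_start) + 1L, end = as.integer(q_end))
  s <- IRanges::IRanges(start = as.integer(s_start) + 1L, end = as.integer(s_end))
  h <- IRanges::findOverlaps(q, s, minoverlap = 1L)
  cbind(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Does each query interval overlap any subject interval on the same chromosome?
#' @keywords internal
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- logical(length(q_start))
  if (length(s_start) == 0L || length(q_start) == 0L) return(out)
  q_chrom <- norm_chrom(q_chrom); s_chrom <- norm_chrom(s_chrom)
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch); si <- which(s_chrom == ch)
    if (length(si) == 0L) next
    h <- interval_hits(q_start[qi], q_end[qi], s_start[si], s_end[si])
    out[qi[unique(h[, "query"])]] <- TRUE
  }
  out
}

#' Indices of probes falling in a half-open interval
#'
#' Probe positions are points; a probe at `pos` lies in `[start, end)`
#' iff `pos >= start` and `pos < end`.
#' @keywords internal
probes_in_interval <- function(pos, start, end) {
  which(pos >= start & pos < end)
}
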