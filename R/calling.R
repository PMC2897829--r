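# Gain/loss calling, run merging and candidate extraction.
#
# A segment is called a gain (loss) when its mean log-ratio lies at least
# one unscaled MAD above (below) the array median; candidates are the
# called gains/losses of span <= 2.3 Mb flanked by at least one normal
# segment, outside chromosomes X/Y and outside physiological regions.

CANDIDATE_LENGTH_CAP <- 2.3e6

#' Robust noise statistics for one array
#'
#' `array_median` and `array_mad` are the median and the unscaled median
#' absolute deviation of all probe log-ratios; `residual_mad` is the
#' unscaled MAD of probe log-ratios about their segment means. No
#' normal-consistency factor (1.4826) is applied anywhere.
#'
#' @param profile probe profile (`data.frame` with `chrom`, `pos`, `lr`).
#' @param segments the sample's segments (internal coordinates).
#' @param strict error (TRUE) or warn (FALSE, default) when a probe falls
#'   on no segment; unassigned probes are excluded from `residual_mad`.
#' @return list with `sample_id`, `array_median`, `array_mad`, `residual_mad`.
#' @export
compute_array_stats <- function(profile, segments, strict = FALSE) {
  if (nrow(profile) == 0) stop("empty profile")
  med <- stats::median(profile$lr)
  amad <- stats::median(abs(profile$lr - med))
  resid <- rep(NA_real_, nrow(profile))
  for (i in seq_len(nrow(segments))) {
    idx <- which(profile$chrom == segments$chrom[i] &
                 profile$pos >= segments$start[i] &
                 profile$pos < segments$end[i])
    resid[idx] <- profile$lr[idx] - segments$mean[i]
  }
  if (anyNA(resid)) {
    msg <- sprintf("%d probes fall on no segment", sum(is.na(resid)))
    if (strict) stop(msg) else warning(msg)
  }
  list(sample_id = attr(profile, "sample_id"),
       array_median = med, array_mad = amad,
       residual_mad = stats::median(abs(resid), na.rm = TRUE))
}

#' Call each segment gain, loss or normal
#'
#' Boundary values are calls: a mean exactly one MAD from the median is a
#' gain/loss. With `array_mad == 0` every nonzero-mean segment is called
#' and a warning notes the degenerate noise level.
#'
#' @param segments segment data.frame.
#' @param stats result of [compute_array_stats()] for the same sample.
#' @return the segments with a `status` column in {"gain","loss","normal"}.
#' @export
call_segments <- function(segments, stats) {
  if (stats$array_mad == 0 && any(segments$mean != stats$array_median)) {
    warning("array MAD is 0: every segment off the median is called")
  }
  status <- rep("normal", nrow(segments))
  status[segments$mean >= stats$array_median + stats$array_mad] <- "gain"
  status[segments$mean <= stats$array_median - stats$array_mad] <- "loss"
  segments$status <- status
  if (is.null(segments$merged_from)) segments$merged_from <- 1L
  segments
}

#' Merge consecutive same-status gain or loss runs under the length cap
#'
#' Maximal runs of adjacent gains (or losses) whose combined span is
#' strictly under 2.3 Mb collapse into one segment whose mean is the
#' marker-count-weighted mean of the members; runs at or over the cap are
#' left as-is. Idempotent.
#'
#' @param called output of [call_segments()], ordered within chromosome.
#' @param cap combined-span cap in bp (default 2.3 Mb).
#' @return merged segment data.frame with `merged_from` counts.
#' @export
merge_candidate_runs <- function(called, cap = CANDIDATE_LENGTH_CAP) {
  if (nrow(called) == 0) return(called)
  if (is.null(called$merged_from)) called$merged_from <- 1L
  out <- list()
  for (ch in unique(called$chrom)) {
    d <- called[called$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    run_id <- cumsum(c(TRUE, d$status[-1] != d$status[-nrow(d)]))
    for (r in unique(run_id)) {
      m <- d[run_id == r, , drop = FALSE]
      span <- max(m$end) - min(m$start)
      if (m$status[1] %in% c("gain", "loss") && nrow(m) > 1 && span < cap) {
        merged <- m[1, , drop = FALSE]
        merged$start <- min(m$start); merged$end <- max(m$end)
        merged$n_markers <- sum(m$n_markers)
        merged$mean <- sum(m$mean * m$n_markers) / sum(m$n_markers)
        merged$merged_from <- sum(m$merged_from)
        out[[length(out) + 1]] <- merged
      } else {
        out[[length(out) + 1]] <- m
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract candidate CNVs from called (and merged) segments
#'
#' A candidate is a gain or loss of genomic span at most 2.3 Mb with a
#' normal segment on at least one side. Chromosome edges do not count as
#' normal flanks. Chromosomes X and Y are excluded, as is any segment
#' intersecting a physiological region by one or more bases. No
#' minimum-length filter is applied.
#'
#' @param called merged, called segments of one sample.
#' @param annotation annotation object ([make_annotation()]); used for the
#'   physiological exclusion list. May be NULL (no exclusions).
#' @param cap admission cap in bp, inclusive (default 2.3 Mb).
#' @return data.frame of candidates with `left_flank`/`right_flank` status
#'   columns ("gain","loss","normal","chromosome_edge") and `merged_from`.
#' @export
extract_candidates <- function(called, annotation = NULL,
                               cap = CANDIDATE_LENGTH_CAP) {
  rows <- list()
  for (ch in unique(called$chrom)) {
    if (is_sex_chrom(ch)) next
    d <- called[called$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    for (i in seq_len(n)) {
      if (!(d$status[i] %in% c("gain", "loss"))) next
      if (d$end[i] - d$start[i] > cap) next
      lf <- if (i == 1) "chromosome_edge" else d$status[i - 1]
      rf <- if (i == n) "chromosome_edge" else d$status[i + 1]
      if (lf != "normal" && rf != "normal") next
      cand <- d[i, , drop = FALSE]
      cand$left_flank <- lf
      cand$right_flank <- rf
      rows[[length(rows) + 1]] <- cand
    }
  }
  if (length(rows) == 0) return(empty_candidates())
  out <- do.call(rbind, rows)
  if (!is.null(annotation) && nrow(annotation$physiological) > 0) {
    hit <- overlaps_any(out$chrom, out$start, out$end,
                        annotation$physiological$chrom,
                        annotation$physiological$start,
                        annotation$physiological$end)
    out <- out[!hit, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(sample = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), n_markers = integer(0), mean = numeric(0),
             status = character(0), merged_from = integer(0),
             left_flank = character(0), right_flank = character(0),
             stringsAsFactors = FALSE)
}

#' Run calling, merging and candidate extraction for one sample
#'
#' @param profile probe profile.
#' @param segments raw segments for the sample.
#' @param annotation annotation object or NULL.
#' @return list with `profile`, `stats`, `called` (merged called
#'   segments) and `candidates`.
#' @export
call_sample <- function(profile, segments, annotation = NULL) {
  stats <- compute_array_stats(profile, segments)
  called <- call_segments(segments, stats)
  merged <- merge_candidate_runs(called)
  cands <- extract_candidates(merged, annotation)
  list(profile = profile, stats = stats, called = merged, candidates = cands)
}
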