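# Paired-normal truth labeling: a candidate is a true (germline) CNV if
# it overlaps a same-sign called gain/loss in the matched normal sample,
# or if the normal-sample probe means under the candidate are significant
# by the conditional segmentation permutation test. Otherwise it is a CNA.

#' Does a candidate overlap a same-sign aberration in the normal sample?
#'
#' Any >= 1 bp intersection with a normal-sample segment called gain or
#' loss with the same sign as the candidate counts; breakpoints need not
#' match.
#'
#' @param candidate one-row candidate data.frame.
#' @param normal_called called segments of the paired normal sample.
#' @return logical scalar.
#' @export
match_to_normal <- function(candidate, normal_called) {
  d <- normal_called[normal_called$status == candidate$status &
                     normal_called$chrom == candidate$chrom, , drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  any(d$start < candidate$end & d$end > candidate$start)
}

#' Conditional segmentation permutation test
#'
#' Tests whether the normal-sample log-ratios under a tumor candidate are
#' extreme relative to a locally drawn null. Let k be the number of normal
#' probes in the candidate interval and mu their mean. The null pool is
#' the normal log-ratios over the candidate plus its immediate left and
#' right tumor segments (whichever exist). R draws of size k are taken
#' from the pool without replacement; `p_extreme` is the fraction of draws
#' whose mean is at least as extreme as mu in the candidate's direction
#' (ties count as extreme). The candidate is declared a CNV when mu passes
#' the gain/loss threshold of the normal array (|mu - median| >= MAD, in
#' the candidate's direction) and `p_extreme < alpha`.
#'
#' @param candidate one-row candidate data.frame (tumor coordinates).
#' @param tumor_called the tumor sample's called segments (to locate the
#'   candidate's neighboring tumor segments).
#' @param normal_profile the paired normal probe profile.
#' @param normal_stats [compute_array_stats()] of the normal sample.
#' @param R number of permutation draws (default 1000).
#' @param alpha significance level (default 0.01).
#' @param rng_seed integer seed; the test is reproducible given it.
#' @return list with `k`, `mu`, `R`, `p_extreme`, `threshold_pass`,
#'   `declared`.
#' @export
conditional_segmentation_test <- function(candidate, tumor_called,
                                          normal_profile, normal_stats,
                                          R = 1000, alpha = 0.01,
                                          rng_seed = 1L) {
  ch <- candidate$chrom
  np <- normal_profile[normal_profile$chrom == ch, , drop = FALSE]
  in_cand <- probes_in_interval(np$pos, candidate$start, candidate$end)
  k <- length(in_cand)
  if (k == 0) stop("candidate covers no probes in the normal profile")
  mu <- mean(np$lr[in_cand])

  d <- tumor_called[tumor_called$chrom == ch, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  i <- which(d$start <= candidate$start & d$end >= candidate$end)
  if (length(i) == 0) {
    # candidate not found among tumor segments (e.g. free-standing interval):
    # fall back to the candidate interval itself as the pool window
    win_start <- candidate$start; win_end <- candidate$end
  } else {
    i <- i[1]
    win_start <- if (i > 1) d$start[i - 1] else d$start[i]
    win_end <- if (i < nrow(d)) d$end[i + 1] else d$end[i]
  }
  pool <- np$lr[probes_in_interval(np$pos, win_start, win_end)]
  if (length(pool) < k) stop("pool smaller than candidate probe count")

  s <- if (candidate$status == "gain") 1 else -1
  mu_star <- with_seed(rng_seed, {
    vapply(seq_len(R), function(j) mean(sample(pool, k, replace = FALSE)),
           numeric(1))
  })
  p_extreme <- mean(s * mu_star >= s * mu)
  threshold_pass <- s * (mu - normal_stats$array_median) >= normal_stats$array_mad
  list(k = k, mu = mu, R = R, p_extreme = p_extreme,
       threshold_pass = threshold_pass,
       declared = threshold_pass && p_extreme < alpha)
}

#' Evaluate an RNG expression under a local seed without disturbing the
#' caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic per-candidate seed derived from a base seed
#'
#' Mixes the base seed with the candidate's sample, chromosome and start
#' so relabeling is order-independent. Result is in [0, 2^31).
#' @keywords internal
candidate_seed <- function(rng_seed, sample_id, chrom, start) {
  key <- paste(sample_id, chrom, start, sep = ":")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((as.numeric(rng_seed) * 7919 + h) %% 2147483647)
}

#' Label candidates CNV or CNA from the paired normal sample
#'
#' Segment-overlap evidence short-circuits the permutation test.
#'
#' @param candidates candidate data.frame (possibly several, one sample).
#' @param tumor_called the tumor sample's called segments.
#' @param normal_profile,normal_called,normal_stats paired normal data.
#' @param R,alpha permutation test parameters.
#' @param rng_seed base seed; per-candidate streams derived from it.
#' @return data.frame with columns `label` ("CNV"/"CNA") and `evidence`
#'   ("segment_overlap", "permutation", "none"), one row per candidate.
#' @export
label_candidates <- function(candidates, tumor_called, normal_profile,
                             normal_called, normal_stats,
                             R = 1000, alpha = 0.01, rng_seed = 1L) {
  n <- nrow(candidates)
  label <- character(n); evidence <- character(n)
  for (i in seq_len(n)) {
    cand <- candidates[i, , drop = FALSE]
    if (match_to_normal(cand, normal_called)) {
      label[i] <- "CNV"; evidence[i] <- "segment_overlap"
    } else {
      seed_i <- candidate_seed(rng_seed, cand$sample, cand$chrom, cand$start)
      res <- conditional_segmentation_test(cand, tumor_called, normal_profile,
                                           normal_stats, R = R, alpha = alpha,
                                           rng_seed = seed_i)
      if (res$declared) {
        label[i] <- "CNV"; evidence[i] <- "permutation"
      } else {
        label[i] <- "CNA"; evidence[i] <- "none"
      }
    }
  }
  data.frame(label = label, evidence = evidence, stringsAsFactors = FALSE)
}
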