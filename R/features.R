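# The 16 Table-1 style predictors plus the two Database scores.
#
# Feature column order is fixed; see feature_columns(). Percentages are
# stored as fractions in [0,1]; published percentage thresholds are
# expressed on the same scale.

CENTROMERE_WINDOW <- 2e6
TELOMERE_WINDOW <- 2e6
PROXIMITY_WINDOW <- 5e5

#' Fixed feature-column order of the feature matrix
#' @export
feature_columns <- function() {
  c("length_bp", "segmental_duplication", "near_centromere", "near_telomere",
    "sign", "height", "relative_height", "break_score",
    "surrounded_by_normals", "overlap_pattern", "overlap_pct",
    "matching_bkpt_pct", "close_to_other_candidates", "pct_normal",
    "ds_other_candidates", "overlap_with_cnas",
    "database_score", "database_score_ii")
}

#' Per-probe counts of overlapping catalogue variants and individuals
#'
#' For every probe, counts the distinct variation ids whose interval
#' contains the probe position (half-open containment) and sums their
#' reported individual counts (records lacking the count contribute 0).
#'
#' @param dgv variant table from [read_dgv()] or [generate_dgv()].
#' @param probes probe profile (`chrom`, `pos`).
#' @return data.frame `chrom`, `pos`, `n_variants`, `n_individuals`
#'   aligned with `probes`.
#' @export
probe_variant_counts <- function(dgv, probes) {
  nv <- integer(nrow(probes))
  ni <- numeric(nrow(probes))
  ind <- ifelse(is.na(dgv$n_individuals), 0, dgv$n_individuals)
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    di <- which(dgv$chrom == ch)
    if (length(di) == 0) next
    h <- interval_hits(probes$pos[pi], probes$pos[pi] + 1,
                       dgv$start[di], dgv$end[di])
    if (nrow(h) == 0) next
    tab <- tapply(rep(1L, nrow(h)), h[, "query"], sum)
    nv[pi[as.integer(names(tab))]] <- as.integer(tab)
    itab <- tapply(ind[di][h[, "subject"]], h[, "query"], sum)
    ni[pi[as.integer(names(itab))]] <- as.numeric(itab)
  }
  data.frame(chrom = probes$chrom, pos = probes$pos,
             n_variants = nv, n_individuals = ni, stringsAsFactors = FALSE)
}

cand_probe_idx <- function(candidate, counts) {
  idx <- which(counts$chrom == candidate$chrom)
  idx[probes_in_interval(counts$pos[idx], candidate$start, candidate$end)]
}

#' Database score: mean variant count over the candidate's probes
#' @param candidate one-row candidate data.frame.
#' @param counts result of [probe_variant_counts()] on the same probe grid.
#' @export
database_score <- function(candidate, counts) {
  idx <- cand_probe_idx(candidate, counts)
  if (length(idx) == 0) stop("candidate covers no probes")
  mean(counts$n_variants[idx])
}

#' Database score II: mean individual count over the candidate's probes
#' @inheritParams database_score
#' @export
database_score_ii <- function(candidate, counts) {
  idx <- cand_probe_idx(candidate, counts)
  if (length(idx) == 0) stop("candidate covers no probes")
  mean(counts$n_individuals[idx])
}

point_interval_dist <- function(p, s, e) {
  ifelse(p < s, s - p, ifelse(p > e, p - e, 0))
}

#' Demographic features of a candidate
#'
#' Length in bases; segmental-duplication overlap; closeness to the
#' centromere/telomere (either endpoint within 2 Mb); sign; height and
#' relative height (|mean| and |mean| / residual MAD); break score
#' (|left-neighbor mean - right-neighbor mean| / residual MAD, 0 at a
#' chromosome edge); whether both flanks are normal.
#'
#' @param candidate one-row candidate data.frame.
#' @param called the sample's called segments.
#' @param stats [compute_array_stats()] result for the sample.
#' @param annotation annotation object with chromosome lengths,
#'   centromeres and segmental duplications.
#' @return one-row data.frame of the demographic columns.
#' @export
demographic_features <- function(candidate, called, stats, annotation) {
  ch <- candidate$chrom
  segdup <- 0L
  sd <- annotation$segdups
  if (nrow(sd) > 0 &&
      any(sd$chrom == ch & sd$start < candidate$end & sd$end > candidate$start)) {
    segdup <- 1L
  }
  cen <- annotation$centromeres
  near_cen <- 0L
  ci <- which(cen$chrom == ch)
  if (length(ci)) {
    dmin <- min(vapply(ci, function(j) {
      min(point_interval_dist(c(candidate$start, candidate$end),
                              cen$start[j], cen$end[j]))
    }, numeric(1)))
    near_cen <- as.integer(dmin <= CENTROMERE_WINDOW)
  }
  clen <- annotation$chrom_lengths[[ch]]
  near_tel <- 0L
  if (!is.null(clen)) {
    near_tel <- as.integer(min(candidate$start, candidate$end) <= TELOMERE_WINDOW ||
                           max(candidate$start, candidate$end) >= clen - TELOMERE_WINDOW)
  }
  d <- called[called$chrom == ch, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  i <- which(d$start == candidate$start & d$end == candidate$end)
  brk <- 0
  if (length(i) == 1 && i > 1 && i < nrow(d) && stats$residual_mad > 0) {
    brk <- abs(d$mean[i - 1] - d$mean[i + 1]) / stats$residual_mad
  } else if (length(i) == 1 && i > 1 && i < nrow(d) && stats$residual_mad == 0) {
    brk <- 0
  }
  height <- abs(candidate$mean)
  rel_h <- if (stats$residual_mad > 0) height / stats$residual_mad else 0
  data.frame(
    length_bp = candidate$end - candidate$start,
    segmental_duplication = segdup,
    near_centromere = near_cen,
    near_telomere = near_tel,
    sign = if (candidate$status == "gain") 1L else -1L,
    height = height,
    relative_height = rel_h,
    break_score = brk,
    surrounded_by_normals = as.integer(candidate$left_flank == "normal" &&
                                       candidate$right_flank == "normal"))
}

#' Cohort-derived features of a candidate
#'
#' Overlap pattern (GG/LL/GL/None) and fraction of other patients with an
#' intersecting candidate; fraction with an exactly matching breakpoint;
#' number of other patients with a same-sign non-candidate gain/loss
#' overlapping the interval. GL requires mixed signs from at least two
#' distinct other patients; a single mixed-sign patient falls back to the
#' majority sign (ties resolve to the candidate's own sign).
#'
#' @param candidate one-row candidate data.frame.
#' @param other_candidates data.frame of candidates from the *other*
#'   patients of the cohort (column `sample` distinguishes them).
#' @param other_noncandidates data.frame of called gain/loss segments of
#'   other patients that failed candidacy.
#' @param n_other_patients total number of other patients in the cohort.
#' @return one-row data.frame of the cohort columns.
#' @export
cohort_features <- function(candidate, other_candidates, other_noncandidates,
                            n_other_patients) {
  if (n_other_patients == 0) {
    return(data.frame(overlap_pattern = "None", overlap_pct = 0,
                      matching_bkpt_pct = 0, overlap_with_cnas = 0L,
                      stringsAsFactors = FALSE))
  }
  oc <- other_candidates
  ov <- oc[oc$chrom == candidate$chrom &
           oc$start < candidate$end & oc$end > candidate$start, , drop = FALSE]
  overlap_pct <- length(unique(ov$sample)) / n_other_patients
  if (nrow(ov) == 0) {
    pattern <- "None"
  } else {
    signs <- unique(ov$status)
    if (length(signs) == 1) {
      pattern <- if (signs == "gain") "GG" else "LL"
    } else if (length(unique(ov$sample)) >= 2) {
      pattern <- "GL"
    } else {
      ng <- sum(ov$status == "gain"); nl <- sum(ov$status == "loss")
      pattern <- if (ng > nl) "GG" else if (nl > ng) "LL" else
        if (candidate$status == "gain") "GG" else "LL"
    }
  }
  bk <- oc[oc$chrom == candidate$chrom &
           (oc$start == candidate$start | oc$start == candidate$end |
            oc$end == candidate$start | oc$end == candidate$end), , drop = FALSE]
  matching_bkpt_pct <- length(unique(bk$sample)) / n_other_patients
  nc <- other_noncandidates
  nco <- nc[nc$chrom == candidate$chrom & nc$status == candidate$status &
            nc$start < candidate$end & nc$end > candidate$start, , drop = FALSE]
  data.frame(overlap_pattern = pattern, overlap_pct = overlap_pct,
             matching_bkpt_pct = matching_bkpt_pct,
             overlap_with_cnas = length(unique(nco$sample)),
             stringsAsFactors = FALSE)
}

#' Spatial (same-chromosome) features of a candidate
#'
#' Nearby-candidate indicator (another same-patient candidate within
#' 500 kb edge-to-edge on the chromosome); fraction of the chromosome's
#' markers lying in normal-status segments; mean Database score of the
#' patient's other candidates on the chromosome (0 when there are none).
#'
#' @param candidate one-row candidate data.frame.
#' @param same_patient_candidates all candidates of the same patient.
#' @param called the patient's called segments.
#' @param candidate_scores numeric vector of Database scores aligned with
#'   `same_patient_candidates` rows.
#' @return one-row data.frame of the spatial columns.
#' @export
spatial_features <- function(candidate, same_patient_candidates, called,
                             candidate_scores) {
  sp <- same_patient_candidates
  others <- which(sp$chrom == candidate$chrom &
                  !(sp$start == candidate$start & sp$end == candidate$end))
  close <- 0L
  if (length(others)) {
    gap <- pmax(sp$start[others], candidate$start) -
           pmin(sp$end[others], candidate$end)
    close <- as.integer(any(gap <= PROXIMITY_WINDOW))
  }
  d <- called[called$chrom == candidate$chrom, , drop = FALSE]
  total <- sum(d$n_markers)
  pct_normal <- if (total > 0) sum(d$n_markers[d$status == "normal"]) / total else 0
  dsoc <- if (length(others)) mean(candidate_scores[others]) else 0
  data.frame(close_to_other_candidates = close, pct_normal = pct_normal,
             ds_other_candidates = dsoc)
}

#' Assemble the full feature matrix for a cohort
#'
#' @param cohort named list (one element per patient) of lists with
#'   components `profile`, `called`, `candidates`, `stats` as produced by
#'   [call_sample()].
#' @param dgv variant table.
#' @param annotation annotation object.
#' @return data.frame with key columns `sample`, `chrom`, `start`, `end`,
#'   `status` followed by [feature_columns()], one row per candidate, in
#'   patient order. No missing values.
#' @export
build_feature_matrix <- function(cohort, dgv, annotation) {
  samples <- names(cohort)
  if (length(samples) == 1) {
    warning("cohort of one patient: cohort-derived features are zero/None")
  }
  # probe->variant counts per distinct probe grid (shared grids computed once)
  counts_cache <- list()
  counts_for <- function(profile) {
    key <- paste(length(profile$pos), sum(profile$pos), collapse = ":")
    if (is.null(counts_cache[[key]])) {
      counts_cache[[key]] <<- probe_variant_counts(dgv, profile)
    }
    counts_cache[[key]]
  }
  all_cands <- do.call(rbind, lapply(samples, function(s) {
    d <- cohort[[s]]$candidates
    if (nrow(d) == 0) return(NULL)
    d$.patient <- s
    d
  }))
  if (is.null(all_cands)) {
    all_cands <- cbind(empty_candidates(), .patient = character(0))
  }
  noncand_by_sample <- lapply(samples, function(s) {
    cl <- cohort[[s]]$called
    gl <- cl[cl$status %in% c("gain", "loss"), , drop = FALSE]
    cd <- cohort[[s]]$candidates
    key_gl <- paste(gl$chrom, gl$start, gl$end)
    key_cd <- paste(cd$chrom, cd$start, cd$end)
    gl[!(key_gl %in% key_cd), , drop = FALSE]
  })
  names(noncand_by_sample) <- samples
  rows <- list()
  for (s in samples) {
    entry <- cohort[[s]]
    cands <- entry$candidates
    if (nrow(cands) == 0) next
    counts <- counts_for(entry$profile)
    scores <- vapply(seq_len(nrow(cands)), function(i)
      database_score(cands[i, , drop = FALSE], counts), numeric(1))
    scores2 <- vapply(seq_len(nrow(cands)), function(i)
      database_score_ii(cands[i, , drop = FALSE], counts), numeric(1))
    other_cands <- all_cands[all_cands$.patient != s, , drop = FALSE]
    other_noncand <- do.call(rbind, noncand_by_sample[setdiff(samples, s)])
    if (is.null(other_noncand)) other_noncand <- empty_candidates()
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, , drop = FALSE]
      fv <- cbind(
        demographic_features(cand, entry$called, entry$stats, annotation),
        cohort_features(cand, other_cands, other_noncand,
                        length(samples) - 1L),
        spatial_features(cand, cands, entry$called, scores),
        data.frame(database_score = scores[i], database_score_ii = scores2[i]))
      key <- data.frame(sample = cand$sample, chrom = cand$chrom,
                        start = cand$start, end = cand$end,
                        status = cand$status, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- cbind(key, fv)
    }
  }
  if (length(rows) == 0) {
    stop("no candidates in cohort")
  }
  out <- do.call(rbind, rows)
  out <- out[, c("sample", "chrom", "start", "end", "status",
                 feature_columns())]
  if (anyNA(out)) {
    bad <- which(is.na(out), arr.ind = TRUE)[1, ]
    stop("undefined feature ", names(out)[bad[2]], " for candidate row ", bad[1])
  }
  rownames(out) <- NULL
  out
}
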