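# Synthetic paired tumor/normal cohorts with oracle segmentations, a
# synthetic variant catalogue, and ground-truth event labels. Everything
# is generated in code so the full pipeline is testable without any
# external download.

#' Specify a synthetic cohort
#'
#' Germline CNV loci are planted in tumor AND normal of carrier patients
#' at their population frequency; recurrent and private CNAs in the tumor
#' only; optional reference-sample CNVs in every genome. Probe log-ratios
#' are the sum of active event shifts plus Gaussian noise; isolated
#' outlier probes are spiked at +/- 5 noise SDs. The oracle segmentation
#' uses the true breakpoints, optionally jittered by a few probes
#' independently in tumor and normal to emulate segmentation error.
#'
#' @param n_patients number of patients (paired genomes).
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param probe_spacing probe spacing in bp (default 9000, 244K-like).
#' @param cnv_loci data.frame `chrom`, `start`, `end`, `freq`, `sign`
#'   (+1/-1), `shift` (log-ratio magnitude) of germline CNV loci; lengths
#'   must not exceed 2.3 Mb.
#' @param cna_recurrent_loci same columns; somatic recurrent events,
#'   tumor only, any length.
#' @param private_cna_rate expected number of private somatic events per
#'   patient (Poisson).
#' @param noise_sd probe noise SD on the log-ratio scale.
#' @param outlier_rate fraction of probes replaced by isolated spikes.
#' @param breakpoint_jitter_probes oracle breakpoint jitter, in probes.
#' @param reference_cnv_loci optional loci (same columns, `freq` ignored)
#'   planted in every tumor and normal, emulating variants carried by the
#'   common reference sample.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 40,
                        chromosomes = c("1" = 6e7, "2" = 6e7,
                                        "3" = 6e7, "4" = 6e7),
                        probe_spacing = 9000,
                        cnv_loci = default_cnv_loci(chromosomes),
                        cna_recurrent_loci = default_cna_loci(chromosomes),
                        private_cna_rate = 3,
                        noise_sd = 0.12,
                        outlier_rate = 0.002,
                        breakpoint_jitter_probes = 2,
                        reference_cnv_loci = NULL,
                        seed = 1L) {
  names(chromosomes) <- norm_chrom(names(chromosomes))
  spec <- list(n_patients = n_patients, chromosomes = chromosomes,
               probe_spacing = probe_spacing, cnv_loci = cnv_loci,
               cna_recurrent_loci = cna_recurrent_loci,
               private_cna_rate = private_cna_rate, noise_sd = noise_sd,
               outlier_rate = outlier_rate,
               breakpoint_jitter_probes = breakpoint_jitter_probes,
               reference_cnv_loci = reference_cnv_loci, seed = seed)
  validate_locus <- function(d, cap = NULL) {
    if (is.null(d) || nrow(d) == 0) return(invisible())
    stopifnot(all(d$freq >= 0 & d$freq <= 1), all(d$end > d$start),
              all(d$sign %in% c(-1, 1)),
              all(norm_chrom(d$chrom) %in% names(chromosomes)),
              all(d$end <= chromosomes[norm_chrom(d$chrom)]))
    if (!is.null(cap) && any(d$end - d$start > cap)) {
      stop("CNV locus longer than the candidate cap")
    }
  }
  validate_locus(cnv_loci, cap = CANDIDATE_LENGTH_CAP)
  validate_locus(cna_recurrent_loci)
  if (!is.null(reference_cnv_loci)) validate_locus(reference_cnv_loci)
  structure(spec, class = "cohort_spec")
}

#' Default germline CNV loci for a synthetic genome
#' @param chromosomes named lengths as in [cohort_spec()].
#' @export
default_cnv_loci <- function(chromosomes) {
  chs <- names(chromosomes)
  lens <- c(1.2e5, 4e5, 2e6, 8e4, 6e5, 1.5e6, 2.5e5, 9e5, 1.8e5, 1.1e6,
            3.2e5, 7e5)
  frac <- c(0.12, 0.30, 0.52, 0.70, 0.22, 0.40, 0.62, 0.81, 0.35, 0.55,
            0.74, 0.90)
  freq <- c(0.6, 0.3, 0.5, 0.8, 0.4, 0.25, 0.7, 0.35, 0.5, 0.3, 0.6, 0.45)
  sign <- rep(c(1, -1), 6)
  shift <- c(0.45, 0.5, 0.35, 0.55, 0.4, 0.38, 0.5, 0.42, 0.48, 0.36,
             0.52, 0.44)
  n <- length(lens)
  ch <- chs[(seq_len(n) - 1) %% length(chs) + 1]
  start <- round(frac * chromosomes[ch])
  end <- pmin(start + lens, chromosomes[ch] - 1e5)
  data.frame(chrom = ch, start = start, end = end, freq = freq,
             sign = sign, shift = shift, stringsAsFactors = FALSE)
}

#' Default recurrent somatic (CNA) loci, including events over the 2.3 Mb
#' candidate cap
#' @param chromosomes named lengths as in [cohort_spec()].
#' @export
default_cna_loci <- function(chromosomes) {
  chs <- names(chromosomes)
  k <- seq_len(min(6, 2 * length(chs)))
  ch_idx <- ((c(1, 2, 3, 4, 1, 2)[k] - 1) %% length(chs)) + 1
  d <- data.frame(
    chrom = chs[ch_idx],
    start = c(0.05, 0.60, 0.08, 0.45, 0.92, 0.05)[k],
    len = c(5e6, 8e6, 3e5, 8e5, 1.5e6, 4e5)[k],
    freq = c(0.4, 0.35, 0.45, 0.3, 0.25, 0.4)[k],
    sign = c(-1, 1, 1, -1, 1, -1)[k],
    shift = c(0.4, 0.45, 0.5, 0.42, 0.38, 0.47)[k],
    stringsAsFactors = FALSE)
  start <- round(d$start * chromosomes[d$chrom])
  data.frame(chrom = d$chrom, start = start,
             end = pmin(start + d$len, chromosomes[d$chrom] - 1e5),
             freq = d$freq, sign = d$sign, shift = d$shift,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic variant-catalogue table for a cohort spec
#'
#' Every germline CNV locus (including reference-sample loci) yields 1-6
#' overlapping records with perturbed endpoints, distinct variation ids
#' and 1-3 distinct study ids; individual counts scale with the locus
#' frequency. Extra records placed uniformly at random emulate catalogue
#' redundancy off the planted loci.
#'
#' @param spec a [cohort_spec()].
#' @param extra_noise_records number of uniform background records.
#' @param redundancy range (min, max) of records per locus.
#' @param seed integer seed (defaults to the spec's).
#' @return data.frame in [read_dgv()] layout (internal coordinates).
#' @export
generate_dgv <- function(spec, extra_noise_records = 30,
                         redundancy = c(1, 6), seed = spec$seed) {
  loci <- rbind(spec$cnv_loci,
                if (!is.null(spec$reference_cnv_loci)) spec$reference_cnv_loci)
  with_seed(seed + 104729, {
    rows <- list()
    vid <- 0L
    study_pool <- paste0("study_", 1:12)
    if (!is.null(loci) && nrow(loci) > 0) {
      for (i in seq_len(nrow(loci))) {
        n_rec <- sample(seq(redundancy[1], redundancy[2]), 1)
        studies <- sample(study_pool, sample(1:3, 1))
        len <- loci$end[i] - loci$start[i]
        for (r in seq_len(n_rec)) {
          jit <- round(stats::rnorm(2, 0, 0.05 * len))
          s <- max(0, loci$start[i] + jit[1])
          e <- min(spec$chromosomes[[loci$chrom[i]]], loci$end[i] + jit[2])
          if (e <= s) { s <- loci$start[i]; e <- loci$end[i] }
          vid <- vid + 1L
          rows[[vid]] <- data.frame(
            variation_id = sprintf("V%05d", vid),
            chrom = loci$chrom[i], start = s, end = e,
            study_id = sample(studies, 1),
            n_individuals = max(1, stats::rbinom(1, 80, loci$freq[i])),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (j in seq_len(extra_noise_records)) {
      ch <- sample(names(spec$chromosomes), 1)
      len <- round(exp(stats::runif(1, log(1e4), log(1e6))))
      s <- sample.int(max(1, spec$chromosomes[[ch]] - len), 1)
      vid <- vid + 1L
      rows[[vid]] <- data.frame(
        variation_id = sprintf("V%05d", vid),
        chrom = ch, start = s, end = s + len,
        study_id = sample(study_pool, 1),
        n_individuals = stats::rbinom(1, 80, 0.2),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(variation_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        study_id = character(0), n_individuals = numeric(0),
                        stringsAsFactors = FALSE)
    }
    out$off_annotation <- rep(FALSE, nrow(out))
    out
  })
}

# drop events (rows) overlapping an earlier-listed kept event in the same
# genome; returns kept rows
resolve_event_overlaps <- function(events) {
  if (nrow(events) <= 1) return(events)
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    clash <- events$chrom[prev] == events$chrom[i] &
      events$start[prev] < events$end[i] & events$end[prev] > events$start[i]
    if (any(clash)) {
      keep[i] <- FALSE
      message("dropping planted event ", events$chrom[i], ":",
              events$start[i], "-", events$end[i], " (overlaps earlier event)")
    }
  }
  events[keep, , drop = FALSE]
}

# oracle segmentation of one genome: true breakpoints (probe indices),
# jittered, then segments with empirical means over the probe values
oracle_segments <- function(sample_id, probes, events, jitter) {
  segs <- list()
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    pos <- probes$pos[idx]
    ev <- events[events$chrom == ch, , drop = FALSE]
    bks <- integer(0)                      # breakpoints as probe offsets 1..n+1
    n <- length(idx)
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        first <- which(pos >= ev$start[i] & pos < ev$end[i])
        if (length(first) == 0) next
        bks <- c(bks, min(first), max(first) + 1L)
      }
    }
    if (jitter > 0 && length(bks) > 0) {
      bks <- bks + sample(seq(-jitter, jitter), length(bks), replace = TRUE)
    }
    bks <- sort(unique(pmin(pmax(bks, 2L), n)))
    bounds <- c(1L, bks, n + 1L)
    bounds <- unique(bounds)
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b]; hi <- bounds[b + 1] - 1L
      if (hi < lo) next
      seg_start <- if (lo == 1L) 0 else pos[lo]
      seg_end <- if (hi == n) pos[n] + 1 else pos[hi + 1]
      segs[[length(segs) + 1]] <- data.frame(
        sample = sample_id, chrom = ch, start = seg_start, end = seg_end,
        n_markers = hi - lo + 1L,
        mean = mean(probes$lr[idx[lo:hi]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Generate a paired synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to the spec's).
#' @return list with `tumor_profiles`, `normal_profiles` (named lists of
#'   probe profiles), `tumor_segments`, `normal_segments` (named lists of
#'   oracle segment data.frames), and `truth` (data.frame of planted
#'   events: `patient`, `chrom`, `start`, `end`, `kind`, `sign`,
#'   `present_in_normal`, `reference_artifact`).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  grid <- do.call(rbind, lapply(names(spec$chromosomes), function(ch) {
    data.frame(chrom = ch,
               pos = seq(round(spec$probe_spacing / 2),
                         spec$chromosomes[[ch]] - 1,
                         by = spec$probe_spacing),
               stringsAsFactors = FALSE)
  }))
  grid <- grid[order(grid$chrom, grid$pos), , drop = FALSE]
  rownames(grid) <- NULL
  n_probes <- nrow(grid)

  with_seed(seed, {
    tumor_profiles <- list(); normal_profiles <- list()
    tumor_segments <- list(); normal_segments <- list()
    truth <- list()
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%02d", p)
      ev <- list()
      add_ev <- function(d, kind, in_normal) {
        if (is.null(d) || nrow(d) == 0) return(NULL)
        data.frame(chrom = norm_chrom(d$chrom), start = d$start, end = d$end,
                   sign = d$sign, shift = d$shift, kind = kind,
                   present_in_normal = in_normal,
                   reference_artifact = kind == "reference",
                   stringsAsFactors = FALSE)
      }
      ev[["ref"]] <- add_ev(spec$reference_cnv_loci, "reference", TRUE)
      if (nrow(spec$cnv_loci) > 0) {
        carrier <- stats::runif(nrow(spec$cnv_loci)) < spec$cnv_loci$freq
        ev[["cnv"]] <- add_ev(spec$cnv_loci[carrier, , drop = FALSE],
                              "CNV", TRUE)
      }
      if (nrow(spec$cna_recurrent_loci) > 0) {
        hit <- stats::runif(nrow(spec$cna_recurrent_loci)) <
          spec$cna_recurrent_loci$freq
        ev[["cna"]] <- add_ev(spec$cna_recurrent_loci[hit, , drop = FALSE],
                              "CNA", FALSE)
      }
      n_priv <- stats::rpois(1, spec$private_cna_rate)
      if (n_priv > 0) {
        priv <- do.call(rbind, lapply(seq_len(n_priv), function(j) {
          ch <- sample(names(spec$chromosomes), 1)
          len <- round(exp(stats::runif(1, log(5e4), log(8e6))))
          s <- sample.int(max(1, spec$chromosomes[[ch]] - len), 1)
          data.frame(chrom = ch, start = s, end = s + len,
                     sign = sample(c(-1, 1), 1),
                     shift = stats::runif(1, 0.3, 0.6), freq = 1,
                     stringsAsFactors = FALSE)
        }))
        ev[["priv"]] <- add_ev(priv, "CNA", FALSE)
      }
      events <- do.call(rbind, ev)
      if (is.null(events)) {
        events <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), sign = numeric(0),
                             shift = numeric(0), kind = character(0),
                             present_in_normal = logical(0),
                             reference_artifact = logical(0),
                             stringsAsFactors = FALSE)
      }
      events <- resolve_event_overlaps(events)

      shift_track <- function(evs) {
        shift <- numeric(n_probes)
        for (i in seq_len(nrow(evs))) {
          idx <- which(grid$chrom == evs$chrom[i] &
                       grid$pos >= evs$start[i] & grid$pos < evs$end[i])
          shift[idx] <- shift[idx] + evs$sign[i] * evs$shift[i]
        }
        shift
      }
      spike <- function(lr) {
        n_out <- stats::rbinom(1, n_probes, spec$outlier_rate)
        if (n_out > 0) {
          at <- sample.int(n_probes, n_out)
          lr[at] <- lr[at] + sample(c(-5, 5), n_out, replace = TRUE) *
            spec$noise_sd
        }
        lr
      }
      normal_events <- events[events$present_in_normal, , drop = FALSE]
      t_lr <- spike(shift_track(events) +
                    stats::rnorm(n_probes, 0, spec$noise_sd))
      n_lr <- spike(shift_track(normal_events) +
                    stats::rnorm(n_probes, 0, spec$noise_sd))
      t_prof <- data.frame(chrom = grid$chrom, pos = grid$pos, lr = t_lr,
                           stringsAsFactors = FALSE)
      n_prof <- data.frame(chrom = grid$chrom, pos = grid$pos, lr = n_lr,
                           stringsAsFactors = FALSE)
      attr(t_prof, "sample_id") <- paste0(pid, "_T")
      attr(n_prof, "sample_id") <- paste0(pid, "_N")
      tumor_profiles[[pid]] <- t_prof
      normal_profiles[[pid]] <- n_prof
      tumor_segments[[pid]] <- oracle_segments(
        paste0(pid, "_T"), t_prof, events, spec$breakpoint_jitter_probes)
      normal_segments[[pid]] <- oracle_segments(
        paste0(pid, "_N"), n_prof, normal_events,
        spec$breakpoint_jitter_probes)
      if (nrow(events) > 0) {
        truth[[pid]] <- data.frame(
          patient = pid, events[, c("chrom", "start", "end")],
          kind = ifelse(events$kind == "reference", "CNV", events$kind),
          sign = events$sign,
          present_in_normal = events$present_in_normal,
          reference_artifact = events$reference_artifact,
          stringsAsFactors = FALSE)
      }
    }
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    list(spec = spec, tumor_profiles = tumor_profiles,
         normal_profiles = normal_profiles,
         tumor_segments = tumor_segments,
         normal_segments = normal_segments, truth = truth_df)
  })
}

#' Default annotation for a synthetic genome: centromeres mid-chromosome,
#' a few segmental duplications, empty physiological list
#' @param spec a [cohort_spec()].
#' @export
synthetic_annotation <- function(spec) {
  chs <- names(spec$chromosomes)
  cen <- data.frame(chrom = chs,
                    start = round(spec$chromosomes / 2) - 5e4,
                    end = round(spec$chromosomes / 2) + 5e4,
                    stringsAsFactors = FALSE)
  segdup <- data.frame(chrom = chs[1],
                       start = round(0.25 * spec$chromosomes[[1]]),
                       end = round(0.25 * spec$chromosomes[[1]]) + 2e5,
                       stringsAsFactors = FALSE)
  make_annotation(spec$chromosomes, centromeres = cen, segdups = segdup,
                  physiological = NULL)
}

#' Build a complete end-to-end fixture
#'
#' Presets: `"small"` (6 patients, 2 chromosomes of 30 Mb — a smoke-scale
#' cohort) and `"default"` (40 patients, 4 chromosomes of 60 Mb, jitter 2,
#' noise SD 0.12 — the documented benchmark scale).
#'
#' @param preset `"small"` or `"default"`.
#' @param dir optional directory; when given, the probe matrices, SEG
#'   files, variant table, BEDs and chromosome lengths are written there
#'   in the [read_probe_profiles()]/[read_seg()]/[read_dgv()] formats.
#' @param seed integer seed.
#' @return list with the [generate_cohort()] bundle plus `dgv` and
#'   `annotation`.
#' @export
end_to_end_fixture <- function(preset = c("small", "default"), dir = NULL,
                               seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    small = cohort_spec(n_patients = 6,
                        chromosomes = c("1" = 3e7, "2" = 3e7),
                        seed = seed),
    default = cohort_spec(seed = seed))
  cohort <- generate_cohort(spec)
  dgv <- generate_dgv(spec)
  annotation <- synthetic_annotation(spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tp <- cohort$tumor_profiles
    names(tp) <- paste0(names(tp), "_T")
    np <- cohort$normal_profiles
    names(np) <- paste0(names(np), "_N")
    write_probe_profiles(tp, file.path(dir, "tumor_probes.tsv"))
    write_probe_profiles(np, file.path(dir, "normal_probes.tsv"))
    write_seg(cohort$tumor_segments, file.path(dir, "tumor.seg"))
    write_seg(cohort$normal_segments, file.path(dir, "normal.seg"))
    ext <- to_external(dgv$start, dgv$end)
    utils::write.table(
      data.frame(VariationID = dgv$variation_id, Chr = dgv$chrom,
                 Start = ext$start, End = ext$end,
                 Reference = dgv$study_id, SampleSize = dgv$n_individuals),
      file.path(dir, "dgv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(chrom = names(annotation$chrom_lengths),
                 length = as.numeric(annotation$chrom_lengths)),
      file.path(dir, "chrom_lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(annotation$centromeres, file.path(dir, "centromeres.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(annotation$segdups, file.path(dir, "segdups.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    file.create(file.path(dir, "physiological.bed"))
  }
  c(cohort, list(dgv = dgv, annotation = annotation))
}
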