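# In-code fixtures: tiny profiles, segment tables and variant catalogues
# used across the unit tests. Internal coordinates (0-based half-open).

make_profile <- function(chrom, pos, lr, sample_id = "S1") {
  p <- data.frame(chrom = as.character(chrom), pos = pos, lr = lr,
                  stringsAsFactors = FALSE)
  attr(p, "sample_id") <- sample_id
  p
}

make_segments <- function(chrom, start, end, n_markers, mean,
                          sample = "S1") {
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, n_markers = as.integer(n_markers), mean = mean,
             stringsAsFactors = FALSE)
}

make_called <- function(chrom, start, end, n_markers, mean, status,
                        sample = "S1") {
  d <- make_segments(chrom, start, end, n_markers, mean, sample)
  d$status <- status
  d$merged_from <- 1L
  d
}

make_candidate <- function(chrom = "1", start = 0, end = 1e5,
                           n_markers = 10, mean = 0.5, status = "gain",
                           sample = "S1", left_flank = "normal",
                           right_flank = "normal") {
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, n_markers = as.integer(n_markers), mean = mean,
             status = status, merged_from = 1L, left_flank = left_flank,
             right_flank = right_flank, stringsAsFactors = FALSE)
}

make_dgv <- function(chrom, start, end, study_id = "study_1",
                     n_individuals = NA_real_,
                     variation_id = sprintf("V%03d", seq_along(start))) {
  data.frame(variation_id = variation_id, chrom = as.character(chrom),
             start = start, end = end, study_id = study_id,
             n_individuals = n_individuals, off_annotation = FALSE,
             stringsAsFactors = FALSE)
}

flat_annotation <- function(chrom_lengths = c("1" = 1e7, "2" = 1e7)) {
  make_annotation(chrom_lengths)
}

# a three-segment chromosome: normal / middle / normal, with a probe grid
# of constant spacing; middle segment probes get `shift` added
three_segment_sample <- function(shift = 0.5, status_mean = shift,
                                 spacing = 1e4, n_per_seg = 20,
                                 noise_sd = 0, seed = 1, chrom = "1",
                                 sample_id = "S1") {
  set.seed(seed)
  n <- 3 * n_per_seg
  pos <- seq(spacing / 2, by = spacing, length.out = n)
  lr <- rnorm(n, 0, noise_sd)
  mid <- (n_per_seg + 1):(2 * n_per_seg)
  lr[mid] <- lr[mid] + shift
  bounds <- c(0, pos[n_per_seg + 1], pos[2 * n_per_seg + 1], pos[n] + spacing)
  seg <- make_segments(chrom, bounds[1:3], bounds[2:4],
                       rep(n_per_seg, 3),
                       c(mean(lr[1:n_per_seg]), mean(lr[mid]),
                         mean(lr[(2 * n_per_seg + 1):n])),
                       sample = sample_id)
  list(profile = make_profile(chrom, pos, lr, sample_id), segments = seg)
}

# brute-force oracle: per-probe variant/individual counts by scanning
# every record for every probe
brute_force_counts <- function(dgv, probes) {
  nv <- integer(nrow(probes)); ni <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    hit <- which(dgv$chrom == probes$chrom[i] &
                 dgv$start <= probes$pos[i] & probes$pos[i] < dgv$end)
    nv[i] <- length(unique(dgv$variation_id[hit]))
    ni[i] <- sum(ifelse(is.na(dgv$n_individuals[hit]), 0,
                        dgv$n_individuals[hit]))
  }
  data.frame(chrom = probes$chrom, pos = probes$pos, n_variants = nv,
             n_individuals = ni, stringsAsFactors = FALSE)
}

# exhaustive-enumeration oracle for the permutation test p-value:
# all subsets of size k from the pool
enumerate_p_extreme <- function(pool, k, mu, sign) {
  subsets <- utils::combn(length(pool), k)
  means <- apply(subsets, 2, function(ix) mean(pool[ix]))
  mean(sign * means >= sign * mu)
}

random_toy_dgv <- function(n_records, chrom_len = 1e6, seed = 1) {
  set.seed(seed)
  start <- sample.int(chrom_len - 1e5, n_records, replace = TRUE)
  len <- sample.int(2e5, n_records, replace = TRUE)
  make_dgv(chrom = sample(c("1", "2"), n_records, replace = TRUE),
           start = start, end = pmin(start + len, chrom_len),
           study_id = sample(paste0("study_", 1:4), n_records, replace = TRUE),
           n_individuals = sample(c(NA, 1:50), n_records, replace = TRUE))
}
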