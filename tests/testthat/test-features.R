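# Database scores and the Table-1 style predictor set.

test_that("per-probe variant counts equal the brute-force scan on random toys", {
  for (seed in 1:8) {
    dgv <- random_toy_dgv(n_records = 30, seed = seed)
    set.seed(seed + 100)
    probes <- data.frame(chrom = sample(c("1", "2"), 40, replace = TRUE),
                         pos = sample.int(1e6, 40),
                         stringsAsFactors = FALSE)
    got <- probe_variant_counts(dgv, probes)
    want <- brute_force_counts(dgv, probes)
    expect_equal(got$n_variants, want$n_variants)
    expect_equal(got$n_individuals, want$n_individuals)
  }
})

test_that("probe containment is half-open: a probe at a variant end is outside", {
  dgv <- make_dgv("1", 100, 200)
  probes <- data.frame(chrom = "1", pos = c(99, 100, 199, 200),
                       stringsAsFactors = FALSE)
  expect_equal(probe_variant_counts(dgv, probes)$n_variants, c(0, 1, 1, 0))
})

test_that("Database scores are probe means, with monotone response to coverage", {
  counts <- data.frame(chrom = "1", pos = c(10, 20, 30),
                       n_variants = c(2L, 3L, 4L),
                       n_individuals = c(10, 30, 20),
                       stringsAsFactors = FALSE)
  cand <- make_candidate(start = 0, end = 40, n_markers = 3)
  expect_equal(database_score(cand, counts), 3)
  expect_equal(database_score_ii(cand, counts), 20)

  none <- data.frame(chrom = "1", pos = c(10, 20), n_variants = 0L,
                     n_individuals = 0, stringsAsFactors = FALSE)
  expect_equal(database_score(make_candidate(end = 30), none), 0)
  expect_equal(database_score_ii(make_candidate(end = 30), none), 0)
  expect_error(database_score(make_candidate(start = 5e6, end = 6e6), counts),
               "no probes")

  # adding one variant covering every candidate probe raises the score by 1
  dgv <- random_toy_dgv(25, seed = 3)
  probes <- data.frame(chrom = "1", pos = seq(1e4, 2e5, by = 1e4),
                       stringsAsFactors = FALSE)
  cand2 <- make_candidate(start = 0, end = 2.1e5, n_markers = nrow(probes))
  before <- database_score(cand2, probe_variant_counts(dgv, probes))
  dgv2 <- rbind(dgv, make_dgv("1", 0, 3e5, variation_id = "VNEW"))
  after <- database_score(cand2, probe_variant_counts(dgv2, probes))
  expect_equal(after, before + 1)
})

test_that("demographic features follow their printed definitions", {
  ann <- make_annotation(
    c("1" = 1e7),
    centromeres = data.frame(chrom = "1", start = 3e6, end = 3.1e6),
    segdups = data.frame(chrom = "1", start = 5e6, end = 5.2e6))
  called <- make_called("1", c(0, 1.5e6, 1.6e6), c(1.5e6, 1.6e6, 2.6e6),
                        c(100, 10, 100), c(0.4, 0.6, 0.1),
                        c("normal", "gain", "normal"))
  cand <- make_candidate(start = 1.5e6, end = 1.6e6, mean = 0.6)
  stats <- list(array_median = 0, array_mad = 0.08, residual_mad = 0.1)
  fv <- demographic_features(cand, called, stats, ann)
  expect_equal(fv$length_bp, 1e5)
  expect_equal(fv$near_centromere, 1L)   # end at 1.6 Mb, centromere at 3 Mb
  expect_equal(fv$near_telomere, 1L)     # start within 2 Mb of position 0
  expect_equal(fv$segmental_duplication, 0L)
  expect_equal(fv$sign, 1L)
  expect_equal(fv$height, 0.6)
  expect_equal(fv$relative_height, 6)
  expect_equal(fv$break_score, abs(0.4 - 0.1) / 0.1)  # = 3.0
  expect_equal(fv$surrounded_by_normals, 1L)

  # one loss flank: not surrounded
  cand2 <- cand; cand2$left_flank <- "loss"
  expect_equal(demographic_features(cand2, called, stats,
                                    ann)$surrounded_by_normals, 0L)

  # far from everything on a long chromosome
  ann2 <- make_annotation(c("1" = 5e7),
                          centromeres = data.frame(chrom = "1", start = 2.5e7,
                                                   end = 2.51e7))
  called3 <- make_called("1", c(0, 1e7, 1.01e7), c(1e7, 1.01e7, 2e7),
                         c(100, 10, 100), c(0, 0.6, 0),
                         c("normal", "gain", "normal"))
  cand3 <- make_candidate(start = 1e7, end = 1.01e7, mean = 0.6)
  fv3 <- demographic_features(cand3, called3, stats, ann2)
  expect_equal(fv3$near_centromere, 0L)
  expect_equal(fv3$near_telomere, 0L)
})

test_that("cohort features count other patients, signs and exact breakpoints", {
  cand <- make_candidate(start = 1e6, end = 1.2e6, status = "gain")
  others <- rbind(
    make_candidate(start = 1.1e6, end = 1.3e6, status = "gain", sample = "S2"),
    make_candidate(start = 0.9e6, end = 1.05e6, status = "loss", sample = "S3"))
  none <- empty <- others[0, ]
  # 3-patient cohort: both others overlap, mixed signs -> GL, pct 1.0
  fv <- cohort_features(cand, others, empty, n_other_patients = 2)
  expect_equal(fv$overlap_pattern, "GL")
  expect_equal(fv$overlap_pct, 1.0)
  expect_equal(fv$matching_bkpt_pct, 0)

  # no other overlaps -> None / 0 / 0
  far <- make_candidate(start = 5e6, end = 5.1e6, sample = "S2")
  fv0 <- cohort_features(cand, far, empty, 2)
  expect_equal(fv0$overlap_pattern, "None")
  expect_equal(fv0$overlap_pct, 0)
  expect_equal(fv0$matching_bkpt_pct, 0)

  # exact shared start counts toward breakpoints and (if intersecting) overlap
  exact <- make_candidate(start = 1e6, end = 1.4e6, status = "gain",
                          sample = "S2")
  fv1 <- cohort_features(cand, exact, empty, 3)
  expect_equal(fv1$matching_bkpt_pct, 1 / 3)
  expect_equal(fv1$overlap_pct, 1 / 3)
  expect_equal(fv1$overlap_pattern, "GG")

  # a shared coordinate without intersection: breakpoint only
  abut <- make_candidate(start = 1.2e6, end = 1.5e6, status = "loss",
                         sample = "S4")
  fv2 <- cohort_features(cand, abut, empty, 3)
  expect_equal(fv2$matching_bkpt_pct, 1 / 3)
  expect_equal(fv2$overlap_pct, 0)

  # same-sign non-candidate segments of other patients
  noncand <- make_called("1", 0.5e6, 3e6, 200, 0.5, "gain", sample = "S2")
  fv3 <- cohort_features(cand, empty, noncand, 2)
  expect_equal(fv3$overlap_with_cnas, 1L)
  # opposite sign does not count
  noncand_l <- make_called("1", 0.5e6, 3e6, 200, -0.5, "loss", sample = "S2")
  expect_equal(cohort_features(cand, empty, noncand_l, 2)$overlap_with_cnas, 0L)

  # cohort of one patient: all zero / None
  lone <- cohort_features(cand, empty, empty, 0)
  expect_equal(lone$overlap_pattern, "None")
  expect_equal(lone$overlap_pct, 0)
})

test_that("spatial features use the 500 kb window and chromosome marker shares", {
  cand <- make_candidate(start = 1e6, end = 1.1e6)
  called <- make_called("1", c(0, 1e6, 1.1e6), c(1e6, 1.1e6, 1e7),
                        c(450, 100, 450), c(0, 0.5, 0),
                        c("normal", "gain", "normal"))
  # lone candidate
  fv <- spatial_features(cand, cand, called, candidate_scores = 2.5)
  expect_equal(fv$close_to_other_candidates, 0L)
  expect_equal(fv$ds_other_candidates, 0)
  expect_equal(fv$pct_normal, 900 / 1000)

  # second candidate 400 kb away: close; its score feeds ds_other_candidates
  sibling <- make_candidate(start = 1.5e6, end = 1.6e6)
  both <- rbind(cand, sibling)
  fv2 <- spatial_features(cand, both, called, candidate_scores = c(2.5, 4.0))
  expect_equal(fv2$close_to_other_candidates, 1L)
  expect_equal(fv2$ds_other_candidates, 4.0)

  # 600 kb away: not close, but still averaged into ds_other_candidates
  farther <- make_candidate(start = 1.7e6, end = 1.8e6)
  fv3 <- spatial_features(cand, rbind(cand, farther), called,
                          candidate_scores = c(2.5, 1.0))
  expect_equal(fv3$close_to_other_candidates, 0L)
  expect_equal(fv3$ds_other_candidates, 1.0)
})

test_that("relative height and break score are scale invariant", {
  ann <- flat_annotation()
  called <- make_called("1", c(0, 1e6, 1.1e6), c(1e6, 1.1e6, 2e6),
                        c(100, 10, 100), c(0.3, 0.6, 0.1),
                        c("normal", "gain", "normal"))
  cand <- make_candidate(start = 1e6, end = 1.1e6, mean = 0.6)
  stats <- list(array_median = 0, array_mad = 0.08, residual_mad = 0.1)
  fv <- demographic_features(cand, called, stats, ann)
  for (c_scale in c(0.5, 4)) {
    called_s <- called; called_s$mean <- called$mean * c_scale
    cand_s <- cand; cand_s$mean <- cand$mean * c_scale
    stats_s <- stats
    stats_s$array_mad <- stats$array_mad * c_scale
    stats_s$residual_mad <- stats$residual_mad * c_scale
    fv_s <- demographic_features(cand_s, called_s, stats_s, ann)
    expect_equal(fv_s$relative_height, fv$relative_height)
    expect_equal(fv_s$break_score, fv$break_score)
  }
})

test_that("the assembled feature matrix is complete, ordered and deterministic", {
  fx <- suppressMessages(end_to_end_fixture("small", seed = 23))
  calls <- process_cohort(fx$tumor_profiles, fx$tumor_segments, fx$annotation)
  m1 <- build_feature_matrix(calls, fx$dgv, fx$annotation)
  expect_equal(setdiff(names(m1), c("sample", "chrom", "start", "end",
                                    "status")), feature_columns())
  expect_equal(nrow(m1), sum(sapply(calls, function(x) nrow(x$candidates))))
  expect_false(anyNA(m1))
  pct_cols <- c("overlap_pct", "matching_bkpt_pct", "pct_normal")
  expect_true(all(m1[, pct_cols] >= 0 & m1[, pct_cols] <= 1))

  # recomputation is bit-identical; patient order does not matter
  m2 <- build_feature_matrix(calls, fx$dgv, fx$annotation)
  expect_identical(m1, m2)
  m3 <- build_feature_matrix(rev(calls), fx$dgv, fx$annotation)
  key <- function(m) paste(m$sample, m$chrom, m$start)
  m3 <- m3[match(key(m1), key(m3)), ]
  rownames(m3) <- NULL
  expect_equal(m1, m3)
})
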