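# End-to-end orchestration: calling across a cohort, truth labeling from
# the paired normals, classification with a chosen model, training with a
# patient-level split. The command-line wrapper in inst/cli/cnvclass.R is
# a thin shell over these functions.

#' Run calling and candidate extraction for every sample of a cohort
#'
#' @param profiles named list of probe profiles.
#' @param segments named list of segment data.frames (same names).
#' @param annotation annotation object or NULL.
#' @param verbose log per-stage counts via `message()`.
#' @return named list of [call_sample()] results.
#' @export
process_cohort <- function(profiles, segments, annotation = NULL,
                           verbose = FALSE) {
  stopifnot(all(names(profiles) %in% names(segments)))
  out <- lapply(names(profiles), function(s) {
    res <- call_sample(profiles[[s]], segments[[s]], annotation)
    if (verbose) {
      message(sprintf(
        "%s: %d segments, %d gain/loss, %d candidates", s,
        nrow(segments[[s]]),
        sum(res$called$status %in% c("gain", "loss")),
        nrow(res$candidates)))
    }
    res
  })
  names(out) <- names(profiles)
  out
}

#' Label every candidate of a processed cohort from the paired normals
#'
#' @param tumor_calls result of [process_cohort()] on the tumor samples.
#' @param normal_profiles,normal_segments paired normal data keyed by the
#'   same patient names.
#' @param R,alpha,rng_seed permutation-test parameters.
#' @return data.frame: candidate keys (`sample`, `chrom`, `start`, `end`,
#'   `status`), `patient`, `label`, `evidence`.
#' @export
label_cohort <- function(tumor_calls, normal_profiles, normal_segments,
                         R = 1000, alpha = 0.01, rng_seed = 1L) {
  rows <- list()
  for (pid in names(tumor_calls)) {
    entry <- tumor_calls[[pid]]
    if (nrow(entry$candidates) == 0) next
    n_prof <- normal_profiles[[pid]]
    n_seg <- normal_segments[[pid]]
    if (is.null(n_prof) || is.null(n_seg)) {
      stop("no paired normal for patient ", pid)
    }
    n_stats <- compute_array_stats(n_prof, n_seg)
    n_called <- merge_candidate_runs(call_segments(n_seg, n_stats))
    lab <- label_candidates(entry$candidates, entry$called, n_prof,
                            n_called, n_stats, R = R, alpha = alpha,
                            rng_seed = rng_seed)
    rows[[pid]] <- cbind(
      entry$candidates[, c("sample", "chrom", "start", "end", "status")],
      patient = pid, lab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no candidates to label")
  rownames(out) <- NULL
  out
}

#' Classify a tumor cohort with a published tree or fitted model
#'
#' Extracts candidates, builds the feature matrix, predicts CNV/CNA and
#' optionally writes the report TSV.
#'
#' @param tumor_profiles,tumor_segments named lists, one entry per sample.
#' @param dgv variant table.
#' @param annotation annotation object.
#' @param model a `published_cnv_tree`, `cnv_cart` or `cnv_forest`
#'   (default: the smoothed-CBS catalogue-only stump).
#' @param report_path optional output TSV path.
#' @param truth optional truth labels aligned to the resulting candidate
#'   rows (passed through to the report).
#' @param verbose log filter-stage counts.
#' @return list with `calls` (per-sample [call_sample()] results),
#'   `features` (feature matrix) and `predictions` (character vector).
#' @export
classify_cohort <- function(tumor_profiles, tumor_segments, dgv, annotation,
                            model = published_tree("cbs_smoothed_dgv_only"),
                            report_path = NULL, truth = NULL,
                            verbose = FALSE) {
  calls <- process_cohort(tumor_profiles, tumor_segments, annotation,
                          verbose = verbose)
  feats <- build_feature_matrix(calls, dgv, annotation)
  preds <- predict(model, feats)
  if (!is.null(report_path)) {
    cands <- do.call(rbind, lapply(calls, function(x) x$candidates))
    write_report(cands, feats, preds, truth = truth, path = report_path)
  }
  list(calls = calls, features = feats, predictions = preds)
}

#' Split patients into training and held-out sets
#' @keywords internal
split_patients <- function(patients, train_fraction = 0.6, seed = 1L) {
  patients <- unique(patients)
  n_train <- max(1L, round(train_fraction * length(patients)))
  if (n_train >= length(patients)) n_train <- length(patients) - 1L
  train <- with_seed(seed, sample(patients, n_train))
  list(train = train, test = setdiff(patients, train))
}

#' Train CART and random-forest classifiers on a paired cohort
#'
#' Labels every candidate from the paired normal, splits by patient
#' (never by candidate), trains both models on the training patients and
#' evaluates them on the held-out patients.
#'
#' @param fixture bundle from [end_to_end_fixture()] (or any list with
#'   `tumor_profiles`, `tumor_segments`, `normal_profiles`,
#'   `normal_segments`, `dgv`, `annotation`).
#' @param train_fraction fraction of patients in the training set.
#' @param R,alpha permutation-test parameters.
#' @param n_trees random-forest size.
#' @param seed seed for labeling streams, the split and both learners.
#' @return list with `cart`, `rf`, `eval_cart`, `eval_rf`, `features`,
#'   `labels`, `split`.
#' @export
train_pipeline <- function(fixture, train_fraction = 0.6, R = 1000,
                           alpha = 0.01, n_trees = 500, seed = 1L) {
  if (length(fixture$tumor_profiles) < 2) stop("need at least 2 patients")
  calls <- process_cohort(fixture$tumor_profiles, fixture$tumor_segments,
                          fixture$annotation)
  labels <- label_cohort(calls, fixture$normal_profiles,
                         fixture$normal_segments, R = R, alpha = alpha,
                         rng_seed = seed)
  feats <- build_feature_matrix(calls, fixture$dgv, fixture$annotation)
  key_f <- paste(feats$sample, feats$chrom, feats$start, feats$end)
  key_l <- paste(labels$sample, labels$chrom, labels$start, labels$end)
  labels <- labels[match(key_f, key_l), , drop = FALSE]
  stopifnot(!anyNA(labels$label))
  split <- split_patients(labels$patient, train_fraction, seed = seed)
  tr <- labels$patient %in% split$train
  if (length(unique(labels$label[tr])) < 2) {
    stop("training partition is single-class; cannot fit classifiers")
  }
  cart <- train_cart(feats[tr, , drop = FALSE], labels$label[tr], seed = seed)
  rf <- train_rf(feats[tr, , drop = FALSE], labels$label[tr],
                 n_trees = n_trees, seed = seed)
  te <- !tr
  eval_cart <- evaluate(predict(cart, feats[te, , drop = FALSE]),
                        labels$label[te], labels$patient[te])
  eval_rf <- evaluate(predict(rf, feats[te, , drop = FALSE]),
                      labels$label[te], labels$patient[te])
  list(cart = cart, rf = rf, eval_cart = eval_cart, eval_rf = eval_rf,
       features = feats, labels = labels, split = split)
}

#' Generate and optionally write a synthetic fixture (preset wrapper)
#' @inheritParams end_to_end_fixture
#' @export
simulate_fixture <- function(preset = c("small", "default"), dir = NULL,
                             seed = 1L) {
  end_to_end_fixture(preset = match.arg(preset), dir = dir, seed = seed)
}
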