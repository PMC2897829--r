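# Published trees, the ad-hoc catalogue rule, trainable CART / random
# forest, the univariate screen and the evaluation report.

fv_row <- function(database_score = 1, length_bp = 1e5, overlap_pct = 0,
                   matching_bkpt_pct = 0, relative_height = 1) {
  data.frame(database_score = database_score, length_bp = length_bp,
             overlap_pct = overlap_pct, matching_bkpt_pct = matching_bkpt_pct,
             relative_height = relative_height)
}

test_that("the smoothed-CBS full tree reproduces its printed splits", {
  tree <- published_tree("cbs_smoothed_full")
  # high database score wins outright (inclusive at 2.45)
  expect_equal(predict(tree, fv_row(database_score = 3.0)), "CNV")
  expect_equal(predict(tree, fv_row(database_score = 2.45)), "CNV")
  expect_equal(predict(tree, fv_row(database_score = 2.44)), "CNA")
  # short segments are CNVs below 30 kb (strict)
  expect_equal(predict(tree, fv_row(length_bp = 2e4)), "CNV")
  expect_equal(predict(tree, fv_row(length_bp = 29999)), "CNV")
  expect_equal(predict(tree, fv_row(length_bp = 30000)), "CNA")
  # longer segments need 37% overlap (inclusive)
  expect_equal(predict(tree, fv_row(length_bp = 1e5, overlap_pct = 0.37)), "CNV")
  expect_equal(predict(tree, fv_row(length_bp = 1e5, overlap_pct = 0.10)), "CNA")
  # the overlap split can be rebound to matching_bkpt_pct
  tree2 <- published_tree("cbs_smoothed_full",
                          overlap_feature = "matching_bkpt_pct")
  expect_equal(predict(tree2, fv_row(length_bp = 1e5, overlap_pct = 0.9,
                                     matching_bkpt_pct = 0)), "CNA")
  expect_equal(predict(tree2, fv_row(length_bp = 1e5,
                                     matching_bkpt_pct = 0.4)), "CNV")
})

test_that("the GLAD and unsmoothed-CBS trees follow their printed rules", {
  glad <- published_tree("glad_full")
  expect_equal(predict(glad, fv_row(database_score = 3, relative_height = 2)),
               "CNV")
  expect_equal(predict(glad, fv_row(database_score = 3, relative_height = 1.5)),
               "CNA")  # "greater than 1.5" is strict
  expect_equal(predict(glad, fv_row(database_score = 2, overlap_pct = 0.38)),
               "CNV")
  expect_equal(predict(glad, fv_row(database_score = 2, overlap_pct = 0.30)),
               "CNA")

  un <- published_tree("cbs_unsmoothed_full")
  # branch with matching breakpoints in > 1.2% of other patients
  expect_equal(predict(un, fv_row(matching_bkpt_pct = 0.05, length_bp = 1e5)),
               "CNV")
  expect_equal(predict(un, fv_row(matching_bkpt_pct = 0.05, length_bp = 5e5)),
               "CNA")
  expect_equal(predict(un, fv_row(matching_bkpt_pct = 0.05, length_bp = 5e5,
                                  database_score = 4.5)), "CNV")
  # branch without matching breakpoints: tiered length / score rules
  expect_equal(predict(un, fv_row(length_bp = 2.1e4)), "CNV")
  expect_equal(predict(un, fv_row(length_bp = 5e4, database_score = 1.3)),
               "CNV")
  expect_equal(predict(un, fv_row(length_bp = 5e4, database_score = 1.2)),
               "CNA")
  expect_equal(predict(un, fv_row(length_bp = 1e5, database_score = 3.1)),
               "CNV")
  expect_equal(predict(un, fv_row(length_bp = 1e5, database_score = 3.0)),
               "CNA")

  # catalogue-only stumps
  expect_equal(predict(published_tree("cbs_smoothed_dgv_only"),
                       fv_row(database_score = 2.45)), "CNV")
  expect_equal(predict(published_tree("glad_dgv_only"),
                       fv_row(database_score = 2.9)), "CNA")
  expect_equal(predict(published_tree("glad_dgv_only"),
                       fv_row(database_score = 3)), "CNV")
})

test_that("published trees are pure functions and reject incomplete inputs", {
  tree <- published_tree("cbs_smoothed_full")
  fv <- fv_row(database_score = 1.7, length_bp = 5e4, overlap_pct = 0.2)
  expect_identical(predict(tree, fv), predict(tree, fv))
  expect_error(predict(tree, fv[, "database_score", drop = FALSE]),
               "incomplete")
  fv_na <- fv; fv_na$length_bp <- NA
  expect_error(predict(tree, fv_na), "incomplete")
})

test_that("the ad-hoc rule needs two distinct studies", {
  cand <- make_candidate(start = 1e5, end = 2e5)
  one_study <- make_dgv("1", c(9e4, 1.2e5, 1.5e5), c(1.5e5, 1.8e5, 2.5e5),
                        study_id = "study_1")
  expect_equal(adhoc_dgv_rule(cand, one_study), "CNA")
  two_studies <- make_dgv("1", c(9e4, 1.2e5), c(1.5e5, 1.8e5),
                          study_id = c("study_1", "study_2"))
  expect_equal(adhoc_dgv_rule(cand, two_studies), "CNV")
  elsewhere <- make_dgv("1", 5e5, 6e5)
  expect_equal(adhoc_dgv_rule(cand, elsewhere), "CNA")
})

# synthetic labeled features: label CNV iff database_score >= cut, with
# optional label noise
threshold_features <- function(n, cut = 2.0, noise = 0, seed = 1) {
  set.seed(seed)
  f <- data.frame(length_bp = sample.int(5e5, n),
                  database_score = round(runif(n, 0, 5), 2),
                  relative_height = runif(n, 0, 8),
                  overlap_pct = runif(n),
                  matching_bkpt_pct = runif(n))
  lab <- ifelse(f$database_score >= cut, "CNV", "CNA")
  flip <- runif(n) < noise
  lab[flip] <- ifelse(lab[flip] == "CNV", "CNA", "CNV")
  list(features = f, labels = lab)
}

test_that("CART recovers a planted database-score threshold at the root", {
  d <- threshold_features(600, cut = 2.0, noise = 0.05, seed = 2)
  fit <- train_cart(d$features, d$labels, seed = 2)
  expect_equal(cart_root_feature(fit), "database_score")
  split_val <- fit$fit$splits[1, "index"]
  gap <- min(diff(sort(unique(d$features$database_score))))
  expect_lt(abs(split_val - 2.0), 0.05 + gap)

  # noise-free separable data prunes to a single split
  d0 <- threshold_features(400, cut = 2.5, noise = 0, seed = 3)
  fit0 <- train_cart(d0$features, d0$labels, seed = 3)
  expect_equal(sum(fit0$fit$frame$var != "<leaf>"), 1)
  expect_equal(cart_root_feature(fit0), "database_score")

  # reproducibility and degenerate input
  fit_b <- train_cart(d$features, d$labels, seed = 2)
  expect_identical(fit$fit$frame, fit_b$fit$frame)
  expect_error(train_cart(d$features, rep("CNA", 600)), "both classes")
})

test_that("random forest finds the planted feature and votes reproducibly", {
  d <- threshold_features(500, cut = 2.0, noise = 0.1, seed = 4)
  rf <- train_rf(d$features, d$labels, n_trees = 200, seed = 4)
  imp <- gini_importance(rf)
  expect_equal(imp$feature[which.max(imp$gini_decrease)], "database_score")

  # training-set accuracy of the forest is at least the pruned tree's
  cart <- train_cart(d$features, d$labels, seed = 4)
  acc <- function(pred) mean(pred == d$labels)
  expect_gte(acc(predict(rf, d$features)), acc(predict(cart, d$features)))

  rf_b <- train_rf(d$features, d$labels, n_trees = 200, seed = 4)
  expect_identical(predict(rf, d$features), predict(rf_b, d$features))
})

test_that("forest importance ranking of the planted feature is seed-stable", {
  d <- threshold_features(400, cut = 2.0, noise = 0.1, seed = 5)
  tops <- vapply(1:5, function(s) {
    imp <- gini_importance(train_rf(d$features, d$labels, n_trees = 100,
                                    seed = s))
    imp$feature[which.max(imp$gini_decrease)]
  }, character(1))
  expect_true(all(tops == "database_score"))
})

test_that("the univariate screen controls type I error and flags degeneracies", {
  # feature independent of labels: p < 0.05 in about 5% of replicates
  set.seed(6)
  hits <- vapply(1:200, function(i) {
    f <- data.frame(database_score = rnorm(2000))
    lab <- sample(c("CNA", "CNV"), 2000, replace = TRUE)
    univariate_screen(f, lab)$p_value[1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)

  # a perfectly separating feature is flagged as non-converged
  f_sep <- data.frame(database_score = c(rep(0, 50), rep(5, 50)))
  lab_sep <- c(rep("CNA", 50), rep("CNV", 50))
  expect_false(univariate_screen(f_sep, lab_sep)$converged[1])

  # constant feature: flagged with p = 1
  f_const <- data.frame(length_bp = rep(1e5, 100))
  sc <- univariate_screen(f_const, sample(c("CNA", "CNV"), 100, TRUE))
  expect_equal(sc$p_value[1], 1)

  # flipping the class labels flips the slope sign
  set.seed(7)
  f <- data.frame(relative_height = rnorm(500))
  lab <- ifelse(f$relative_height + rnorm(500) > 0, "CNV", "CNA")
  b1 <- univariate_screen(f, lab)$beta[1]
  b2 <- univariate_screen(f, ifelse(lab == "CNV", "CNA", "CNV"))$beta[1]
  expect_equal(b1, -b2, tolerance = 1e-8)

  # a multi-level factor yields one beta per non-reference level
  f_fac <- data.frame(overlap_pattern = sample(c("None", "GG", "LL", "GL"),
                                               400, replace = TRUE))
  lab_f <- sample(c("CNA", "CNV"), 400, replace = TRUE)
  sc_f <- univariate_screen(f_fac, lab_f)
  expect_equal(nrow(sc_f), 3)
  expect_equal(length(unique(sc_f$p_value)), 1)
})

test_that("evaluation arithmetic matches the printed confusion tables", {
  # pooled accuracy from the smoothed-CBS CART-full test-set counts
  pred <- c(rep("CNA", 654), rep("CNA", 54), rep("CNV", 182), rep("CNV", 793))
  truth <- c(rep("CNA", 654), rep("CNV", 54), rep("CNA", 182), rep("CNV", 793))
  ev <- evaluate(pred, truth)
  expect_equal(unname(ev$counts), c(654, 54, 182, 793))
  expect_equal(round(ev$accuracy, 2), 0.86)

  # the full-RF row: predictive values 0.82 / 0.94 at 2 d.p.
  pred2 <- c(rep("CNA", 659), rep("CNA", 42), rep("CNV", 177), rep("CNV", 805))
  truth2 <- c(rep("CNA", 659), rep("CNV", 42), rep("CNA", 177), rep("CNV", 805))
  ev2 <- evaluate(pred2, truth2)
  expect_equal(round(ev2$ppv, 2), 0.82)
  expect_equal(round(ev2$npv, 2), 0.94)

  expect_equal(evaluate(c("CNV", "CNA"), c("CNV", "CNA"))$accuracy, 1)
  expect_error(evaluate(character(0), character(0)), "empty")

  # random-input property: accuracy == (tn+tp)/total by direct recount
  set.seed(8)
  for (i in 1:10) {
    p <- sample(c("CNV", "CNA"), 50, replace = TRUE)
    t <- sample(c("CNV", "CNA"), 50, replace = TRUE)
    sid <- sample(paste0("S", 1:5), 50, replace = TRUE)
    ev_i <- evaluate(p, t, sid)
    expect_equal(ev_i$accuracy, mean(p == t))
    expect_equal(sum(ev_i$counts), 50)
    expect_equal(unname(ev_i$per_tumor_median),
                 unname(median(tapply(p == t, sid, mean))))
  }
})
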