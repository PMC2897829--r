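# Classifiers: the hard-coded published decision trees, the ad-hoc
# two-study catalogue rule, trainable CART (1-SE pruned) and random
# forest, the univariate logistic screen and the evaluation report.

PUBLISHED_TREE_IDS <- c("cbs_smoothed_full", "glad_full", "cbs_unsmoothed_full",
                        "cbs_smoothed_dgv_only", "glad_dgv_only")

#' Construct a published decision tree
#'
#' The five trees reported for the original glioblastoma models, encoded
#' from their printed split rules. Thresholds quoted as "at least" / "or
#' more" are inclusive; "shorter than" / "greater than" / "more than" are
#' strict. Only CNV paths were printed; every unprinted complement branch
#' predicts CNA. Percentage thresholds are stored as fractions to match
#' the feature-matrix units.
#'
#' @param id one of `r paste(PUBLISHED_TREE_IDS, collapse = ", ")`.
#' @param overlap_feature which feature feeds the smoothed-CBS tree's
#'   "matching candidate segments in 37% or more of the other patients"
#'   split: `"overlap_pct"` (default) or `"matching_bkpt_pct"`.
#' @return object of class `published_cnv_tree` with a [predict] method.
#' @export
published_tree <- function(id = PUBLISHED_TREE_IDS,
                           overlap_feature = c("overlap_pct",
                                               "matching_bkpt_pct")) {
  id <- match.arg(id)
  overlap_feature <- match.arg(overlap_feature)
  structure(list(id = id, overlap_feature = overlap_feature),
            class = "published_cnv_tree")
}

#' @export
print.published_cnv_tree <- function(x, ...) {
  cat("Published CNV/CNA decision tree:", x$id, "\n")
  rules <- switch(x$id,
    cbs_smoothed_full = c(
      "CNV if database_score >= 2.45",
      "else CNV if length < 30 Kb",
      sprintf("else CNV if %s >= 0.37", x$overlap_feature),
      "else CNA"),
    glad_full = c(
      "CNV if database_score >= 3 and relative_height > 1.5",
      "else CNV if database_score < 3 and overlap_pct >= 0.38",
      "else CNA"),
    cbs_unsmoothed_full = c(
      "if matching_bkpt_pct > 0.012:",
      "  CNV if length < 396 Kb, or length >= 396 Kb and database_score >= 4.5",
      "else:",
      "  CNV if length < 22 Kb,",
      "  or length < 77 Kb and database_score >= 1.3,",
      "  or length >= 77 Kb and database_score >= 3.1",
      "else CNA"),
    cbs_smoothed_dgv_only = "CNV if database_score >= 2.45, else CNA",
    glad_dgv_only = "CNV if database_score >= 3, else CNA")
  cat(paste0("  ", rules, collapse = "\n"), "\n")
  invisible(x)
}

#' Predict CNV/CNA with a published tree
#'
#' @param object a `published_cnv_tree`.
#' @param newdata data.frame holding the feature columns the tree uses
#'   (subset of [feature_columns()]); percentages as fractions.
#' @param ... unused.
#' @return character vector of "CNV"/"CNA", one per row of `newdata`.
#' @export
predict.published_cnv_tree <- function(object, newdata, ...) {
  need <- switch(object$id,
    cbs_smoothed_full = c("database_score", "length_bp", object$overlap_feature),
    glad_full = c("database_score", "relative_height", "overlap_pct"),
    cbs_unsmoothed_full = c("matching_bkpt_pct", "length_bp", "database_score"),
    cbs_smoothed_dgv_only = "database_score",
    glad_dgv_only = "database_score")
  missing_cols <- setdiff(need, names(newdata))
  if (length(missing_cols)) {
    stop("feature vector incomplete; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(newdata[, need, drop = FALSE])) {
    stop("feature vector incomplete: NA in ", paste(need, collapse = ", "))
  }
  ds <- newdata$database_score
  cnv <- switch(object$id,
    cbs_smoothed_full = {
      ov <- newdata[[object$overlap_feature]]
      ds >= 2.45 | (ds < 2.45 & (newdata$length_bp < 30000 |
                                 (newdata$length_bp >= 30000 & ov >= 0.37)))
    },
    glad_full = {
      (ds >= 3 & newdata$relative_height > 1.5) |
        (ds < 3 & newdata$overlap_pct >= 0.38)
    },
    cbs_unsmoothed_full = {
      mb <- newdata$matching_bkpt_pct
      len <- newdata$length_bp
      branch1 <- mb > 0.012 &
        (len < 396000 | (len >= 396000 & ds >= 4.5))
      branch2 <- mb <= 0.012 &
        (len < 22000 |
         (len < 77000 & ds >= 1.3) |
         (len >= 77000 & ds >= 3.1))
      branch1 | branch2
    },
    cbs_smoothed_dgv_only = ds >= 2.45,
    glad_dgv_only = ds >= 3)
  ifelse(cnv, "CNV", "CNA")
}

#' Ad-hoc two-study catalogue rule
#'
#' Classifies a candidate CNV when its interval intersects catalogue
#' variants from at least two distinct studies, CNA otherwise.
#'
#' @param candidates candidate data.frame (one or more rows).
#' @param dgv variant table with `study_id`.
#' @return character vector of "CNV"/"CNA".
#' @export
adhoc_dgv_rule <- function(candidates, dgv) {
  vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    hit <- dgv$chrom == cand$chrom & dgv$start < cand$end & dgv$end > cand$start
    if (length(unique(dgv$study_id[hit])) >= 2) "CNV" else "CNA"
  }, character(1))
}

prepare_training_frame <- function(features, labels) {
  labels <- factor(as.character(labels), levels = c("CNA", "CNV"))
  if (length(unique(labels[!is.na(labels)])) < 2) {
    stop("training requires both classes present")
  }
  x <- features[, intersect(feature_columns(), names(features)), drop = FALSE]
  if ("overlap_pattern" %in% names(x)) {
    x$overlap_pattern <- factor(x$overlap_pattern,
                                levels = c("None", "GG", "LL", "GL"))
  }
  cbind(x, .label = labels)
}

#' Train a CART classifier with 1-SE cost-complexity pruning
#'
#' Grows a Gini-impurity classification tree with 10-fold cross-validation
#' and prunes to the smallest tree whose cross-validated error is within
#' one standard error of the minimum.
#'
#' @param features feature matrix (the [feature_columns()] subset is used).
#' @param labels "CNV"/"CNA" per row.
#' @param seed integer seed controlling the cross-validation folds.
#' @param minbucket minimum leaf size (default 5).
#' @param xval cross-validation folds (default 10).
#' @return object of class `cnv_cart` wrapping the pruned [rpart::rpart] fit.
#' @export
train_cart <- function(features, labels, seed = 1L, minbucket = 5, xval = 10) {
  df <- prepare_training_frame(features, labels)
  fit <- with_seed(seed, {
    rpart::rpart(.label ~ ., data = df, method = "class",
                 parms = list(split = "gini"),
                 control = rpart::rpart.control(minbucket = minbucket,
                                                xval = xval, cp = 0.001))
  })
  cp <- fit$cptable
  i_min <- which.min(cp[, "xerror"])
  thresh <- cp[i_min, "xerror"] + cp[i_min, "xstd"]
  i_1se <- which(cp[, "xerror"] <= thresh)[1]
  pruned <- rpart::prune(fit, cp = cp[i_1se, "CP"])
  structure(list(fit = pruned, cptable = cp, seed = seed),
            class = "cnv_cart")
}

#' @export
print.cnv_cart <- function(x, ...) {
  cat("CNV/CNA classification tree (Gini, 1-SE pruned)\n")
  print(x$fit)
  invisible(x)
}

#' @method summary cnv_cart
#' @export
summary.cnv_cart <- function(object, ...) {
  cat("1-SE pruned classification tree; cp table:\n")
  print(object$cptable)
  invisible(object)
}

#' @export
predict.cnv_cart <- function(object, newdata, ...) {
  df <- newdata[, intersect(feature_columns(), names(newdata)), drop = FALSE]
  if ("overlap_pattern" %in% names(df)) {
    df$overlap_pattern <- factor(df$overlap_pattern,
                                 levels = c("None", "GG", "LL", "GL"))
  }
  as.character(predict(object$fit, newdata = df, type = "class"))
}

#' Root split feature of a fitted CART model
#' @param model a `cnv_cart`.
#' @return character scalar, or NA for a stump with no split.
#' @export
cart_root_feature <- function(model) {
  fr <- model$fit$frame
  if (nrow(fr) == 0 || fr$var[1] == "<leaf>") return(NA_character_)
  as.character(fr$var[1])
}

#' Train a random forest classifier
#'
#' Bootstrap-resampled Gini trees with a random feature subset per split
#' (default `floor(sqrt(p))`); majority vote; per-feature total
#' Gini-decrease importance.
#'
#' @inheritParams train_cart
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @return object of class `cnv_forest`.
#' @export
train_rf <- function(features, labels, n_trees = 500, seed = 1L, mtry = NULL) {
  df <- prepare_training_frame(features, labels)
  p <- ncol(df) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fit <- with_seed(seed, {
    randomForest::randomForest(.label ~ ., data = df, ntree = n_trees,
                               mtry = mtry, importance = FALSE)
  })
  structure(list(fit = fit, seed = seed), class = "cnv_forest")
}

#' @export
print.cnv_forest <- function(x, ...) {
  cat("CNV/CNA random forest (", x$fit$ntree, " trees, mtry ",
      x$fit$mtry, ")\n", sep = "")
  imp <- gini_importance(x)
  top <- utils::head(imp[order(-imp$gini_decrease), ], 5)
  cat("top features by Gini decrease:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
predict.cnv_forest <- function(object, newdata, ...) {
  df <- newdata[, intersect(feature_columns(), names(newdata)), drop = FALSE]
  if ("overlap_pattern" %in% names(df)) {
    df$overlap_pattern <- factor(df$overlap_pattern,
                                 levels = c("None", "GG", "LL", "GL"))
  }
  as.character(predict(object$fit, newdata = df, type = "response"))
}

#' Per-feature Gini importance of a forest
#' @param model a `cnv_forest`.
#' @return data.frame `feature`, `gini_decrease`, in model column order.
#' @export
gini_importance <- function(model) {
  imp <- randomForest::importance(model$fit)
  data.frame(feature = rownames(imp),
             gini_decrease = imp[, "MeanDecreaseGini"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate logistic screen of every feature
#'
#' One single-predictor logistic regression per feature against CNV
#' status, with a likelihood-ratio p-value against the intercept-only
#' model. Multi-level factors contribute one beta per non-reference level
#' but a single LRT p. Constant features are flagged with p = 1;
#' non-convergence (e.g. perfect separation) is flagged, not raised.
#'
#' @param features feature matrix.
#' @param labels "CNV"/"CNA" per row.
#' @return data.frame `feature`, `term`, `beta`, `p_value`, `converged`.
#' @export
univariate_screen <- function(features, labels) {
  y <- as.integer(as.character(labels) == "CNV")
  rows <- list()
  for (f in intersect(feature_columns(), names(features))) {
    x <- features[[f]]
    if (f == "overlap_pattern") {
      x <- factor(x, levels = intersect(c("None", "GG", "LL", "GL"), unique(x)))
    }
    if (length(unique(x)) < 2) {
      rows[[f]] <- data.frame(feature = f, term = f, beta = NA_real_,
                              p_value = 1, converged = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          sep_warn <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    null_dev <- fit$null.deviance
    lrt <- null_dev - fit$deviance
    df <- fit$df.null - fit$df.residual
    p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
    co <- stats::coef(fit)[-1]
    term <- sub("^x", "", names(co))
    term[term == ""] <- f
    rows[[f]] <- data.frame(feature = f,
                            term = ifelse(term == f | term == "x", f,
                                          paste0(f, ":", term)),
                            beta = as.numeric(co), p_value = p,
                            converged = fit$converged && !sep_warn &&
                              max(abs(fit$linear.predictors)) < 15,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate predictions against truth labels
#'
#' CNV is the positive class. Reports the confusion counts, pooled
#' accuracy, standard per-class recalls, predictive values, and per-tumor
#' accuracies with their median.
#'
#' @param predictions,truths character vectors of "CNV"/"CNA".
#' @param sample_ids sample of each candidate (for per-tumor accuracy).
#' @return object of class `cnv_eval`.
#' @export
evaluate <- function(predictions, truths, sample_ids = NULL) {
  n <- length(predictions)
  if (n == 0 || length(truths) != n) stop("empty or misaligned input")
  predictions <- as.character(predictions); truths <- as.character(truths)
  tp <- sum(predictions == "CNV" & truths == "CNV")
  tn <- sum(predictions == "CNA" & truths == "CNA")
  fp <- sum(predictions == "CNV" & truths == "CNA")
  fn <- sum(predictions == "CNA" & truths == "CNV")
  per_tumor <- NULL; per_tumor_median <- NA_real_
  if (!is.null(sample_ids)) {
    per_tumor <- tapply(predictions == truths, sample_ids, mean)
    per_tumor_median <- stats::median(per_tumor)
  }
  structure(list(
    counts = c(tn = tn, fn = fn, fp = fp, tp = tp),
    accuracy = (tn + tp) / n,
    sensitivity_std = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity_std = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    per_tumor = per_tumor, per_tumor_median = per_tumor_median),
    class = "cnv_eval")
}

#' @export
print.cnv_eval <- function(x, ...) {
  cat("CNV/CNA classification evaluation (positive class: CNV)\n")
  cat(sprintf("  counts: TN %d  FN %d  FP %d  TP %d\n",
              x$counts["tn"], x$counts["fn"], x$counts["fp"], x$counts["tp"]))
  cat(sprintf("  accuracy %.3f  sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
              x$accuracy, x$sensitivity_std, x$specificity_std,
              x$ppv, x$npv))
  if (!is.null(x$per_tumor)) {
    cat(sprintf("  per-tumor median accuracy %.3f over %d tumors\n",
                x$per_tumor_median, length(x$per_tumor)))
  }
  invisible(x)
}
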