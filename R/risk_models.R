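#' Assemble per-sample risk features
#'
#' Joins hotspot mutation burden with personal risk factors. Burden is the
#' count of a sample's records inside the selected panel's windows
#' (1-based inclusive). Feature sets mirror the three combinations used in
#' burden-based risk modeling: MIBC hotspots + risk factors, NMIBC hotspots
#' + risk factors, or risk factors only. Rows with missing age or sex are
#' dropped with a message; missing smoking status sets both one-hot columns
#' to 0 and a `smoking_missing` indicator to 1.
#'
#' @param catalogs a `mutation_catalog` or list of them (pooled); every
#'   clinical sample must belong to the cohort, possibly with zero records.
#' @param panels named list of `window_panel`s, e.g.
#'   `list(mibc = ..., nmibc = ...)`; panels not needed by `feature_set`
#'   may be omitted.
#' @param clinical a `clinical_table` (see [read_clinical()]).
#' @param feature_set one of `"mibc+risk"`, `"nmibc+risk"`, `"risk_only"`.
#' @return data.frame of class `risk_feature_table`: `sample_id`, `label`
#'   (factor low/high), burden column (unless risk only), `age`,
#'   `sex_male`, `smoking_current`, `smoking_former`, `smoking_missing`.
#' @export
assemble_features <- function(catalogs, panels, clinical,
                              feature_set = c("mibc+risk", "nmibc+risk", "risk_only")) {
  feature_set <- match.arg(feature_set)
  if (inherits(catalogs, "mutation_catalog")) catalogs <- list(catalogs)
  rec <- do.call(rbind, lapply(catalogs, function(cc) cc$records))
  cl <- as.data.frame(clinical)
  keep <- !is.na(cl$age) & !is.na(cl$sex) & cl$sex %in% c("male", "female")
  if (any(!keep)) {
    message("assemble_features: dropped ", sum(!keep),
            " sample(s) with missing age or sex")
    cl <- cl[keep, , drop = FALSE]
  }
  out <- data.frame(
    sample_id = cl$sample_id,
    label = factor(cl$risk_label, levels = c("low", "high")),
    age = as.numeric(cl$age),
    sex_male = as.integer(cl$sex == "male"),
    smoking_current = as.integer(!is.na(cl$smoking) & cl$smoking == "current"),
    smoking_former = as.integer(!is.na(cl$smoking) & cl$smoking == "former"),
    smoking_missing = as.integer(is.na(cl$smoking) | cl$smoking == "unknown")
  )
  if (any(is.na(out$label))) stop("risk_label must be 'high' or 'low' for every sample")
  if (feature_set != "risk_only") {
    key <- sub("\\+risk$", "", feature_set)
    if (is.null(panels[[key]])) stop("panels must contain a '", key, "' panel")
    w <- panels[[key]]$windows
    burden <- integer(nrow(out))
    if (!is.null(rec) && nrow(rec) && nrow(w)) {
      hits <- .overlap_pairs(rec$chrom, rec$pos, rec$pos, w$chrom, w$start, w$end)
      if (nrow(hits)) {
        tab <- table(factor(rec$sample_id[hits$q], levels = out$sample_id))
        burden <- as.integer(tab)
      }
    }
    out[[paste0("hotspot_burden_", key)]] <- burden
  }
  class(out) <- c("risk_feature_table", "data.frame")
  out
}

#' Stratified 70/30 train/test split
#'
#' Random split stratified by label: per label, `floor(train_frac * n)`
#' rows go to training. Deterministic given `seed`.
#'
#' @param table a `risk_feature_table` (any data.frame with a `label`
#'   column containing both classes).
#' @param train_frac training fraction in (0, 1) (default 0.7).
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data.frames (disjoint, union = all
#'   rows).
#' @export
split_train_test <- function(table, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac <= 1)
  labs <- table$label
  tab <- table(labs)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("both labels need at least 2 rows to split")
  }
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(levels(labs), function(lv) {
    idx <- which(labs == lv)
    sample(idx, floor(train_frac * length(idx)))
  }), use.names = FALSE)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  if (length(test_idx) == 0L) stop("train_frac leaves an empty test set")
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE])
}

.feature_matrix <- function(tbl) {
  drop_cols <- c("sample_id", "label")
  as.matrix(tbl[, setdiff(names(tbl), drop_cols), drop = FALSE])
}

.scale_apply <- function(x, center, scale) {
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' Fit a risk classifier and score the test set
#'
#' Fits one of three model families on standardized features (train
#' mean/sd only) and scores test samples with the class probability of
#' "high" risk. Hyperparameters are fixed, ecosystem-typical defaults:
#' logistic = L2-regularized (ridge) with penalty chosen by 5-fold CV;
#' neural net = one hidden layer of 5 logistic units; random forest = 500
#' trees with sqrt(p) candidate features per split. Non-convergence of the
#' neural net is reported in the result, not thrown.
#'
#' @param train,test data.frames from [split_train_test()].
#' @param model_type `"logistic"`, `"neural_net"` or `"random_forest"`.
#' @param seed integer seed for CV folds, weight init and tree bootstraps.
#' @return An object of class `model_report`: `model_type`, `auc`,
#'   `roc_points`, `scores`, `test_labels`, `converged`, plus the fitted
#'   model and the scaling needed to score new data.
#' @export
fit_and_score <- function(train, test,
                          model_type = c("logistic", "neural_net", "random_forest"),
                          seed = 1L) {
  model_type <- match.arg(model_type)
  x_tr <- .feature_matrix(train)
  x_te <- .feature_matrix(test)
  center <- colMeans(x_tr)
  scl <- apply(x_tr, 2L, sd)
  scl[scl == 0] <- 1
  xs_tr <- .scale_apply(x_tr, center, scl)
  xs_te <- .scale_apply(x_te, center, scl)
  y_tr <- train$label == "high"
  converged <- TRUE
  set.seed(as.integer(seed))
  if (model_type == "logistic") {
    fit <- glmnet::cv.glmnet(xs_tr, factor(y_tr), family = "binomial",
                             alpha = 0, nfolds = 5L)
    score_fun <- function(xs) {
      as.numeric(predict(fit, newx = xs, s = "lambda.min", type = "response"))
    }
  } else if (model_type == "neural_net") {
    fit <- nnet::nnet(xs_tr, as.numeric(y_tr), size = 5L, decay = 0.01,
                      maxit = 500L, entropy = TRUE, trace = FALSE)
    converged <- !isTRUE(fit$convergence == 1L)
    score_fun <- function(xs) as.numeric(predict(fit, xs))
  } else {
    fit <- randomForest::randomForest(
      xs_tr, factor(ifelse(y_tr, "high", "low"), levels = c("low", "high")),
      ntree = 500L, mtry = max(1L, floor(sqrt(ncol(xs_tr)))))
    score_fun <- function(xs) predict(fit, xs, type = "prob")[, "high"]
  }
  scores <- unname(score_fun(xs_te))
  ra <- roc_auc(scores, test$label == "high")
  structure(list(model_type = model_type, auc = ra$auc,
                 roc_points = ra$roc_points, scores = scores,
                 test_labels = test$label, converged = converged,
                 fit = fit, center = center, scale = scl,
                 feature_names = colnames(x_tr), score_fun = score_fun),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: %s, test AUC = %.4f%s\n", x$model_type, x$auc,
              if (!x$converged) " (did not converge)" else ""))
  invisible(x)
}

#' ROC curve and AUC by pairwise concordance
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counted 1/2 — computed from ranks, which is exactly the
#' pairwise-concordance (Mann-Whitney) formulation. ROC points are taken
#' at thresholds between distinct scores; the curve starts at (0,0), ends
#' at (1,1), and is monotone non-decreasing in both coordinates.
#'
#' @param scores numeric scores (higher = more "high risk").
#' @param labels logical/0-1 vector (TRUE/1 = positive class).
#' @return list with `roc_points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  }
  list(roc_points = roc, auc = auc)
}

#' Permutation variable importance on held-out data
#'
#' Mean decrease in test AUC when a feature column is permuted, averaged
#' over `n_perm` seeded permutations. Model-honest and comparable across
#' burden scales; primarily intended for the random-forest model but
#' applicable to any fitted report.
#'
#' @param report a `model_report` from [fit_and_score()].
#' @param test the test data.frame the report was scored on.
#' @param n_perm permutations per feature (default 20).
#' @param seed integer seed.
#' @return Named numeric vector of importances, sorted descending.
#' @export
variable_importance <- function(report, test, n_perm = 20L, seed = 1L) {
  x_te <- .feature_matrix(test)
  labels <- test$label == "high"
  base_auc <- roc_auc(unname(report$score_fun(
    .scale_apply(x_te, report$center, report$scale))), labels)$auc
  set.seed(as.integer(seed))
  imp <- vapply(seq_len(ncol(x_te)), function(j) {
    drops <- vapply(seq_len(n_perm), function(b) {
      xp <- x_te
      xp[, j] <- xp[sample(nrow(xp)), j]
      auc_p <- roc_auc(unname(report$score_fun(
        .scale_apply(xp, report$center, report$scale))), labels)$auc
      base_auc - auc_p
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  names(imp) <- colnames(x_te)
  sort(imp, decreasing = TRUE)
}
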