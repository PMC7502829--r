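
# --- internal helpers -------------------------------------------------------

as_label <- function(y) {
  y <- as.integer(as.character(y))
  if (!all(y %in% c(-1L, 1L))) stop("labels must be coded +1 / -1")
  factor(y, levels = c(-1, 1))
}

std_fit <- function(X) {
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  list(center = colMeans(X), scale = s)
}

std_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

fit_linear_svm <- function(X, y, cost = 1) {
  e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
             fitted = FALSE)
}

# |weight vector| entries of a fitted linear-kernel SVM, named by feature.
svm_weights <- function(model, feature_names) {
  w <- drop(crossprod(model$coefs, model$SV))
  stats::setNames(abs(w), feature_names)
}

svm_predict_label <- function(model, X) {
  as.integer(as.character(predict(model, X)))
}

# LOOCV accuracy (proportion) via libsvm's internal cross-validation; for
# leave-one-out the fold assignment is exhaustive, so the result is
# deterministic.
inner_loocv_accuracy <- function(X, y, cost = 1) {
  m <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                  fitted = FALSE, cross = nrow(X))
  m$tot.accuracy / 100
}

confusion_counts <- function(pred, truth, positive = -1L) {
  c(tp = sum(pred == positive & truth == positive),
    tn = sum(pred != positive & truth != positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

model_report <- function(pred, truth, positive = -1L) {
  cc <- confusion_counts(pred, truth, positive)
  structure(list(
    accuracy = (cc[["tp"]] + cc[["tn"]]) / sum(cc),
    sensitivity = if (cc[["tp"]] + cc[["fn"]] > 0)
      cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]) else NA_real_,
    specificity = if (cc[["tn"]] + cc[["fp"]] > 0)
      cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]) else NA_real_,
    confusion = cc, predictions = pred, truth = truth,
    positive_class = positive, ci = NULL, permutation_p = NA_real_),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" (95%% CI %.1f-%.1f%%)", 100 * ci[1], 100 * ci[2])
  cat(sprintf("<model_report> accuracy %.1f%%%s, sensitivity %.1f%%, specificity %.1f%% (positive class: %d = not recovered)\n",
              100 * x$accuracy, fmt_ci(x$ci$accuracy),
              100 * x$sensitivity, 100 * x$specificity, x$positive_class))
  if (!is.na(x$permutation_p))
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  invisible(x)
}

# --- recursive feature elimination -----------------------------------------

#' SVM recursive feature elimination
#'
#' Fits a linear-kernel maximum-margin classifier on standardized features,
#' repeatedly removes the feature with the smallest absolute weight, and
#' retains the nested subset whose leave-one-out cross-validated accuracy
#' is maximal (ties broken toward fewer features). Weights of the final
#' model are max-normalized so the top-ranked feature has weight 1.
#'
#' @param X feature matrix (subjects x features, column names required).
#' @param y class labels, +1 (improved) / -1 (not recovered).
#' @param cost SVM regularization constant C (default 1).
#' @return An object of class `rfe_result`: `elimination_order`
#'   (worst-first), `cv_accuracy` (per subset size), `optimal` (feature
#'   names), `weights` (normalized, max = 1).
#' @export
rfe_select <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features for elimination")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  y <- as_label(y)
  if (nlevels(droplevels(y)) < 2) stop("single-class labels")
  Xs <- std_apply(X, std_fit(X))

  surviving <- colnames(X)
  removed <- character(0)
  path <- vector("list", ncol(X))
  accuracy <- numeric(ncol(X))
  for (size in seq(ncol(X), 1)) {
    path[[size]] <- surviving
    accuracy[size] <- inner_loocv_accuracy(Xs[, surviving, drop = FALSE],
                                           y, cost)
    if (size == 1) break
    m <- fit_linear_svm(Xs[, surviving, drop = FALSE], y, cost)
    w <- svm_weights(m, surviving)
    worst <- names(which.min(w))
    removed <- c(removed, worst)
    surviving <- setdiff(surviving, worst)
  }
  best_size <- which(accuracy == max(accuracy))[1]  # smallest size wins ties
  optimal <- path[[best_size]]
  final <- fit_linear_svm(Xs[, optimal, drop = FALSE], y, cost)
  w <- svm_weights(final, optimal)
  structure(list(
    elimination_order = c(removed, surviving),
    cv_accuracy = stats::setNames(accuracy, seq_along(accuracy)),
    optimal = optimal,
    weights = sort(w / max(w), decreasing = TRUE),
    cost = cost), class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d -> %d features, inner LOOCV accuracy %.1f%%\n",
              length(x$elimination_order), length(x$optimal),
              100 * max(x$cv_accuracy)))
  invisible(x)
}

# --- cross-validated classification ----------------------------------------

#' Leave-one-subject-out cross-validated classification
#'
#' For every subject, a linear SVM is trained on the remaining n - 1
#' (feature standardization refit inside each fold) and tested on the
#' holdout; accuracy, sensitivity and specificity are computed from the
#' pooled predictions. Sensitivity is anchored to the -1 (not-recovered)
#' class as the clinically positive class. With `refit_rfe = TRUE` the
#' whole feature-selection procedure is re-run inside each training fold
#' (no selection leakage); otherwise the fixed `subset` is used.
#'
#' @param X feature matrix (subjects x features).
#' @param y labels +1 / -1.
#' @param subset character vector of feature names (ignored when
#'   `refit_rfe = TRUE`).
#' @param refit_rfe nest [rfe_select()] inside each fold.
#' @param cost SVM regularization constant.
#' @return A `model_report`.
#' @export
loocv_classify <- function(X, y, subset = NULL, refit_rfe = FALSE,
                           cost = 1) {
  X <- as.matrix(X)
  y <- as_label(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects for LOOCV")
  if (nlevels(droplevels(y)) < 2) stop("single-class labels")
  if (!refit_rfe && (is.null(subset) || length(subset) == 0))
    stop("feature subset is empty")
  if (!refit_rfe && !all(subset %in% colnames(X)))
    stop("subset features missing from X: ",
         paste(setdiff(subset, colnames(X)), collapse = ", "))
  pred <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- droplevels(y[-i])
    std <- std_fit(Xtr)
    Xtr <- std_apply(Xtr, std)
    Xte <- std_apply(X[i, , drop = FALSE], std)
    sub <- if (refit_rfe) rfe_select(Xtr, ytr, cost)$optimal else subset
    m <- fit_linear_svm(Xtr[, sub, drop = FALSE], ytr, cost)
    pred[i] <- svm_predict_label(m, Xte[, sub, drop = FALSE])
  }
  model_report(pred, as.integer(as.character(y)))
}

#' Repeated random-subsampling validation
#'
#' Repeatedly holds out `n_test` randomly chosen subjects, trains on the
#' rest (standardization refit per split) and records the test accuracy;
#' the 95% CI is the 2.5/97.5 percentile of the accuracy distribution.
#' With `exhaustive = TRUE` and `n_test = 1`, every subject is held out
#' exactly once (equivalent to LOOCV).
#'
#' @param X,y,subset,cost as in [loocv_classify()].
#' @param n_test held-out test-set size (1-8 in the shipped analyses).
#' @param reps number of random splits (>= 100 recommended).
#' @param seed integer seed.
#' @param exhaustive enumerate all subjects once instead of sampling.
#' @return list with `accuracies`, `mean`, `ci` (2.5/97.5 percentiles).
#' @export
repeated_subsampling <- function(X, y, subset, n_test = 1L, reps = 1000L,
                                 seed = 1L, cost = 1, exhaustive = FALSE) {
  X <- as.matrix(X)
  y <- as_label(y)
  n <- nrow(X)
  if (n_test >= n) stop("n_test must be smaller than the number of subjects")
  if (exhaustive && n_test == 1L) reps <- n
  acc <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      test <- if (exhaustive && n_test == 1L) r else sample.int(n, n_test)
      ytr <- droplevels(y[-test])
      if (nlevels(ytr) < 2) { acc[r] <- NA; next }
      std <- std_fit(X[-test, , drop = FALSE])
      m <- fit_linear_svm(
        std_apply(X[-test, , drop = FALSE], std)[, subset, drop = FALSE],
        ytr, cost)
      p <- svm_predict_label(
        m, std_apply(X[test, , drop = FALSE], std)[, subset, drop = FALSE])
      acc[r] <- mean(p == as.integer(as.character(y[test])))
    }
  })
  acc <- acc[!is.na(acc)]
  list(accuracies = acc, mean = mean(acc),
       ci = unname(quantile(acc, c(0.025, 0.975))), n_test = n_test)
}

#' Subsampling validation profile over test-set sizes 1..8
#'
#' @inheritParams repeated_subsampling
#' @param n_grid test-set sizes to profile.
#' @return data.frame with one row per `n_test`: mean accuracy and CI.
#' @export
subsampling_profile <- function(X, y, subset, n_grid = 1:8, reps = 200L,
                                seed = 1L, cost = 1) {
  rows <- lapply(n_grid, function(nt) {
    r <- repeated_subsampling(X, y, subset, n_test = nt, reps = reps,
                              seed = seed + nt, cost = cost)
    data.frame(n_test = nt, mean_accuracy = r$mean,
               ci_lower = r$ci[1], ci_upper = r$ci[2])
  })
  do.call(rbind, rows)
}

#' Permutation test of classification performance
#'
#' Class labels are randomly reassigned (class counts preserved) and the
#' classification accuracy recomputed per permutation; the p-value is
#' (1 + #\{permuted >= observed\}) / (1 + n_perm) (add-one smoothing). In
#' `"full"` mode the entire pipeline — feature elimination and subset-size
#' choice — is refit for every permutation, so selection optimism cancels
#' between observed and null; `"fast"` mode keeps the observed feature
#' subset fixed and only recomputes the LOOCV accuracy (cheaper, slightly
#' anticonservative; reports are labelled with the mode).
#'
#' @param X,y,cost as in [loocv_classify()].
#' @param subset fixed feature subset for `"fast"` mode; when NULL it is
#'   selected once from the observed labels.
#' @param n_perm number of permutations (the shipped analyses use 5000;
#'   smaller values are used in fast reruns).
#' @param seed integer seed.
#' @param mode `"fast"` or `"full"`.
#' @return list with `p`, `observed`, `perm_accuracies`, `mode`, `n_perm`.
#' @export
permutation_test <- function(X, y, subset = NULL, n_perm = 5000L,
                             seed = 1L, mode = c("fast", "full"),
                             cost = 1) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  X <- as.matrix(X)
  y <- as_label(y)
  stat <- if (mode == "full") {
    function(yy) {
      rs <- rfe_select(X, yy, cost)
      loocv_classify(X, yy, rs$optimal, cost = cost)$accuracy
    }
  } else {
    if (is.null(subset)) subset <- rfe_select(X, y, cost)$optimal
    function(yy) loocv_classify(X, yy, subset, cost = cost)$accuracy
  }
  observed <- stat(y)
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) perm[b] <- stat(sample(y))
  })
  list(p = (1 + sum(perm >= observed)) / (1 + n_perm),
       observed = observed, perm_accuracies = perm,
       mode = mode, n_perm = n_perm)
}

# --- support-vector regression ---------------------------------------------

#' LOOCV support-vector regression of a continuous score
#'
#' Predicts a continuous neuropsychological score from the (fixed) feature
#' subset by epsilon-SVR under leave-one-out cross-validation and reports
#' Spearman's correlation between predicted and actual scores with a
#' subject-bootstrap percentile CI. The subset is taken as given (the
#' classification-trained features are reused without re-selection).
#'
#' @param X feature matrix.
#' @param scores continuous outcome (e.g. follow-up TMT-A seconds).
#' @param subset feature names to use.
#' @param cost,epsilon SVR hyperparameters (C = 1, epsilon = 0.1).
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `regression_report`: `predicted`, `actual`,
#'   `rho`, `ci`, `p`.
#' @export
svr_predict <- function(X, scores, subset, cost = 1, epsilon = 0.1,
                        n_boot = 1000L, seed = 1L) {
  X <- as.matrix(X)
  scores <- as.numeric(scores)
  if (sd(scores) == 0) stop("scores are constant; correlation undefined")
  stopifnot(length(scores) == nrow(X), length(subset) >= 1)
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    std <- std_fit(X[-i, , drop = FALSE])
    m <- e1071::svm(
      std_apply(X[-i, , drop = FALSE], std)[, subset, drop = FALSE],
      scores[-i], type = "eps-regression", kernel = "linear",
      cost = cost, epsilon = epsilon, scale = FALSE, fitted = FALSE)
    pred[i] <- predict(
      m, std_apply(X[i, , drop = FALSE], std)[, subset, drop = FALSE])
  }
  rho <- cor(pred, scores, method = "spearman")
  p <- suppressWarnings(
    cor.test(pred, scores, method = "spearman", exact = FALSE)$p.value)
  boot <- with_seed(seed, replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(pred[idx], scores[idx], method = "spearman"))
  }))
  structure(list(predicted = pred, actual = scores, rho = rho,
                 ci = unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
                 p = p), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> Spearman rho = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
    x$rho, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

# --- domain combination -----------------------------------------------------

#' Build a cytokine feature matrix from a serum table
#'
#' @param cytokines data.frame with `id` and analyte columns (IL1b, IL6,
#'   CCL2).
#' @param ids subject ids selecting and ordering the rows.
#' @return `feature_matrix` with domain `"cytokine"`.
#' @export
cytokine_features <- function(cytokines, ids) {
  m <- match(ids, cytokines$id)
  if (anyNA(m))
    stop("cytokines missing for subject(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  analytes <- setdiff(names(cytokines), "id")
  X <- as.matrix(cytokines[m, analytes, drop = FALSE])
  rownames(X) <- ids
  structure(X,
            feature_info = data.frame(feature = analytes, tract = NA,
                                      tract_name = NA, direction = NA,
                                      extent = NA, domain = "cytokine"),
            class = c("feature_matrix", "matrix"))
}

#' Combine imaging and cytokine feature domains
#'
#' Column-wise concatenation after standardizing each domain separately,
#' so neither domain dominates the margin by scale; column metadata records
#' the domain of every feature. An empty cytokine table returns the FA
#' matrix unchanged.
#'
#' @param fa_features FA cluster `feature_matrix`.
#' @param cytokine_features_ cytokine `feature_matrix` (same subjects, same
#'   order), or NULL/zero columns.
#' @return Combined `feature_matrix`.
#' @export
combine_domains <- function(fa_features, cytokine_features_) {
  if (is.null(cytokine_features_) || ncol(cytokine_features_) == 0)
    return(fa_features)
  if (!identical(rownames(fa_features), rownames(cytokine_features_))) {
    diff <- union(setdiff(rownames(fa_features),
                          rownames(cytokine_features_)),
                  setdiff(rownames(cytokine_features_),
                          rownames(fa_features)))
    stop("subject mismatch between domains: ",
         paste(if (length(diff)) diff else "row order differs",
               collapse = ", "))
  }
  zf <- std_apply(unclass(fa_features), std_fit(unclass(fa_features)))
  zc <- std_apply(unclass(cytokine_features_),
                  std_fit(unclass(cytokine_features_)))
  out <- cbind(zf, zc)
  structure(out,
            feature_info = rbind(feature_info(fa_features),
                                 feature_info(cytokine_features_)),
            class = c("feature_matrix", "matrix"))
}

# --- frozen model + external validation ------------------------------------

#' Freeze a trained prognostic model for external validation
#'
#' Stores the standardization constants, the selected feature subset with
#' its normalized weights, and the SVM trained once on the full training
#' cohort. Applying the frozen model involves no refitting of any kind.
#'
#' @param X training feature matrix.
#' @param y training labels.
#' @param rfe optional precomputed [rfe_select()] result.
#' @param cost SVM regularization constant.
#' @return An object of class `frozen_model`.
#' @export
finalize_model <- function(X, y, rfe = NULL, cost = 1) {
  X <- as.matrix(X)
  y <- as_label(y)
  if (is.null(rfe)) rfe <- rfe_select(X, y, cost)
  std <- std_fit(X)
  Xs <- std_apply(X, std)
  m <- fit_linear_svm(Xs[, rfe$optimal, drop = FALSE], y, cost)
  structure(list(svm = m, subset = rfe$optimal, weights = rfe$weights,
                 std = std, cost = cost, rfe = rfe,
                 n_train = nrow(X)), class = "frozen_model")
}

#' Apply a frozen model to an external replicate cohort
#'
#' The replicate features must have been cut with the original cohort's
#' cluster catalogue and normative model; the frozen model (selected
#' features, weights, standardization, SVM) is applied exactly once with
#' no refitting, and performance is reported as in [loocv_classify()].
#' Identical inputs give bit-identical reports.
#'
#' @param model a [finalize_model()] result.
#' @param X_rep replicate feature matrix (must contain every selected
#'   feature).
#' @param y_rep replicate labels +1 / -1.
#' @return A `model_report`.
#' @export
external_validate <- function(model, X_rep, y_rep) {
  stopifnot(inherits(model, "frozen_model"))
  X_rep <- as.matrix(X_rep)
  missing <- setdiff(names(model$std$center), colnames(X_rep))
  if (length(missing) > 0)
    stop("replicate cohort lacks catalogue feature(s): ",
         paste(missing, collapse = ", "))
  Xs <- std_apply(X_rep[, names(model$std$center), drop = FALSE],
                  model$std)
  pred <- svm_predict_label(model$svm,
                            Xs[, model$subset, drop = FALSE])
  model_report(pred, as.integer(as.character(as_label(y_rep))))
}

# --- importance filtering and group statistics ------------------------------

#' Two-sample group comparison with normality-gated test choice
#'
#' Shapiro-Wilk normality at alpha = .05 in each group selects an
#' independent two-sample t-test (both normal) or a Wilcoxon rank-sum test
#' (mid-ranks for ties); Cohen's d is computed from the pooled SD and a
#' percentile-bootstrap CI of the mean difference is attached.
#'
#' @param values numeric measurements.
#' @param groups two-level grouping (factor or character).
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed.
#' @return list with `test`, `p`, `d`, `mean_diff`, `ci`, `n`.
#' @export
group_stats <- function(values, groups, n_boot = 2000L, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per group")
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups")
  normal <- function(z) {
    if (sd(z) == 0) return(FALSE)
    shapiro.test(z)$p.value >= 0.05
  }
  use_t <- normal(x) && normal(y)
  p <- if (use_t) t.test(x, y, var.equal = TRUE)$p.value
  else suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  sp <- sqrt(((length(x) - 1) * v1 + (length(y) - 1) * v2) /
               (length(x) + length(y) - 2))
  md <- mean(x) - mean(y)
  d <- if (sp == 0) 0 else md / sp
  ci <- with_seed(seed, {
    boot <- replicate(n_boot, {
      mean(sample(x, replace = TRUE)) - mean(sample(y, replace = TRUE))
    })
    unname(quantile(boot, c(0.025, 0.975)))
  })
  list(test = if (use_t) "t" else "wilcoxon", p = p, d = d,
       mean_diff = md, ci = ci,
       n = c(length(x), length(y)), groups = levels(groups))
}

#' Filter catalogue clusters by model weight and group differences
#'
#' Keeps the clusters whose normalized RFE weight ranks in the top 25% of
#' the selected features (count = floor(0.25 x number of selected
#' features)), then retains only those whose feature differs between
#' not-recovered and recovered patients AND between not-recovered patients
#' and controls at the Bonferroni-adjusted level 0.05 / m (m = number of
#' top-weight clusters), using [group_stats()].
#'
#' @param rfe an [rfe_select()] result.
#' @param X feature matrix covering patients and controls.
#' @param groups per-subject group: `"not_recovered"`, `"recovered"` or
#'   `"control"`.
#' @return list with `kept` (feature names), `top` (top-weight features),
#'   `alpha_adjusted`, and the per-feature test table.
#' @export
importance_filter <- function(rfe, X, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X))
  need <- c("not_recovered", "recovered", "control")
  for (g in need) if (!any(groups == g)) stop("empty group: ", g)
  m <- max(1L, floor(0.25 * length(rfe$optimal)))
  top <- names(sort(rfe$weights[rfe$optimal], decreasing = TRUE))[seq_len(m)]
  alpha_adj <- 0.05 / m
  tests <- lapply(top, function(f) {
    v <- X[, f]
    nr_rec <- groups %in% c("not_recovered", "recovered")
    nr_ctl <- groups %in% c("not_recovered", "control")
    p1 <- group_stats(v[nr_rec], groups[nr_rec])$p
    p2 <- group_stats(v[nr_ctl], groups[nr_ctl])$p
    data.frame(feature = f, p_vs_recovered = p1, p_vs_controls = p2)
  })
  tab <- do.call(rbind, tests)
  kept <- tab$feature[tab$p_vs_recovered < alpha_adj &
                        tab$p_vs_controls < alpha_adj]
  list(kept = kept, top = top, alpha_adjusted = alpha_adj, tests = tab)
}
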