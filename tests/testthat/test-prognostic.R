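sep_data <- function(n = 30, p = 4, gap = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1] <- X[, 1] * 0.3 + y * gap / 2
  list(X = X, y = y)
}

test_that("RFE ranks, eliminates and max-normalizes weights", {
  d <- sep_data(n = 24, p = 5)
  r <- rfe_select(d$X, d$y)
  expect_equal(max(r$weights), 1)          # top weight is 1 by convention
  expect_equal(unname(r$weights[1]), 1)
  expect_setequal(r$elimination_order, colnames(d$X))  # a permutation
  expect_length(r$elimination_order, 5)
  expect_true(all(r$cv_accuracy >= 0 & r$cv_accuracy <= 1))
  expect_error(rfe_select(d$X, rep(1L, 24)), "single-class")
  expect_error(rfe_select(d$X[, 1, drop = FALSE], d$y), "2 features")
})

test_that("a perfectly separating feature survives elimination", {
  kept <- vapply(1:20, function(s) {
    d <- sep_data(n = 30, p = 21, gap = 6, seed = s)
    "f1" %in% rfe_select(d$X, d$y)$optimal
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("LOOCV is perfect on wide-margin data and chance on noise", {
  d <- sep_data(n = 24, p = 3, gap = 8)
  rep_ <- loocv_classify(d$X, d$y, subset = "f1")
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$confusion[c("fp", "fn")]), c(0L, 0L))

  inside <- vapply(1:50, function(s) {
    set.seed(s + 900)
    X <- matrix(rnorm(120 * 10), 120, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c(-1L, 1L), 60)
    acc <- loocv_classify(X, y, subset = colnames(X))$accuracy
    acc >= 0.35 && acc <= 0.65
  }, logical(1))
  expect_gte(mean(inside), 0.9)

  expect_error(loocv_classify(d$X, d$y, subset = character(0)), "empty")
})

test_that("LOOCV predictions are invariant to feature column order", {
  d <- sep_data(n = 20, p = 4, gap = 3, seed = 7)
  a <- loocv_classify(d$X, d$y, subset = c("f1", "f3"))
  b <- loocv_classify(d$X[, c(4, 3, 2, 1)], d$y, subset = c("f3", "f1"))
  expect_identical(a$predictions, b$predictions)
})

test_that("sensitivity is anchored to the not-recovered (-1) class", {
  truth <- c(-1L, -1L, -1L, 1L, 1L, 1L, 1L, 1L)
  pred <- c(-1L, -1L, 1L, 1L, 1L, 1L, -1L, 1L)
  rep_ <- faburden:::model_report(pred, truth)
  expect_equal(rep_$sensitivity, 2 / 3)   # -1 detected among true -1
  expect_equal(rep_$specificity, 4 / 5)
  expect_equal(rep_$accuracy,
               (rep_$confusion[["tp"]] + rep_$confusion[["tn"]]) / 8)
})

test_that("exhaustive size-1 subsampling equals LOOCV", {
  d <- sep_data(n = 18, p = 3, gap = 2, seed = 3)
  loo <- loocv_classify(d$X, d$y, subset = c("f1", "f2"))
  sub <- repeated_subsampling(d$X, d$y, c("f1", "f2"), n_test = 1,
                              seed = 1, exhaustive = TRUE)
  expect_equal(sub$mean, loo$accuracy)

  # an all-correct classifier has a degenerate CI at 100%
  d2 <- sep_data(n = 16, p = 2, gap = 10, seed = 4)
  sub2 <- repeated_subsampling(d2$X, d2$y, "f1", n_test = 2, reps = 120,
                               seed = 2)
  expect_equal(unname(sub2$ci), c(1, 1))
  expect_error(repeated_subsampling(d2$X, d2$y, "f1", n_test = 16),
               "smaller")
})

test_that("subsampling CIs tighten with more repetitions", {
  set.seed(11)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c(-1L, 1L), 20)
  X[, 1] <- X[, 1] + y * 1.2   # imperfect signal, accuracy ~80-90%
  w50 <- diff(repeated_subsampling(X, y, "f1", n_test = 5, reps = 50,
                                   seed = 5)$ci)
  w500 <- diff(repeated_subsampling(X, y, "f1", n_test = 5, reps = 500,
                                    seed = 5)$ci)
  expect_lte(w500, w50)
})

test_that("permutation p attains its add-one floor on separable data", {
  d <- sep_data(n = 20, p = 3, gap = 10, seed = 5)
  pt <- permutation_test(d$X, d$y, subset = "f1", n_perm = 99, seed = 3)
  expect_equal(pt$p, 1 / 100)
  expect_equal(pt$observed, 1)
})

test_that("permutation p is near uniform mid-range on null data", {
  ps <- vapply(1:10, function(s) {
    set.seed(s + 40)
    X <- matrix(rnorm(24 * 3), 24, 3, dimnames = list(NULL, paste0("f", 1:3)))
    y <- rep(c(-1L, 1L), 12)
    permutation_test(X, y, subset = colnames(X), n_perm = 99,
                     seed = s, mode = "fast")$p
  }, numeric(1))
  expect_gte(mean(ps >= 0.15 & ps <= 0.85), 0.8)
})

test_that("SVR recovers a linear score and rejects constant scores", {
  set.seed(21)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  score <- 30 + 8 * X[, 2] + rnorm(60, 0, 1)
  rr <- svr_predict(X, score, subset = colnames(X), n_boot = 100, seed = 2)
  expect_gte(rr$rho, 0.9)
  expect_lt(rr$p, 1e-6)
  expect_true(rr$ci[1] <= rr$rho && rr$rho <= rr$ci[2])
  expect_error(svr_predict(X, rep(5, 60), "f1"), "constant")
})

test_that("Spearman rho hits its sign bounds for monotone predictions", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(cor(x, x, method = "spearman"), 1)
  expect_equal(cor(x, rev(sort(x))[rank(x)], method = "spearman"), -1)
})

test_that("domain combination concatenates standardized blocks", {
  set.seed(31)
  ids <- sprintf("p%02d", 1:20)
  fa <- matrix(rnorm(20 * 53, 0.5, 0.02), 20, 53,
               dimnames = list(ids, sprintf("cl%02d", 1:53)))
  attr(fa, "feature_info") <- data.frame(feature = colnames(fa),
                                         tract = NA, tract_name = NA,
                                         direction = NA, extent = NA,
                                         domain = "fa")
  class(fa) <- c("feature_matrix", "matrix")
  cyt <- cytokine_features(
    data.frame(id = ids, IL1b = rnorm(20, 2.5), IL6 = rnorm(20, 1),
               CCL2 = rnorm(20, 250, 50)), ids)
  comb <- combine_domains(fa, cyt)
  expect_equal(ncol(comb), 56)   # 53 imaging + 3 cytokine features
  expect_equal(unname(colMeans(comb)), rep(0, 56), tolerance = 1e-12)
  expect_equal(table(feature_info(comb)$domain)[["cytokine"]], 3L)

  expect_identical(combine_domains(fa, NULL), fa)
  bad <- cyt; rownames(bad)[1] <- "zz"
  expect_error(combine_domains(fa, bad), "zz")
})

test_that("frozen external validation never refits", {
  d <- sep_data(n = 30, p = 4, gap = 5, seed = 8)
  frozen <- finalize_model(d$X, d$y)
  r1 <- external_validate(frozen, d$X, d$y)
  r2 <- external_validate(frozen, d$X, d$y)
  expect_identical(r1, r2)  # bit-identical reports

  # resubstitution bound: training data scores at least as well as LOOCV
  loo <- loocv_classify(d$X, d$y, frozen$subset)
  expect_gte(r1$accuracy, loo$accuracy)

  # label flip symmetry
  flipped <- external_validate(frozen, d$X, -d$y)
  expect_equal(flipped$accuracy, 1 - r1$accuracy)

  expect_error(external_validate(frozen, d$X[, 1:2], d$y), "lacks")
})

test_that("external validation tracks internal accuracy across seeds", {
  gaps <- vapply(1:12, function(s) {
    d <- sep_data(n = 40, p = 4, gap = 2.5, seed = s)
    r <- rfe_select(d$X, d$y)
    loo <- loocv_classify(d$X, d$y, r$optimal)
    d2 <- sep_data(n = 40, p = 4, gap = 2.5, seed = s + 1000)
    ext <- external_validate(finalize_model(d$X, d$y, r), d2$X, d2$y)
    abs(ext$accuracy - loo$accuracy)
  }, numeric(1))
  expect_lte(median(gaps), 0.15)
})

test_that("importance filter reproduces the top-25% and Bonferroni rules", {
  set.seed(41)
  n <- 45
  grp <- rep(c("not_recovered", "recovered", "control"), each = 15)
  X <- matrix(rnorm(n * 27), n, 27, dimnames = list(NULL, sprintf("w%02d", 1:27)))
  X[grp == "not_recovered", 1:3] <- X[grp == "not_recovered", 1:3] + 3
  w <- sort(runif(27, 0.1, 0.9), decreasing = TRUE)
  w[1] <- 1
  names(w) <- colnames(X)
  rfe <- structure(list(optimal = colnames(X), weights = w),
                   class = "rfe_result")
  out <- importance_filter(rfe, X, grp)
  expect_length(out$top, 6)                    # floor(0.25 * 27)
  expect_equal(out$alpha_adjusted, 0.05 / 6)
  expect_lt(out$alpha_adjusted, 0.00834)
  expect_true(all(out$kept %in% out$top))
  expect_error(importance_filter(rfe, X, rep("recovered", n)),
               "empty group")
})

test_that("importance filter keeps nothing on null cohorts", {
  empties <- vapply(1:20, function(s) {
    set.seed(s + 60)
    n <- 36
    grp <- rep(c("not_recovered", "recovered", "control"), each = 12)
    X <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(NULL, sprintf("w%02d", 1:12)))
    w <- stats::setNames(c(1, sort(runif(11), TRUE)), colnames(X))
    rfe <- structure(list(optimal = colnames(X), weights = w),
                     class = "rfe_result")
    length(importance_filter(rfe, X, grp)$kept) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})

test_that("group statistics gate the test on normality and report d", {
  set.seed(51)
  x <- rnorm(50); y <- rnorm(50, 1)
  g <- rep(c("a", "b"), each = 50)
  gs <- group_stats(c(x, y), g)
  expect_equal(gs$test, "t")
  expect_lt(abs(abs(gs$d) - 1), 0.35)
  expect_true(gs$ci[1] <= gs$mean_diff && gs$mean_diff <= gs$ci[2])

  # swapping group order flips the effect sign but not the p-value
  gs_rev <- group_stats(c(x, y), rep(c("b", "a"), each = 50))
  expect_equal(gs_rev$d, -gs$d)
  expect_equal(gs_rev$p, gs$p)

  ident <- group_stats(rep(c(1, 2, 3), 4), rep(c("a", "b"), each = 6))
  expect_equal(ident$d, 0)
  expect_gt(ident$p, 0.9)

  skewed <- c(rexp(40), rexp(40) + 0.5)
  expect_equal(group_stats(skewed, rep(c("a", "b"), each = 40))$test,
               "wilcoxon")
  expect_error(group_stats(rep(c(1, 1, 1, 2, 2, 2)), rep(c("a", "b"), each = 3)),
               "zero variance")
})
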