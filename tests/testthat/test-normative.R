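make_controls <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("c%02d", seq_len(n)),
             age = round(runif(n, 20, 60)),
             sex = rep_len(c(0L, 1L), n),
             education = round(runif(n, 6, 16)))
}

test_that("split_controls returns disjoint exhaustive matched halves", {
  cov <- make_controls(40)
  sp <- split_controls(cov, seed = 3)
  expect_length(intersect(sp$reference, sp$normal), 0)
  expect_setequal(c(sp$reference, sp$normal), cov$id)
  expect_equal(length(sp$reference), 20)

  # identical covariate pairs are separated one per half
  cov2 <- make_controls(10)
  cov2 <- rbind(cov2, transform(cov2, id = paste0(id, "_dup")))
  sp2 <- split_controls(cov2, seed = 1)
  for (i in 1:10) {
    pair <- c(cov2$id[i], paste0(cov2$id[i], "_dup"))
    expect_equal(sum(pair %in% sp2$reference), 1)
  }
  expect_error(split_controls(make_controls(6)), "8")
})

test_that("matched splitting balances age better than random splitting", {
  diffs <- vapply(1:20, function(s) {
    cov <- make_controls(30, seed = s)
    sp <- split_controls(cov, seed = s)
    matched <- abs(mean(cov$age[cov$id %in% sp$reference]) -
                     mean(cov$age[cov$id %in% sp$normal]))
    set.seed(s + 500)
    idx <- sample(30, 15)
    rand <- abs(mean(cov$age[idx]) - mean(cov$age[-idx]))
    c(matched, rand)
  }, numeric(2))
  expect_lte(mean(diffs[1, ]), mean(diffs[2, ]) / 2)
})

test_that("covariate regression recovers noiseless slopes exactly", {
  cov <- make_controls(20)
  V <- 50
  fa <- matrix(0.5, 20, V) - 0.001 * cov$age
  rownames(fa) <- cov$id
  fit <- fit_covariate_model(fa, cov)
  expect_equal(unname(fit$coef["age", ]), rep(-0.001, V), tolerance = 1e-10)
  expect_true(all(fit$sig_mask))
})

test_that("null covariates flag ~5% of voxels and slopes are unbiased", {
  set.seed(4)
  cov <- make_controls(30)
  fa <- matrix(rnorm(30 * 12000, 0.5, 0.04), 30, 12000)
  rownames(fa) <- cov$id
  fit <- fit_covariate_model(fa, cov)
  expect_lt(abs(mean(fit$sig_mask) - 0.05), 0.01)

  # unbiasedness: mean estimated age slope over repeated draws within 2 SE
  slopes <- vapply(1:100, function(s) {
    set.seed(s)
    fa <- matrix(0.5 - 8e-4 * cov$age + rnorm(30 * 50, 0, 0.04), 30, 50)
    rownames(fa) <- cov$id
    mean(fit_covariate_model(fa, cov)$coef["age", ])
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 8e-4), 2 * se)
})

test_that("rank-deficient designs are rejected naming the covariate", {
  cov <- make_controls(12)
  cov$sex <- 1L
  fa <- matrix(runif(12 * 10, 0.3, 0.7), 12, 10,
               dimnames = list(cov$id, NULL))
  expect_error(fit_covariate_model(fa, cov), "sex")
})

test_that("adjust_fa is the identity at reference-mean covariates", {
  cov <- make_controls(20)
  set.seed(2)
  fa <- matrix(runif(20 * 30, 0.3, 0.7), 20, 30,
               dimnames = list(cov$id, NULL))
  fit <- fit_covariate_model(fa, cov)
  avg <- data.frame(id = "avg", age = fit$ref_means[["age"]],
                    sex = fit$ref_means[["sex"]],
                    education = fit$ref_means[["education"]])
  x <- matrix(runif(30, 0.3, 0.7), 1, dimnames = list("avg", NULL))
  expect_equal(adjust_fa(x, fit, avg), x)

  # empty significance mask: adjustment is a no-op for anyone
  fit0 <- fit
  fit0$sig_mask[] <- FALSE
  anyone <- data.frame(id = "s", age = 99, sex = 1, education = 0)
  x2 <- matrix(runif(30, 0.3, 0.7), 1, dimnames = list("s", NULL))
  expect_equal(adjust_fa(x2, fit0, anyone), x2)
})

test_that("adjustment adds covariate deviation times slope exactly", {
  cov <- make_controls(20)
  V <- 25
  fa <- matrix(0.5, 20, V) - 0.001 * cov$age
  rownames(fa) <- cov$id
  fit <- fit_covariate_model(fa, cov)
  subj <- data.frame(id = "s", age = fit$ref_means[["age"]] + 10,
                     sex = fit$ref_means[["sex"]],
                     education = fit$ref_means[["education"]])
  x <- matrix(0.5, 1, V, dimnames = list("s", NULL))
  adj <- adjust_fa(x, fit, subj)
  expect_equal(unname(adj[1, ]), rep(0.5 + 10 * 0.001, V),
               tolerance = 1e-10)
})

test_that("degenerate identity bootstrap reproduces plain sample statistics", {
  cov <- make_controls(24)
  set.seed(6)
  fa <- matrix(rnorm(24 * 40, 0.5, 0.05), 24, 40,
               dimnames = list(cov$id, NULL))
  m <- build_normative_model(fa, cov, B = 1, seed = 2,
                             sd_correction = FALSE, identity_boot = TRUE)
  ref <- fa[m$split$reference, ]
  adj <- adjust_fa(ref, m, cov)
  expect_equal(m$mu, colMeans(adj))
  expect_equal(m$sigma, apply(adj, 2, sd))
})

test_that("an all-identical reference raises the zero-SD guard", {
  cov <- make_controls(16)
  fa <- matrix(0.5, 16, 20, dimnames = list(cov$id, NULL))
  expect_error(build_normative_model(fa, cov, B = 2, seed = 1),
               "zero reference SD")
})

test_that("normative mean stabilizes as bootstrap replicates grow", {
  cov <- make_controls(20)
  set.seed(8)
  fa <- matrix(0.5 - 8e-4 * cov$age + rnorm(20 * 200, 0, 0.04), 20, 200,
               dimnames = list(cov$id, NULL))
  sp <- split_controls(cov, seed = 1)
  mu_at <- function(B, seed) build_normative_model(
    fa, cov, B = B, seed = seed, split = sp)$mu
  spread_small <- mean(abs(mu_at(4L, 21) - mu_at(4L, 22)))
  spread_large <- mean(abs(mu_at(60L, 23) - mu_at(60L, 24)))
  expect_lt(spread_large, spread_small)
})

test_that("EZ scores standardize against the normative mean and SD", {
  # handmade model: mu = 0.5, sigma = 0.1, no covariate adjustment
  V <- 5
  model <- structure(list(
    coef = matrix(0, 4, V, dimnames = list(
      c("intercept", "age", "sex", "education"), NULL)),
    sig_mask = rep(FALSE, V),
    ref_means = c(age = 40, sex = 0.5, education = 10),
    mu = rep(0.5, V), sigma = rep(0.1, V),
    n_reference = 20L, B = 1L, seed = 1L, sd_correction = FALSE),
    class = "normative_model")
  covs <- data.frame(id = "s", age = 40, sex = 0, education = 10)

  at <- function(v) unname(compute_ez(
    matrix(v, 1, V, dimnames = list("s", NULL)), model, covs)[1, 1])
  expect_equal(at(0.5), 0)
  expect_equal(at(0.72), 2.2)
  ez_boundary <- at(0.304)
  expect_equal(ez_boundary, -1.96)
  expect_false(abs(ez_boundary) > 1.96)  # strict threshold excludes boundary
})
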