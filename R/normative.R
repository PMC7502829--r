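
# Align a covariate table to the rows of an FA matrix by subject id.
align_covariates <- function(fa, covariates) {
  stopifnot(is.matrix(fa), !is.null(rownames(fa)),
            all(c("id", "age", "sex", "education") %in% names(covariates)))
  m <- match(rownames(fa), covariates$id)
  if (anyNA(m))
    stop("covariates missing for subject(s): ",
         paste(rownames(fa)[is.na(m)], collapse = ", "))
  covariates[m, , drop = FALSE]
}

#' Split controls into matched reference and normal-control halves
#'
#' Greedy pairwise matching on standardized (age, sex, education): the two
#' closest unmatched controls are paired and split at random between the
#' two halves, so the halves are balanced by construction. Deterministic
#' given `seed`.
#'
#' @param covariates data.frame of control subjects with columns `id`,
#'   `age`, `sex`, `education`.
#' @param seed integer seed for the within-pair coin flips.
#' @return list with character vectors `reference` and `normal`
#'   (disjoint, exhaustive).
#' @export
split_controls <- function(covariates, seed = 1L) {
  n <- nrow(covariates)
  if (n < 8) stop("need at least 8 controls to split, got ", n)
  Z <- scale(as.matrix(covariates[, c("age", "sex", "education")]))
  Z[, apply(Z, 2, function(z) all(!is.finite(z)))] <- 0
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  with_seed(seed, {
    unmatched <- seq_len(n)
    ref <- integer(0); nor <- integer(0)
    imbalance <- numeric(ncol(Z))  # running sum(ref) - sum(normal)
    while (length(unmatched) >= 2) {
      sub <- D[unmatched, unmatched, drop = FALSE]
      k <- arrayInd(which.min(sub), dim(sub))
      pair <- unmatched[c(k[1], k[2])]
      # orient the pair to shrink the running covariate imbalance
      delta <- Z[pair[1], ] - Z[pair[2], ]
      if (sum((imbalance + delta)^2) > sum((imbalance - delta)^2))
        pair <- rev(pair)
      else if (all(delta == 0) && runif(1) < 0.5)
        pair <- rev(pair)
      imbalance <- imbalance + Z[pair[1], ] - Z[pair[2], ]
      ref <- c(ref, pair[1]); nor <- c(nor, pair[2])
      unmatched <- setdiff(unmatched, pair)
    }
    if (length(unmatched) == 1) {
      if (runif(1) < 0.5) ref <- c(ref, unmatched)
      else nor <- c(nor, unmatched)
    }
    list(reference = covariates$id[sort(ref)],
         normal = covariates$id[sort(nor)])
  })
}

#' Per-voxel covariate regression on the reference controls
#'
#' Ordinary least squares of FA on (age, sex, education) at every skeleton
#' voxel, with covariates centred at the reference-group means. A voxel is
#' marked covariate-significant when the regression's omnibus F-test has
#' p < `sig_level` (uncorrected).
#'
#' @param fa matrix (reference subjects x skeleton voxels) with subject ids
#'   as rownames.
#' @param covariates data.frame with `id`, `age`, `sex`, `education`.
#' @param sig_level per-voxel omnibus significance level (default 0.05).
#' @return list with `coef` (4 x voxels: intercept and slopes), `sig_mask`
#'   (logical), `p_value`, `ref_means`, `n`.
#' @export
fit_covariate_model <- function(fa, covariates, sig_level = 0.05) {
  cov <- align_covariates(fa, covariates)
  n <- nrow(fa)
  p <- 3L
  if (n <= p + 1)
    stop("reference group too small (", n, ") for ", p, " covariates")
  ref_means <- c(age = mean(cov$age), sex = mean(cov$sex),
                 education = mean(cov$education))
  X <- cbind(intercept = 1,
             age = cov$age - ref_means[["age"]],
             sex = cov$sex - ref_means[["sex"]],
             education = cov$education - ref_means[["education"]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    sds <- apply(X[, -1, drop = FALSE], 2, sd)
    bad <- names(sds)[sds == 0]
    if (length(bad) == 0) bad <- "collinear covariates"
    stop("rank-deficient covariate design: ", paste(bad, collapse = ", "))
  }
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, fa))
  res <- fa - X %*% beta
  rss <- colSums(res^2)
  tss <- colSums(scale(fa, center = TRUE, scale = FALSE)^2)
  fstat <- ((tss - rss) / p) / (rss / (n - p - 1))
  pval <- pf(fstat, p, n - p - 1, lower.tail = FALSE)
  pval[tss == 0] <- 1  # constant voxel: no covariate effect testable
  rownames(beta) <- colnames(X)
  list(coef = beta, sig_mask = pval < sig_level, p_value = pval,
       ref_means = ref_means, n = n)
}

#' Covariate-adjust FA maps using fitted reference coefficients
#'
#' At covariate-significant voxels, subtracts the subject's covariate
#' deviations from the reference means times the fitted slopes; other
#' voxels are returned unchanged. A subject whose covariates equal the
#' reference means is returned identical.
#'
#' @param fa matrix (subjects x voxels) with subject ids as rownames, or a
#'   [skeleton_image()].
#' @param fit result of [fit_covariate_model()].
#' @param covariates data.frame covering every subject in `fa`.
#' @return Adjusted FA in the same form as the input.
#' @export
adjust_fa <- function(fa, fit, covariates) {
  if (inherits(fa, "skeleton_image")) {
    m <- matrix(fa$values, 1, dimnames = list(fa$id, NULL))
    adj <- adjust_fa(m, fit, covariates)
    out <- fa
    out$values <- adj[1, ]
    return(out)
  }
  cov <- align_covariates(fa, covariates)
  dev <- cbind(cov$age - fit$ref_means[["age"]],
               cov$sex - fit$ref_means[["sex"]],
               cov$education - fit$ref_means[["education"]])
  slopes <- fit$coef[c("age", "sex", "education"), , drop = FALSE]
  correction <- dev %*% slopes
  correction[, !fit$sig_mask] <- 0
  fa - correction
}

# Finite-sample unbiasing constant for the sample SD (E[S] = c4 * sigma).
c4_constant <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

#' Build the bootstrap-stabilized normative model from healthy controls
#'
#' Splits the controls into matched reference / normal halves, fits the
#' covariate regression on the full reference half, then repeatedly
#' resamples the reference subjects with replacement; each replicate refits
#' the covariate model on the resample and contributes the per-voxel mean
#' and SD of the full reference group adjusted with that replicate's
#' coefficients (accumulating over the unique subjects, not the resample,
#' so duplicated error terms cannot deflate the SD). The normative mean and
#' SD are the averages over replicates. Rank-deficient replicates (e.g. a
#' resample with a single sex) are redrawn and logged; more than 50%
#' redraws is an error.
#'
#' With `sd_correction = TRUE` (default) the model is calibrated for finite
#' reference samples: at covariate-adjusted voxels the replicate SD uses
#' the residual degrees of freedom (n - 4), and the aggregate SD is
#' unbiased by the c4 constant. `FALSE` reproduces the plain sample
#' statistics (so a B = 1 identity resample equals the sample mean/SD
#' exactly).
#'
#' @param fa matrix of control FA (subjects x voxels), rownames = ids.
#' @param covariates control covariate table.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed (split + resampling).
#' @param sd_correction apply finite-sample SD calibration (default TRUE).
#' @param split optional precomputed list(reference, normal) of ids.
#' @param identity_boot degenerate validation mode: every replicate uses
#'   the identity resample, so with `B = 1` and `sd_correction = FALSE`
#'   the model equals the plain sample mean/SD of the adjusted reference.
#' @return An object of class `normative_model`.
#' @export
build_normative_model <- function(fa, covariates, B = 1000L, seed = 1L,
                                  sd_correction = TRUE, split = NULL,
                                  identity_boot = FALSE) {
  stopifnot(B >= 1)
  if (is.null(split))
    split <- split_controls(align_covariates(fa, covariates),
                            seed = stage_seed(seed, "split"))
  ref_fa <- fa[split$reference, , drop = FALSE]
  ref_cov <- covariates[covariates$id %in% split$reference, , drop = FALSE]
  fit <- fit_covariate_model(ref_fa, ref_cov)
  nr <- nrow(ref_fa)

  mu_acc <- numeric(ncol(fa))
  sd_acc <- numeric(ncol(fa))
  p_cov <- 3L
  redraws <- 0L
  with_seed(stage_seed(seed, "normative"), {
    b <- 0L
    while (b < B) {
      idx <- if (identity_boot) seq_len(nr)
      else sample.int(nr, nr, replace = TRUE)
      boot_fa <- ref_fa[idx, , drop = FALSE]
      rownames(boot_fa) <- sprintf("boot_%03d", seq_len(nr))
      boot_cov <- ref_cov[match(split$reference[idx], ref_cov$id), ]
      boot_cov$id <- rownames(boot_fa)
      bfit <- tryCatch(fit_covariate_model(boot_fa, boot_cov),
                       error = function(e) NULL)
      if (is.null(bfit)) {
        redraws <- redraws + 1L
        if (redraws > B / 2)
          stop("more than 50% of bootstrap replicates were rank-deficient")
        next
      }
      adj <- adjust_fa(ref_fa, bfit, ref_cov)
      m_b <- colMeans(adj)
      ss <- colSums(sweep(adj, 2, m_b)^2)
      df <- rep(nr - 1L, ncol(fa))
      if (sd_correction) df[bfit$sig_mask] <- nr - 1L - p_cov
      s_b <- sqrt(ss / df)
      mu_acc <- mu_acc + m_b
      sd_acc <- sd_acc + s_b
      b <- b + 1L
    }
  })
  mu <- mu_acc / B
  sigma <- sd_acc / B
  if (sd_correction) sigma <- sigma / c4_constant(nr)
  if (any(sigma <= 0))
    stop("zero reference SD at ", sum(sigma <= 0),
         " voxel(s): degenerate reference sample")
  if (redraws > 0)
    message("normative bootstrap: ", redraws, " rank-deficient replicate(s) redrawn")
  structure(list(coef = fit$coef, sig_mask = fit$sig_mask,
                 ref_means = fit$ref_means, mu = mu, sigma = sigma,
                 n_reference = nr, B = as.integer(B),
                 seed = as.integer(seed), sd_correction = sd_correction,
                 split = split, redraws = redraws),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model> %d reference controls, B=%d bootstrap, %d voxels (%.1f%% covariate-significant)\n",
    x$n_reference, x$B, length(x$mu), 100 * mean(x$sig_mask)))
  invisible(x)
}

#' Voxelwise EZ deviation map of a subject against the normative model
#'
#' The subject's FA is covariate-adjusted with the model's reference
#' coefficients (at significant voxels), then standardized against the
#' bootstrap normative mean and SD: EZ(v) = (FA_adj(v) - mu(v)) / sd(v).
#' When the model was built with `sd_correction`, the denominator includes
#' the sqrt(1 + 1/n_reference) new-subject prediction factor so that EZ is
#' calibrated for subjects outside the reference sample.
#'
#' @param fa matrix (subjects x voxels, rownames = ids) or
#'   [skeleton_image()].
#' @param model a [build_normative_model()] result.
#' @param covariates covariate table covering the subjects.
#' @return Matrix of EZ scores (same shape as `fa`), or a `skeleton_image`
#'   whose values are EZ scores.
#' @export
compute_ez <- function(fa, model, covariates) {
  stopifnot(inherits(model, "normative_model"))
  if (inherits(fa, "skeleton_image")) {
    m <- matrix(fa$values, 1, dimnames = list(fa$id, NULL))
    ez <- compute_ez(m, model, covariates)
    out <- fa
    out$values <- ez[1, ]
    class(out) <- c("ez_map", class(out))
    return(out)
  }
  if (ncol(fa) != length(model$mu))
    stop("FA maps and normative model cover different voxel sets")
  adj <- adjust_fa(fa, model, covariates)
  denom <- model$sigma
  if (model$sd_correction) denom <- denom * sqrt(1 + 1 / model$n_reference)
  sweep(sweep(adj, 2, model$mu), 2, denom, "/")
}
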