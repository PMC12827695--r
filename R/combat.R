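# ComBat multi-site harmonization: empirical-Bayes location/scale batch
# correction with parametric priors (normal on site means, inverse-gamma on
# site variances), preserving designated covariate effects.

# moment-matched hyperparameters of the inverse-gamma prior on site variances
aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m^2) / s2
}
bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m^3) / s2
}

# iterate the conditional EB posterior updates for one site to convergence
eb_site_solve <- function(s_data, gamma_hat, delta_hat, gamma_bar, tau2,
                          a, b, tol = 1e-6) {
  n <- ncol(s_data)
  gamma_old <- gamma_hat
  delta_old <- delta_hat
  repeat {
    gamma_new <- (tau2 * n * gamma_hat + delta_old * gamma_bar) /
      (tau2 * n + delta_old)
    sum2 <- rowSums((s_data - gamma_new)^2)
    delta_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(gamma_new - gamma_old) / pmax(abs(gamma_old), 1e-12),
                  abs(delta_new - delta_old) / delta_old)
    gamma_old <- gamma_new
    delta_old <- delta_new
    if (change < tol) break
  }
  list(gamma_star = gamma_old, delta_star = delta_old)
}

#' ComBat harmonization of derived features across sites
#'
#' Removes additive and multiplicative site (batch) effects from a
#' subject x feature table while preserving designated covariate effects
#' (typically the group indicator). Features are standardized against the
#' covariate-adjusted grand mean and pooled SD; per-site location and scale
#' estimates are shrunk toward common priors by parametric empirical Bayes
#' (normal prior on locations, inverse-gamma on scales, moment-matched
#' hyperparameters, conditional updates iterated to relative tolerance
#' 1e-6) and removed; covariate effects are restored.
#'
#' With a single site the data are returned unchanged.
#'
#' @param features Numeric matrix or data.frame, subjects x features.
#' @param batch Site/batch label per subject (factor or vector).
#' @param covariates Optional numeric matrix/data.frame of effects to
#'   preserve (subjects x q), e.g. a 0/1 group indicator. No intercept
#'   column: one is implicit in the batch design.
#' @param parametric Only parametric priors are implemented; must be TRUE.
#' @param eb Apply empirical-Bayes shrinkage (default TRUE; FALSE uses the
#'   per-site estimates directly).
#' @return List with `harmonized` (same shape and dimnames as `features`)
#'   and `model` (class `combat_model`): `batch_levels`, `gamma_star`,
#'   `delta_star` (site x feature), `grand_mean`, `pooled_var`,
#'   `beta_cov`.
#' @export
combat_fit_apply <- function(features, batch, covariates = NULL,
                             parametric = TRUE, eb = TRUE) {
  if (!isTRUE(parametric))
    stop_edgedyn("only parametric empirical Bayes is implemented")
  x <- as.matrix(features)
  if (!is.numeric(x)) stop_edgedyn("'features' must be numeric")
  if (anyNA(x)) stop_edgedyn("'features' contains missing values")
  n <- nrow(x); p <- ncol(x)
  batch <- factor(batch)
  if (length(batch) != n)
    stop_edgedyn("batch length %d != subject count %d", length(batch), n)
  counts <- table(batch)
  if (any(counts < 2L))
    stop_edgedyn("site(s) with fewer than 2 subjects: %s",
                 paste(names(counts)[counts < 2L], collapse = ", "))
  nb <- nlevels(batch)
  if (nb == 1L) {
    model <- structure(list(batch_levels = levels(batch),
                            gamma_star = matrix(0, 1L, p),
                            delta_star = matrix(1, 1L, p),
                            grand_mean = colMeans(x),
                            pooled_var = apply(x, 2L, stats::var),
                            beta_cov = NULL, eb = eb),
                       class = "combat_model")
    return(list(harmonized = features, model = model))
  }
  bdes <- stats::model.matrix(~ batch - 1)          # n x nb one-hot
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_mat <- as.matrix(covariates)
    if (nrow(cov_mat) != n)
      stop_edgedyn("covariates rows %d != subject count %d", nrow(cov_mat), n)
    storage.mode(cov_mat) <- "double"
  }
  design <- cbind(bdes, cov_mat)
  if (qr(design)$rank < ncol(design))
    stop_edgedyn("design matrix is rank deficient (covariate confounded with site?)")
  beta <- solve(crossprod(design), crossprod(design, x))  # (nb+q) x p
  grand_mean <- as.numeric(counts / n) %*% beta[seq_len(nb), , drop = FALSE]
  fitted <- design %*% beta
  pooled_var <- colSums((x - fitted)^2) / n
  if (any(pooled_var == 0))
    stop_edgedyn("feature(s) with zero residual variance cannot be harmonized")
  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(cov_mat))
    stand_mean <- stand_mean +
      cov_mat %*% beta[-seq_len(nb), , drop = FALSE]
  s_data <- (x - stand_mean) / matrix(sqrt(pooled_var), n, p, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, nb, p)   # site x feature locations
  delta_hat <- matrix(NA_real_, nb, p)   # site x feature scales
  for (i in seq_len(nb)) {
    rows <- which(batch == levels(batch)[i])
    gamma_hat[i, ] <- colMeans(s_data[rows, , drop = FALSE])
    delta_hat[i, ] <- apply(s_data[rows, , drop = FALSE], 2L, stats::var)
  }
  if (eb && p >= 2L) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (i in seq_len(nb)) {
      rows <- which(batch == levels(batch)[i])
      sol <- eb_site_solve(t(s_data[rows, , drop = FALSE]),
                           gamma_hat[i, ], delta_hat[i, ],
                           gamma_bar = mean(gamma_hat[i, ]),
                           tau2 = stats::var(gamma_hat[i, ]),
                           a = aprior(delta_hat[i, ]),
                           b = bprior(delta_hat[i, ]))
      gamma_star[i, ] <- sol$gamma_star
      delta_star[i, ] <- sol$delta_star
    }
  } else {
    # EB shrinkage needs >= 2 features to estimate priors; fall back to
    # the direct location/scale estimates
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }
  adj <- s_data
  for (i in seq_len(nb)) {
    rows <- which(batch == levels(batch)[i])
    adj[rows, ] <- sweep(sweep(s_data[rows, , drop = FALSE], 2L,
                               gamma_star[i, ], "-"),
                         2L, sqrt(delta_star[i, ]), "/")
  }
  harmonized <- adj * matrix(sqrt(pooled_var), n, p, byrow = TRUE) + stand_mean
  dimnames(harmonized) <- dimnames(x)
  out <- features
  if (is.data.frame(features)) out[] <- as.data.frame(harmonized)
  else out <- harmonized
  model <- structure(list(batch_levels = levels(batch),
                          gamma_star = gamma_star, delta_star = delta_star,
                          grand_mean = as.numeric(grand_mean),
                          pooled_var = pooled_var,
                          beta_cov = if (is.null(cov_mat)) NULL
                                     else beta[-seq_len(nb), , drop = FALSE],
                          eb = eb),
                     class = "combat_model")
  list(harmonized = out, model = model)
}
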