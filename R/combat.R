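#' Parametric empirical-Bayes batch correction
#'
#' Removes additive (location) and multiplicative (scale) batch effects from a
#' complete normalized matrix.  Each protein is standardized against a linear
#' model containing batch indicators and, by default, the case/control group
#' as a protected covariate so biological signal is not absorbed into the
#' batch terms.  Per-batch, per-protein location and scale estimates are then
#' shrunk towards parametric priors -- Normal for locations, inverse-gamma for
#' scales, with hyperparameters estimated across proteins by the method of
#' moments -- via the standard iterative conditional-posterior-mean update,
#' and the shrunken effects are removed.  The grand mean and covariate
#' structure are restored afterwards.
#'
#' With a single distinct batch label the input is returned unchanged.
#'
#' @param x Complete normalized matrix (after [drop_missing()]).
#' @param protect_group Model the case/control contrast as a covariate so it
#'   is excluded from the batch estimates (default `FALSE`).  With a
#'   batch-balanced design the contrast is preserved without protection, and
#'   leaving the outcome out of the adjustment keeps downstream permutation
#'   tests exchangeable; enable protection for unbalanced designs where batch
#'   removal would otherwise absorb biological signal.
#' @param tol Convergence tolerance of the empirical-Bayes iteration (maximum
#'   relative change of any location/scale estimate).
#' @param max_iter Iteration cap; exceeding it is an error reporting the count.
#' @return The adjusted tibble.  Fitted parameters (per-batch location
#'   estimates `gamma_hat`/`gamma_star`, scale estimates
#'   `delta2_hat`/`delta2_star`, prior hyperparameters and iteration counts)
#'   are attached and retrievable with [batch_params()].
#' @export
combat_adjust <- function(x, protect_group = FALSE, tol = 1e-4, max_iter = 100L) {
  check_steps(x, c("drop_missing", "combat"), "combat")
  ann <- tmt_annotation_attr(x)
  m <- tmt_matrix(x)
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "Batch correction requires a complete matrix.")
  }
  batch <- factor(ann$batch)
  if (nlevels(batch) < 2) {
    inform("Single batch: batch correction is the identity.")
    return(stamp(x, ann, c(tmt_steps(x), "combat")))
  }
  n_per <- table(batch)
  if (any(n_per < 2)) {
    tmt_error("tmtdiff_design_error", sprintf(
      "Every batch needs at least 2 samples (singleton: %s).",
      paste(names(n_per)[n_per < 2], collapse = ", ")))
  }

  N <- ncol(m); G <- nrow(m); B <- nlevels(batch)
  design <- model.matrix(~ -1 + batch)
  if (protect_group && length(unique(ann$group)) > 1) {
    design <- cbind(design, model.matrix(~ factor(ann$group))[, -1, drop = FALSE])
  }
  # per-protein OLS of the full design; batch coefficients are the first B
  beta_hat <- solve(crossprod(design), t(design) %*% t(m))   # p x G
  grand_mean <- crossprod(as.numeric(n_per) / N, beta_hat[1:B, , drop = FALSE])
  var_pooled <- rowMeans((m - t(design %*% beta_hat))^2)
  if (any(var_pooled <= 0)) {
    tmt_error("tmtdiff_input_error", "Zero residual variance for some proteins.")
  }

  stand_mean <- matrix(grand_mean, G, N)
  if (ncol(design) > B) {
    covars <- design[, -(1:B), drop = FALSE]
    stand_mean <- stand_mean +
      t(covars %*% beta_hat[-(1:B), , drop = FALSE])
  }
  z <- (m - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, G, B)
  delta2_hat <- matrix(NA_real_, G, B)
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    gamma_hat[, b] <- rowMeans(z[, in_b, drop = FALSE])
    delta2_hat[, b] <- apply(z[, in_b, drop = FALSE], 1, var)
  }

  # method-of-moments priors per batch
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, var)
  d_mean <- colMeans(delta2_hat)
  d_var <- apply(delta2_hat, 2, var)
  lambda <- (2 * d_var + d_mean^2) / d_var           # inverse-gamma shape
  theta <- (d_mean * d_var + d_mean^3) / d_var       # inverse-gamma scale

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iterations <- integer(B)
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    nb <- sum(in_b)
    zb <- z[, in_b, drop = FALSE]
    g_old <- gamma_hat[, b]; d_old <- delta2_hat[, b]
    it <- 0L; change <- Inf
    while (change > tol) {
      it <- it + 1L
      if (it > max_iter) {
        tmt_error("tmtdiff_convergence_error", sprintf(
          "Empirical-Bayes update for batch '%s' did not converge in %d iterations.",
          levels(batch)[b], max_iter))
      }
      g_new <- (nb * tau2[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (nb * tau2[b] + d_old)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (theta[b] + 0.5 * ss) / (nb / 2 + lambda[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new; d_old <- d_new
    }
    gamma_star[, b] <- g_old
    delta2_star[, b] <- d_old
    iterations[b] <- it
  }

  adj <- z
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    adj[, in_b] <- (z[, in_b, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean

  dimnames(gamma_hat) <- dimnames(delta2_hat) <- dimnames(gamma_star) <-
    dimnames(delta2_star) <- list(rownames(m), levels(batch))
  out <- stamp(mat_to_tbl(adj), ann, c(tmt_steps(x), "combat"))
  attr(out, "batch_params") <- structure(list(
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    priors = tibble(batch = levels(batch), gamma_bar = gamma_bar, tau2 = tau2,
                    lambda = lambda, theta = theta),
    iterations = iterations, tol = tol, protect_group = protect_group
  ), class = "batch_model_params")
  out
}

#' Fitted batch-model parameters of a corrected matrix
#'
#' @param x Output of [combat_adjust()].
#' @return A `batch_model_params` list (location/scale estimates before and
#'   after shrinkage, prior hyperparameters, iterations), or `NULL` when the
#'   correction was the identity.
#' @export
batch_params <- function(x) attr(x, "batch_params")

#' @export
print.batch_model_params <- function(x, ...) {
  cat(sprintf("<batch_model_params> %d proteins x %d batches; iterations: %s\n",
              nrow(x$gamma_hat), ncol(x$gamma_hat),
              paste(x$iterations, collapse = ", ")))
  print(x$priors)
  invisible(x)
}
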