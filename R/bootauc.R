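#' Area under the ROC curve by Mann-Whitney pair counting
#'
#' AUC of a score vector for separating cases from controls, computed from
#' the Mann-Whitney identity: the fraction of case/control pairs where the
#' case scores higher, ties counting one half.  Cases are the positive class,
#' so AUC > 0.5 means higher scores in cases.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (`TRUE` = case) or a vector with values
#'   `"case"`/`"control"`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- labels == "case"
  if (length(scores) != length(labels)) {
    tmt_error("tmtdiff_input_error", "`scores` and `labels` lengths differ.")
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    tmt_error("tmtdiff_input_error", "Both classes must be non-empty.")
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pairwise comparison tensor: G x (n1*n0) matrix with entries
# 1{case > control} + 0.5 * 1{tie}; pair k = (j-1)*n1 + i for case i,
# control j.  Every bootstrap AUC is a bilinear form in this tensor.
pair_tensor <- function(m, is_case) {
  cs <- which(is_case); ct <- which(!is_case)
  n1 <- length(cs); n0 <- length(ct)
  a <- matrix(NA_real_, nrow(m), n1 * n0)
  for (j in seq_len(n0)) {
    y <- m[, ct[j]]
    for (i in seq_len(n1)) {
      x <- m[, cs[i]]
      a[, (j - 1) * n1 + i] <- (x > y) + 0.5 * (x == y)
    }
  }
  a
}

# Column-wise resample count matrices for B bootstrap replicates.
resample_counts <- function(n, B) {
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  apply(idx, 2, tabulate, nbins = n)
}

boot_means_sds <- function(a, n1, n0, B, stratified) {
  if (stratified) {
    w <- resample_counts(n1, B)            # n1 x B case multiplicities
    v <- resample_counts(n0, B)            # n0 x B control multiplicities
    denom <- rep(n1 * n0, B)
  } else {
    n <- n1 + n0
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    cnt <- apply(idx, 2, tabulate, nbins = n)
    w <- cnt[seq_len(n1), , drop = FALSE]
    v <- cnt[n1 + seq_len(n0), , drop = FALSE]
    denom <- colSums(w) * colSums(v)
  }
  o <- w[rep(seq_len(n1), times = n0), , drop = FALSE] *
    v[rep(seq_len(n0), each = n1), , drop = FALSE]   # (n1*n0) x B
  s <- a %*% o                                       # G x B pair sums
  aucs <- sweep(s, 2, denom, "/")
  aucs[, denom == 0] <- 0.5                          # resample lost a class
  mean_auc <- rowMeans(aucs)
  sd_auc <- sqrt(pmax(rowSums((aucs - mean_auc)^2) / (B - 1), 0))
  list(mean = mean_auc, sd = sd_auc)
}

#' Bootstrap AUC summaries per protein
#'
#' For every protein, resamples subjects with replacement `B` times --
#' stratified by default, cases drawn from cases and controls from controls
#' with the original group sizes -- computes the ROC AUC of each resample,
#' and reports the mean and SD over resamples next to the point AUC.  A
#' resample whose scores carry no class contrast contributes AUC 0.5.
#' Deterministic under `seed`.
#'
#' @param x Complete normalized matrix.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param stratified Resample within each group (default) or from the pooled
#'   cohort.
#' @return A `bootauc_result` tibble: `protein`, `auc`, `mean_auc`, `sd_auc`.
#' @export
bootstrap_auc <- function(x, B = 1000, seed = 1L, stratified = TRUE) {
  if (B < 2) tmt_error("tmtdiff_config_error", "'B' must be >= 2.")
  m <- tmt_matrix(x)
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "bootstrap_auc() requires a complete matrix.")
  }
  ann <- tmt_groups(x)
  check_two_groups(ann)
  is_case <- ann$group == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  a <- pair_tensor(m, is_case)
  res <- with_seed(seed, boot_means_sds(a, n1, n0, B, stratified))
  out <- tibble(protein = rownames(m), auc = rowMeans(a),
                mean_auc = res$mean, sd_auc = res$sd)
  structure(out, class = c("bootauc_result", class(out)),
            bootauc_config = list(B = B, seed = seed, stratified = stratified,
                                  group_sizes = c(case = n1, control = n0)))
}

#' Null distribution of bootstrap mean AUCs under label permutation
#'
#' Re-runs the bootstrap mean-AUC computation after permuting the case/control
#' labels, once per permutation, pooling all proteins' null mean AUCs with
#' per-permutation provenance.  Label permutations are stratified by batch
#' (each keeps the observed number of cases per batch).  This is the
#' reference distribution for [bootauc_q()].
#'
#' @inheritParams bootstrap_auc
#' @param n_permutations Number of seeded label permutations (default 20).
#' @return Tibble: `permutation`, `protein`, `mean_auc`, with the number of
#'   permutations in `attr(., "n_permutations")`.
#' @export
null_bootstrap_auc <- function(x, B = 1000, n_permutations = 20, seed = 1L,
                               stratified = TRUE) {
  if (n_permutations < 1) {
    tmt_error("tmtdiff_config_error", "'n_permutations' must be >= 1.")
  }
  m <- tmt_matrix(x)
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "null_bootstrap_auc() requires a complete matrix.")
  }
  ann <- tmt_groups(x)
  check_two_groups(ann)
  is_case <- ann$group == "case"
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_permutations), function(p) {
      flag <- permute_labels(is_case, ann$batch)
      a <- pair_tensor(m, flag)
      res <- boot_means_sds(a, sum(flag), sum(!flag), B, stratified)
      tibble(permutation = p, protein = rownames(m), mean_auc = res$mean)
    })
  })
  attr(out, "n_permutations") <- n_permutations
  out
}

#' Sorted-ratio permutation q-values for bootstrap mean AUCs
#'
#' Assigns each protein a q-value by comparing the observed bootstrap mean
#' AUCs with the pooled permutation nulls, tail by tail: proteins with mean
#' AUC above 0.5 are ranked descending, proteins below 0.5 ascending, and at
#' each observed value the q is the per-permutation average count of null
#' means at least as extreme divided by the count of observed means at least
#' as extreme, clipped to \[0, 1\] and monotonized towards the extremes.
#' Proteins sitting exactly at 0.5 get q = 1.
#'
#' @param real_rows A `bootauc_result` from [bootstrap_auc()].
#' @param null_means Output of [null_bootstrap_auc()].
#' @param q_threshold Significance cut on q (default 0.05).
#' @return `real_rows` with `q` and `significant` columns added.
#' @export
bootauc_q <- function(real_rows, null_means, q_threshold = 0.05) {
  if (!nrow(null_means)) {
    tmt_error("tmtdiff_input_error", "Empty null distribution.")
  }
  n_perm <- attr(null_means, "n_permutations") %||%
    length(unique(null_means$permutation))
  q <- rep(1, nrow(real_rows))
  upper <- real_rows$mean_auc > 0.5
  lower <- real_rows$mean_auc < 0.5
  if (any(upper)) {
    q[upper] <- permutation_q(real_rows$mean_auc[upper] - 0.5,
                              pmax(null_means$mean_auc - 0.5, 0), n_perm)
  } else {
    inform("No proteins with mean AUC > 0.5; upper tail skipped.")
  }
  if (any(lower)) {
    q[lower] <- permutation_q(0.5 - real_rows$mean_auc[lower],
                              pmax(0.5 - null_means$mean_auc, 0), n_perm)
  } else {
    inform("No proteins with mean AUC < 0.5; lower tail skipped.")
  }
  out <- real_rows
  out$q <- q
  out$significant <- q < q_threshold
  cfg <- attr(real_rows, "bootauc_config")
  attr(out, "bootauc_config") <- c(cfg, list(q_threshold = q_threshold,
                                             n_permutations = n_perm))
  out
}

#' Rank bootstrap-AUC rows by stability
#'
#' Stable ascending sort by the bootstrap SD of the AUC -- the most stable
#' discriminators first -- breaking ties by larger |mean AUC - 0.5|, then by
#' protein id.
#'
#' @param rows A `bootauc_result`, optionally after [bootauc_q()].
#' @param significant_only Keep only rows flagged significant (requires the
#'   `significant` column).
#' @return The reordered tibble.
#' @export
rank_by_sd <- function(rows, significant_only = FALSE) {
  if (significant_only) {
    if (is.null(rows$significant)) {
      tmt_error("tmtdiff_input_error", "No 'significant' column; run bootauc_q() first.")
    }
    rows <- rows[rows$significant, ]
  }
  dplyr::arrange(rows, .data$sd_auc, dplyr::desc(abs(.data$mean_auc - 0.5)),
                 .data$protein)
}

#' One-call bootstrap-AUC differential analysis
#'
#' Convenience wrapper chaining [bootstrap_auc()], [null_bootstrap_auc()] and
#' [bootauc_q()] with a shared seed.
#'
#' @inheritParams bootstrap_auc
#' @inheritParams null_bootstrap_auc
#' @inheritParams bootauc_q
#' @return A `bootauc_result` tibble with q-values and significance flags.
#' @export
diff_auc <- function(x, B = 1000, n_permutations = 20, seed = 1L,
                     stratified = TRUE, q_threshold = 0.05) {
  real <- bootstrap_auc(x, B = B, seed = seed, stratified = stratified)
  null <- null_bootstrap_auc(x, B = B, n_permutations = n_permutations,
                             seed = derive_seed(seed, "null"),
                             stratified = stratified)
  bootauc_q(real, null, q_threshold = q_threshold)
}

#' @export
print.bootauc_result <- function(x, ...) {
  cfg <- attr(x, "bootauc_config")
  cat(sprintf("<bootauc_result> %d proteins; B = %d%s\n", nrow(x), cfg$B,
              if (!is.null(x$significant))
                sprintf("; %d significant at q < %g", sum(x$significant),
                        cfg$q_threshold) else ""))
  NextMethod()
}
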