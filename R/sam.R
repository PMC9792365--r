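#' Per-protein two-sample Student t-test
#'
#' Pooled-variance two-sided Student t-test of case versus control for every
#' protein of a complete normalized matrix; a Welch variant (unequal
#' variances, Satterthwaite degrees of freedom) is available behind a flag.
#' Proteins with zero standard error are guarded: equal means give t = 0 and
#' p = 1, unequal means give an infinite t and p = 0.
#'
#' @param x Complete normalized matrix (after [drop_missing()], usually after
#'   [combat_adjust()]).
#' @param var_equal Pooled variance (default) or Welch.
#' @return Tibble: `protein`, `mean_case`, `mean_control`, `mean_diff`
#'   (case - control), `se`, `t`, `p`, `df`.
#' @export
two_sample_t <- function(x, var_equal = TRUE) {
  m <- tmt_matrix(x)
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "t-tests require a complete matrix; run drop_missing().")
  }
  ann <- tmt_groups(x)
  check_two_groups(ann)
  st <- t_stats(m, ann$group == "case", var_equal = var_equal)
  tibble(protein = rownames(m), mean_case = st$m1, mean_control = st$m0,
         mean_diff = st$diff, se = st$se, t = st$t, p = st$p, df = st$df)
}

# Vectorized group means/variances and the t statistic for a case indicator.
t_stats <- function(m, is_case, var_equal = TRUE) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  m1 <- rowMeans(m[, is_case, drop = FALSE])
  m0 <- rowMeans(m[, !is_case, drop = FALSE])
  v1 <- rowSums((m[, is_case, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((m[, !is_case, drop = FALSE] - m0)^2) / (n0 - 1)
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- diff / se
  degenerate <- se == 0
  if (any(degenerate)) {
    t[degenerate] <- ifelse(diff[degenerate] == 0, 0,
                            sign(diff[degenerate]) * Inf)
    df[degenerate & diff == 0] <- n1 + n0 - 2
  }
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  lapply(list(m1 = m1, m0 = m0, diff = diff, se = se, t = t, p = p, df = df),
         unname)
}

#' Shapiro-Wilk normality screen across proteins
#'
#' Runs the Shapiro-Wilk test on each protein row and summarizes what
#' fraction of proteins look consistent with normality (p > 0.05), the usual
#' justification for a downstream t-test.  Constant rows are flagged and get
#' no statistic.
#'
#' @param x Complete normalized matrix.
#' @return Tibble: `protein`, `W`, `p`, `flagged`; the fraction with
#'   p > 0.05 is in `attr(., "fraction_normal")`.
#' @export
shapiro_normality <- function(x) {
  m <- tmt_matrix(x)
  if (ncol(m) < 3) {
    tmt_error("tmtdiff_input_error", "Shapiro-Wilk needs at least 3 observations per protein.")
  }
  res <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(unique(v)) < 2) return(c(NA_real_, NA_real_))
    s <- shapiro.test(v)
    c(s$statistic, s$p.value)
  })
  out <- tibble(protein = rownames(m), W = res[1, ], p = res[2, ],
                flagged = is.na(res[1, ]))
  attr(out, "fraction_normal") <- mean(out$p > 0.05, na.rm = TRUE)
  out
}

#' Per-protein linear fold change (case over control)
#'
#' Fold change on the linear relative-abundance scale: the mean of the
#' median-centred ratios over case samples divided by the mean over control
#' samples.  Computed before the log2/z-score transform so the ratio keeps
#' its natural units.
#'
#' @param x Output of [median_center()] (linear relative abundances).
#' @return Tibble: `protein`, `fold_change`, `log2fc`; non-finite ratios
#'   (zero control mean) are flagged with a warning.
#' @export
fold_change <- function(x) {
  steps <- tmt_steps(x)
  if (!"median" %in% steps || "log2_zscore" %in% steps) {
    tmt_error("tmtdiff_state_error",
              "fold_change() expects the median-centred linear table (after median_center(), before log2_zscore()).")
  }
  m <- tmt_matrix(x)
  ann <- tmt_groups(x)
  m1 <- rowMeans(m[, ann$group == "case", drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(m[, ann$group == "control", drop = FALSE], na.rm = TRUE)
  fc <- unname(m1 / m0)
  if (any(!is.finite(fc))) {
    warn(sprintf("%d proteins have a non-finite fold change (zero control mean).",
                 sum(!is.finite(fc))))
  }
  tibble(protein = rownames(m), fold_change = fc, log2fc = log2(fc))
}

#' SAM-style moderated t-statistics with permutation q-values
#'
#' Computes, per protein, the moderated statistic d = (mean_case -
#' mean_control) / (s + s0), where s is the pooled standard error and s0 a
#' small stabilization constant, then estimates a false discovery rate for
#' each |d| threshold by permuting group labels: q(|d|) is the average number
#' of permuted |d*| at least as large, divided by the observed count at least
#' as large, clipped to [0, 1] and monotonized (running minimum from the
#' largest |d| down) so q never decreases as the threshold relaxes.
#' Permutations are stratified by batch -- each keeps the observed number of
#' cases per batch -- so they stay exchangeable with the batch-balanced
#' design after batch correction.  When the number of distinct
#' batch-balanced assignments is no larger than `n_permutations` they are
#' enumerated exhaustively.
#'
#' @param x Complete normalized matrix.
#' @param s0 Stabilization constant added to the standard error (default 0.1;
#'   with `s0 = 0` the ranking equals the ordinary |t| ranking).
#' @param n_permutations Number of label permutations (default 250).
#' @param seed RNG seed for the permutations.
#' @param q_threshold Significance cut on q (default 0.05).
#' @param var_equal Pooled (default) or Welch standard errors.
#' @param fold_changes Optional output of [fold_change()] to merge into the
#'   result.
#' @return A `sam_result` tibble: `protein`, `mean_diff`, `fold_change`,
#'   `log2fc`, `t`, `p`, `d`, `q`, `significant`.  The configuration, the
#'   |d| cutoff actually attained and the permutation summary are attached as
#'   attributes.
#' @export
sam <- function(x, s0 = 0.1, n_permutations = 250, seed = 1L,
                q_threshold = 0.05, var_equal = TRUE, fold_changes = NULL) {
  if (s0 < 0) tmt_error("tmtdiff_config_error", "'s0' must be non-negative.")
  if (n_permutations < 1) tmt_error("tmtdiff_config_error", "'n_permutations' must be >= 1.")
  if (q_threshold <= 0 || q_threshold >= 1) {
    tmt_error("tmtdiff_config_error", "'q_threshold' must be in (0, 1).")
  }
  m <- tmt_matrix(x)
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "sam() requires a complete matrix; run drop_missing().")
  }
  ann <- tmt_groups(x)
  check_two_groups(ann)
  is_case <- ann$group == "case"
  n <- ncol(m); n1 <- sum(is_case)

  st <- t_stats(m, is_case, var_equal = var_equal)
  d_obs <- st$diff / (st$se + s0)

  batch <- ann$batch
  n_distinct <- n_distinct_assignments(is_case, batch)
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_permutations
  perms <- if (exhaustive) {
    inform(sprintf(
      "Requested %d permutations but only %d distinct batch-balanced label assignments exist: enumerating exhaustively.",
      n_permutations, n_distinct))
    enumerate_assignments(is_case, batch)
  } else {
    with_seed(seed, replicate(n_permutations, permute_labels(is_case, batch),
                              simplify = FALSE))
  }
  perm_abs_d <- vapply(perms, function(flag) {
    stp <- t_stats(m, flag, var_equal = var_equal)
    abs(stp$diff / (stp$se + s0))
  }, numeric(nrow(m)))

  q <- permutation_q(abs(d_obs), as.vector(perm_abs_d), length(perms))
  significant <- q < q_threshold
  d_cut <- if (any(significant)) min(abs(d_obs)[significant]) else Inf

  out <- tibble(protein = rownames(m), mean_diff = st$diff,
                t = st$t, p = st$p, d = d_obs, q = q,
                significant = significant)
  if (!is.null(fold_changes)) {
    out <- dplyr::left_join(out, fold_changes[, c("protein", "fold_change", "log2fc")],
                            by = "protein")
    out <- out[, c("protein", "mean_diff", "fold_change", "log2fc",
                   "t", "p", "d", "q", "significant")]
  }
  structure(out,
            class = c("sam_result", class(out)),
            sam_config = list(s0 = s0, n_permutations = length(perms),
                              seed = seed, q_threshold = q_threshold,
                              var_equal = var_equal, exhaustive = exhaustive),
            d_cut = d_cut, df = st$df[1],
            group_sizes = c(case = n1, control = n - n1))
}

# Shared permutation-FDR machinery: for each observed extremeness value,
#   q = (average permuted count at least as extreme) / (observed count),
# clipped to [0,1] and monotonized so q is non-decreasing as the threshold
# relaxes (running minimum from the most extreme observation inward).
permutation_q <- function(obs_extreme, null_extreme, n_perm) {
  ord <- order(obs_extreme, decreasing = TRUE)
  sorted_null <- sort(null_extreme)
  k <- length(obs_extreme)
  obs_count <- rank(-obs_extreme, ties.method = "max")
  null_count <- (length(sorted_null) -
                   findInterval(obs_extreme - 1e-12, sorted_null)) / n_perm
  q_raw <- pmin(pmax(null_count / obs_count, 0), 1)
  q_sorted <- q_raw[ord]
  q_mono <- rev(cummin(rev(q_sorted)))
  q <- numeric(k)
  q[ord] <- q_mono
  q
}

#' @export
print.sam_result <- function(x, ...) {
  cfg <- attr(x, "sam_config")
  cat(sprintf("<sam_result> %d proteins; %d significant at q < %g (s0 = %g, %d permutations%s)\n",
              nrow(x), sum(x$significant), cfg$q_threshold, cfg$s0,
              cfg$n_permutations, if (cfg$exhaustive) ", exhaustive" else ""))
  NextMethod()
}

#' q-value significance boundary for a volcano plot
#'
#' For a grid of absolute mean differences (z-score units), the smallest
#' -log10 p at which a protein with that effect would still reach the
#' attained |d| cutoff of a [sam()] fit.  With `s0 = 0` the boundary is a
#' horizontal line; with `s0 > 0` it falls away as the effect grows, giving
#' the familiar curved volcano boundary.  Effects too small to ever reach the
#' cutoff get an infinite boundary.
#'
#' @param sam_rows A `sam_result` from [sam()].
#' @param effects Optional grid of mean differences; defaults to an even grid
#'   over the observed range.
#' @return Tibble: `mean_diff`, `t_min`, `neg_log10_p`.
#' @export
volcano_boundary <- function(sam_rows, effects = NULL) {
  stopifnot(inherits(sam_rows, "sam_result"))
  cfg <- attr(sam_rows, "sam_config")
  d_cut <- attr(sam_rows, "d_cut")
  df <- attr(sam_rows, "df")
  if (is.null(effects)) {
    r <- max(abs(sam_rows$mean_diff))
    effects <- seq(-r, r, length.out = 201)
  }
  a <- abs(effects)
  s_max <- a / d_cut - cfg$s0
  t_min <- ifelse(s_max > 0, a / s_max, Inf)
  if (!is.finite(d_cut)) t_min <- rep(Inf, length(a))
  tibble(mean_diff = effects, t_min = t_min,
         neg_log10_p = -log10(2 * pt(t_min, df, lower.tail = FALSE)))
}
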