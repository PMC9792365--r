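# broom-style views of fitted objects.

#' @exportS3Method generics::tidy
tidy.tmt_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.tmt_pca <- function(x, ...) {
  tibble(silhouette = x$silhouette,
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2],
         n_samples = nrow(x$scores))
}

#' @exportS3Method generics::glance
glance.sam_result <- function(x, ...) {
  cfg <- attr(x, "sam_config")
  tibble(n_proteins = nrow(x), n_significant = sum(x$significant),
         d_cut = attr(x, "d_cut"), s0 = cfg$s0,
         n_permutations = cfg$n_permutations, q_threshold = cfg$q_threshold,
         exhaustive = cfg$exhaustive)
}

#' @exportS3Method generics::glance
glance.bootauc_result <- function(x, ...) {
  cfg <- attr(x, "bootauc_config")
  tibble(n_proteins = nrow(x),
         n_significant = if (is.null(x$significant)) NA_integer_ else sum(x$significant),
         B = cfg$B,
         q_threshold = cfg$q_threshold %||% NA_real_)
}

#' @exportS3Method generics::tidy
tidy.tmt_run <- function(x, ...) {
  out <- dplyr::left_join(
    as_tibble(x$sam)[, c("protein", "mean_diff", "fold_change", "log2fc",
                         "t", "p", "d", "q", "significant")],
    as_tibble(x$bootauc)[, c("protein", "auc", "mean_auc", "sd_auc", "q",
                             "significant")],
    by = "protein", suffix = c("_sam", "_auc"))
  out$selected <- out$protein %in% x$intersection$protein
  out
}

#' @exportS3Method generics::glance
glance.tmt_run <- function(x, ...) as_tibble(x$counts)
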