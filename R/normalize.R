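#' Divide each sample by its batch's master-pool reference channel
#'
#' First step of the normalization cascade for multiplexed reporter-ion data.
#' Every batch must carry exactly one reference (master pool) sample; each
#' biological intensity is divided, protein by protein, by the same-batch
#' reference intensity, which cancels shared per-batch effects.  Reference
#' columns are dropped from the output.  Zero intensities are treated as
#' missing on input (a reporter signal of 0 is non-detection).  Missingness
#' propagates: if a protein's reference value is missing in a batch, the
#' protein becomes missing in all of that batch's samples.
#'
#' @param abundance Data frame: `protein` column plus one linear-intensity
#'   column per sample (`NA` = missing).
#' @param annotation Data frame with `sample`, `group` (case/control/reference),
#'   `batch` and optionally `channel`.
#' @return Tibble of per-protein ratios for the biological samples, carrying
#'   the annotation and step history used by the downstream verbs.
#' @export
reference_normalize <- function(abundance, annotation) {
  abundance <- as_tibble(abundance)
  annotation <- as_tibble(annotation)
  if (names(abundance)[1] != "protein") {
    tmt_error("tmtdiff_input_error", "First column of `abundance` must be 'protein'.")
  }
  if (anyDuplicated(abundance$protein)) {
    tmt_error("tmtdiff_input_error", "Protein ids must be unique.")
  }
  samples <- names(abundance)[-1]
  if (!setequal(samples, annotation$sample)) {
    tmt_error("tmtdiff_input_error",
              "Sample columns and annotation rows do not match.")
  }
  annotation <- annotation[match(samples, annotation$sample), ]
  bad <- setdiff(unique(annotation$group), c("case", "control", "reference"))
  if (length(bad)) {
    tmt_error("tmtdiff_input_error",
              paste0("Unknown group labels: ", paste(bad, collapse = ", ")))
  }
  ref_per_batch <- tapply(annotation$group == "reference", annotation$batch, sum)
  if (any(ref_per_batch != 1L)) {
    tmt_error("tmtdiff_design_error", sprintf(
      "Each batch needs exactly one reference sample (got: %s).",
      paste(sprintf("batch %s: %d", names(ref_per_batch), ref_per_batch),
            collapse = ", ")))
  }

  m <- tmt_matrix(abundance)
  if (any(m < 0, na.rm = TRUE)) {
    tmt_error("tmtdiff_input_error", "Intensities must be non-negative.")
  }
  n_zero <- sum(m == 0, na.rm = TRUE)
  if (n_zero > 0) {
    warn(sprintf("%d zero intensities treated as missing.", n_zero))
    m[m == 0] <- NA_real_
  }

  is_ref <- annotation$group == "reference"
  out <- m[, !is_ref, drop = FALSE]
  for (b in unique(annotation$batch)) {
    in_b <- annotation$batch == b & !is_ref
    ref_col <- m[, annotation$batch == b & is_ref]
    out[, in_b[!is_ref]] <- m[, in_b, drop = FALSE] / ref_col
  }
  stamp(mat_to_tbl(out), annotation[!is_ref, ], "reference")
}

#' Centre each protein at its median relative abundance
#'
#' Divides every protein row by its median over observed biological samples,
#' so each protein's output median is 1.  Rows with no observed value are
#' passed through all-missing and flagged.
#'
#' @param x Output of [reference_normalize()].
#' @return Tibble of median-centred ratios; ids of all-missing rows are in
#'   `attr(., "all_missing")`.
#' @export
median_center <- function(x) {
  check_steps(x, "reference", "median")
  m <- tmt_matrix(x)
  med <- apply(m, 1, median, na.rm = TRUE)
  all_missing <- rownames(m)[!is.finite(med)]
  if (length(all_missing)) {
    inform(sprintf("%d all-missing protein rows passed through unchanged.",
                   length(all_missing)))
    med[!is.finite(med)] <- 1
  }
  out <- stamp(mat_to_tbl(m / med), tmt_annotation_attr(x),
               c(tmt_steps(x), "median"))
  attr(out, "all_missing") <- all_missing
  out
}

#' Log2-transform and z-score the normalized ratios
#'
#' Applies `log2` elementwise, then standardizes to mean 0 and SD 1 over the
#' observed entries of each sample column (the default) or of each protein
#' row.  The sample-SD convention (denominator n - 1) is used throughout.
#'
#' @param x Output of [median_center()].
#' @param by Standardize within each `"sample"` column (default) or each
#'   `"protein"` row.
#' @return Tibble of log2 z-scores with the step history updated.
#' @export
log2_zscore <- function(x, by = c("sample", "protein")) {
  by <- match.arg(by)
  check_steps(x, "median", "log2_zscore")
  m <- tmt_matrix(x)
  nonpos <- which(m <= 0, arr.ind = TRUE)
  if (nrow(nonpos)) {
    tmt_error("tmtdiff_transform_error", sprintf(
      "Non-positive value at protein '%s', sample '%s': cannot log2-transform.",
      rownames(m)[nonpos[1, 1]], colnames(m)[nonpos[1, 2]]))
  }
  lm <- log2(m)
  zscore <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(NULL)
    (v - mean(v, na.rm = TRUE)) / s
  }
  if (by == "sample") {
    for (j in seq_len(ncol(lm))) {
      z <- zscore(lm[, j])
      if (is.null(z)) {
        tmt_error("tmtdiff_transform_error", sprintf(
          "Sample '%s' has zero spread; z-score undefined.", colnames(lm)[j]))
      }
      lm[, j] <- z
    }
  } else {
    for (i in seq_len(nrow(lm))) {
      z <- zscore(lm[i, ])
      if (is.null(z)) {
        tmt_error("tmtdiff_transform_error", sprintf(
          "Protein '%s' has zero spread; z-score undefined.", rownames(lm)[i]))
      }
      lm[i, ] <- z
    }
  }
  out <- stamp(mat_to_tbl(lm), tmt_annotation_attr(x),
               c(tmt_steps(x), "log2_zscore"))
  attr(out, "zscore_by") <- by
  out
}

#' Remove proteins with any missing value
#'
#' Retains exactly the proteins observed in every biological sample,
#' preserving order.  Statistics downstream assume a complete matrix.
#'
#' @param x Output of [log2_zscore()].
#' @return Tibble restricted to complete rows; the number dropped is reported.
#' @export
drop_missing <- function(x) {
  check_steps(x, "log2_zscore", "drop_missing")
  keep <- complete.cases(x[, -1, drop = FALSE])
  inform(sprintf("drop_missing: retained %d of %d proteins.",
                 sum(keep), length(keep)))
  out <- stamp(x[keep, ], tmt_annotation_attr(x),
               c(tmt_steps(x), "drop_missing"))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Two-dimensional PCA batch diagnostic with a silhouette score
#'
#' Projects samples onto the first two principal components of the
#' sample-by-protein matrix and scores how separated the batches are as the
#' mean silhouette width of the batch labels on those coordinates (Euclidean
#' distance).  Values near 0 mean batches are intermixed; values near 1 mean
#' strong batch structure.
#'
#' @param x A complete normalized matrix (after [drop_missing()], before or
#'   after [combat_adjust()]).
#' @param batches Optional batch labels; defaults to the attached annotation.
#' @return A `tmt_pca` list: `scores` (tibble: sample, group, batch, PC1, PC2),
#'   `silhouette` (mean width, `NA` with a single batch), `var_explained`.
#' @export
batch_pca <- function(x, batches = NULL) {
  m <- tmt_matrix(x)
  if (ncol(m) < 3) {
    tmt_error("tmtdiff_input_error", "PCA diagnostic needs at least 3 samples.")
  }
  if (nrow(m) < 2) {
    tmt_error("tmtdiff_input_error", "PCA diagnostic needs at least 2 proteins.")
  }
  if (anyNA(m)) {
    tmt_error("tmtdiff_input_error", "Matrix must be complete; run drop_missing() first.")
  }
  ann <- tmt_annotation_attr(x)
  if (is.null(batches)) batches <- ann$batch
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  sil <- if (length(unique(batches)) < 2) NA_real_ else {
    mean(cluster::silhouette(as.integer(factor(batches)),
                             stats::dist(coords))[, "sil_width"])
  }
  structure(list(
    scores = tibble(sample = colnames(m), group = ann$group,
                    batch = batches, PC1 = coords[, 1], PC2 = coords[, 2]),
    silhouette = sil,
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  ), class = "tmt_pca")
}

#' @export
print.tmt_pca <- function(x, ...) {
  cat(sprintf("<tmt_pca> %d samples; PC1 %.1f%%, PC2 %.1f%%; batch silhouette %.3f\n",
              nrow(x$scores), 100 * x$var_explained[1], 100 * x$var_explained[2],
              x$silhouette))
  invisible(x)
}
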