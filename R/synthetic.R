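#' Configuration for the synthetic multi-batch TMT generator
#'
#' Describes a multiplexed isobaric-labelling experiment: several TMT batches,
#' each carrying one pooled-reference (master pool) channel, with case and
#' control samples spread across batches as evenly as possible.  Defaults
#' mirror a three-batch 11-plex design with 15 cases and 15 controls, a
#' spiked differential fraction at +/- log2(1.5) and residual log2-scale
#' noise of 0.208.
#'
#' @param n_proteins Number of proteins simulated.
#' @param n_case,n_control Biological sample sizes per group.
#' @param n_batches Number of TMT batches; each gets one reference channel.
#' @param spike_fraction Fraction of proteins given a true group effect.
#' @param effect_log2fc Absolute log2 fold change of spiked proteins
#'   (default `log2(1.5)` = 0.585); signs split half up, half down.
#' @param residual_sigma Within-group residual SD on the log2 scale.
#' @param batch_additive_sd SD of the per-protein-per-batch additive log2
#'   shift (location batch effect).
#' @param batch_multiplicative_shape Shape of the inverse-gamma law (mean 1)
#'   generating per-protein-per-batch variance inflation; larger means less
#'   inflation, `Inf` disables it. Must exceed 1.
#' @param missing_rate Probability that a biological-sample entry is missing
#'   (missing completely at random); reference channels are never missing.
#' @param baseline_mean,baseline_sd Log2-scale mean and SD of per-protein
#'   baseline intensities.
#' @param seed Integer RNG seed; the same config and seed reproduce the
#'   dataset bit for bit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1000, n_case = 15, n_control = 15,
                             n_batches = 3, spike_fraction = 0.1,
                             effect_log2fc = log2(1.5), residual_sigma = 0.208,
                             batch_additive_sd = 0.3,
                             batch_multiplicative_shape = 25,
                             missing_rate = 0.02,
                             baseline_mean = 20, baseline_sd = 2,
                             seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_case = n_case, n_control = n_control,
              n_batches = n_batches, spike_fraction = spike_fraction,
              effect_log2fc = effect_log2fc, residual_sigma = residual_sigma,
              batch_additive_sd = batch_additive_sd,
              batch_multiplicative_shape = batch_multiplicative_shape,
              missing_rate = missing_rate, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      tmt_error("tmtdiff_config_error",
                sprintf("Invalid synthetic config: '%s' %s.", field, what))
    }
  }
  for (f in c("n_proteins", "n_case", "n_control", "n_batches")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1 &&
          cfg[[f]] == round(cfg[[f]]), f, "must be a count >= 1")
  }
  for (f in c("spike_fraction", "missing_rate")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must be a proportion in [0, 1]")
  }
  chk(cfg$residual_sigma > 0, "residual_sigma", "must be > 0")
  chk(cfg$batch_additive_sd >= 0, "batch_additive_sd", "must be >= 0")
  chk(cfg$batch_multiplicative_shape > 1, "batch_multiplicative_shape",
      "must be > 1 (use Inf for no inflation)")
  chk(cfg$baseline_sd >= 0, "baseline_sd", "must be >= 0")
  invisible(cfg)
}

tmt11_channels <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C")

# Round-robin assignment of each group across batches: as balanced as the
# counts allow.
assign_batches <- function(n_case, n_control, n_batches) {
  tibble(
    sample = c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("control_%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    batch = c(rep_len(seq_len(n_batches), n_case),
              rep_len(seq_len(n_batches), n_control))
  )
}

#' Generate a synthetic multi-batch TMT dataset with known ground truth
#'
#' Simulates per-protein log2 intensities with a protein baseline, a signed
#' group effect on a spiked subset, an additive per-batch location shift, a
#' multiplicative per-batch variance inflation of the residual noise, and
#' MCAR missingness on biological entries, then exponentiates to linear
#' reporter-style intensities.  Each batch carries one master-pool reference
#' column whose value per protein is the mean of all biological samples'
#' pre-noise linear intensities, shifted by that batch's location effect
#' (the pool is mixed once and measured in every batch).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `tmt_dataset` with elements `abundance` (tibble:
#'   `protein` + one column per sample, linear scale, `NA` = missing),
#'   `annotation` (tibble: `sample`, `group`, `batch`, `channel`), `truth`
#'   (tibble: `protein`, `is_spiked`, `true_log2fc`, with per-batch effects in
#'   `attr(truth, "batch_effects")`), and the `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  G <- config$n_proteins
  ann <- assign_batches(config$n_case, config$n_control, config$n_batches)
  n_bio <- nrow(ann)
  if (any(table(ann$batch) + 1L > length(tmt11_channels))) {
    inform("More than 10 biological samples per batch: channel ids recycle beyond the 11-plex set.")
  }
  ann$channel <- character(n_bio)
  for (b in unique(ann$batch)) {
    i <- which(ann$batch == b)
    ann$channel[i] <- rep_len(tmt11_channels[-length(tmt11_channels)], length(i))
  }
  # reference channel uses the last 11-plex label in every batch
  ref_ann <- tibble(sample = sprintf("ref_b%d", seq_len(config$n_batches)),
                    group = "reference", batch = seq_len(config$n_batches),
                    channel = tmt11_channels[length(tmt11_channels)])

  proteins <- sprintf("P%05d", seq_len(G))
  with_seed(config$seed, {
    base <- rnorm(G, config$baseline_mean, config$baseline_sd)
    n_spike <- round(config$spike_fraction * G)
    spiked_idx <- sample.int(G, n_spike)
    signs <- rep(c(1, -1), length.out = n_spike)
    if (n_spike > 1) signs <- sample(signs)
    effect <- numeric(G)
    effect[spiked_idx] <- signs * config$effect_log2fc

    # pre-noise log2 means per protein x biological sample
    mu <- matrix(base, G, n_bio) +
      outer(effect, as.numeric(ann$group == "case"))
    # per-batch effects
    gamma <- matrix(rnorm(G * config$n_batches, 0, config$batch_additive_sd),
                    G, config$n_batches)
    delta2 <- if (is.finite(config$batch_multiplicative_shape)) {
      a <- config$batch_multiplicative_shape
      matrix(1 / rgamma(G * config$n_batches, shape = a, rate = a - 1),
             G, config$n_batches)
    } else {
      matrix(1, G, config$n_batches)
    }
    bcol <- ann$batch
    noise <- matrix(rnorm(G * n_bio, 0, config$residual_sigma), G, n_bio)
    y <- mu + gamma[, bcol, drop = FALSE] +
      sqrt(delta2[, bcol, drop = FALSE]) * noise
    intensities <- 2^y

    # master pool: linear-scale mean of pre-noise biological intensities
    pool <- rowMeans(2^mu)
    ref <- pool * 2^gamma  # one column per batch

    if (config$missing_rate > 0) {
      mask <- matrix(runif(G * n_bio) < config$missing_rate, G, n_bio)
      intensities[mask] <- NA_real_
    }
  })

  colnames(intensities) <- ann$sample
  colnames(ref) <- ref_ann$sample
  abundance <- dplyr::bind_cols(tibble(protein = proteins),
                                as_tibble(intensities), as_tibble(ref))
  annotation <- dplyr::bind_rows(ann, ref_ann)

  truth <- tibble(protein = proteins,
                  is_spiked = seq_len(G) %in% spiked_idx,
                  true_log2fc = effect)
  attr(truth, "batch_effects") <- tibble(
    protein = rep(proteins, config$n_batches),
    batch = rep(seq_len(config$n_batches), each = G),
    gamma = as.vector(gamma), delta2 = as.vector(delta2))
  attr(truth, "seed") <- config$seed

  structure(list(abundance = abundance, annotation = annotation,
                 truth = truth, config = config),
            class = "tmt_dataset")
}

#' @export
print.tmt_dataset <- function(x, ...) {
  cat(sprintf("<tmt_dataset> %d proteins x %d samples (%d batches, %d spiked)\n",
              nrow(x$abundance), nrow(x$annotation),
              x$config$n_batches, sum(x$truth$is_spiked)))
  invisible(x)
}

#' Score a selection against synthetic ground truth
#'
#' Confusion counts and the empirical false-discovery proportion / power of a
#' selected protein set, judged against the spiked set of a synthetic dataset.
#' The 0/0 cases are defined as 0 (empty selection gives FDR 0; no spiked
#' proteins give power 0).
#'
#' @param selected Character vector of selected protein ids (subset of the
#'   generated ids).
#' @param truth The `truth` tibble from [generate_dataset()].
#' @return One-row tibble: `true_positives`, `false_positives`,
#'   `true_negatives`, `false_negatives`, `empirical_fdr`, `empirical_power`.
#' @export
evaluate_selection <- function(selected, truth) {
  selected <- unique(as.character(selected))
  unknown <- setdiff(selected, truth$protein)
  if (length(unknown)) {
    tmt_error("tmtdiff_input_error",
              paste0("Unknown protein ids: ",
                     paste(head(unknown, 5), collapse = ", "),
                     if (length(unknown) > 5) ", ..."))
  }
  sel <- truth$protein %in% selected
  tp <- sum(sel & truth$is_spiked)
  fp <- sum(sel & !truth$is_spiked)
  fn <- sum(!sel & truth$is_spiked)
  tn <- sum(!sel & !truth$is_spiked)
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  tibble(true_positives = tp, false_positives = fp,
         true_negatives = tn, false_negatives = fn,
         empirical_fdr = ratio0(fp, tp + fp),
         empirical_power = ratio0(tp, tp + fn))
}
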