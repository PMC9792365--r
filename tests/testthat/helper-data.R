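# Builders shared across test files.  Everything is generated in code.

# Wrap a numeric matrix as a mid-pipeline normalized table.
norm_tbl <- function(m, groups, batches = rep(1, ncol(m)),
                     proteins = sprintf("P%04d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  x <- dplyr::bind_cols(tibble::tibble(protein = proteins),
                        tibble::as_tibble(m, .name_repair = "minimal"))
  ann <- tibble::tibble(sample = colnames(m), group = groups, batch = batches)
  as_normalized(x, ann)
}

# iid standard-normal null matrix with alternating case/control labels.
null_norm_tbl <- function(G, n = 30, seed = 1, batches = rep(1, n)) {
  set.seed(seed)
  norm_tbl(matrix(rnorm(G * n), G, n),
           groups = rep(c("case", "control"), length.out = n),
           batches = batches)
}

# Batch-shifted unit-noise matrix plus its true per-batch shifts.
batch_shift_tbl <- function(G, seed, gamma_sd = 1, n_per_batch = 10,
                            n_batches = 3) {
  set.seed(seed)
  n <- n_per_batch * n_batches
  batch <- rep(seq_len(n_batches), each = n_per_batch)
  gamma <- matrix(rnorm(G * n_batches, 0, gamma_sd), G, n_batches)
  m <- matrix(rnorm(G * n), G, n) + gamma[, batch]
  list(x = norm_tbl(m, groups = rep(c("case", "control"), length.out = n),
                    batches = batch),
       gamma = gamma)
}

# Raw abundance table with one reference per batch, built by hand.
raw_abundance <- function(values, groups, batches,
                          proteins = sprintf("P%04d", seq_len(nrow(values)))) {
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  list(abundance = dplyr::bind_cols(tibble::tibble(protein = proteins),
                                    tibble::as_tibble(values, .name_repair = "minimal")),
       annotation = tibble::tibble(sample = colnames(values), group = groups,
                                   batch = batches))
}

# Full normalization cascade on a generated dataset.
norm_chain <- function(ds, protect_group = FALSE) {
  suppressMessages(suppressWarnings(
    ds$abundance |>
      reference_normalize(ds$annotation) |>
      median_center() |>
      log2_zscore() |>
      drop_missing() |>
      combat_adjust(protect_group = protect_group)))
}

# Brute-force AUC by explicit pair enumeration (independent oracle).
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels]; ct <- scores[!labels]
  tot <- 0
  for (x in cs) for (y in ct) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cs) * length(ct))
}

# Exhaustive hypergeometric upper tail (independent oracle).
hyper_tail_bruteforce <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Deterministic id universes for enrichment tests.
bg_ids <- function(N) sprintf("G%04d", seq_len(N))
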