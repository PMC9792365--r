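test_that("auc matches hand-enumerated pair counting", {
  expect_equal(auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auc(c(3, 1, 2, 0), c("case", "case", "control", "control")), 0.75)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), class = "tmtdiff_input_error")
})

test_that("auc equals the brute-force pairwise oracle and the Mann-Whitney U", {
  set.seed(20)
  for (i in 1:1000) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    scores <- round(rnorm(n1 + n0), 1)  # rounding forces ties
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_identical(auc(scores, labels), auc_bruteforce(scores, labels))
  }
  # U-statistic identity on tie-free data
  for (i in 1:50) {
    s <- rnorm(12); l <- rep(c(TRUE, FALSE), each = 6)
    w <- suppressWarnings(wilcox.test(s[l], s[!l]))
    expect_equal(auc(s, l), unname(w$statistic) / 36)
  }
})

test_that("negating scores reflects the AUC exactly", {
  set.seed(21)
  for (i in 1:200) {
    s <- round(rnorm(10), 1)
    l <- sample(c(rep(TRUE, 4), rep(FALSE, 6)))
    expect_equal(auc(-s, l), 1 - auc(s, l))
  }
})

test_that("bootstrap summaries behave at the separation limit and under the null", {
  sep <- norm_tbl(matrix(c(rep(10, 8), rep(0, 8)), 1), groups = rep(c("case", "control"), each = 8))
  out <- bootstrap_auc(sep, B = 200, seed = 1)
  expect_equal(out$auc, 1)
  expect_equal(out$mean_auc, 1)
  expect_equal(out$sd_auc, 0)

  x <- null_norm_tbl(400, n = 30, seed = 22)
  res <- bootstrap_auc(x, B = 300, seed = 2)
  expect_equal(mean(res$mean_auc), 0.5, tolerance = 3 * 0.1 / sqrt(400))
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  expect_true(all(res$sd_auc >= 0))

  # determinism
  expect_identical(res$mean_auc, bootstrap_auc(x, B = 300, seed = 2)$mean_auc)
})

test_that("swapping class labels reflects the bootstrap mean about one half", {
  x <- null_norm_tbl(100, n = 20, seed = 23)
  ann <- attr(x, "tmt_annotation")
  y <- x
  attr(y, "tmt_annotation")$group <- ifelse(ann$group == "case", "control", "case")
  a <- bootstrap_auc(x, B = 400, seed = 5)
  b <- bootstrap_auc(y, B = 400, seed = 5)
  expect_equal(b$auc, 1 - a$auc)                      # point AUC: exact
  expect_equal(b$mean_auc, 1 - a$mean_auc, tolerance = 0.05)  # Monte-Carlo
})

test_that("increasing B stabilizes the bootstrap mean", {
  x <- null_norm_tbl(1, n = 24, seed = 24)
  spread <- function(B) {
    ms <- vapply(1:15, function(s) bootstrap_auc(x, B = B, seed = s)$mean_auc, 0)
    var(ms)
  }
  expect_lt(spread(400), spread(25))
})

test_that("null permutation pool centres on one half with full provenance", {
  x <- null_norm_tbl(2, n = 16, seed = 25)
  nb <- null_bootstrap_auc(x, B = 50, n_permutations = 1, seed = 1)
  expect_equal(nrow(nb), 2)
  expect_named(nb, c("permutation", "protein", "mean_auc"))
  expect_identical(nb, null_bootstrap_auc(x, B = 50, n_permutations = 1, seed = 1))

  ds <- generate_dataset(synthetic_config(n_proteins = 300, missing_rate = 0, seed = 26))
  z <- norm_chain(ds)
  nb <- null_bootstrap_auc(z, B = 100, n_permutations = 8, seed = 2)
  expect_equal(mean(nb$mean_auc), 0.5, tolerance = 0.01)
})

test_that("sorted-ratio q-values: extremes, monotonicity, exact-half convention", {
  real <- tibble::tibble(
    protein = sprintf("P%02d", 1:6),
    auc = c(0.99, 0.9, 0.8, 0.5, 0.2, 0.1),
    mean_auc = c(0.99, 0.9, 0.8, 0.5, 0.2, 0.1),
    sd_auc = rep(0.05, 6))
  null_means <- tibble::tibble(
    permutation = rep(1:2, each = 4),
    protein = rep(sprintf("P%02d", 1:4), 2),
    mean_auc = c(0.6, 0.55, 0.45, 0.4, 0.62, 0.5, 0.48, 0.38))
  attr(null_means, "n_permutations") <- 2
  out <- bootauc_q(real, null_means)
  expect_equal(out$q[1], 0)            # nothing in the null is as extreme
  expect_equal(out$q[4], 1)            # mean AUC exactly 0.5
  up <- out$mean_auc > 0.5
  expect_true(all(diff(out$q[up][order(-out$mean_auc[up])]) >= -1e-12))
  dn <- out$mean_auc < 0.5
  expect_true(all(diff(out$q[dn][order(out$mean_auc[dn])]) >= -1e-12))
  expect_true(all(out$q >= 0 & out$q <= 1))
})

test_that("label swap leaves sorted-ratio q-values essentially invariant", {
  ds <- generate_dataset(synthetic_config(n_proteins = 200, missing_rate = 0, seed = 27))
  z <- norm_chain(ds)
  a <- diff_auc(z, B = 150, n_permutations = 10, seed = 3)
  y <- z
  attr(y, "tmt_annotation")$group <-
    ifelse(attr(z, "tmt_annotation")$group == "case", "control", "case")
  b <- diff_auc(y, B = 150, n_permutations = 10, seed = 3)
  expect_equal(b$mean_auc, 1 - a$mean_auc, tolerance = 0.05)
  expect_equal(mean(b$significant == a$significant), 1, tolerance = 0.02)
})

test_that("rank_by_sd sorts ascending with the documented tie-breaks, stably", {
  rows <- tibble::tibble(
    protein = c("B", "A", "C", "D"),
    auc = c(0.9, 0.6, 0.7, 0.8),
    mean_auc = c(0.9, 0.6, 0.95, 0.8),
    sd_auc = c(0.2, 0.01, 0.2, 0.01))
  r <- rank_by_sd(rows)
  # SD 0.01 rows first; within the tie, |mean - 0.5| larger first
  expect_equal(r$protein, c("D", "A", "C", "B"))
  expect_identical(rank_by_sd(rows), r)
})
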