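test_that("reference normalization divides by the same-batch master pool", {
  # batch 1: s01 s02 + ref s03; batch 2: s04 s05 + ref s06
  vals <- rbind(c(4, 8, 4, 6, 3, 3),
                c(10, 10, 10, 5, 5, 5))
  d <- raw_abundance(vals,
                     groups = c("case", "control", "reference",
                                "case", "control", "reference"),
                     batches = c(1, 1, 1, 2, 2, 2))
  out <- reference_normalize(d$abundance, d$annotation)
  expect_setequal(names(out)[-1], c("s01", "s02", "s04", "s05"))
  expect_equal(out$s01, c(1, 1))
  expect_equal(out$s02, c(2, 1))
  expect_equal(out$s04, c(2, 1))
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(1, 2, 2, 1))
})

test_that("missing or zero reference values blank the whole batch for that protein", {
  vals <- rbind(c(4, 8, NA, 6, 3, 3),
                c(10, 10, 10, 5, 5, 0))
  d <- raw_abundance(vals,
                     groups = c("case", "control", "reference",
                                "case", "control", "reference"),
                     batches = c(1, 1, 1, 2, 2, 2))
  expect_warning(reference_normalize(d$abundance, d$annotation),
                 "zero intensities")
  out <- suppressWarnings(reference_normalize(d$abundance, d$annotation))
  expect_true(all(is.na(out[1, c("s01", "s02")])))   # missing reference
  expect_true(all(is.na(out[2, c("s04", "s05")])))   # zero reference
  expect_false(anyNA(out[2, c("s01", "s02")]))
})

test_that("a batch-wide multiplicative shift cancels exactly in the ratios", {
  set.seed(1)
  vals <- matrix(2^rnorm(30 * 6, 10), 30, 6)
  groups <- c("case", "control", "reference", "case", "control", "reference")
  batches <- c(1, 1, 1, 2, 2, 2)
  d0 <- raw_abundance(vals, groups, batches)
  shifted <- vals
  shifted[, batches == 2] <- shifted[, batches == 2] * 2^1.7  # batch shift
  d1 <- raw_abundance(shifted, groups, batches)
  expect_equal(reference_normalize(d1$abundance, d1$annotation),
               reference_normalize(d0$abundance, d0$annotation))
})

test_that("a batch without a reference channel is a design error", {
  vals <- matrix(1, 2, 4)
  d <- raw_abundance(vals, groups = c("case", "control", "reference", "case"),
                     batches = c(1, 1, 1, 2))
  expect_error(reference_normalize(d$abundance, d$annotation),
               class = "tmtdiff_design_error")
})

test_that("median centring fixes each protein's median at one", {
  d <- raw_abundance(matrix(c(2, 2, 2, 4, 1), 1),
                     groups = c("case", "case", "control", "control", "reference"),
                     batches = rep(1, 5))
  out <- reference_normalize(d$abundance, d$annotation) |> median_center()
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(1, 1, 1, 2))

  d2 <- raw_abundance(matrix(c(1, 2, 3, 1), 1),
                      groups = c("case", "control", "case", "reference"),
                      batches = rep(1, 4))
  out2 <- reference_normalize(d2$abundance, d2$annotation) |> median_center()
  expect_equal(unlist(out2[1, -1], use.names = FALSE), c(1 / 2, 1, 3 / 2))

  # property: output median is 1 for every row, under missingness too
  set.seed(8)
  m <- matrix(2^rnorm(2000 * 8), 2000, 8)
  m[sample(length(m), 800)] <- NA
  d <- raw_abundance(cbind(m, 1), groups = c(rep(c("case", "control"), 4), "reference"),
                     batches = rep(1, 9))
  out <- reference_normalize(d$abundance, d$annotation) |> median_center()
  meds <- apply(as.matrix(out[, -1]), 1, median, na.rm = TRUE)
  expect_equal(meds[is.finite(meds)], rep(1, sum(is.finite(meds))),
               ignore_attr = TRUE)
})

test_that("log2/z-score uses the sample-SD convention per sample column", {
  vals <- cbind(c(1, 2, 4), c(1, 2, 4), c(8, 2, 1), c(16, 4, 1))
  # feed already-centred ratios in at the right pipeline stage
  x <- norm_tbl(vals, groups = c("case", "control", "case", "control"))
  attr(x, "tmt_steps") <- c("reference", "median")
  out <- log2_zscore(x)
  expect_equal(out$s01, c(-1, 0, 1))                # sample SD (n - 1)
  expect_equal(colMeans(as.matrix(out[, -1])), rep(0, 4),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(apply(as.matrix(out[, -1]), 2, sd), rep(1, 4),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("degenerate and non-positive inputs to the transform are errors", {
  x <- norm_tbl(cbind(c(1, 1, 1), c(1, 2, 4)), groups = c("case", "control"))
  attr(x, "tmt_steps") <- c("reference", "median")
  expect_error(log2_zscore(x), "zero spread", class = "tmtdiff_transform_error")

  y <- norm_tbl(cbind(c(1, 2, -4), c(1, 2, 4)), groups = c("case", "control"))
  attr(y, "tmt_steps") <- c("reference", "median")
  expect_error(log2_zscore(y), "Non-positive", class = "tmtdiff_transform_error")
})

test_that("per-protein z-scoring is available as an option", {
  set.seed(2)
  x <- norm_tbl(matrix(2^rnorm(40), 4, 10),
                groups = rep(c("case", "control"), 5))
  attr(x, "tmt_steps") <- c("reference", "median")
  out <- log2_zscore(x, by = "protein")
  expect_equal(apply(as.matrix(out[, -1]), 1, sd), rep(1, 4),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("drop_missing keeps exactly the complete rows, preserving order", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 1] <- NA; m[4, 3] <- NA
  x <- norm_tbl(m, groups = rep(c("case", "control"), 2))
  attr(x, "tmt_steps") <- c("reference", "median", "log2_zscore")
  out <- suppressMessages(drop_missing(x))
  expect_equal(out$protein, sprintf("P%04d", c(1, 3, 5)))
  expect_equal(attr(out, "n_dropped"), 2)
  # no missing anywhere -> identity
  y <- norm_tbl(matrix(rnorm(20), 5, 4), groups = rep(c("case", "control"), 2))
  attr(y, "tmt_steps") <- c("reference", "median", "log2_zscore")
  expect_equal(nrow(suppressMessages(drop_missing(y))), 5)
})

test_that("retention under MCAR matches the analytic expectation", {
  cfg <- synthetic_config(n_proteins = 4000, missing_rate = 0.02, seed = 14)
  ds <- generate_dataset(cfg)
  z <- suppressMessages(
    ds$abundance |> reference_normalize(ds$annotation) |> median_center() |>
      log2_zscore() |> drop_missing())
  expected <- 0.98^30
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_equal(nrow(z) / 4000, expected, tolerance = 5 * se / expected)
})

test_that("pipeline order is enforced", {
  ds <- generate_dataset(synthetic_config(n_proteins = 30, seed = 2))
  r <- reference_normalize(ds$abundance, ds$annotation)
  expect_error(log2_zscore(r), class = "tmtdiff_state_error")      # skipped median
  expect_error(drop_missing(r), class = "tmtdiff_state_error")
  m <- median_center(r)
  expect_error(combat_adjust(m), class = "tmtdiff_state_error")
  expect_no_error(suppressMessages(m |> log2_zscore() |> drop_missing()))
})

test_that("PCA diagnostic: duplicated batches score near zero, and it is input-order invariant", {
  set.seed(4)
  m <- matrix(rnorm(200 * 10), 200, 10)
  x <- norm_tbl(cbind(m, m), groups = rep(c("case", "control"), 10),
                batches = rep(c(1, 2), each = 10),
                proteins = sprintf("P%04d", 1:200))
  # with every point duplicated across the two fictitious batches the
  # silhouette is exactly -1/n_per_batch: no separation, vanishing with n
  expect_equal(batch_pca(x)$silhouette, -0.1, tolerance = 1e-8)

  # protein reordering leaves coordinates (hence silhouette) unchanged
  y <- norm_tbl(m, groups = rep(c("case", "control"), 5),
                batches = rep(c(1, 2), 5))
  perm <- sample(200)
  y_perm <- y[perm, ]
  p1 <- batch_pca(y); p2 <- batch_pca(y_perm)
  expect_equal(abs(p1$scores$PC1), abs(p2$scores$PC1), tolerance = 1e-8)
  expect_equal(p1$silhouette, p2$silhouette, tolerance = 1e-8)

  small <- norm_tbl(matrix(rnorm(4), 2, 2), groups = c("case", "control"))
  expect_error(batch_pca(small), class = "tmtdiff_input_error")
})
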