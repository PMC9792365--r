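test_that("pooled t matches hand computation and stats::t.test", {
  x <- norm_tbl(matrix(c(1, 2, 3, 4, 5, 6), 1),
                groups = rep(c("case", "control"), each = 3))
  out <- two_sample_t(x)
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$p, 0.0214, tolerance = 1e-2)
  expect_equal(out$df, 4)

  set.seed(5)
  m <- matrix(rnorm(20 * 12), 20, 12)
  grp <- rep(c("case", "control"), each = 6)
  y <- norm_tbl(m, groups = grp)
  pooled <- two_sample_t(y)
  welch <- two_sample_t(y, var_equal = FALSE)
  for (i in 1:20) {
    rp <- t.test(m[i, grp == "case"], m[i, grp == "control"], var.equal = TRUE)
    rw <- t.test(m[i, grp == "case"], m[i, grp == "control"])
    expect_equal(pooled$t[i], unname(rp$statistic))
    expect_equal(pooled$p[i], rp$p.value)
    expect_equal(welch$t[i], unname(rw$statistic))
    expect_equal(welch$df[i], unname(rw$parameter))
  }
})

test_that("identical groups hit the degenerate-variance guard", {
  m <- matrix(5, 2, 6)
  y <- norm_tbl(m, groups = rep(c("case", "control"), 3))
  out <- two_sample_t(y)
  expect_equal(out$t, c(0, 0))
  expect_equal(out$p, c(1, 1))
})

test_that("null p-values are uniform", {
  x <- null_norm_tbl(10000, n = 30, seed = 6)
  p <- two_sample_t(x)$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("type-I error at alpha 1e-4 matches the nominal rate", {
  hits <- 0L; total <- 0L
  for (chunk in 1:4) {
    x <- null_norm_tbl(250000, n = 30, seed = 600 + chunk)
    p <- two_sample_t(x)$p
    hits <- hits + sum(p < 1e-4)
    total <- total + length(p)
  }
  expect_equal(total, 1e6)
  # 95% binomial band around 1e-4
  expect_true(abs(hits - 100) < 4 * 10)
})

test_that("fold change behaves on constructed and simulated data", {
  vals <- rbind(c(2, 2, 2, 2, 1), c(4, 4, 2, 2, 1))
  d <- raw_abundance(vals, groups = c("case", "case", "control", "control", "reference"),
                     batches = rep(1, 5))
  ctr <- reference_normalize(d$abundance, d$annotation) |> median_center()
  fc <- fold_change(ctr)
  expect_equal(fc$fold_change[1], 1)
  expect_equal(fc$fold_change[2], 2)

  z <- suppressMessages(log2_zscore(ctr))
  expect_error(fold_change(z), class = "tmtdiff_state_error")

  ds <- generate_dataset(synthetic_config(n_proteins = 800, missing_rate = 0, seed = 12))
  ctr <- suppressMessages(
    ds$abundance |> reference_normalize(ds$annotation) |> median_center())
  fc <- fold_change(ctr)
  up <- ds$truth$true_log2fc > 0
  expect_equal(mean(fc$fold_change[up]), 1.5, tolerance = 0.03)
  expect_equal(mean(fc$fold_change[ds$truth$true_log2fc < 0]), 1 / 1.5,
               tolerance = 0.03)
})

test_that("with s0 = 0 the moderated ranking equals the |t| ranking", {
  x <- null_norm_tbl(200, n = 16, seed = 7)
  sr <- sam(x, s0 = 0, n_permutations = 25, seed = 1)
  expect_equal(order(abs(sr$d)), order(abs(sr$t)))
  expect_equal(sr$d, sr$t)  # d reduces to t exactly when s0 = 0
})

test_that("sam is deterministic under a fixed seed and invariant to protein order", {
  x <- null_norm_tbl(150, n = 20, seed = 8)
  a <- sam(x, n_permutations = 50, seed = 99)
  b <- sam(x, n_permutations = 50, seed = 99)
  expect_identical(a$q, b$q)

  perm <- sample(150)
  xp <- x[perm, ]
  cp <- sam(xp, n_permutations = 50, seed = 99)
  expect_equal(cp$q, a$q[perm])
})

test_that("relabelling case and control flips d and preserves q (exhaustive permutations)", {
  set.seed(9)
  m <- matrix(rnorm(40 * 8), 40, 8)
  grp <- rep(c("case", "control"), 4)
  x <- norm_tbl(m, groups = grp)
  y <- norm_tbl(m, groups = ifelse(grp == "case", "control", "case"))
  a <- suppressMessages(sam(x, n_permutations = 100, seed = 1))  # C(8,4)=70 -> exhaustive
  b <- suppressMessages(sam(y, n_permutations = 100, seed = 1))
  expect_equal(b$d, -a$d)
  expect_equal(b$q, a$q)
  expect_true(attr(a, "sam_config")$exhaustive)
  expect_equal(attr(a, "sam_config")$n_permutations, 70)
})

test_that("q-values are monotone in |d| and flags match the attained cutoff", {
  ds <- generate_dataset(synthetic_config(n_proteins = 500, missing_rate = 0, seed = 15))
  z <- norm_chain(ds)
  sr <- sam(z, n_permutations = 100, seed = 3)
  ord <- order(abs(sr$d), decreasing = TRUE)
  expect_true(all(diff(sr$q[ord]) >= -1e-12))
  expect_true(all(sr$q >= 0 & sr$q <= 1))
  d_cut <- attr(sr, "d_cut")
  expect_equal(sr$significant, abs(sr$d) >= d_cut)
})

test_that("the volcano boundary is flat at s0 = 0 and curved, monotone, consistent otherwise", {
  ds <- generate_dataset(synthetic_config(n_proteins = 400, missing_rate = 0, seed = 16))
  z <- norm_chain(ds)

  s_flat <- sam(z, s0 = 0, n_permutations = 100, seed = 4)
  b_flat <- volcano_boundary(s_flat)
  finite <- is.finite(b_flat$neg_log10_p)
  expect_lt(diff(range(b_flat$neg_log10_p[finite])), 1e-8)

  s_curv <- sam(z, s0 = 0.1, n_permutations = 100, seed = 4)
  b_curv <- volcano_boundary(s_curv)
  pos <- b_curv$mean_diff > 0 & is.finite(b_curv$neg_log10_p)
  expect_true(all(diff(b_curv$neg_log10_p[pos]) <= 1e-9))

  # the boundary classifies exactly as the q flag: significance iff the
  # protein's own (|mean_diff|, -log10 p) sits on or above the curve
  bd <- volcano_boundary(s_curv, effects = s_curv$mean_diff)
  above <- -log10(s_curv$p) >= bd$neg_log10_p - 1e-9
  expect_equal(above, s_curv$significant)
})

test_that("the normality screen separates normal from skewed rows", {
  set.seed(17)
  norm_x <- norm_tbl(matrix(rnorm(1000 * 30), 1000, 30),
                     groups = rep(c("case", "control"), 15))
  res_n <- shapiro_normality(norm_x)
  expect_equal(attr(res_n, "fraction_normal"), 0.95, tolerance = 0.04)

  skew_x <- norm_tbl(matrix(rexp(200 * 30), 200, 30),
                     groups = rep(c("case", "control"), 15))
  res_s <- shapiro_normality(skew_x)
  expect_lt(median(res_s$p), median(res_n$p))

  const <- norm_tbl(rbind(rep(1, 10), rnorm(10)),
                    groups = rep(c("case", "control"), 5))
  res_c <- shapiro_normality(const)
  expect_true(res_c$flagged[1])
  expect_false(res_c$flagged[2])
})
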