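test_that("welch_t_test matches the independent textbook evaluation", {
  x <- c(0.1, 0.2, 0.3)
  y <- c(0.4, 0.5, 0.6)
  w <- welch_t_test(x, y)
  expect_equal(w$welch_t, -3.674, tolerance = 1e-3)
  expect_equal(w$welch_df, 4.0, tolerance = 1e-6)
  expect_equal(w$p_value, 0.0213, tolerance = 1e-3)
  # cross-check against stats::t.test on random inputs, to 1e-9
  set.seed(33)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), mean = runif(1))
    w <- welch_t_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$welch_t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$welch_df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("welch_t_test is antisymmetric and handles degenerate input", {
  a <- c(0.2, 0.25, 0.3, 0.4)
  b <- c(0.5, 0.55, 0.7)
  w1 <- welch_t_test(a, b)
  w2 <- welch_t_test(b, a)
  expect_equal(w1$p_value, w2$p_value)
  expect_equal(w1$welch_t, -w2$welch_t)
  # identical zero-variance groups: t = 0, p = 1
  w <- welch_t_test(rep(0.4, 3), rep(0.4, 5))
  expect_equal(w$welch_t, 0)
  expect_equal(w$p_value, 1)
  expect_false(w$untestable)
  # zero variance, different means: untestable rather than p = 0
  w <- welch_t_test(rep(0.4, 3), rep(0.6, 5))
  expect_true(w$untestable)
  expect_true(is.na(w$p_value))
  # fewer than 2 per group: untestable
  expect_true(welch_t_test(0.4, c(0.5, 0.6))$untestable)
})

test_that("bh_adjust reproduces the hand-stepped procedure", {
  # step-up by hand: sorted p (m/i) -> cumulative min from the largest
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.31, 0.04, 0.9, 0.02)
  manual <- {
    o <- order(p)
    m <- length(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_adjust(p), manual)
  # stable under permutation
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # monotone on the sorted raw p's and idempotent once adjusted
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("differential_editing tests per site and adjusts jointly", {
  design <- tibble::tibble(
    sample_id = c(sprintf("c%02d", 1:4), sprintf("e%02d", 1:4)),
    group = rep(c("control", "case"), each = 4)
  )
  set.seed(12)
  n <- matrix(500L, 3, 8, dimnames = list(
    c("mA:6", "mB:4", "mC:2"), design$sample_id
  ))
  k <- n
  k["mA:6", ] <- rbinom(8, 500, rep(c(0.8, 0.4), each = 4)) # real difference
  k["mB:4", ] <- rbinom(8, 500, 0.5)                        # null
  k["mC:2", ] <- rbinom(8, 500, 0.5)                        # null
  em <- as_editing_matrix(k, n, design)
  de <- differential_editing(em, design, alpha = 0.05)
  expect_s3_class(de, "edit_diff")
  expect_equal(nrow(de), 3L)
  expect_true(de$significant[de$mature_id == "mA"])
  # row-wise results equal the scalar Welch on the same cells
  i <- which(de$mature_id == "mA")
  w <- welch_t_test(em$level["mA:6", design$group == "control"],
                    em$level["mA:6", design$group == "case"])
  expect_equal(de$welch_t[i], w$welch_t, tolerance = 1e-12)
  expect_equal(de$welch_df[i], w$welch_df, tolerance = 1e-12)
  expect_equal(de$p_raw[i], w$p_value, tolerance = 1e-12)
  # BH family: adjusted values match bh_adjust over all testable rows
  expect_equal(de$p_bh, bh_adjust(de$p_raw))
  # glance and tidy are consistent
  g <- glance(de)
  expect_equal(g$n_significant, sum(de$significant))
  expect_equal(names(tidy(de))[1], "mature_id")
})

test_that("a single-site matrix gets p_bh equal to p_raw", {
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           group = rep(c("a", "b"), each = 3))
  k <- matrix(c(400L, 410L, 390L, 200L, 210L, 190L), 1,
              dimnames = list("m:6", design$sample_id))
  n <- matrix(500L, 1, 6, dimnames = dimnames(k))
  de <- differential_editing(as_editing_matrix(k, n, design), design)
  expect_equal(de$p_bh, de$p_raw)
})

test_that("design errors are caught", {
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                           group = rep(c("a", "b"), each = 2))
  k <- matrix(1L, 1, 4, dimnames = list("m:1", design$sample_id))
  em <- as_editing_matrix(k, k + 10L, design)
  expect_error(differential_editing(em, dplyr::mutate(design, sample_id = paste0("x", sample_id))),
               "not in matrix")
  expect_error(differential_editing(em, dplyr::mutate(design, group = "a")),
               "two groups")
})

test_that("abundance residuals are zero for proportional data and sum to ~0", {
  d <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                      total = c(100, 200, 400, 800, 1600, 3200))
  d$edited <- 0.5 * d$total
  fit <- abundance_residuals(d, edited, total, transform = "linear")
  expect_equal(fit$residual, rep(0, 6), tolerance = 1e-9)
  expect_equal(attr(fit, "pearson_r"), 1)
  # noisy case: least-squares residuals sum to zero
  set.seed(5)
  d$edited <- 0.5 * d$total + rnorm(6, sd = 20)
  fit <- abundance_residuals(d, edited, total, transform = "log2_cpm_plus1")
  expect_lt(abs(sum(fit$residual)), 1e-9 * max(abs(fit$edited_t)))
  g <- glance(fit)
  expect_equal(g$transform, "log2_cpm_plus1")
  expect_false(g$degenerate)
})

test_that("degenerate and undersized abundance input is flagged or rejected", {
  d <- tibble::tibble(total = rep(100, 5), edited = c(10, 20, 30, 40, 50))
  fit <- abundance_residuals(d, edited, total, transform = "linear")
  expect_true(attr(fit, "degenerate"))
  expect_true(is.na(attr(fit, "pearson_r")))
  expect_error(
    abundance_residuals(tibble::tibble(total = 1:2, edited = 1:2), edited, total),
    "at least 3"
  )
})

test_that("a group shifted above the fitted line has all-positive residuals", {
  set.seed(8)
  total <- c(rexp(8, 1 / 500) + 200, rexp(8, 1 / 500) + 200)
  edited <- 0.6 * total
  edited[9:16] <- edited[9:16] * 2.2 # planted offset group
  d <- tibble::tibble(sample_id = sprintf("s%02d", 1:16),
                      group = rep(c("base", "shift"), each = 8),
                      total = total, edited = edited)
  fit <- abundance_residuals(d, edited, total, transform = "log2_cpm_plus1")
  expect_true(all(fit$residual[fit$group == "shift"] > 0))
})

test_that("median-of-ratios reproduces hand-computed factors and DESeq2", {
  m <- rbind(c(2, 4), c(4, 8), c(6, 12))
  sf <- median_of_ratios_normalize(m)$size_factors
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)
  # identical columns -> unit factors
  m2 <- cbind(c(5, 9, 2), c(5, 9, 2))
  expect_equal(unname(median_of_ratios_normalize(m2)$size_factors), c(1, 1))
  # scale equivariance of factor ratios: multiplying one sample's counts by
  # c multiplies its size factor relative to any other sample by exactly c
  # (raw factors each absorb a c^(1/n) change of the geometric means)
  m3 <- cbind(a = c(10, 20, 30), b = c(12, 25, 28), c = c(9, 18, 33))
  sf3 <- median_of_ratios_normalize(m3)$size_factors
  m3c <- m3
  m3c[, 2] <- m3c[, 2] * 3
  sf3c <- median_of_ratios_normalize(m3c)$size_factors
  expect_equal(unname(sf3c[2] / sf3c[1]), unname(3 * sf3[2] / sf3[1]),
               tolerance = 1e-12)
  # agreement with the reference implementation (odd gene count: the median
  # of ratios then coincides exactly with the exponentiated log-space median)
  skip_if_not_installed("DESeq2")
  set.seed(2)
  cm <- matrix(rnbinom(606, mu = 100, size = 5), ncol = 6)
  expect_equal(
    unname(median_of_ratios_normalize(cm)$size_factors),
    unname(DESeq2::estimateSizeFactorsForMatrix(cm)),
    tolerance = 1e-9
  )
  expect_error(median_of_ratios_normalize(rbind(c(0, 1), c(1, 0))),
               "all-positive")
})

test_that("spearman correlation equals the mid-rank Pearson oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  expect_equal(spearman_correlation(x, y), cor(rank(x), rank(y)))
  # monotone transforms give +/- 1
  z <- sort(runif(10))
  expect_equal(spearman_correlation(z, exp(z)), 1)
  expect_equal(spearman_correlation(z, rev(z)), -1)
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})
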