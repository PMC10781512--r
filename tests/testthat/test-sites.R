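# counts fixture: one A>G candidate site at m1:+6 across a chosen number of
# samples, with per-sample edited (k) and total (n) read counts
counts_fixture <- function(k, n, samples = sprintf("s%02d", seq_along(k))) {
  tibble::tibble(
    sample_id = samples, mature_id = "m1-3p", position = 6L, ref_base = "A",
    A = as.integer(n - k), C = 0L, G = as.integer(k), U = 0L
  )
}

test_that("editing level is the k/n ratio, missing at zero coverage", {
  expect_equal(compute_editing_level(80, 100), 0.8)
  expect_equal(compute_editing_level(0, 50), 0)
  expect_true(is.na(compute_editing_level(0, 0)))
  expect_error(compute_editing_level(10, 0), "exceed")
  expect_error(compute_editing_level(5, 4), "exceed")
})

test_that("binomial error tail matches a naive pmf-summation oracle", {
  pmf_sum <- function(k, n, p) sum(dbinom(k:n, n, p))
  expect_equal(binomial_error_pvalue(0, 50, 0.01), 1.0)
  expect_equal(binomial_error_pvalue(2, 100, 0.01), pmf_sum(2, 100, 0.01),
               tolerance = 1e-12)
  expect_equal(round(binomial_error_pvalue(2, 100, 0.01), 3), 0.264)
  expect_lt(binomial_error_pvalue(10, 100, 0.01), 1e-6)
  # exhaustive agreement over a grid of n up to 1000
  set.seed(1)
  for (n in c(1, 7, 64, 333, 1000)) {
    ks <- unique(c(0, 1, sample(0:n, min(5, n + 1)), n))
    for (k in ks) {
      expect_equal(binomial_error_pvalue(k, n, 0.01), pmf_sum(k, n, 0.01),
                   tolerance = 1e-10)
    }
  }
  # monotone non-increasing in k
  tails <- binomial_error_pvalue(0:200, 200, 0.01)
  expect_true(all(diff(tails) <= 1e-15))
  # stable at large n
  expect_gte(binomial_error_pvalue(1e4, 1e6, 0.01), 0.4)
  expect_error(binomial_error_pvalue(1, 10, 0), "in \\(0, 1\\)")
})

test_that("call_sites applies the three retention filters", {
  # 24 samples, k = 15 of n = 100 everywhere: retained under defaults
  st <- call_sites(counts_fixture(rep(15, 24), rep(100, 24)))
  expect_true(all(st$retained))
  expect_equal(unique(st$level), 0.15)

  # summed edited reads 9 < 10: dropped by the count filter
  st <- call_sites(counts_fixture(c(5, 4, 0), c(100, 100, 100)))
  expect_false(any(st$retained))
  expect_false(st$pass_min_edited[1])
  expect_true(st$pass_level[1] == FALSE) # mean 0.03 also fails, by the way

  # mean level 0.06 < 0.10: dropped by the level filter despite high counts
  st <- call_sites(counts_fixture(rep(30, 4), rep(500, 4)))
  expect_false(any(st$retained))
  expect_false(st$pass_level[1])
  expect_true(st$pass_min_edited[1])
  expect_true(st$pass_error[1])
})

test_that("the error filter excludes counts explainable by sequencing error", {
  # k = 2 of 100 in every sample: P(X >= 2 | n=100, p=.01) ~ 0.264 > 0.05
  st <- call_sites(counts_fixture(rep(2, 6), rep(100, 6)))
  expect_false(any(st$pass_error))
  # one sample with a strong signal is enough (min_samples_pass = 1)
  st <- call_sites(counts_fixture(c(30, 2, 2), c(100, 100, 100)))
  expect_true(all(st$pass_error))
})

test_that("retention is invariant to filter order (flags are independent)", {
  set.seed(7)
  for (i in 1:20) {
    k <- rpois(8, sample(c(1, 8, 30), 1))
    n <- k + rpois(8, 150)
    st <- call_sites(counts_fixture(k, n))
    f <- st[1, c("pass_min_edited", "pass_error", "pass_level")]
    expect_equal(st$retained[1],
                 f$pass_min_edited && f$pass_error && f$pass_level)
  }
})

test_that("non-A>G substitutions are reported but flagged not-ADAR", {
  cnt <- tibble::tibble(
    sample_id = "s1", mature_id = "m1-3p", position = c(6L, 9L),
    ref_base = c("A", "C"),
    A = c(10L, 2L), C = c(0L, 90L), G = c(90L, 8L), U = c(0L, 0L)
  )
  st <- call_sites(cnt)
  ag <- dplyr::filter(st, position == 6L, alt_base == "G")
  cg <- dplyr::filter(st, position == 9L)
  expect_true(all(ag$is_adar))
  expect_false(any(cg$is_adar))
  expect_false(any(cg$retained))
  # A>C at position 6 had zero counts: not reported as a diagnostic row
  expect_false(any(st$position == 6L & st$alt_base == "C"))
})

test_that("the editing matrix is complete, consistent and design-ordered", {
  # sample s3 has no coverage: its cell must be missing, not zero
  cnt <- counts_fixture(c(40, 50), c(100, 100), samples = c("s1", "s2"))
  design <- tibble::tibble(sample_id = c("s3", "s1", "s2"),
                           group = c("case", "control", "control"))
  st <- call_sites(cnt, samples = design$sample_id)
  em <- build_matrix(st, design)
  expect_equal(dim(em$level), c(1L, 3L))
  expect_equal(colnames(em$level), c("s3", "s1", "s2"))
  expect_true(is.na(em$level["m1-3p:6", "s3"]))
  expect_equal(em$n["m1-3p:6", "s3"], 0L)
  # cells equal k/n recomputed from the carried matrices
  nz <- em$n > 0
  expect_equal(em$level[nz], (em$k / em$n)[nz])
  # long form round-trips the same values
  td <- tidy(em)
  expect_equal(nrow(td), 3L)
  expect_equal(td$level[td$sample_id == "s1"], 0.40)
})

test_that("duplicate (site, sample) rows are rejected", {
  cnt <- counts_fixture(c(40, 40), c(100, 100), samples = c("s1", "s1"))
  design <- tibble::tibble(sample_id = "s1", group = "control")
  st <- call_sites(cnt, samples = "s1")
  expect_error(build_matrix(st, design), "duplicated")
})

test_that("pure-error counts yield no surviving sites", {
  # one seeded run here (the multi-run specificity study lives with the
  # acceptance checks): 50 miRNAs, 24 samples, coverage 500, error only
  cfg <- sim_config(n_hairpins = 50L, planted_sites = NULL,
                    coverage_mean = 500, rng_seed = 101L)
  sc <- simulate_position_counts(cfg)
  st <- call_sites(sc$counts, samples = sc$design$sample_id)
  expect_equal(sum(dplyr::distinct(
    dplyr::filter(st, retained), mature_id, position
  ) |> nrow()), 0L)
})
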