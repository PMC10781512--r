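small_cfg <- function(rng_seed = 11L, ...) {
  sim_config(
    n_hairpins = 4L, group_sizes = c(control = 2L, case = 2L),
    coverage_mean = 120, rng_seed = rng_seed,
    planted_sites = tibble::tibble(
      mature_id = "syn-mir-001-3p", position = 6L,
      fraction_control = 0.85, fraction_case = 0.79
    ),
    ...
  )
}

test_that("the generated reference is deterministic and plants A in context", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  ann <- r1$mature[r1$mature$mature_id == "syn-mir-001-3p", ]
  hp <- r1$hairpins$sequence[r1$hairpins$id == ann$hairpin_id]
  centre <- ann$start + 6L - 1L
  expect_identical(substr(hp, centre - 1L, centre + 1L), "UAG")
  # different seed, different sequences
  r3 <- simulate_reference(small_cfg(rng_seed = 12L))
  expect_false(identical(r1$hairpins$sequence, r3$hairpins$sequence))
})

test_that("read simulation is reproducible and conserves read counts", {
  cfg <- small_cfg()
  s1 <- simulate_reads(cfg)
  s2 <- simulate_reads(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth_sites, s2$truth_sites)
  # conservation: ground-truth per-miRNA counts sum to reads written
  per_sample <- dplyr::count(s1$reads, sample_id)
  truth <- dplyr::summarise(dplyr::group_by(s1$truth_reads, sample_id),
                            n = sum(n_reads), .groups = "drop")
  expect_equal(
    dplyr::arrange(per_sample, sample_id)$n,
    dplyr::arrange(dplyr::filter(truth, n > 0), sample_id)$n
  )
})

test_that("degenerate fractions and zero error rate behave exactly", {
  cfg <- sim_config(
    n_hairpins = 1L, group_sizes = c(control = 2L, case = 2L),
    coverage_mean = 50, error_rate = 0,
    planted_sites = tibble::tibble(
      mature_id = "syn-mir-001-3p", position = 6L,
      fraction_control = 1.0, fraction_case = 1.0
    ),
    rng_seed = 3L
  )
  sim <- simulate_reads(cfg)
  # every read carries G at the planted position
  expect_true(all(substr(sim$reads$sequence, 6, 6) == "G"))
  expect_equal(sim$truth_sites$true_edited, sim$truth_sites$total)
})

test_that("with error_rate 0 the tally reproduces ground truth exactly", {
  cfg <- sim_config(
    n_hairpins = 3L, group_sizes = c(control = 2L, case = 2L),
    coverage_mean = 80, error_rate = 0,
    planted_sites = tibble::tibble(
      mature_id = "syn-mir-001-3p", position = 6L,
      fraction_control = 0.6, fraction_case = 0.3
    ),
    rng_seed = 5L
  )
  sim <- simulate_reads(cfg)
  counts <- count_positions(sim$reads, sim$reference$hairpins, sim$reference$mature)
  at_site <- dplyr::filter(counts, mature_id == "syn-mir-001-3p", position == 6L)
  truth <- dplyr::arrange(sim$truth_sites, sample_id)
  at_site <- dplyr::arrange(at_site, sample_id)
  expect_equal(at_site$G, truth$true_edited)
  expect_equal(at_site$A + at_site$G, truth$total)
})

test_that("observed editing proportion falls in its 99% binomial interval", {
  # coverage fixed high, fraction 0.5, no errors: edited-read count is
  # Binomial(n, 0.5); check the observed proportion against the exact
  # central interval computed from qbinom (independent of the generator)
  cfg <- sim_config(
    n_hairpins = 1L, group_sizes = c(control = 2L, case = 2L),
    coverage_mean = 1000, coverage_dispersion = 1e9, error_rate = 0,
    planted_sites = tibble::tibble(
      mature_id = "syn-mir-001-3p", position = 6L,
      fraction_control = 0.5, fraction_case = 0.5
    ),
    rng_seed = 21L
  )
  sim <- simulate_reads(cfg)
  for (i in seq_len(nrow(sim$truth_sites))) {
    n <- sim$truth_sites$total[i]
    lo <- qbinom(0.005, n, 0.5)
    hi <- qbinom(0.995, n, 0.5)
    expect_gte(sim$truth_sites$true_edited[i], lo)
    expect_lte(sim$truth_sites$true_edited[i], hi)
  }
})

test_that("counts-level simulation matches the read-level marginal moments", {
  # same config through both generators: per-site editing levels must agree
  # in distribution; compare means within binomial Monte-Carlo tolerance
  cfg <- sim_config(
    n_hairpins = 2L, group_sizes = c(control = 6L, case = 6L),
    coverage_mean = 400, rng_seed = 9L,
    planted_sites = tibble::tibble(
      mature_id = "syn-mir-001-3p", position = 6L,
      fraction_control = 0.8, fraction_case = 0.8
    )
  )
  sim_r <- simulate_reads(cfg)
  counts_r <- count_positions(sim_r$reads, sim_r$reference$hairpins,
                              sim_r$reference$mature)
  sim_c <- simulate_position_counts(cfg)
  lev <- function(cnt) {
    x <- dplyr::filter(cnt, mature_id == "syn-mir-001-3p", position == 6L)
    x$G / (x$A + x$C + x$G + x$U)
  }
  # expected observed level: 0.8*(1-e) + 0.2*e/3 with e = 0.01
  expected <- 0.8 * 0.99 + 0.2 * 0.01 / 3
  expect_equal(mean(lev(counts_r)), expected, tolerance = 0.02)
  expect_equal(mean(lev(sim_c$counts)), expected, tolerance = 0.02)
})

test_that("simulated UTR sets plant sites where requested and nowhere else", {
  pa <- site_patterns("UCAUGGA")
  pb <- site_patterns("UCAUAGA")
  utrs <- simulate_utrs(pa, pb, n_a = 5, n_b = 5, n_both = 2, n_neither = 3,
                        rng_seed = 2L)
  ma <- scan_utr(utrs, pa)
  mb <- scan_utr(utrs, pb)
  expect_setequal(unique(ma$utr_id), utrs$id[utrs$planted %in% c("a", "both")])
  expect_setequal(unique(mb$utr_id), utrs$id[utrs$planted %in% c("b", "both")])
})

test_that("write_simulation emits a complete, readable file set", {
  dir <- tempfile("simout_")
  cfg <- small_cfg()
  sim <- simulate_reads(cfg)
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  fq <- read_fastq(files[["fastq_control_01"]])
  expect_equal(
    nrow(fq),
    sum(sim$truth_reads$n_reads[sim$truth_reads$sample_id == "control_01"])
  )
  hp <- read_fasta(files[["hairpins"]])
  expect_identical(hp, sim$reference$hairpins)
})
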