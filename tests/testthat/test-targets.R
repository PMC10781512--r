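test_that("apply_edit replaces the adenosine and nothing else", {
  non <- mir376a_3p()
  ed <- apply_edit(non, 6)
  expect_identical(ed, mir376a_3p(edited = TRUE))
  # Hamming distance exactly 1
  expect_equal(sum(strsplit(non, "")[[1]] != strsplit(ed, "")[[1]]), 1L)
  expect_error(apply_edit(non, 7), "not 'A'") # G at position 7
  expect_error(apply_edit(non, 0), "inside")
})

test_that("the seed is positions 2-8 and a +6 edit changes it at one spot", {
  expect_equal(seed_of("AUCAUGGAGGAAAAUCCACGU"), "UCAUGGA")
  expect_equal(seed_of("AUCAUAGAGGAAAAUCCACGU"), "UCAUAGA")
  expect_error(seed_of("AUCAUGG"), "at least 8")
  s1 <- seed_of(mir376a_3p())
  s2 <- seed_of(mir376a_3p(edited = TRUE))
  expect_equal(sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]]), 1L)
})

test_that("site patterns follow the canonical 8mer/7mer-m8/7mer-A1 forms", {
  p <- site_patterns("UCAUGGA")
  expect_equal(p$pattern[p$site_type == "7mer-m8"], "UCCAUGA")
  expect_equal(p$pattern[p$site_type == "8mer"], "UCCAUGAA")
  expect_equal(p$pattern[p$site_type == "7mer-A1"], "CCAUGAA")
  expect_equal(site_patterns("UCAUAGA")$pattern[2], "UCUAUGA")
  # revcomp consistency: the seed is recoverable from the 7mer-m8 pattern
  for (seed in c("UCAUGGA", "UCAUAGA", "ACGUACG")) {
    expect_identical(rna_revcomp(site_patterns(seed)$pattern[2]), seed)
  }
  # edited and non-edited 7mer-m8 differ at exactly one position
  a <- site_patterns(seed_of(mir376a_3p()))$pattern[2]
  b <- site_patterns(seed_of(mir376a_3p(TRUE)))$pattern[2]
  expect_equal(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), 1L)
  expect_error(site_patterns("UCAUGG"), "7 nt")
  expect_error(site_patterns("UCAUGGN"), "outside")
})

test_that("UTR scanning applies the site-type hierarchy", {
  pats <- site_patterns("UCAUGGA")
  # one 8mer: reported once, as 8mer, not additionally as 7mer
  utr <- tibble::tibble(id = "u1", sequence = "CCCCCUCCAUGAACCCCC")
  m <- scan_utr(utr, pats)
  expect_equal(nrow(m), 1L)
  expect_equal(m$site_type, "8mer")
  expect_equal(m$start, 6L)
  # a bare 7mer-m8 (not followed by A)
  utr <- tibble::tibble(id = "u1", sequence = "CCCCCUCCAUGACCCCC")
  m <- scan_utr(utr, pats)
  expect_equal(m$site_type, "7mer-m8")
  # a bare 7mer-A1 (core not preceded by the m8 base)
  utr <- tibble::tibble(id = "u1", sequence = "CCCCCCCAUGAACCCCC")
  m <- scan_utr(utr, pats)
  expect_equal(m$site_type, "7mer-A1")
  # all-C UTR: nothing
  expect_equal(nrow(scan_utr(tibble::tibble(id = "u", sequence = strrep("C", 100)),
                             pats)), 0L)
})

test_that("the scanner equals the brute-force substring oracle on random UTRs", {
  set.seed(99)
  pats <- site_patterns("UCAUGGA")
  for (len in c(500, 10000, 50000)) {
    utr <- paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
    m <- scan_utr(tibble::tibble(id = "u", sequence = utr), pats)
    # oracle: all matches of each pattern, deduplicated by the same
    # anchor-hierarchy rule
    oracle <- NULL
    for (ty in c("8mer", "7mer-m8", "7mer-A1")) {
      st <- brute_force_scan(utr, pats$pattern[pats$site_type == ty])
      if (length(st) > 0) {
        anchor <- if (ty == "7mer-A1") st - 1L else st
        oracle <- rbind(oracle, data.frame(start = st, site_type = ty,
                                           anchor = anchor))
      }
    }
    if (is.null(oracle)) {
      expect_equal(nrow(m), 0L)
    } else {
      oracle$rank <- match(oracle$site_type, c("8mer", "7mer-m8", "7mer-A1"))
      oracle <- oracle[order(oracle$anchor, oracle$rank), ]
      oracle <- oracle[!duplicated(oracle$anchor), ]
      oracle <- oracle[order(oracle$start), ]
      expect_equal(m$start, oracle$start)
      expect_equal(m$site_type, oracle$site_type)
    }
  }
})

test_that("overlapping pattern occurrences are all found", {
  # UCCAUGA planted so that two occurrences overlap via shared prefix/suffix
  pats <- site_patterns("UCAUGGA")[2, ] # 7mer-m8 only
  utr <- tibble::tibble(id = "u", sequence = "GGUCCAUGAUCCAUGAGG")
  m <- scan_utr(utr, pats)
  expect_equal(m$start, c(3L, 10L))
})

test_that("target pools compare by set arithmetic", {
  a <- tibble::tibble(utr_id = c("a", "b", "c", "c"), start = 1:4,
                      site_type = "7mer-m8")
  b <- tibble::tibble(utr_id = c("c", "d"), start = 1:2, site_type = "8mer")
  cmp <- compare_target_pools(a, b)
  s <- tidy(cmp)
  expect_equal(s$n_shared, 1L)
  expect_equal(s$shared_fraction, 0.25)
  expect_equal(s$shared_pct_a, 100 / 3, tolerance = 1e-12)
  # identical pools
  cmp <- compare_target_pools(a, a)
  expect_equal(tidy(cmp)$shared_fraction, 1)
})

test_that("a seed edit redirects the target pool on constructed UTRs", {
  non <- mir376a_3p()
  ed <- mir376a_3p(edited = TRUE)
  utrs <- simulate_utrs(site_patterns(seed_of(non)),
                        site_patterns(seed_of(ed)),
                        n_a = 10, n_b = 10, n_both = 0, n_neither = 5,
                        rng_seed = 4L)
  ts <- target_switch(non, 6, utrs)
  s <- tidy(ts$comparison)
  expect_equal(s$n_targets_a, 10L)
  expect_equal(s$n_targets_b, 10L)
  expect_equal(s$n_shared, 0L)
  expect_equal(s$shared_fraction, 0)
  # planting both patterns in k UTRs yields n_shared = k exactly
  utrs2 <- simulate_utrs(site_patterns(seed_of(non)),
                         site_patterns(seed_of(ed)),
                         n_a = 8, n_b = 8, n_both = 3, n_neither = 2,
                         rng_seed = 5L)
  s2 <- tidy(target_switch(non, 6, utrs2)$comparison)
  expect_equal(s2$n_shared, 3L)
  expect_equal(s2$n_targets_a, 11L)
})

test_that("edit localization recovers position 6 from the miR-376a-3p isomiRs", {
  expect_equal(infer_edit_site(mir376a_3p(), mir376a_3p(TRUE)), 6L)
  expect_error(infer_edit_site("ACGU", "ACGG"), "not A->G")
  expect_error(infer_edit_site("AACC", "GGCC"), "2 positions")
  expect_error(infer_edit_site("ACG", "ACGU"), "length")
})
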