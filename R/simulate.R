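## Synthetic small RNA-seq generator: hairpin references with annotated
## mature arms, group-structured read sets with planted per-site editing
## fractions and uniform per-base sequencing errors, and ground-truth
## tables.  Everything is deterministic given the config's rng_seed.

default_planted_sites <- function() {
  tibble::tibble(
    mature_id = "syn-mir-001-3p",
    position = 6L,
    fraction_control = 0.85,
    fraction_case = 0.79
  )
}

#' Simulation configuration
#'
#' Defines the conditions of a synthetic two-group small RNA-seq experiment.
#' The defaults encode the study design the package is validated against:
#' 8 control vs 16 case libraries, one miRNA carrying a seed edit at mature
#' position +6 with true editing fractions 0.85 (control) and 0.79 (case),
#' 50 additional unedited miRNAs, a mean of 2000 reads per miRNA per library
#' (negative-binomial across libraries), and a uniform per-base sequencing
#' error rate of 0.01.
#'
#' @param n_hairpins Number of hairpins, one annotated mature arm each.
#' @param mature_length Mature miRNA length in nt.
#' @param group_sizes Named integer vector `c(control = , case = )` giving
#'   the number of libraries per group (each at least 2).
#' @param coverage_mean Mean reads per miRNA per library.
#' @param coverage_dispersion Negative-binomial `size` (dispersion) of
#'   per-miRNA per-library read counts; larger is closer to Poisson.
#' @param planted_sites Tibble with columns `mature_id`, `position`,
#'   `fraction_control`, `fraction_case` describing A-to-I edits to plant
#'   (fractions in `[0,1]`, positions within the mature span).  `NULL`
#'   plants nothing.
#' @param error_rate Per-base substitution probability in `[0,1)`; an
#'   errored base is replaced uniformly by one of the other three bases.
#' @param adapter Optional 3' adapter sequence appended to every read.
#' @param end_jitter Probability that a read end is shifted by one base
#'   (trimmed or extended into the hairpin), exercised independently at
#'   each end.  Default 0: reads are exact full-length mature sequences.
#' @param planted_context Trinucleotide context enforced at planted sites
#'   in the generated reference (middle base is always `A`).  Default
#'   `"UAG"`, the preferred ADAR substrate context; `NULL` leaves the
#'   flanks random.
#' @param include_mir376a Also add a hairpin carrying the real (miRBase)
#'   mature miR-376a-3p sequence between synthetic flanks, annotated as
#'   `syn-mir-376a-3p`.
#' @param rng_seed Integer seed controlling every random draw.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_hairpins = 5, coverage_mean = 100, rng_seed = 7)
#' @export
sim_config <- function(n_hairpins = 51L,
                       mature_length = 21L,
                       group_sizes = c(control = 8L, case = 16L),
                       coverage_mean = 2000,
                       coverage_dispersion = 8,
                       planted_sites = default_planted_sites(),
                       error_rate = 0.01,
                       adapter = NULL,
                       end_jitter = 0,
                       planted_context = "UAG",
                       include_mir376a = FALSE,
                       rng_seed = 1L) {
  if (!is_count(n_hairpins) || n_hairpins < 1) abort("n_hairpins must be a positive integer")
  if (!is_count(mature_length) || mature_length < 15) {
    abort("mature_length must be an integer >= 15")
  }
  if (length(group_sizes) != 2L || is.null(names(group_sizes)) ||
      any(!nzchar(names(group_sizes)))) {
    abort("group_sizes must be a named length-2 vector, e.g. c(control = 8, case = 16)")
  }
  if (any(group_sizes < 2)) abort("each group needs at least 2 samples")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    abort("error_rate must be in [0, 1)")
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0) {
    abort("coverage_mean must be positive")
  }
  if (!is.numeric(end_jitter) || end_jitter < 0 || end_jitter > 1) {
    abort("end_jitter must be a probability")
  }
  if (!is.null(planted_sites)) {
    planted_sites <- tibble::as_tibble(planted_sites)
    need <- c("mature_id", "position", "fraction_control", "fraction_case")
    if (!all(need %in% names(planted_sites))) {
      abort(sprintf("planted_sites needs columns %s", paste(need, collapse = ", ")))
    }
    fr <- c(planted_sites$fraction_control, planted_sites$fraction_case)
    if (any(fr < 0 | fr > 1)) abort("planted fractions must lie in [0, 1]")
    if (any(planted_sites$position < 1 | planted_sites$position > mature_length)) {
      abort("planted positions must lie within the mature span")
    }
  } else {
    planted_sites <- default_planted_sites()[0, ]
  }
  if (!is.null(planted_context)) {
    planted_context <- normalize_rna(planted_context)
    if (nchar(planted_context) != 3L || substr(planted_context, 2, 2) != "A") {
      abort("planted_context must be a trinucleotide with A in the middle")
    }
    check_rna(planted_context, "planted_context")
  }
  if (!is.null(adapter)) {
    adapter <- normalize_rna(adapter)
    check_rna(adapter, "adapter")
  }
  structure(
    list(
      n_hairpins = as.integer(n_hairpins),
      mature_length = as.integer(mature_length),
      group_sizes = group_sizes,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      planted_sites = planted_sites,
      error_rate = error_rate,
      adapter = adapter,
      end_jitter = end_jitter,
      planted_context = planted_context,
      include_mir376a = isTRUE(include_mir376a),
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d hairpins, mature %d nt, groups %s, coverage ~NB(mu=%g, size=%g), error %g, seed %d\n",
    x$n_hairpins, x$mature_length,
    paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = "/"),
    x$coverage_mean, x$coverage_dispersion, x$error_rate, x$rng_seed
  ))
  if (nrow(x$planted_sites) > 0) {
    cat(sprintf(
      "  planted: %s\n",
      paste(sprintf("%s@%d (%.2f vs %.2f)", x$planted_sites$mature_id,
                    x$planted_sites$position, x$planted_sites$fraction_control,
                    x$planted_sites$fraction_case), collapse = "; ")
    ))
  }
  invisible(x)
}

## group label per planted-site fraction column
sim_design <- function(config) {
  g <- config$group_sizes
  tibble::tibble(
    sample_id = c(
      sprintf("%s_%02d", names(g)[1], seq_len(g[[1]])),
      sprintf("%s_%02d", names(g)[2], seq_len(g[[2]]))
    ),
    group = rep(names(g), times = g)
  )
}

#' Generate a synthetic hairpin reference with annotated mature arms
#'
#' Each hairpin is a random RNA sequence carrying one mature arm at recorded
#' 1-based coordinates (3p side of the sequence).  Planted editing sites are
#' forced to reference base `A` (so an A-to-G edit is well defined) inside
#' the configured trinucleotide context.  Deterministic given
#' `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `hairpins` (tibble `id`, `sequence`) and
#'   `mature` (annotation tibble as in [read_mature_table()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$mature_length
  flank5 <- 31L
  flank3 <- 8L
  hp_len <- flank5 + L + flank3
  withr::with_seed(config$rng_seed, {
    hp_ids <- sprintf("syn-mir-%03d", seq_len(config$n_hairpins))
    mat_ids <- paste0(hp_ids, "-3p")
    seqs <- vapply(
      seq_len(config$n_hairpins),
      function(i) paste(sample(RNA_BASES, hp_len, replace = TRUE), collapse = ""),
      character(1)
    )
    start <- flank5 + 1L
    end <- flank5 + L
    unknown <- setdiff(config$planted_sites$mature_id, mat_ids)
    if (length(unknown) > 0) {
      abort(sprintf("planted_sites refer to unknown mature_id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (r in seq_len(nrow(config$planted_sites))) {
      i <- match(config$planted_sites$mature_id[r], mat_ids)
      pos <- start + config$planted_sites$position[r] - 1L
      seqs[i] <- sub_base_at(seqs[i], pos, "A")
      if (!is.null(config$planted_context)) {
        if (pos > 1L) {
          seqs[i] <- sub_base_at(seqs[i], pos - 1L, substr(config$planted_context, 1, 1))
        }
        if (pos < hp_len) {
          seqs[i] <- sub_base_at(seqs[i], pos + 1L, substr(config$planted_context, 3, 3))
        }
      }
    }
    hairpins <- tibble::tibble(id = hp_ids, sequence = seqs)
    mature <- tibble::tibble(
      mature_id = mat_ids, hairpin_id = hp_ids,
      start = start, end = end, arm = "3p"
    )
    if (config$include_mir376a) {
      m376 <- mir376a_3p()
      pad5 <- paste(sample(RNA_BASES, flank5, replace = TRUE), collapse = "")
      pad3 <- paste(sample(RNA_BASES, flank3, replace = TRUE), collapse = "")
      hairpins <- dplyr::bind_rows(
        hairpins,
        tibble::tibble(id = "syn-mir-376a", sequence = paste0(pad5, m376, pad3))
      )
      mature <- dplyr::bind_rows(
        mature,
        tibble::tibble(
          mature_id = "syn-mir-376a-3p", hairpin_id = "syn-mir-376a",
          start = flank5 + 1L, end = flank5 + nchar(m376), arm = "3p"
        )
      )
    }
    list(hairpins = hairpins, mature = validate_mature(mature, hairpins))
  })
}

## uniform substitution to one of the 3 other bases, vectorized over cells
substitute_errors <- function(mat, error_rate) {
  if (error_rate <= 0) return(mat)
  hit <- which(runif(length(mat)) < error_rate)
  if (length(hit) > 0) {
    idx <- match(mat[hit], RNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    mat[hit] <- RNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  mat
}

#' Simulate small RNA-seq reads with planted editing and ground truth
#'
#' For each library and miRNA, a negative-binomial number of reads is drawn;
#' each read starts as the full-length mature sequence, carries a `G` at
#' each planted site with its group's true fraction (independent Bernoulli
#' per read), is then passed through uniform per-base substitution errors,
#' optional one-base end jitter, and an optional 3' adapter.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()]; regenerated from
#'   `config` when omitted.
#' @return An object of class `sim_reads`: a list with `reads` (tibble
#'   `sample_id`, `id`, `sequence`, `quality`), `design`, `truth_reads`
#'   (reads per miRNA per library), `truth_sites` (true edited/total counts
#'   per planted site per library), `reference` and `config`.
#' @export
simulate_reads <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  reference <- reference %||% simulate_reference(config)
  design <- sim_design(config)
  mature <- reference$mature
  hp_seq <- setNames(reference$hairpins$sequence, reference$hairpins$id)
  mat_seq <- substr(hp_seq[mature$hairpin_id], mature$start, mature$end)
  names(mat_seq) <- mature$mature_id
  planted <- split(config$planted_sites, config$planted_sites$mature_id)

  withr::with_seed(config$rng_seed + 1L, {
    out_reads <- vector("list", nrow(design) * nrow(mature))
    truth_reads <- vector("list", length(out_reads))
    truth_sites <- list()
    z <- 0L
    for (s in seq_len(nrow(design))) {
      sid <- design$sample_id[s]
      grp <- design$group[s]
      ## first group listed in group_sizes maps to fraction_control
      frac_col <- if (grp == names(config$group_sizes)[1]) {
        "fraction_control"
      } else {
        "fraction_case"
      }
      for (m in seq_len(nrow(mature))) {
        mid <- mature$mature_id[m]
        n <- rnbinom(1L, mu = config$coverage_mean, size = config$coverage_dispersion)
        z <- z + 1L
        truth_reads[[z]] <- tibble::tibble(sample_id = sid, mature_id = mid, n_reads = n)
        if (n == 0L) next
        L <- nchar(mat_seq[[mid]])
        base_chars <- strsplit(mat_seq[[mid]], "")[[1]]
        mat <- matrix(base_chars, nrow = n, ncol = L, byrow = TRUE)
        ps <- planted[[mid]]
        if (!is.null(ps)) {
          if (!frac_col %in% names(ps)) {
            abort(sprintf("planted_sites has no column '%s' for group '%s'", frac_col, grp))
          }
          for (r in seq_len(nrow(ps))) {
            f <- ps[[frac_col]][r]
            edited <- runif(n) < f
            mat[edited, ps$position[r]] <- "G"
            truth_sites[[length(truth_sites) + 1L]] <- tibble::tibble(
              sample_id = sid, mature_id = mid, position = ps$position[r],
              true_fraction = f, true_edited = sum(edited), total = n
            )
          }
        }
        mat <- substitute_errors(mat, config$error_rate)
        seqs <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
        if (config$end_jitter > 0) {
          seqs <- jitter_ends(seqs, hp_seq[[mature$hairpin_id[m]]],
                              mature$start[m], mature$end[m], config$end_jitter)
        }
        if (!is.null(config$adapter)) seqs <- paste0(seqs, config$adapter)
        out_reads[[z]] <- tibble::tibble(
          sample_id = sid,
          id = sprintf("%s_%s_r%06d", sid, mid, seq_len(n)),
          sequence = seqs,
          quality = strrep("I", nchar(seqs))
        )
      }
    }
    structure(
      list(
        reads = dplyr::bind_rows(out_reads),
        design = design,
        truth_reads = dplyr::bind_rows(truth_reads),
        truth_sites = if (length(truth_sites) > 0) {
          dplyr::bind_rows(truth_sites)
        } else {
          edit_schema_tibble("ground_truth_sites")
        },
        reference = reference,
        config = config
      ),
      class = "sim_reads"
    )
  })
}

## one-base 5'/3' end jitter; extensions pull the flanking hairpin base
jitter_ends <- function(seqs, hairpin, start, end, p) {
  n <- length(seqs)
  d5 <- ifelse(runif(n) < p, sample(c(-1L, 1L), n, replace = TRUE), 0L)
  d3 <- ifelse(runif(n) < p, sample(c(-1L, 1L), n, replace = TRUE), 0L)
  d5[start + d5 < 1L] <- 0L
  d3[end + d3 > nchar(hairpin)] <- 0L
  left <- substr(hairpin, start - 1L, start - 1L)
  right <- substr(hairpin, end + 1L, end + 1L)
  out <- seqs
  out <- ifelse(d5 == 1L, substr(out, 2L, nchar(out)), out)
  out <- ifelse(d5 == -1L, paste0(left, out), out)
  out <- ifelse(d3 == 1L, substr(out, 1L, nchar(out) - 1L), out)
  out <- ifelse(d3 == -1L, paste0(out, right), out)
  out
}

## empty tibble matching a schema
edit_schema_tibble <- function(schema) {
  sch <- schema_cols(schema)
  cols <- lapply(sch, function(t) {
    switch(t, c = character(), i = integer(), d = double(), l = logical())
  })
  tibble::as_tibble(cols)
}

## Vectorized multinomial via chained binomials: size[i] trials with
## probability row prob[i, ] -> integer matrix of per-category counts.
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  k <- ncol(prob)
  out <- matrix(0L, n, k)
  rem <- as.integer(size)
  cum <- rep(0, n)
  for (j in seq_len(k - 1L)) {
    denom <- pmax(1 - cum, .Machine$double.eps)
    pj <- pmin(pmax(prob[, j] / denom, 0), 1)
    out[, j] <- rbinom(n, rem, pj)
    rem <- rem - out[, j]
    cum <- cum + prob[, j]
  }
  out[, k] <- rem
  out
}

#' Simulate per-position base tallies directly (counts level)
#'
#' Draws the per-position base counts a full read-level simulation followed
#' by alignment and tallying would produce, without materializing reads:
#' per-miRNA per-library coverage is negative binomial, a planted site's
#' true edited count is Binomial(coverage, fraction), and every base is
#' passed through the uniform substitution error channel.  This is the
#' distributional marginal of [simulate_reads()] at the tally and is the
#' generator of choice for large repeated-simulation studies.
#'
#' @param config A [sim_config()] (`adapter` and `end_jitter` are ignored at
#'   the counts level).
#' @param reference Optional [simulate_reference()] output.
#' @return An object of class `sim_counts`: list with `counts` (tibble in
#'   the `position_counts` schema), `design`, `truth_sites`, `reference`,
#'   `config`.
#' @export
simulate_position_counts <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  reference <- reference %||% simulate_reference(config)
  design <- sim_design(config)
  mature <- reference$mature
  hp_seq <- setNames(reference$hairpins$sequence, reference$hairpins$id)
  mat_seq <- substr(hp_seq[mature$hairpin_id], mature$start, mature$end)
  names(mat_seq) <- mature$mature_id

  pos_tbl <- tidyr::unnest(
    tibble::tibble(
      mature_id = mature$mature_id,
      position = lapply(nchar(mat_seq), seq_len),
      ref_base = strsplit(unname(mat_seq), "")
    ),
    cols = c("position", "ref_base")
  )

  withr::with_seed(config$rng_seed + 2L, {
    cov_tbl <- tidyr::expand_grid(
      sample_id = design$sample_id, mature_id = mature$mature_id
    )
    cov_tbl$n <- rnbinom(nrow(cov_tbl), mu = config$coverage_mean,
                         size = config$coverage_dispersion)

    grid <- dplyr::inner_join(
      tidyr::expand_grid(sample_id = design$sample_id, pos_tbl),
      cov_tbl, by = c("sample_id", "mature_id")
    )
    grid <- dplyr::left_join(grid, design, by = "sample_id")
    pl <- config$planted_sites
    grid <- dplyr::left_join(
      grid,
      dplyr::mutate(pl, planted = TRUE),
      by = c("mature_id", "position")
    )
    grid$planted <- !is.na(grid$planted)
    grid$fraction <- ifelse(
      grid$group == names(config$group_sizes)[1],
      grid$fraction_control, grid$fraction_case
    )

    eps <- config$error_rate
    err_prob <- function(ref) {
      p <- matrix(eps / 3, length(ref), 4L,
                  dimnames = list(NULL, RNA_BASES))
      p[cbind(seq_along(ref), match(ref, RNA_BASES))] <- 1 - eps
      p
    }

    counts <- matrix(0L, nrow(grid), 4L, dimnames = list(NULL, RNA_BASES))
    plain <- which(!grid$planted)
    if (length(plain) > 0) {
      counts[plain, ] <- rmultinom_rows(grid$n[plain], err_prob(grid$ref_base[plain]))
    }
    planted <- which(grid$planted)
    truth_sites <- edit_schema_tibble("ground_truth_sites")
    if (length(planted) > 0) {
      e <- rbinom(length(planted), grid$n[planted], grid$fraction[planted])
      counts[planted, ] <-
        rmultinom_rows(e, err_prob(rep("G", length(planted)))) +
        rmultinom_rows(grid$n[planted] - e, err_prob(grid$ref_base[planted]))
      truth_sites <- tibble::tibble(
        sample_id = grid$sample_id[planted],
        mature_id = grid$mature_id[planted],
        position = grid$position[planted],
        true_fraction = grid$fraction[planted],
        true_edited = e,
        total = grid$n[planted]
      )
    }

    out <- tibble::tibble(
      sample_id = grid$sample_id,
      mature_id = grid$mature_id,
      position = as.integer(grid$position),
      ref_base = grid$ref_base,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], U = counts[, "U"]
    )
    structure(
      list(counts = out, design = design, truth_sites = truth_sites,
           reference = reference, config = config),
      class = "sim_counts"
    )
  })
}

#' Simulate a 3'UTR set with planted seed-match sites
#'
#' Builds UTR sequences on a random background with canonical sites for one
#' or two seed patterns planted in chosen subsets, for exercising the
#' target-pool comparison.  Backgrounds are drawn from `{C,G}` only, so no
#' seed-match site (all of which contain `A` or `U` here) can arise by
#' chance unless planted.
#'
#' @param patterns_a,patterns_b Pattern tibbles from [site_patterns()] (or
#'   any tibble with a `pattern` column); `patterns_b` may be `NULL`.
#' @param n_a,n_b,n_both,n_neither How many UTRs carry only A sites, only B
#'   sites, both, or none.
#' @param utr_length UTR length in nt.
#' @param rng_seed Integer seed.
#' @return Tibble with columns `id`, `sequence`, `planted` (one of
#'   `"a"`, `"b"`, `"both"`, `"none"`).
#' @export
simulate_utrs <- function(patterns_a, patterns_b = NULL,
                          n_a = 20L, n_b = 20L, n_both = 0L, n_neither = 10L,
                          utr_length = 300L, rng_seed = 1L) {
  pa <- patterns_a$pattern
  pb <- if (is.null(patterns_b)) character() else patterns_b$pattern
  if (is.null(patterns_b)) n_b <- 0L
  withr::with_seed(rng_seed, {
    lab <- rep(c("a", "b", "both", "none"), times = c(n_a, n_b, n_both, n_neither))
    n <- length(lab)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("C", "G"), utr_length, replace = TRUE), collapse = "")
    }, character(1))
    plant <- function(s, pats, at) {
      for (j in seq_along(pats)) {
        pos <- at + (j - 1L) * 12L
        substr(s, pos, pos + nchar(pats[j]) - 1L) <- pats[j]
      }
      s
    }
    for (i in seq_len(n)) {
      if (lab[i] %in% c("a", "both")) seqs[i] <- plant(seqs[i], pa, 20L)
      if (lab[i] %in% c("b", "both")) seqs[i] <- plant(seqs[i], pb, 120L)
    }
    tibble::tibble(
      id = sprintf("utr_%03d", seq_len(n)),
      sequence = seqs,
      planted = lab
    )
  })
}

#' Write a simulated read set to disk
#'
#' Emits the reference FASTA, the mature annotation TSV, a design TSV, one
#' FASTQ per library and the ground-truth TSVs into `dir`.
#'
#' @param sim A `sim_reads` object from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @param gzip Write FASTQ gzip-compressed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, gzip = FALSE) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    hairpins = file.path(dir, "hairpins.fa"),
    mature = file.path(dir, "mature.tsv"),
    design = file.path(dir, "design.tsv"),
    truth_sites = file.path(dir, "ground_truth_sites.tsv"),
    truth_reads = file.path(dir, "ground_truth_reads.tsv")
  )
  write_fasta(sim$reference$hairpins, files[["hairpins"]])
  write_table_checked(sim$reference$mature, files[["mature"]], "mature_annotation")
  write_table_checked(sim$design, files[["design"]], "design")
  write_table_checked(sim$truth_sites, files[["truth_sites"]], "ground_truth_sites")
  write_table_checked(sim$truth_reads, files[["truth_reads"]], "ground_truth_reads")
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (sid in sim$design$sample_id) {
    fq <- file.path(dir, paste0(sid, ext))
    write_fastq(dplyr::filter(sim$reads, .data$sample_id == sid), fq)
    files[[paste0("fastq_", sid)]] <- fq
  }
  invisible(files)
}
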