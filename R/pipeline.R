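## Config-driven orchestration: simulate (or load) -> align/tally ->
## call sites -> differential editing -> target switch -> motif context,
## with stage-tagged logging to stderr and a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects every stage's inputs and parameters.  Either a simulation
#' config (`sim`) or a set of input paths (`inputs`) must be supplied;
#' seeds are always explicit (the pipeline never draws a time-based seed).
#'
#' @param out_dir Output directory for stage tables and the manifest.
#' @param sim A [sim_config()], or `NULL` when reading real inputs.
#' @param inputs `NULL`, or a list with paths `hairpin_fasta`,
#'   `mature_tsv`, `design_tsv` and `fastq` (named character vector or list
#'   of per-sample FASTQ paths, names = sample ids).
#' @param align An [align_params()].
#' @param filters A [site_filter_params()].
#' @param alpha FDR threshold for differential editing.
#' @param utr_fasta Optional path to a 3'UTR FASTA; when present the
#'   target-switch stage runs on `target_site` (or on the top
#'   differentially edited site).
#' @param target_site Optional list `list(mature_id=, position=)` selecting
#'   the site whose isomiRs are scanned against the UTRs; default: the most
#'   significant retained site.
#' @param counts_level Simulate at the counts level
#'   ([simulate_position_counts()]) instead of generating and aligning
#'   reads; only meaningful with `sim`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            inputs = NULL,
                            align = align_params(),
                            filters = site_filter_params(),
                            alpha = 0.05,
                            utr_fasta = NULL,
                            target_site = NULL,
                            counts_level = FALSE) {
  if (is.null(sim) && is.null(inputs)) {
    abort("either a simulation config or input paths must be given")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(
    list(out_dir = out_dir, sim = sim, inputs = inputs, align = align,
         filters = filters, alpha = alpha, utr_fasta = utr_fasta,
         target_site = target_site, counts_level = isTRUE(counts_level)),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from a YAML file
#'
#' Declarative key-value mirror of [pipeline_config()]: top-level keys
#' `out_dir`, `alpha`, `utr_fasta`, `target_site`, `counts_level`, and
#' nested maps `sim`, `align`, `filters`, `inputs` whose entries are passed
#' to [sim_config()], [align_params()] and [site_filter_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) {
    a <- y$sim
    if (!is.null(a$group_sizes)) a$group_sizes <- unlist(a$group_sizes)
    if (!is.null(a$planted_sites)) {
      a$planted_sites <- dplyr::bind_rows(lapply(a$planted_sites, tibble::as_tibble))
    }
    do.call(sim_config, a)
  } else if (is.null(y$inputs)) {
    sim_config()
  } else {
    NULL
  }
  pipeline_config(
    out_dir = y$out_dir %||% ".",
    sim = sim,
    inputs = y$inputs,
    align = do.call(align_params, as.list(y$align)),
    filters = do.call(site_filter_params, as.list(y$filters)),
    alpha = y$alpha %||% 0.05,
    utr_fasta = y$utr_fasta,
    target_site = y$target_site,
    counts_level = isTRUE(y$counts_level)
  )
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full editing-analysis pipeline
#'
#' Executes simulate (or load) -> align + tally -> call sites -> build
#' matrix -> differential editing -> motif context -> (optionally) target
#' switch, writing every stage's table into `config$out_dir` and a
#' `manifest.json` recording parameter values, the seed, input checksums
#' and per-stage record counts.  Identical configs produce byte-identical
#' outputs and manifests.  A stage failure raises an error naming the
#' stage; tables already written are left in place.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "miredit",
    version = as.character(utils::packageVersion("miredit")),
    seed = if (!is.null(config$sim)) config$sim$rng_seed else NA,
    alpha = config$alpha,
    align = unclass(config$align),
    filters = unclass(config$filters),
    stages = list(), files = list()
  )
  record <- function(stage, path, n) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], setNames(n, basename(path)))
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  ## ---- inputs / simulation -------------------------------------------
  if (!is.null(config$inputs)) {
    wrap("load", {
      inp <- config$inputs
      need <- c("hairpin_fasta", "mature_tsv", "design_tsv", "fastq")
      miss <- setdiff(need, names(inp))
      if (length(miss) > 0) {
        abort(sprintf("inputs missing: %s", paste(miss, collapse = ", ")))
      }
      paths <- c(inp$hairpin_fasta, inp$mature_tsv, inp$design_tsv,
                 unlist(inp$fastq))
      gone <- paths[!file.exists(paths)]
      if (length(gone) > 0) {
        abort(sprintf("input file(s) not found: %s", paste(gone, collapse = ", ")))
      }
      stage_log("load", "reading %d input file(s)", length(paths))
      hairpins <- read_fasta(inp$hairpin_fasta)
      mature <- read_mature_table(inp$mature_tsv, hairpins)
      design <- read_table_checked(inp$design_tsv, "design")
      fq <- unlist(inp$fastq)
      if (is.null(names(fq)) || any(!nzchar(names(fq)))) {
        abort("inputs$fastq must be named by sample id")
      }
      reads <- dplyr::bind_rows(lapply(names(fq), function(sid) {
        dplyr::mutate(read_fastq(fq[[sid]]), sample_id = sid)
      }))
      ## plain <- : this code runs directly in run_pipeline's frame
      for (p in paths) manifest$files[[basename(p)]] <- unname(tools::md5sum(p))
      truth_sites <- NULL
      sim_counts <- NULL
    })
  } else {
    wrap("simulate", {
      stage_log("simulate", "seed %d, %d hairpins, %d samples%s",
                config$sim$rng_seed, config$sim$n_hairpins,
                sum(config$sim$group_sizes),
                if (config$counts_level) " (counts level)" else "")
      if (config$counts_level) {
        sim_counts <- simulate_position_counts(config$sim)
        hairpins <- sim_counts$reference$hairpins
        mature <- sim_counts$reference$mature
        design <- sim_counts$design
        truth_sites <- sim_counts$truth_sites
        reads <- NULL
      } else {
        sim <- simulate_reads(config$sim)
        sim_counts <- NULL
        hairpins <- sim$reference$hairpins
        mature <- sim$reference$mature
        design <- sim$design
        truth_sites <- sim$truth_sites
        reads <- sim$reads
      }
      p <- file.path(config$out_dir, "design.tsv")
      write_table_checked(design, p, "design")
      record("simulate", p, nrow(design))
      if (!is.null(truth_sites)) {
        p <- file.path(config$out_dir, "ground_truth_sites.tsv")
        write_table_checked(truth_sites, p, "ground_truth_sites")
        record("simulate", p, nrow(truth_sites))
      }
    })
  }

  ## ---- align + tally --------------------------------------------------
  counts <- wrap("align", {
    if (!is.null(config$sim) && config$counts_level) {
      stage_log("align", "counts-level simulation: tally drawn directly")
      sim_counts$counts
    } else {
      stage_log("align", "aligning %d reads to %d hairpins",
                nrow(reads), nrow(hairpins))
      count_positions(reads, hairpins, mature, config$align)
    }
  })
  p <- file.path(config$out_dir, "position_counts.tsv")
  write_table_checked(counts, p, "position_counts")
  record("align", p, nrow(counts))

  ## ---- call sites -----------------------------------------------------
  sites <- wrap("call-sites", {
    stage_log("call-sites", "calling sites over %d samples", nrow(design))
    call_sites(counts, config$filters, samples = design$sample_id)
  })
  p <- file.path(config$out_dir, "sites.tsv")
  write_table_checked(sites, p, "sites")
  record("call-sites", p, nrow(sites))

  em <- wrap("call-sites", build_matrix(sites, design))
  p <- file.path(config$out_dir, "editing_matrix.tsv")
  write_table_checked(tidy(em), p, "matrix_long")
  record("call-sites", p, nrow(em$level))

  ## ---- differential ---------------------------------------------------
  de <- wrap("diff-edit", {
    stage_log("diff-edit", "%d retained site(s)", nrow(em$level))
    if (nrow(em$level) > 0) differential_editing(em, design, config$alpha) else NULL
  })
  if (!is.null(de)) {
    p <- file.path(config$out_dir, "differential.tsv")
    write_table_checked(tidy(de), p, "differential")
    record("diff-edit", p, nrow(de))
  }

  ## ---- motif ----------------------------------------------------------
  mt <- wrap("motif", motif_table(sites, hairpins, mature))
  p <- file.path(config$out_dir, "motifs.tsv")
  write_table_checked(mt, p, "motif_counts")
  record("motif", p, nrow(mt))

  ## ---- target switch --------------------------------------------------
  if (!is.null(config$utr_fasta)) {
    wrap("target-switch", {
      site <- config$target_site
      if (is.null(site)) {
        if (is.null(de) || !any(!de$untestable)) {
          abort("no testable site available to scan; set target_site explicitly")
        }
        i <- which.min(replace(de$p_bh, is.na(de$p_bh), Inf))
        site <- list(mature_id = de$mature_id[i], position = de$position[i])
      }
      stage_log("target-switch", "site %s:+%d", site$mature_id, site$position)
      ann <- mature[mature$mature_id == site$mature_id, ]
      if (nrow(ann) != 1) abort(sprintf("unknown mature_id '%s'", site$mature_id))
      hp <- hairpins$sequence[hairpins$id == ann$hairpin_id]
      mseq <- substr(hp, ann$start, ann$end)
      utrs <- read_fasta(config$utr_fasta)
      ts <- target_switch(mseq, site$position, utrs)
      matches <- dplyr::bind_rows(
        dplyr::mutate(ts$matches$non_edited, isomir = "non_edited"),
        dplyr::mutate(ts$matches$edited, isomir = "edited")
      )
      p <- file.path(config$out_dir, "site_matches.tsv")
      write_table_checked(matches, p, "site_matches")
      record("target-switch", p, nrow(matches))
      p <- file.path(config$out_dir, "pool_comparison.tsv")
      write_table_checked(tidy(ts$comparison), p, "pool_comparison")
      record("target-switch", p, 1L)
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  stage_log("done", "manifest written to %s", manifest_path)
  invisible(manifest)
}

#' A small, fast demonstration configuration
#'
#' Eight libraries (4 per group), 8 hairpins, mean coverage 300 and a
#' strongly differential planted site - sized so a full read-level run
#' completes in seconds, for examples and smoke tests.
#'
#' @param out_dir Output directory.
#' @param rng_seed Seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(out_dir = tempfile("miredit_demo_"),
                                 rng_seed = 1L) {
  pipeline_config(
    out_dir = out_dir,
    sim = sim_config(
      n_hairpins = 8L,
      group_sizes = c(control = 4L, case = 4L),
      coverage_mean = 300,
      planted_sites = tibble::tibble(
        mature_id = "syn-mir-001-3p", position = 6L,
        fraction_control = 0.85, fraction_case = 0.40
      ),
      rng_seed = rng_seed
    )
  )
}
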