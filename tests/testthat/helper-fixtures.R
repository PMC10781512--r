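# In-code fixtures shared across test files.  Everything is generated at
# test time; nothing is read from disk except files these helpers write to
# tempdir().

# two tiny hairpins with one 3p mature arm each; mature of h1 carries an A
# at mature position 6 in a UAG context
tiny_reference <- function() {
  m1 <- "CGGUUAGGCAUCGAUGCAGCA" # 21 nt, A at +6 (U A G at 5..7)
  m2 <- "GGCAUCCGUAAGGCUUCGGCA" # 21 nt
  hairpins <- tibble::tibble(
    id = c("h1", "h2"),
    sequence = c(
      paste0("GCAUGCAUGC", m1, "CGUAC"),
      paste0("AUAUAUAUGG", m2, "GGCAU")
    )
  )
  mature <- tibble::tibble(
    mature_id = c("m1-3p", "m2-3p"),
    hairpin_id = c("h1", "h2"),
    start = 11L, end = 31L, arm = "3p"
  )
  list(hairpins = hairpins, mature = mature, m1 = m1, m2 = m2)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

write_tmp_fastq <- function(lines) {
  f <- tempfile(fileext = ".fq")
  writeLines(lines, f)
  f
}

# exhaustive reference aligner: scans every ungapped placement on every
# hairpin, independent of the package's band-lookup implementation
brute_force_align <- function(seq, hairpins, max_mismatch) {
  L <- nchar(seq)
  hits <- NULL
  for (i in seq_len(nrow(hairpins))) {
    H <- nchar(hairpins$sequence[i])
    if (H < L) next
    for (o in seq_len(H - L + 1)) {
      win <- substr(hairpins$sequence[i], o, o + L - 1)
      mm <- sum(strsplit(seq, "")[[1]] != strsplit(win, "")[[1]])
      if (mm <= max_mismatch) {
        hits <- rbind(hits, data.frame(hairpin_id = hairpins$id[i],
                                       offset = o, n_mismatch = mm))
      }
    }
  }
  if (is.null(hits)) {
    return(list(status = "unaligned", hairpin_id = NA, offset = NA,
                n_mismatch = NA))
  }
  best <- hits[hits$n_mismatch == min(hits$n_mismatch), , drop = FALSE]
  if (length(unique(best$hairpin_id)) > 1) {
    return(list(status = "ambiguous", hairpin_id = NA, offset = NA,
                n_mismatch = NA))
  }
  list(status = "aligned", hairpin_id = best$hairpin_id[1],
       offset = min(best$offset), n_mismatch = best$n_mismatch[1])
}

# naive substring scanner used as the oracle for scan_utr
brute_force_scan <- function(utr, pattern) {
  L <- nchar(pattern)
  n <- nchar(utr)
  if (n < L) return(integer())
  which(vapply(seq_len(n - L + 1),
               function(i) substr(utr, i, i + L - 1) == pattern,
               logical(1)))
}
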