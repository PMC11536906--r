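# Shared fixtures and independent oracles, built in code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# two-exon plus-strand transcript used across coordinate tests:
# exons [100,110) + [120,130), tx length 20
tx_plus <- function() {
  transcript_model("txp", "gp", "chr1", "+",
                   data.frame(start = c(100, 120), end = c(110, 130)))
}

tx_minus <- function() {
  transcript_model("txm", "gm", "chr1", "-",
                   data.frame(start = c(100, 120), end = c(110, 130)))
}

# a random spliced transcript on a given chromosome length
random_transcript <- function(id, chrom_len = 10000) {
  n_ex <- sample(1:4, 1)
  len <- sample(30:120, n_ex, replace = TRUE)
  gaps <- sample(20:200, n_ex, replace = TRUE)
  starts <- cumsum(gaps + c(0, len[-n_ex])) + sample(1:50, 1)
  transcript_model(id, paste0("g", id), "chr1",
                   sample(c("+", "-"), 1),
                   data.frame(start = starts, end = starts + len))
}

# minimal psite_track around a named list of per-transcript count vectors
fake_track <- function(counts, sample_id = "S1") {
  structure(list(sample_id = sample_id, counts = counts,
                 n_assigned = sum(vapply(counts, sum, 0)),
                 n_unassigned = 0L),
            class = "psite_track")
}

# ORF-shaped record sufficient for score_translation / presence counting
fake_orf <- function(orf_id, transcript_id, tx_start, tx_end) {
  list(orf_id = orf_id, transcript_id = transcript_id,
       tx_start = tx_start, tx_end = tx_end,
       length_codons = (tx_end - tx_start) %/% 3L)
}

# Independent brute-force ORF oracle: every (frame, ATG, in-frame stop)
# pair where the stop is the first in-frame stop at or after the ATG and
# the ATG is the first ATG of its stop-delimited region (default mode).
brute_force_orfs <- function(seq, min_codons, max_codons) {
  out <- list()
  L <- nchar(seq)
  codon_at <- function(i) substr(seq, i, i + 2L)
  for (fr in 0:2) {
    starts <- seq(fr + 1L, L - 2L, by = 3L)
    if (!length(starts)) next
    cods <- vapply(starts, codon_at, "")
    is_stop <- cods %in% c("TAA", "TAG", "TGA")
    is_atg <- cods == "ATG"
    region_start <- 1L
    for (si in which(is_stop)) {
      in_region <- region_start:si
      atg <- in_region[is_atg[in_region] & in_region < si]
      if (length(atg)) {
        a <- atg[1L]
        lc <- si - a + 1L
        if (lc >= min_codons && lc <= max_codons) {
          gc_table <- Biostrings::GENETIC_CODE
          pep <- paste(vapply(starts[a:(si - 1L)], function(p) {
            cod <- substr(seq, p, p + 2L)
            if (cod %in% names(gc_table)) gc_table[[cod]] else "X"
          }, ""), collapse = "")
          if (!grepl("X", pep, fixed = TRUE))
            out[[length(out) + 1L]] <- list(
              frame = fr, tx_start = starts[a] - 1L,
              tx_end = starts[si] + 2L, aa_seq = pep, length_codons = lc)
        }
      }
      region_start <- si + 1L
    }
  }
  out
}

# Independent affine-gap Smith-Waterman oracle in plain R (full
# three-state DP; gap of length g costs open + g * ext).
sw_oracle_score <- function(q, t, mat, open = 11, ext = 1) {
  qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
  m <- length(qs); n <- length(ts)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[qs[i - 1], ts[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# small simulated world shared by rescue/pipeline-style tests
small_sim_config <- function(seed, ...) {
  simulation_config(seed, n_chrom = 2L, chrom_len = 200000L,
                    n_transcripts = 40L, n_smorfs = 15L,
                    n_extra_genes = 60L, ...)
}
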