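# smORF discovery: three-frame ORF enumeration, novelty filtering and the
# translation-calling statistic.
#
# The calling statistic is a transparent product of two scale-free terms:
#   f    = in-frame fraction of P-sites over the ORF (3-nt periodicity)
#   pme  = normalized entropy of the in-frame per-codon counts
#          (coverage uniformity; "percentage of maximum entropy")
# score = f * pme, thresholded at 0.7 by default, with a minimum P-site
# count (default 10) required to call.

#' Enumerate candidate ORFs in a transcript sequence
#'
#' Scans all three reading frames.  Within each stop-delimited region the
#' ORF runs from the 5'-most ATG to the in-frame stop (stop included in the
#' span and in `length_codons`); with `all_starts = TRUE` internal-ATG
#' variants are also reported.  ORFs lacking an in-frame stop inside the
#' transcript are excluded, as are ORFs whose peptide contains X (from
#' N-containing codons).
#'
#' @param tx_seq nucleotide string over A,C,G,T,N
#' @param min_codons,max_codons bounds on `length_codons` (ATG..stop
#'   inclusive); defaults 6 and 151 (= 150 aa + stop)
#' @param all_starts also report ORFs starting at internal ATGs
#' @return list of records: `frame` (0/1/2), `tx_start`, `tx_end`
#'   (transcript coordinates, end exclusive, stop included), `aa_seq`
#'   (peptide without stop), `length_codons`
#' @export
enumerate_candidate_orfs <- function(tx_seq, min_codons = 6L,
                                     max_codons = 151L,
                                     all_starts = FALSE) {
  check_nt_alphabet(tx_seq, "transcript sequence")
  stopifnot(min_codons >= 2L, max_codons >= min_codons)
  out <- list()
  L <- nchar(tx_seq)
  for (fr in 0:2) {
    n_cod <- (L - fr) %/% 3L
    if (n_cod < min_codons) next
    pep <- translate_nt(substr(tx_seq, fr + 1L, fr + 3L * n_cod))
    aa <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- which(aa == "*")
    if (!length(stops)) next
    region_start <- 1L
    for (st in stops) {
      if (st > region_start) {
        ms <- region_start - 1L + which(aa[region_start:(st - 1L)] == "M")
        if (length(ms)) {
          starts <- if (all_starts) ms else ms[1L]
          for (m in starts) {
            lc <- st - m + 1L
            if (lc < min_codons || lc > max_codons) next
            aaseq <- paste(aa[m:(st - 1L)], collapse = "")
            if (grepl("X", aaseq, fixed = TRUE)) next
            out[[length(out) + 1L]] <- list(
              frame = fr,
              tx_start = fr + 3L * (m - 1L),
              tx_end = fr + 3L * st,
              aa_seq = aaseq, length_codons = lc)
          }
        }
      }
      region_start <- st + 1L
    }
  }
  out
}

#' Enumerate candidate ORFs across an annotation set
#'
#' Runs [enumerate_candidate_orfs()] on every transcript and attaches
#' identifiers and genomic blocks.  ORF ids are
#' `"<transcript_id>:<tx_start>-<tx_end>"`.
#'
#' @param genome named character vector of chromosome sequences
#' @param ann [annotation_set()]
#' @inheritParams enumerate_candidate_orfs
#' @return list of candidate records additionally carrying `orf_id`,
#'   `transcript_id`, `chrom`, `strand`, `blocks`
#' @export
candidate_orfs <- function(genome, ann, min_codons = 6L, max_codons = 151L,
                           all_starts = FALSE) {
  out <- list()
  for (tx in ann$transcripts) {
    seqs <- extract_transcript_seq(genome, tx)
    cands <- enumerate_candidate_orfs(seqs, min_codons, max_codons,
                                      all_starts)
    for (cd in cands) {
      cd$transcript_id <- tx$transcript_id
      cd$chrom <- tx$chrom
      cd$strand <- tx$strand
      cd$orf_id <- paste0(tx$transcript_id, ":", cd$tx_start, "-", cd$tx_end)
      cd$blocks <- tx_to_genome(tx, cd$tx_start, cd$tx_end)
      out[[length(out) + 1L]] <- cd
    }
  }
  out
}

.blocks_gr <- function(cand) {
  GenomicRanges::GRanges(
    seqnames = cand$chrom,
    ranges = IRanges::IRanges(start = cand$blocks$start + 1L,
                              end = cand$blocks$end),
    strand = cand$strand)
}

#' Novelty filter for a candidate ORF
#'
#' A candidate is rejected, in this order of precedence, when (i) any
#' genomic block overlaps an annotated CDS exon on the same strand by at
#' least 1 nt (`cds_overlap`); (ii) its peptide attains a local-alignment
#' E-value at or below `e_thresh` against any known protein
#' (`known_protein_match`; BLOSUM62, same scoring as the conservation
#' module); or (iii) it falls outside the codon-length bounds
#' (`too_long`/`too_short`).  Otherwise it is `kept`.
#'
#' @param cand candidate record with `blocks` (see [candidate_orfs()])
#' @param ann [annotation_set()] supplying annotated CDS
#' @param known_proteins character vector of known peptide sequences
#' @param e_thresh E-value threshold for a protein match (default 1e-3)
#' @param min_codons,max_codons codon-length bounds (ATG..stop inclusive)
#' @return list with `keep` (logical) and `reason` (one of `cds_overlap`,
#'   `known_protein_match`, `too_long`, `too_short`, `kept`)
#' @export
novelty_filter <- function(cand, ann, known_proteins = character(0),
                           e_thresh = 1e-3, min_codons = 6L,
                           max_codons = 151L) {
  if (length(ann$cds_gr)) {
    ov <- GenomicRanges::countOverlaps(.blocks_gr(cand), ann$cds_gr)
    if (any(ov > 0))
      return(list(keep = FALSE, reason = "cds_overlap"))
  }
  if (length(known_proteins)) {
    n_total <- sum(nchar(known_proteins))
    m <- nchar(cand$aa_seq)
    pars <- alignment_params()
    # one local alignment against the '*'-joined proteome: the stop
    # penalty prevents alignments from crossing protein boundaries, so
    # the best score equals the best per-protein score
    target <- paste(known_proteins, collapse = "*")
    s <- sw_align(cand$aa_seq, target, pars)$score
    if (evalue_from_score(s, m, n_total, pars) <= e_thresh)
      return(list(keep = FALSE, reason = "known_protein_match"))
  }
  if (cand$length_codons > max_codons)
    return(list(keep = FALSE, reason = "too_long"))
  if (cand$length_codons < min_codons)
    return(list(keep = FALSE, reason = "too_short"))
  list(keep = TRUE, reason = "kept")
}

#' Batch novelty filter
#'
#' Vectorized equivalent of applying [novelty_filter()] to every
#' candidate: one interval query for all CDS overlaps and one batched
#' score-only alignment pass against the `*`-joined known proteome.
#'
#' @inheritParams novelty_filter
#' @param cands list of candidate records
#' @return character vector of reasons, one per candidate
#' @export
novelty_filter_all <- function(cands, ann, known_proteins = character(0),
                               e_thresh = 1e-3, min_codons = 6L,
                               max_codons = 151L) {
  if (!length(cands)) return(character(0))
  reason <- rep("kept", length(cands))
  if (length(ann$cds_gr)) {
    nb <- vapply(cands, function(cd) nrow(cd$blocks), 0L)
    all_gr <- GenomicRanges::GRanges(
      seqnames = rep(vapply(cands, `[[`, "", "chrom"), nb),
      ranges = IRanges::IRanges(
        start = unlist(lapply(cands, function(cd) cd$blocks$start)) + 1L,
        end = unlist(lapply(cands, function(cd) cd$blocks$end))),
      strand = rep(vapply(cands, `[[`, "", "strand"), nb))
    ov <- GenomicRanges::countOverlaps(all_gr, ann$cds_gr) > 0
    hit <- unique(rep(seq_along(cands), nb)[ov])
    reason[hit] <- "cds_overlap"
  }
  todo <- which(reason == "kept")
  if (length(known_proteins) && length(todo)) {
    pars <- alignment_params()
    target <- paste(known_proteins, collapse = "*")
    n_total <- sum(nchar(known_proteins))
    aa <- vapply(cands[todo], `[[`, "", "aa_seq")
    s <- sw_scores(aa, target, pars)
    ev <- evalue_from_score(s, nchar(aa), n_total, pars)
    reason[todo[ev <= e_thresh]] <- "known_protein_match"
  }
  lc <- vapply(cands, `[[`, 0L, "length_codons")
  reason[reason == "kept" & lc > max_codons] <- "too_long"
  reason[reason == "kept" & lc < min_codons] <- "too_short"
  reason
}

#' Score translation of an ORF from a P-site track
#'
#' With per-position counts v over the ORF span (stop codon included),
#' `f` is the fraction of counts at positions congruent to `tx_start`
#' modulo 3.  The in-frame per-codon vector c covers the
#' `length_codons - 1` coding codons (stop excluded);
#' `pme = (-sum p_i log p_i) / log(length_codons - 1)` with `p = c/sum(c)`,
#' defined as 0 when `sum(c) = 0` and as 1 when there is a single coding
#' codon.  `score = f * pme`; an ORF passes when `score >= threshold` and
#' `n_psites >= min_psites`.
#'
#' @param orf candidate record with `transcript_id`, `tx_start`, `tx_end`,
#'   `length_codons`
#' @param track `psite_track` (see [assign_psites()])
#' @param threshold score threshold in (0, 1]; default 0.7
#' @param min_psites minimum total P-site count to call; default 10
#' @return list with `n_psites`, `f`, `pme`, `score`, `passes`
#' @export
score_translation <- function(orf, track, threshold = 0.7,
                              min_psites = 10L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (orf$tx_end <= orf$tx_start) stop("zero-length ORF")
  v <- track$counts[[orf$transcript_id]]
  if (is.null(v)) stop("track has no transcript ", orf$transcript_id)
  v <- v[(orf$tx_start + 1L):orf$tx_end]
  n <- sum(v)
  if (n == 0)
    return(list(n_psites = 0L, f = 0, pme = 0, score = 0, passes = FALSE))
  inframe_pos <- seq(1L, length(v), by = 3L)
  f <- sum(v[inframe_pos]) / n
  n_coding <- orf$length_codons - 1L
  cvec <- v[inframe_pos[seq_len(n_coding)]]
  tot <- sum(cvec)
  pme <- if (tot == 0) 0
         else if (n_coding == 1L) 1
         else {
           p <- cvec[cvec > 0] / tot
           (-sum(p * log(p))) / log(n_coding)
         }
  score <- f * pme
  list(n_psites = n, f = f, pme = pme, score = score,
       passes = score >= threshold && n >= min_psites)
}

#' Call translated smORFs per sample
#'
#' Applies [score_translation()] to every candidate in every sample's track
#' independently.
#'
#' @param candidates list of (novelty-filtered) candidate records
#' @param tracks named list of `psite_track`
#' @inheritParams score_translation
#' @return named list, sample -> character vector of passing `orf_id`s
#' @export
call_smorfs <- function(candidates, tracks, threshold = 0.7,
                        min_psites = 10L) {
  out <- lapply(tracks, function(tr) {
    if (track_total(tr) == 0)
      warning("sample ", tr$sample_id, " has an empty track")
    ids <- vapply(candidates, function(cd) {
      sc <- score_translation(cd, tr, threshold, min_psites)
      if (sc$passes) cd$orf_id else NA_character_
    }, "")
    ids[!is.na(ids)]
  })
  names(out) <- names(tracks)
  out
}

#' Tabulate candidates with per-sample scores
#'
#' Convenience reporter: one row per candidate with score components and
#' pass flags for each sample.
#' @inheritParams call_smorfs
#' @return data.frame
#' @export
smorf_score_table <- function(candidates, tracks, threshold = 0.7,
                              min_psites = 10L) {
  base <- data.frame(
    orf_id = vapply(candidates, `[[`, "", "orf_id"),
    transcript_id = vapply(candidates, `[[`, "", "transcript_id"),
    frame = vapply(candidates, `[[`, 0L, "frame"),
    length_codons = vapply(candidates, `[[`, 0L, "length_codons"),
    stringsAsFactors = FALSE)
  for (s in names(tracks)) {
    scs <- lapply(candidates, score_translation, track = tracks[[s]],
                  threshold = threshold, min_psites = min_psites)
    base[[paste0("score_", s)]] <- vapply(scs, `[[`, 0, "score")
    base[[paste0("pass_", s)]] <- vapply(scs, `[[`, TRUE, "passes")
  }
  base
}
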