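# Cross-sample coverage rescue, overlap sets, genomic-context
# classification and dataset summaries.
#
# Rescue rationale: per-sample periodicity-based calling has false
# negatives (coverage can be excellent while periodicity fails a
# threshold), so every smORF called in at least one sample is re-counted
# in all samples and declared present wherever its raw P-site count
# reaches a threshold.  Calls are never revoked: a called-but-low-count
# smORF stays present in its calling sample.

#' Build the cross-sample presence matrix
#'
#' Counts P-sites in all frames within each smORF's transcript span
#' (coverage, not periodicity) in every sample, then thresholds presence.
#'
#' @param master list of smORF records (the union of all per-sample calls),
#'   each with `orf_id`, `transcript_id`, `tx_start`, `tx_end`
#' @param tracks named list of `psite_track`
#' @param threshold presence count threshold (default 10; the relaxed
#'   alternative used in exploratory reporting is 2)
#' @param calls optional named list sample -> called `orf_id`s; calling
#'   samples are kept present regardless of count
#' @return object of class `presence_matrix`: integer matrix `counts`,
#'   logical matrix `present` (smORFs x samples), `threshold`
#' @export
build_presence_matrix <- function(master, tracks, threshold = 10L,
                                  calls = NULL) {
  if (!length(master)) stop("empty master smORF set")
  ids <- vapply(master, `[[`, "", "orf_id")
  samples <- names(tracks)
  counts <- matrix(0L, length(ids), length(samples),
                   dimnames = list(ids, samples))
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(master)) {
    sm <- master[[i]]
    if (is.null(tracks[[1]]$counts[[sm$transcript_id]])) {
      warning("smORF ", sm$orf_id, " has unresolvable coordinates; skipped")
      keep[i] <- FALSE
      next
    }
    for (s in samples) {
      v <- tracks[[s]]$counts[[sm$transcript_id]]
      counts[i, s] <- sum(v[(sm$tx_start + 1L):sm$tx_end])
    }
  }
  counts <- counts[keep, , drop = FALSE]
  present <- counts >= threshold
  if (!is.null(calls)) {
    for (s in intersect(names(calls), samples))
      present[rownames(present) %in% calls[[s]], s] <- TRUE
  }
  structure(list(counts = counts, present = present,
                 threshold = threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix: %d smORFs x %d samples, threshold %d, %d present cells>\n",
              nrow(x$counts), ncol(x$counts), x$threshold, sum(x$present)))
  invisible(x)
}

#' Venn partition of smORF presence across samples
#'
#' @param pm [build_presence_matrix()] result, or a logical matrix
#' @return list: `partitions` (named counts for every non-empty sample
#'   subset, names like `"A&B"`), `n_present` (smORFs present somewhere),
#'   `shared_fraction` (fraction present in more than one sample)
#' @export
overlap_sets <- function(pm) {
  present <- if (inherits(pm, "presence_matrix")) pm$present else pm
  if (ncol(present) < 2L) stop("need at least 2 samples")
  somewhere <- rowSums(present) > 0
  pat <- apply(present[somewhere, , drop = FALSE], 1, function(r)
    paste(colnames(present)[r], collapse = "&"))
  partitions <- table(pat)
  list(partitions = stats::setNames(as.integer(partitions),
                                    names(partitions)),
       n_present = sum(somewhere),
       shared_fraction = if (sum(somewhere) == 0) NA_real_
                         else mean(rowSums(present[somewhere, , drop = FALSE]) > 1))
}

#' Classify the genomic context of a smORF
#'
#' Precedence on same-strand overlap: 5'UTR => `uORF`; else 3'UTR =>
#' `dORF`; else exon of a non-coding biotype => `ncRNA`; else overlap with
#' any gene's span (either strand) => `intragenic`; else `intergenic`,
#' with the signed genomic distance to the nearest gene (negative when the
#' gene lies to the left; ties broken toward the gene with the lower start
#' coordinate).
#'
#' @param smorf record with `chrom`, `strand`, `blocks`
#' @param ann [annotation_set()]
#' @return list with `label` and `distance` (0 unless intergenic)
#' @export
classify_context <- function(smorf, ann) {
  gr <- .blocks_gr(smorf)
  hit <- function(subject) {
    length(subject) > 0 &&
      any(GenomicRanges::countOverlaps(gr, subject) > 0)
  }
  nc_exons <- ann$exon_gr[S4Vectors::mcols(ann$exon_gr)$biotype !=
                            "protein_coding"]
  if (hit(ann$utr5_gr)) return(list(label = "uORF", distance = 0))
  if (hit(ann$utr3_gr)) return(list(label = "dORF", distance = 0))
  if (hit(nc_exons)) return(list(label = "ncRNA", distance = 0))
  if (length(ann$gene_gr) &&
      any(GenomicRanges::countOverlaps(gr, ann$gene_gr,
                                       ignore.strand = TRUE) > 0))
    return(list(label = "intragenic", distance = 0))
  # intergenic: signed distance to nearest gene, either strand
  lo <- min(smorf$blocks$start); hi <- max(smorf$blocks$end)
  genes <- ann$gene_gr[as.character(GenomicRanges::seqnames(ann$gene_gr)) ==
                         smorf$chrom]
  if (!length(genes)) return(list(label = "intergenic", distance = NA_real_))
  gs <- GenomicRanges::start(genes) - 1L  # back to 0-based
  ge <- GenomicRanges::end(genes)
  dist <- ifelse(gs >= hi, gs - hi,          # gene to the right: >= 0
          ifelse(ge <= lo, -(lo - ge), 0))   # gene to the left: <= 0
  best <- which(abs(dist) == min(abs(dist)))
  if (length(best) > 1L) best <- best[which.min(gs[best])]
  list(label = "intergenic", distance = dist[best])
}

#' Summarize a smORF set
#'
#' Length histogram (in coding codons = microprotein amino acids), median
#' length, exponential decay constant of the length distribution, and the
#' pooled amino-acid frequency vector.
#'
#' The decay constant k comes from a count-weighted least-squares fit of
#' log-frequency against length over occupied histogram bins, modelling
#' `N(l) ~ exp(-k * l)`.  With fewer than 10 smORFs (or a single occupied
#' bin) k is reported as `NA`.
#'
#' @param smorfs list of records with `length_codons` and `aa_seq`
#' @return list: `lengths`, `hist` (named counts), `median_length`,
#'   `decay_k`, `aa_freq` (20-vector summing to 1)
#' @export
summarize_smorfs <- function(smorfs) {
  lens <- vapply(smorfs, `[[`, 0L, "length_codons") - 1L  # aa
  hist <- table(lens)
  k <- NA_real_
  if (length(smorfs) >= 10L && length(hist) > 1L) {
    l <- as.numeric(names(hist)); n <- as.numeric(hist)
    fit <- stats::lm(log(n) ~ l, weights = n)
    k <- max(0, -unname(stats::coef(fit)[2]))
  } else if (length(hist) == 1L) {
    k <- 0
  }
  peps <- paste(vapply(smorfs, `[[`, "", "aa_seq"), collapse = "")
  cnt <- table(factor(strsplit(peps, "", fixed = TRUE)[[1]], levels = AA20))
  aa_freq <- if (sum(cnt) > 0) as.numeric(cnt) / sum(cnt)
             else rep(0, length(AA20))
  names(aa_freq) <- AA20
  list(lengths = as.integer(lens),
       hist = stats::setNames(as.integer(hist), names(hist)),
       median_length = stats::median(lens),
       decay_k = k, aa_freq = aa_freq)
}
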