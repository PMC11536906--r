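# BED12 serialization of multi-block smORF coordinates.

#' Write smORFs as BED12
#'
#' One line per smORF; 0-based half-open; the score column carries the
#' translation score scaled by 1000 and clamped to `[0, 1000]`.
#'
#' @param smorfs list of candidate-ORF records (see
#'   [enumerate_candidate_orfs()]), each with `orf_id`, `chrom`, `strand`,
#'   `blocks` (data.frame `start`/`end` in genomic order) and optionally
#'   `score`
#' @param path output file
#' @export
write_bed12 <- function(smorfs, path) {
  lines <- vapply(smorfs, function(s) {
    b <- s$blocks
    if (is.null(b) || !nrow(b)) stop("smORF ", s$orf_id, " has no blocks")
    b <- b[order(b$start), , drop = FALSE]
    chrom_start <- b$start[1]; chrom_end <- b$end[nrow(b)]
    score <- if (is.null(s$score) || is.na(s$score)) 0
             else max(0, min(1000, round(s$score * 1000)))
    paste(s$chrom, chrom_start, chrom_end, s$orf_id, score, s$strand,
          chrom_start, chrom_end, "0",
          nrow(b),
          paste0(paste(b$end - b$start, collapse = ","), ","),
          paste0(paste(b$start - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file written by [write_bed12()]
#'
#' @param path file
#' @return list of records with `orf_id`, `chrom`, `strand`, `score`
#'   (back on the 0-1 scale) and `blocks`
#' @export
read_bed12 <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L) stop("not BED12: ", ncol(d), " columns")
  lapply(seq_len(nrow(d)), function(i) {
    sizes <- as.numeric(strsplit(d[i, 11], ",")[[1]])
    starts <- as.numeric(strsplit(d[i, 12], ",")[[1]])
    gs <- d[i, 2] + starts
    list(orf_id = d[i, 4], chrom = d[i, 1], strand = d[i, 6],
         score = d[i, 5] / 1000,
         blocks = data.frame(start = gs, end = gs + sizes))
  })
}
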