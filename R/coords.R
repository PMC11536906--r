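# Transcript <-> genome coordinate mapping.
#
# Transcript position 0 is the 5' end of the spliced transcript: the first
# base of the leftmost exon on "+", the last base of the rightmost exon on
# "-".  All intervals are 0-based half-open.

# cumulative exon lengths in transcript (5'->3') order
.tx_exon_chain <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  len <- ex$end - ex$start
  data.frame(start = ex$start, end = ex$end,
             tx_start = cumsum(c(0, len[-length(len)])),
             tx_end = cumsum(len))
}

#' Map a transcript interval onto the genome
#'
#' @param tx [transcript_model()]
#' @param start,end transcript coordinates, 0-based half-open,
#'   `0 <= start < end <= tx_length`
#' @return data.frame of genomic blocks (`start`, `end`) in genomic order;
#'   total block length equals `end - start`
#' @export
tx_to_genome <- function(tx, start, end) {
  if (start < 0 || end > tx$tx_length || start >= end)
    stop("transcript interval [", start, ",", end, ") outside transcript ",
         tx$transcript_id, " (length ", tx$tx_length, ")")
  ch <- .tx_exon_chain(tx)
  blocks <- list()
  for (i in seq_len(nrow(ch))) {
    lo <- max(start, ch$tx_start[i]); hi <- min(end, ch$tx_end[i])
    if (lo >= hi) next
    if (tx$strand == "+") {
      g0 <- ch$start[i] + (lo - ch$tx_start[i])
      blocks[[length(blocks) + 1L]] <- c(g0, g0 + (hi - lo))
    } else {
      g1 <- ch$end[i] - (lo - ch$tx_start[i])   # exclusive end
      blocks[[length(blocks) + 1L]] <- c(g1 - (hi - lo), g1)
    }
  }
  m <- do.call(rbind, blocks)
  out <- data.frame(start = m[, 1], end = m[, 2])
  out[order(out$start), , drop = FALSE]
}

# genomic position of every transcript position (vector of length
# tx_length); vectorized companion to tx_to_genome for single positions
.tx_pos_map <- function(tx) {
  ch <- .tx_exon_chain(tx)
  out <- numeric(tx$tx_length)
  for (i in seq_len(nrow(ch))) {
    idx <- (ch$tx_start[i] + 1L):ch$tx_end[i]
    out[idx] <- if (tx$strand == "+") ch$start[i]:(ch$end[i] - 1L)
                else (ch$end[i] - 1L):ch$start[i]
  }
  out
}

#' Map genomic positions into transcript coordinates
#'
#' Inverse of [tx_to_genome()] on exonic positions.  Intronic or
#' out-of-range positions map to `NA` (a defined "not exonic" result,
#' not an error).
#'
#' @param tx [transcript_model()]
#' @param gpos numeric vector of 0-based genomic positions
#' @return integer vector of transcript positions, `NA` where not exonic
#' @export
genome_to_tx <- function(tx, gpos) {
  ch <- .tx_exon_chain(tx)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ch))) {
    hit <- !is.na(gpos) & gpos >= ch$start[i] & gpos < ch$end[i]
    if (!any(hit)) next
    if (tx$strand == "+")
      out[hit] <- as.integer(ch$tx_start[i] + (gpos[hit] - ch$start[i]))
    else
      out[hit] <- as.integer(ch$tx_start[i] + (ch$end[i] - 1 - gpos[hit]))
  }
  out
}
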