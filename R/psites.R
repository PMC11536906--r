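# Footprint handling: P-site offsetting and per-transcript track
# construction.  A P-site track stores, per sample, an integer coverage
# vector along each transcript (0-based transcript positions).

#' P-site offset table
#'
#' Maps footprint read length (nt) to the offset of the P-site from the
#' read's 5' end.  The default assigns 12 nt for read lengths 26-32, the
#' common ribosome-profiling convention; reads of other lengths are skipped
#' (`fallback = "skip"`) or given `default_offset`.
#'
#' @param offsets named numeric vector, names = read lengths
#' @param fallback `"skip"` or `"default_offset"`
#' @param default_offset offset used when `fallback = "default_offset"`
#' @return object of class `psite_offset_table`
#' @export
psite_offset_table <- function(offsets = stats::setNames(rep(12L, 7L), 26:32),
                               fallback = c("skip", "default_offset"),
                               default_offset = 12L) {
  fallback <- match.arg(fallback)
  lens <- as.integer(names(offsets))
  if (any(offsets < 0) || any(offsets >= lens))
    stop("offsets must satisfy 0 <= offset < read_length")
  structure(list(offsets = stats::setNames(as.integer(offsets), lens),
                 fallback = fallback,
                 default_offset = as.integer(default_offset)),
            class = "psite_offset_table")
}

.offset_for <- function(tbl, len) {
  key <- as.character(len)
  if (key %in% names(tbl$offsets)) return(tbl$offsets[[key]])
  if (tbl$fallback == "skip") return(NA_integer_)
  tbl$default_offset
}

#' Construct an empty P-site track for a sample
#' @keywords internal
.empty_track <- function(sample_id, ann) {
  counts <- lapply(ann$transcripts, function(tx) integer(tx$tx_length))
  structure(list(sample_id = sample_id, counts = counts,
                 n_assigned = 0L, n_unassigned = 0L),
            class = "psite_track")
}

#' @export
print.psite_track <- function(x, ...) {
  cat(sprintf("<psite_track %s: %d P-sites over %d transcripts (%d reads unassigned)>\n",
              x$sample_id, sum(vapply(x$counts, sum, 0)), length(x$counts),
              x$n_unassigned))
  invisible(x)
}

#' Assign footprint P-sites to transcript tracks
#'
#' The P-site genomic position of a footprint is its 5' end plus the
#' read-length-dependent offset: `start + offset` on "+", `(end-1) - offset`
#' on "-".  Each P-site is mapped into every same-strand transcript whose
#' exons contain it (no fractional assignment; a position inside two
#' overlapping transcripts increments both tracks).  Reads whose length has
#' no offset are handled by the table's fallback policy; unmappable
#' (intronic/intergenic) P-sites are counted in the per-track log fields.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `sample` (`length` is derived as `end - start`)
#' @param ann [annotation_set()]
#' @param offsets [psite_offset_table()]
#' @return named list of `psite_track`, one per sample (sorted by sample id)
#' @export
assign_psites <- function(reads, ann, offsets = psite_offset_table()) {
  stopifnot(all(c("chrom", "start", "end", "strand", "sample") %in%
                  names(reads)))
  len <- reads$end - reads$start
  off <- vapply(len, function(l) .offset_for(offsets, l), 0L)
  usable <- !is.na(off)
  psite <- ifelse(reads$strand == "+",
                  reads$start + off,
                  (reads$end - 1L) - off)
  samples <- sort(unique(reads$sample))
  tracks <- lapply(samples, .empty_track, ann = ann)
  names(tracks) <- samples

  if (any(usable)) {
    pg <- GenomicRanges::GRanges(
      seqnames = reads$chrom[usable],
      ranges = IRanges::IRanges(start = psite[usable] + 1L, width = 1L),
      strand = reads$strand[usable])
    ov <- GenomicRanges::findOverlaps(pg, ann$exon_gr)
    qh <- S4Vectors::queryHits(ov)
    txh <- S4Vectors::mcols(ann$exon_gr)$transcript_id[S4Vectors::subjectHits(ov)]
    usable_idx <- which(usable)
    hit_read <- usable_idx[qh]                 # row in `reads`
    assigned_reads <- logical(nrow(reads))
    if (length(qh)) {
      # a read may hit several exons of the same transcript only if exons
      # overlap, which transcript_model forbids; so (read, tx) pairs are unique
      key <- split(seq_along(qh), txh)
      for (tx_id in names(key)) {
        tx <- ann$transcripts[[tx_id]]
        rows <- hit_read[key[[tx_id]]]
        tpos <- genome_to_tx(tx, psite[rows])
        ok <- !is.na(tpos)
        assigned_reads[rows[ok]] <- TRUE
        if (!any(ok)) next
        d <- data.frame(s = reads$sample[rows[ok]], p = tpos[ok])
        for (s in unique(d$s)) {
          v <- tabulate(d$p[d$s == s] + 1L, nbins = tx$tx_length)
          tracks[[s]]$counts[[tx_id]] <- tracks[[s]]$counts[[tx_id]] + v
        }
      }
    }
    for (s in samples) {
      in_s <- reads$sample == s
      tracks[[s]]$n_assigned <- sum(assigned_reads & in_s)
      tracks[[s]]$n_unassigned <- sum(in_s) - sum(assigned_reads & in_s)
    }
  } else {
    for (s in samples)
      tracks[[s]]$n_unassigned <- sum(reads$sample == s)
  }
  tracks
}

#' Total P-site count of a track
#' @param track `psite_track`
#' @export
track_total <- function(track) sum(vapply(track$counts, sum, 0))

# -- file formats ------------------------------------------------------------

#' Read/write footprint BED6+1 (7th column = sample label)
#'
#' Columns: chrom, start, end, name, score, strand, sample; coordinates
#' 0-based half-open as in BED.
#' @param path file
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `length`,
#'   `sample`
#' @export
read_footprints <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 7L) stop("footprint BED needs 7 columns, got ", ncol(d))
  data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]],
             strand = d[[6]], length = d[[3]] - d[[2]], sample = d[[7]],
             stringsAsFactors = FALSE)
}

#' @rdname read_footprints
#' @param reads data.frame as accepted by [assign_psites()]
#' @export
write_footprints <- function(reads, path) {
  d <- data.frame(reads$chrom, reads$start, reads$end, ".",
                  0L, reads$strand, reads$sample)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a precomputed P-site count table
#'
#' Three tab-separated columns: sample, `transcript_id:pos` (0-based
#' transcript position), count.
#' @param path file
#' @param ann [annotation_set()] giving transcript lengths
#' @return named list of `psite_track`
#' @export
read_psite_table <- function(path, ann) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(d[[2]], ":", fixed = TRUE)
  tx_id <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  samples <- sort(unique(d[[1]]))
  tracks <- lapply(samples, .empty_track, ann = ann)
  names(tracks) <- samples
  for (i in seq_len(nrow(d))) {
    tx <- ann$transcripts[[tx_id[i]]]
    if (is.null(tx) || pos[i] < 0L || pos[i] >= tx$tx_length)
      stop("P-site outside transcript at table row ", i)
    s <- d[[1]][i]
    tracks[[s]]$counts[[tx_id[i]]][pos[i] + 1L] <-
      tracks[[s]]$counts[[tx_id[i]]][pos[i] + 1L] + d[[3]][i]
  }
  for (s in samples) tracks[[s]]$n_assigned <- track_total(tracks[[s]])
  tracks
}

#' @rdname read_psite_table
#' @param tracks named list of `psite_track`
#' @export
write_psite_table <- function(tracks, path) {
  rows <- list()
  for (tr in tracks) {
    for (tx_id in names(tr$counts)) {
      v <- tr$counts[[tx_id]]
      nz <- which(v > 0L)
      if (!length(nz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = tr$sample_id,
        key = paste0(tx_id, ":", nz - 1L), count = v[nz])
    }
  }
  d <- if (length(rows)) do.call(rbind, rows)
       else data.frame(sample = character(0), key = character(0),
                       count = integer(0))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
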