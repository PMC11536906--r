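# Transcript models and annotation sets.
#
# Internal coordinates are 0-based half-open throughout; GTF is 1-based
# inclusive on disk and is converted on read/write.  Exon tables are plain
# data.frames (chrom, start, end) sorted in genomic order; interval indices
# are GRanges built once per annotation set.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   genomic order, non-overlapping
#' @param biotype one of `"protein_coding"`, `"lncRNA"`, `"pseudogene"`,
#'   `"other"`
#' @param cds optional data.frame like `exons` giving the CDS footprint
#' @return object of class `transcript_model`; 5'/3' UTR interval lists are
#'   derived when a CDS is present
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "other", cds = NULL) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start))
    stop("transcript ", transcript_id, ": exon with end <= start")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (!is.null(cds)) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    rownames(cds) <- NULL
  }
  tx <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons, biotype = biotype, cds = cds,
    tx_length = sum(exons$end - exons$start)
  ), class = "transcript_model")
  if (!is.null(cds) && nrow(cds)) {
    utr <- .derive_utrs(tx)
    tx$utr5 <- utr$utr5
    tx$utr3 <- utr$utr3
  }
  tx
}

# UTRs as genomic interval data.frames, derived from exons minus CDS span.
.derive_utrs <- function(tx) {
  cds_lo <- min(tx$cds$start); cds_hi <- max(tx$cds$end)
  left <- right <- list()
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (s < cds_lo) left[[length(left) + 1L]] <- c(s, min(e, cds_lo))
    if (e > cds_hi) right[[length(right) + 1L]] <- c(max(s, cds_hi), e)
  }
  mk <- function(l) {
    if (!length(l)) return(data.frame(start = numeric(0), end = numeric(0)))
    m <- do.call(rbind, l)
    data.frame(start = m[, 1], end = m[, 2])
  }
  left <- mk(left); right <- mk(right)
  if (tx$strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), %d nt, %s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$tx_length, x$biotype))
  invisible(x)
}

#' Bundle transcripts into an indexed annotation set
#'
#' Builds per-chromosome, stranded interval indices (exons, CDS, UTRs, gene
#' spans) used by overlap queries and context classification.
#'
#' @param transcripts list of [transcript_model()] objects
#' @return object of class `annotation_set`
#' @export
annotation_set <- function(transcripts) {
  if (!length(transcripts)) stop("empty annotation set")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(names(transcripts)))
    stop("duplicate transcript_id in annotation")
  gr_of <- function(field) {
    rows <- lapply(transcripts, function(tx) {
      df <- tx[[field]]
      if (is.null(df) || !nrow(df)) return(NULL)
      data.frame(chrom = tx$chrom, start = df$start, end = df$end,
                 strand = tx$strand, transcript_id = tx$transcript_id,
                 gene_id = tx$gene_id, biotype = tx$biotype,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
      seqnames = rows$chrom,
      ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
      strand = rows$strand,
      transcript_id = rows$transcript_id, gene_id = rows$gene_id,
      biotype = rows$biotype)
  }
  exon_gr <- gr_of("exons")
  # gene span: union of transcript spans per gene
  tx_span <- data.frame(
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    start = vapply(transcripts, function(t) min(t$exons$start), 0),
    end = vapply(transcripts, function(t) max(t$exons$end), 0),
    strand = vapply(transcripts, `[[`, "", "strand"),
    gene_id = vapply(transcripts, `[[`, "", "gene_id"),
    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(tx_span, tx_span$gene_id), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], gene_id = d$gene_id[1])))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = agg$chrom,
    ranges = IRanges::IRanges(start = agg$start + 1L, end = agg$end),
    strand = agg$strand, gene_id = agg$gene_id)
  structure(list(
    transcripts = transcripts,
    exon_gr = exon_gr, cds_gr = gr_of("cds"),
    utr5_gr = gr_of("utr5"), utr3_gr = gr_of("utr3"),
    gene_gr = gene_gr
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  bt <- table(vapply(x$transcripts, `[[`, "", "biotype"))
  cat(sprintf("<annotation_set: %d transcripts (%s)>\n",
              length(x$transcripts),
              paste(names(bt), bt, sep = ":", collapse = ", ")))
  invisible(x)
}

# -- GTF I/O -----------------------------------------------------------------

.parse_gtf_attrs <- function(s) {
  m <- gregexpr('(\\w+) "([^"]*)"', s)
  hits <- regmatches(s, m)[[1]]
  keys <- sub('^(\\w+) .*$', "\\1", hits)
  vals <- sub('^\\w+ "([^"]*)"$', "\\1", hits)
  stats::setNames(vals, keys)
}

#' Read a GTF annotation
#'
#' Parses exon and CDS features into an [annotation_set()].  On-disk
#' coordinates are 1-based inclusive and converted to the internal 0-based
#' half-open convention.  Only `transcript_id` and `gene_id` attributes are
#' required; `transcript_biotype`/`gene_biotype` are honored when present,
#' otherwise the biotype defaults to `"other"`.
#'
#' @param path GTF file with tab-delimited exon (and optional CDS) lines
#' @return [annotation_set()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  recs <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("GTF parse error at line ", i, ": expected 9 tab-delimited ",
           "columns, got ", length(f))
    feat <- f[3]
    if (!feat %in% c("exon", "CDS")) next
    start1 <- suppressWarnings(as.numeric(f[4]))
    end1 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start1) || is.na(end1) || end1 < start1)
      stop("GTF parse error at line ", i, ": invalid coordinates")
    at <- .parse_gtf_attrs(f[9])
    if (!all(c("transcript_id", "gene_id") %in% names(at)))
      stop("GTF parse error at line ", i,
           ": missing transcript_id/gene_id attribute")
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = f[1], feature = feat, start = start1 - 1, end = end1,
      strand = f[7], transcript_id = at[["transcript_id"]],
      gene_id = at[["gene_id"]],
      biotype = if ("transcript_biotype" %in% names(at)) at[["transcript_biotype"]]
                else if ("gene_biotype" %in% names(at)) at[["gene_biotype"]]
                else "other",
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("GTF contains no exon features: ", path)
  tab <- do.call(rbind, recs)
  txs <- lapply(split(tab, tab$transcript_id), function(d) {
    ex <- d[d$feature == "exon", , drop = FALSE]
    if (!nrow(ex)) stop("transcript ", d$transcript_id[1], " has no exons")
    cds <- d[d$feature == "CDS", , drop = FALSE]
    transcript_model(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = d$chrom[1], strand = d$strand[1],
      exons = ex[, c("start", "end")],
      biotype = d$biotype[1],
      cds = if (nrow(cds)) cds[, c("start", "end")] else NULL)
  })
  annotation_set(unname(txs))
}

#' Write an annotation set as GTF
#'
#' Inverse of [read_gtf()] for exon/CDS structure, strand and biotype
#' (coordinates re-emitted 1-based inclusive).
#' @param ann [annotation_set()]
#' @param path output file
#' @export
write_gtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in ann$transcripts) {
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
      tx$gene_id, tx$transcript_id, tx$biotype)
    emit <- function(df, feat) {
      for (i in seq_len(nrow(df)))
        writeLines(paste(tx$chrom, "smorfreg", feat, df$start[i] + 1,
                         df$end[i], ".", tx$strand, ".", attr_str,
                         sep = "\t"), con)
    }
    emit(tx$exons, "exon")
    if (!is.null(tx$cds) && nrow(tx$cds)) emit(tx$cds, "CDS")
  }
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequence in 5'->3' transcript orientation;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param genome named character vector of chromosome sequences
#' @param tx [transcript_model()]
#' @return uppercase nucleotide string over A,C,G,T,N
#' @export
extract_transcript_seq <- function(genome, tx) {
  if (!tx$chrom %in% names(genome))
    stop("unknown chromosome: ", tx$chrom)
  chrom_seq <- genome[[tx$chrom]]
  clen <- nchar(chrom_seq)
  if (any(tx$exons$start < 0) || any(tx$exons$end > clen))
    stop("exon out of chromosome bounds on ", tx$chrom,
         " (length ", clen, ")")
  pieces <- substring(chrom_seq, tx$exons$start + 1L, tx$exons$end)
  s <- toupper(paste(pieces, collapse = ""))
  if (tx$strand == "-") s <- revcomp(s)
  s
}
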