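# Low-level sequence and serialization helpers shared across modules.

#' @useDynLib smorfreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Most-used human codon per amino acid; used only for back-translation in the
# synthetic-data module (nucleotide-level realism is a non-goal there).
COMMON_CODON <- c(
  A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG", `*` = "TGA"
)

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Reverse complement of a nucleotide string
#'
#' Base-R path for short strings (avoids S4 dispatch overhead in tight
#' loops); Biostrings for chromosome-scale input.
#' @param s character scalar over A,C,G,T,N
#' @return character scalar
#' @keywords internal
revcomp <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(s)
  if (n > 50000L)
    return(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

.GC_TABLE <- local({
  gc_env <- as.list(Biostrings::GENETIC_CODE)
  unlist(gc_env)
})

# resolve a single N-containing codon: unique translation or X
.solve_fuzzy_codon <- function(codon) {
  pos <- gregexpr("[^ACGT]", codon)[[1]]
  if (pos[1] == -1L) return("X")
  expand <- codon
  for (p in pos) {
    expand <- unlist(lapply(expand, function(cd) {
      vapply(c("A", "C", "G", "T"), function(b) {
        substr(cd, p, p) <- b; cd
      }, "")
    }))
  }
  aa <- unique(.GC_TABLE[expand])
  if (length(aa) == 1L && !is.na(aa)) aa else "X"
}

#' Translate a nucleotide string to amino acids
#'
#' Trailing partial codons are dropped; codons containing N translate to X
#' unless the ambiguity is resolvable; stop codons become `*`.
#' @param s nucleotide string
#' @return amino-acid string (may contain `*` and `X`)
#' @keywords internal
translate_nt <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- .GC_TABLE[codons]
  fuzzy <- which(is.na(aa))
  if (length(fuzzy))
    aa[fuzzy] <- vapply(codons[fuzzy], .solve_fuzzy_codon, "")
  paste(aa, collapse = "")
}

#' Back-translate a peptide with the common-codon table
#' @param aa peptide string (20 amino acids), no stop
#' @param stop append a stop codon?
#' @keywords internal
back_translate <- function(aa, stop = TRUE) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(COMMON_CODON))
  if (length(bad))
    stop("cannot back-translate residues: ", paste(bad, collapse = ","))
  nt <- paste0(paste(COMMON_CODON[chars], collapse = ""),
               if (stop) "TGA" else "")
  nt
}

#' Validate a nucleotide alphabet
#' @keywords internal
check_nt_alphabet <- function(s, what = "sequence") {
  if (grepl("[^ACGTN]", s))
    stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(TRUE)
}

#' Deterministic JSON writer (no timestamps, stable key order)
#' @keywords internal
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a named FASTA into a plain character vector
#' @param path FASTA file
#' @return named character vector, sequences upper-cased
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Amino-acid length of a printed genomic span
#'
#' Published smORF loci are printed as 1-based inclusive genomic spans, e.g.
#' `"chr6:32845552-32845740"`.  Under the convention that the span covers the
#' coding codons only (stop codon excluded), the microprotein length in amino
#' acids is span-length / 3.  The alternative convention (span includes the
#' stop codon) gives span-length / 3 - 1.  Both are returned so reports can
#' carry the two readings side by side.
#'
#' @param span character like `"chr6:32845552-32845740"` (en dash or hyphen)
#' @return named list: `chrom`, `start`, `end` (1-based inclusive),
#'   `nt_length`, `aa_coding` (span covers coding codons),
#'   `aa_with_stop` (span includes the stop codon)
#' @export
span_aa_length <- function(span) {
  span <- gsub("–", "-", span)
  m <- regmatches(span, regexec("^([^:]+):([0-9]+)-([0-9]+)$", span))[[1]]
  if (length(m) != 4L) stop("cannot parse genomic span: ", span)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (end < start) stop("span end before start: ", span)
  nt <- end - start + 1
  if (nt %% 3 != 0) warning("span length not a multiple of 3: ", span)
  list(chrom = m[2], start = start, end = end, nt_length = nt,
       aa_coding = nt / 3, aa_with_stop = nt / 3 - 1)
}
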