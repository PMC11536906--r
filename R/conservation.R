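# Translated homology search: six-frame Smith-Waterman with
# Karlin-Altschul E-values, and conservation tiering over a species panel.

#' Alignment parameters for the translated search
#'
#' Defaults reproduce the standard gapped protein scoring system:
#' BLOSUM62, gap open 11, gap extend 1 (a gap of length g costs 11 + g),
#' with the published Karlin-Altschul parameters for that system
#' (lambda = 0.267, K = 0.041).
#'
#' @param matrix substitution matrix with amino-acid dimnames (including
#'   X and `*`); default `Biostrings` BLOSUM62
#' @param gap_open,gap_extend positive gap penalties
#' @param lambda,K Karlin-Altschul parameters for the scoring system
#' @return object of class `alignment_params`
#' @export
alignment_params <- function(matrix = NULL, gap_open = 11L,
                             gap_extend = 1L, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "alignment_params")
}

#' Gapped local alignment (Smith-Waterman)
#'
#' Affine-gap Smith-Waterman between two peptide strings under the scoring
#' system in `params`.  Coordinates in the result are 1-based inclusive.
#'
#' @param query,target peptide strings (may contain X and `*`)
#' @param params [alignment_params()]
#' @return list: `score`, `q_start`, `q_end`, `t_start`, `t_end`,
#'   `identity` (percent of alignment columns), `coverage` (percent of the
#'   query covered)
#' @export
sw_align <- function(query, target, params = alignment_params()) {
  alpha <- paste(rownames(params$matrix), collapse = "")
  r <- .sw_align_cpp(query, target, params$matrix, alpha,
                     params$gap_open, params$gap_extend)
  r$identity <- if (r$columns > 0) 100 * r$matches / r$columns else 0
  r$coverage <- if (nchar(query) > 0)
    100 * (r$q_end - r$q_start + 1) / nchar(query) else 0
  if (r$score == 0) r$coverage <- 0
  r
}

#' Score-only local alignment of many queries against one target
#'
#' Batched counterpart of [sw_align()] returning only the best raw score
#' per query (no traceback); used for bulk screens such as the novelty
#' filter.
#' @param queries character vector of peptides
#' @param target peptide string
#' @param params [alignment_params()]
#' @return integer vector of raw scores
#' @export
sw_scores <- function(queries, target, params = alignment_params()) {
  alpha <- paste(rownames(params$matrix), collapse = "")
  .sw_scores_cpp(queries, target, params$matrix, alpha,
                 params$gap_open, params$gap_extend)
}

#' Karlin-Altschul E-value for a raw local-alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with m the query length (aa) and n
#' the total translated target length (aa).
#'
#' @param score raw alignment score S
#' @param m query length (aa)
#' @param n total translated target length (aa)
#' @param params [alignment_params()]
#' @export
evalue_from_score <- function(score, m, n, params = alignment_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Six-frame translation of a chromosome
#'
#' @param seq nucleotide string
#' @return list of records `strand` (+/-), `frame` (0,1,2 from the 5' end
#'   of that strand), `aa` (translated string; stops as `*`)
#' @export
six_frame_translate <- function(seq) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (fr in 0:2) {
      n_cod <- (nchar(s) - fr) %/% 3L
      if (n_cod < 1L) next
      out[[length(out) + 1L]] <- list(
        strand = strand, frame = fr,
        aa = translate_nt(substr(s, fr + 1L, fr + 3L * n_cod)))
    }
  }
  out
}

#' Precompute the six-frame translation of a target genome
#'
#' [conservation_search()] accepts this in place of a raw genome; build it
#' once per species when searching many queries.
#' @param genome named character vector of chromosome sequences
#' @return object of class `translated_genome`
#' @export
translated_genome <- function(genome) {
  frames <- list()
  for (chrom in names(genome)) {
    for (f in six_frame_translate(genome[[chrom]])) {
      f$chrom <- chrom
      frames[[length(frames) + 1L]] <- f
    }
  }
  structure(list(frames = frames,
                 n_total = sum(vapply(frames, function(f) nchar(f$aa), 0))),
            class = "translated_genome")
}

#' Translated homology search of a peptide against a genome
#'
#' Translates all six frames of every chromosome (stop codons remain in
#' the translated string and, through their substitution penalty, break
#' alignments into stop-delimited segments), aligns the query locally
#' against each frame, and reports hits at or below the E-value threshold,
#' sorted ascending by E.  Within one frame, non-overlapping secondary
#' hits are recovered by masking the best hit and re-aligning, up to
#' `max_hits_per_frame`; overlapping hits are thereby deduplicated keeping
#' the best.
#'
#' @param query_aa peptide (>= 6 aa; 20 amino acids plus X)
#' @param target_genome named character vector of chromosome sequences,
#'   or a prebuilt [translated_genome()]
#' @param params [alignment_params()]
#' @param e_thresh E-value threshold (default 1e-3)
#' @param max_hits_per_frame secondary-hit limit per frame (default 2)
#' @return data.frame of hits: `chrom`, `strand`, `frame`, `aa_offset`
#'   (0-based position of the hit in the translated frame), `score`,
#'   `bit_score`, `e_value`, `identity`, `coverage`, `starts_with_met`
#' @export
conservation_search <- function(query_aa, target_genome,
                                params = alignment_params(),
                                e_thresh = 1e-3,
                                max_hits_per_frame = 2L) {
  if (grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), query_aa))
    stop("query contains characters outside the 20 amino acids + X")
  if (nchar(query_aa) < 6L) stop("query shorter than 6 aa")
  if (!length(target_genome)) stop("empty target genome")
  tg <- if (inherits(target_genome, "translated_genome")) target_genome
        else translated_genome(target_genome)
  frames <- tg$frames
  n_total <- tg$n_total
  m <- nchar(query_aa)
  rows <- list()
  for (f in frames) {
    # score-only prescreen; the full traceback alignment runs only for
    # frames that can yield a reportable hit
    s0 <- sw_scores(query_aa, f$aa, params)[1]
    if (evalue_from_score(s0, m, n_total, params) > e_thresh) next
    aa <- f$aa
    for (k in seq_len(max_hits_per_frame)) {
      r <- sw_align(query_aa, aa, params)
      if (r$score <= 0) break
      ev <- evalue_from_score(r$score, m, n_total, params)
      if (ev > e_thresh) break
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f$chrom, strand = f$strand, frame = f$frame,
        aa_offset = r$t_start - 1L, score = r$score,
        bit_score = (params$lambda * r$score - log(params$K)) / log(2),
        e_value = ev, identity = r$identity, coverage = r$coverage,
        starts_with_met = substr(f$aa, r$t_start, r$t_start) == "M",
        stringsAsFactors = FALSE)
      # mask the hit and look for a further, non-overlapping one
      substr(aa, r$t_start, r$t_end) <-
        paste(rep("*", r$t_end - r$t_start + 1L), collapse = "")
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), strand = character(0),
                      frame = integer(0), aa_offset = integer(0),
                      score = integer(0), bit_score = numeric(0),
                      e_value = numeric(0), identity = numeric(0),
                      coverage = numeric(0), starts_with_met = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$e_value), , drop = FALSE]
}

#' Default species panel with clade metadata
#'
#' Eight mammals grouped by clade: chimp (primate); mouse, rat (rodent);
#' horse, sheep, cow, pig, dog (other mammals).
#' @return named character vector species -> clade
#' @export
species_panel <- function() {
  c(chimp = "primate", mouse = "rodent", rat = "rodent",
    horse = "mammal", sheep = "mammal", cow = "mammal",
    pig = "mammal", dog = "mammal")
}

#' Assign a conservation tier from per-species hits
#'
#' `human_specific` when no species has a hit; `primate_restricted` when
#' hits occur only in the primate clade; `rodent_conserved` when mouse or
#' rat has a hit; `broad_mammal` otherwise.
#'
#' @param hits_by_species named list, species -> best hit (or `NULL`) —
#'   or a character vector of species with hits
#' @param panel named vector species -> clade, see [species_panel()]
#' @return list with `tier` and `species_with_hits`
#' @export
assign_tier <- function(hits_by_species, panel = species_panel()) {
  species <- if (is.character(hits_by_species)) hits_by_species
             else names(hits_by_species)[!vapply(hits_by_species, is.null,
                                                 TRUE)]
  unknown <- setdiff(species, names(panel))
  if (length(unknown))
    stop("species not in panel: ", paste(unknown, collapse = ","))
  clades <- unique(unname(panel[species]))
  tier <- if (!length(species)) "human_specific"
          else if (identical(clades, "primate")) "primate_restricted"
          else if ("rodent" %in% clades) "rodent_conserved"
          else "broad_mammal"
  list(tier = tier, species_with_hits = sort(species))
}
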