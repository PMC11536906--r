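# Seeded synthetic-data generators: genome + annotation with planted
# smORFs, ribosome-footprint tracks with tunable 3-nt periodicity,
# NB count matrices with planted fold-changes, and ortholog genomes with
# per-species divergence.  Every generator is deterministic per seed and
# emits ground truth alongside its outputs.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: a 2 Mb genome over 4
#' chromosomes, 300 transcripts (60% protein-coding with CDS + UTRs, 40%
#' lncRNA), 150 planted smORFs with context quotas mirroring the observed
#' dominance of 5'UTR smORFs (70% uORF, 22% ncRNA, 7% dORF, 1%
#' intergenic), a codon-length law decaying at k = 0.02, amino-acid usage
#' mildly enriched in A/G/P/R, 4 ribosome-profiling samples, and an
#' RNA-seq design of 2 conditions x 3 replicates.
#'
#' Periodicity scheme: every planted smORF is translated in all
#' footprint samples, cleanly (p = `p_clean`, default 0.95) in one
#' designated sample and in each further sample cleanly with probability
#' `clean_extra_prob` (default 0.15), otherwise with degraded periodicity
#' `p_suppressed` (default 0.5) that defeats the 0.7 score threshold while
#' leaving coverage intact — the regime in which per-sample calling fails
#' but count-based rescue succeeds.
#'
#' @param seed integer seed (mandatory); sub-generators use seed+1..seed+3
#' @param ... overrides for any default listed below
#' @return object of class `sim_config`
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # genome / annotation
    n_chrom = 4L, chrom_len = 500000L,
    n_transcripts = 300L,
    biotype_mix = c(protein_coding = 0.6, lncRNA = 0.4),
    cds_codons = c(50L, 250L), utr5_len = c(450L, 700L),
    utr3_len = c(450L, 700L), lnc_len = c(600L, 1500L),
    max_exons = 3L, intron_len = c(200L, 1500L),
    locus_gap = c(500L, 3000L),
    # planted smORFs
    n_smorfs = 150L,
    context_quotas = c(uORF = 0.70, ncRNA = 0.22, dORF = 0.07,
                       intergenic = 0.01),
    length_decay_k = 0.02, aa_min = 5L, aa_max = 150L,
    aa_enrichment = c(A = 2, G = 2, P = 2, R = 2),
    # footprints
    samples = paste0("S", 1:4),
    mean_depth = 100, p_clean = 0.95, p_suppressed = 0.5,
    clean_extra_prob = 0.15, background_per_nt = 0.02,
    read_lengths = 26:32,
    # RNA-seq counts
    conditions = c("control", "treatment"), n_replicates = 3L,
    n_extra_genes = 350L, de_fraction = 0.1, beta_abs = 2,
    dispersion = 0.05, mu_meanlog = log(500), mu_sdlog = 1,
    planted_size_factors = NULL,
    # orthologs
    panel = species_panel(), divergence = 0.05,
    ortholog_background = 30000L,
    tier_quotas = c(human_specific = 0.25, primate_restricted = 0.25,
                    broad_mammal = 0.25, rodent_conserved = 0.25)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ","))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random peptide under the configured amino-acid enrichment, no M start
# requirement, no internal stops by construction
.random_peptide <- function(n_aa, cfg) {
  w <- rep(1, length(AA20)); names(w) <- AA20
  w[names(cfg$aa_enrichment)] <- cfg$aa_enrichment
  paste(sample(AA20, n_aa, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

# smORF amino-acid length under N(l) ~ exp(-k l) truncated to [aa_min, cap]
.sample_aa_len <- function(cfg, cap) {
  hi <- min(cfg$aa_max, cap)
  if (hi < cfg$aa_min)
    stop("planted smORF cannot fit requested context: host region admits ",
         "at most ", cap, " aa but aa_min is ", cfg$aa_min)
  l <- seq(cfg$aa_min, hi)
  w <- exp(-cfg$length_decay_k * l)
  sample(l, 1L, prob = w / sum(w))
}

# cassette = in-frame stop guard + ATG + codons + stop; guarantees the
# planted ATG is the 5'-most of its stop-delimited region in its frame
.make_cassette <- function(aa_seq) {
  paste0("TAA", "ATG", back_translate(substr(aa_seq, 2L, nchar(aa_seq)),
                                      stop = TRUE))
}

#' Simulate a genome with annotation and planted smORFs
#'
#' Generates chromosome sequences, an annotated reference (protein-coding
#' transcripts with CDS/UTRs, lncRNAs), an assembled transcriptome (the
#' reference plus novel intergenic transcripts hosting intergenic
#' smORFs), and plants `n_smorfs` ATG..stop cassettes at positions
#' matching their context class.  Each cassette is preceded by an in-frame
#' stop so the planted ATG is the 5'-most of its region and enumeration
#' recovers exactly the planted span.
#'
#' @param cfg [simulation_config()]
#' @return list: `genome` (named character), `ann_ref` (reference
#'   [annotation_set()]), `ann_asm` (assembled, superset of reference),
#'   `truth` (planted smORF table, per-sample translated/periodicity
#'   matrices, known reference proteins)
#' @export
simulate_genome_annotation <- function(cfg) {
  set.seed(cfg$seed)
  quotas <- round(cfg$context_quotas * cfg$n_smorfs)
  quotas[1] <- cfg$n_smorfs - sum(quotas[-1])
  n_coding <- round(cfg$n_transcripts * cfg$biotype_mix[["protein_coding"]])
  n_lnc <- cfg$n_transcripts - n_coding
  if (quotas[["uORF"]] + quotas[["dORF"]] > n_coding ||
      quotas[["ncRNA"]] > n_lnc)
    stop("planted smORF cannot fit requested context: quotas exceed ",
         "available host transcripts")

  # -- transcript sequence plans -------------------------------------------
  plans <- list()
  for (i in seq_len(n_coding)) {
    n_cod <- .runif_int(1, cfg$cds_codons)
    cds_nt <- paste0("ATG",
                     back_translate(.random_peptide(n_cod - 2L, cfg),
                                    stop = FALSE), "TGA")
    plans[[length(plans) + 1L]] <- list(
      biotype = "protein_coding",
      utr5 = .random_dna(.runif_int(1, cfg$utr5_len)),
      cds = cds_nt,
      utr3 = .random_dna(.runif_int(1, cfg$utr3_len)))
  }
  for (i in seq_len(n_lnc)) {
    plans[[length(plans) + 1L]] <- list(
      biotype = "lncRNA", seq = .random_dna(.runif_int(1, cfg$lnc_len)))
  }

  # -- plant cassettes in transcript space ---------------------------------
  coding_idx <- which(vapply(plans, `[[`, "", "biotype") == "protein_coding")
  lnc_idx <- setdiff(seq_along(plans), coding_idx)
  hosts_u <- sample(coding_idx, quotas[["uORF"]])
  hosts_d <- sample(setdiff(coding_idx, hosts_u), quotas[["dORF"]])
  hosts_n <- sample(lnc_idx, quotas[["ncRNA"]])

  truth_rows <- list()
  plant <- function(plan_i, region, context) {
    pl <- plans[[plan_i]]
    reg_seq <- if (region == "seq") pl$seq else pl[[region]]
    cap <- (nchar(reg_seq) - 9L) %/% 3L - 1L    # guard+ATG+stop overhead
    n_aa <- .sample_aa_len(cfg, cap)
    aa_seq <- paste0("M", .random_peptide(n_aa - 1L, cfg))
    cas <- .make_cassette(aa_seq)
    pos <- sample(seq_len(nchar(reg_seq) - nchar(cas) + 1L), 1L) - 1L
    substr(reg_seq, pos + 1L, pos + nchar(cas)) <- cas
    if (region == "seq") plans[[plan_i]]$seq <<- reg_seq
    else plans[[plan_i]][[region]] <<- reg_seq
    # transcript-space offset of the region
    off <- switch(region,
                  utr5 = 0L, seq = 0L,
                  cds = nchar(plans[[plan_i]]$utr5),
                  utr3 = nchar(plans[[plan_i]]$utr5) +
                         nchar(plans[[plan_i]]$cds))
    truth_rows[[length(truth_rows) + 1L]] <<- list(
      plan_i = plan_i, context = context, aa_seq = aa_seq,
      tx_start = off + pos + 3L,
      tx_end = off + pos + 3L + 3L * (n_aa + 1L),
      length_codons = n_aa + 1L)
    invisible(NULL)
  }
  for (i in hosts_u) plant(i, "utr5", "uORF")
  for (i in hosts_d) plant(i, "utr3", "dORF")
  for (i in hosts_n) plant(i, "seq", "ncRNA")
  # intergenic smORFs live on novel single-exon transcripts absent from
  # the reference annotation
  for (i in seq_len(quotas[["intergenic"]])) {
    plans[[length(plans) + 1L]] <- list(
      biotype = "novel", seq = .random_dna(.runif_int(1, cfg$lnc_len)))
    plant(length(plans), "seq", "intergenic")
  }

  # -- lay loci onto chromosomes -------------------------------------------
  genome_parts <- lapply(seq_len(cfg$n_chrom), function(i) character(0))
  cursor <- rep(100L, cfg$n_chrom)
  pad0 <- .random_dna(100L)
  genome_parts <- lapply(genome_parts, function(p) pad0)
  names(cursor) <- paste0("chr", seq_len(cfg$n_chrom))
  txs_ref <- list(); txs_asm <- list()
  order_ix <- sample(seq_along(plans))   # shuffle loci over chromosomes
  chrom_of <- integer(length(plans)); tx_ids <- character(length(plans))
  for (k in seq_along(order_ix)) {
    i <- order_ix[k]
    pl <- plans[[i]]
    tx_seq <- if (pl$biotype == "protein_coding")
      paste0(pl$utr5, pl$cds, pl$utr3) else pl$seq
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq_len(cfg$max_exons), 1L)
    # split transcript into exons (5'->3'), then introns between them
    L <- nchar(tx_seq)
    if (n_ex > 1L) {
      cuts <- sort(sample(seq_len(L - 1L), n_ex - 1L))
      bounds <- c(0L, cuts, L)
    } else bounds <- c(0L, L)
    ex_seqs <- substring(tx_seq, bounds[-length(bounds)] + 1L,
                         bounds[-1]) # 5'->3'
    introns <- if (n_ex > 1L) .runif_int(n_ex - 1L, cfg$intron_len)
               else integer(0)
    chrom_i <- which.min(cursor)
    chrom <- names(cursor)[chrom_i]
    gap <- .runif_int(1, cfg$locus_gap)
    gstart <- cursor[chrom_i] + gap
    # genomic exon order: transcript order on "+", reversed on "-"
    g_ex <- if (strand == "+") ex_seqs else rev(vapply(ex_seqs, revcomp, ""))
    g_int <- if (strand == "+") introns else rev(introns)
    pieces <- character(0); exon_tab <- NULL; pos <- gstart
    for (e in seq_along(g_ex)) {
      exon_tab <- rbind(exon_tab,
                        data.frame(start = pos, end = pos + nchar(g_ex[e])))
      pieces <- c(pieces, g_ex[e])
      pos <- pos + nchar(g_ex[e])
      if (e < length(g_ex)) {
        pieces <- c(pieces, .random_dna(g_int[e]))
        pos <- pos + g_int[e]
      }
    }
    genome_parts[[chrom_i]] <- c(genome_parts[[chrom_i]],
                                 .random_dna(gap), paste(pieces, collapse = ""))
    if (pos > cfg$chrom_len)
      stop("planted loci exceed chromosome length ", cfg$chrom_len,
           "; increase chrom_len or reduce n_transcripts")
    cursor[chrom_i] <- pos
    tx_id <- sprintf("TX%04d", i)
    tx_ids[i] <- tx_id; chrom_of[i] <- chrom_i
    cds_tab <- NULL
    if (pl$biotype == "protein_coding") {
      u5 <- nchar(pl$utr5)
      tmp <- transcript_model(tx_id, paste0("G", tx_id), chrom, strand,
                              exon_tab, biotype = "protein_coding")
      cds_blocks <- tx_to_genome(tmp, u5, u5 + nchar(pl$cds))
      cds_tab <- cds_blocks
    }
    tx <- transcript_model(
      tx_id, paste0("G", tx_id), chrom, strand, exon_tab,
      biotype = if (pl$biotype == "novel") "other" else pl$biotype,
      cds = cds_tab)
    txs_asm[[length(txs_asm) + 1L]] <- tx
    if (pl$biotype != "novel") txs_ref[[length(txs_ref) + 1L]] <- tx
  }
  genome <- vapply(genome_parts, paste, "", collapse = "")
  names(genome) <- names(cursor)
  ann_ref <- annotation_set(txs_ref)
  ann_asm <- annotation_set(txs_asm)

  # -- assemble truth -------------------------------------------------------
  sm <- do.call(rbind, lapply(truth_rows, function(r) {
    tx_id <- tx_ids[r$plan_i]
    data.frame(orf_id = paste0(tx_id, ":", r$tx_start, "-", r$tx_end),
               transcript_id = tx_id, tx_start = r$tx_start,
               tx_end = r$tx_end, length_codons = r$length_codons,
               aa_seq = r$aa_seq, context = r$context,
               stringsAsFactors = FALSE)
  }))
  sm <- sm[order(sm$orf_id), , drop = FALSE]
  rownames(sm) <- NULL
  ns <- length(cfg$samples)
  translated <- matrix(TRUE, nrow(sm), ns,
                       dimnames = list(sm$orf_id, cfg$samples))
  periodicity <- matrix(cfg$p_suppressed, nrow(sm), ns,
                        dimnames = list(sm$orf_id, cfg$samples))
  for (i in seq_len(nrow(sm))) {
    clean <- sample(ns, 1L)
    extra <- stats::runif(ns) < cfg$clean_extra_prob
    periodicity[i, extra] <- cfg$p_clean
    periodicity[i, clean] <- cfg$p_clean
  }
  known_proteins <- vapply(
    plans[coding_idx],
    function(pl) sub("\\*$", "", translate_nt(pl$cds)), "")
  list(genome = genome, ann_ref = ann_ref, ann_asm = ann_asm,
       truth = list(smorfs = sm, translated = translated,
                    periodicity = periodicity,
                    known_proteins = unname(known_proteins)))
}

#' Simulate ribosome footprints for every sample
#'
#' For each translated (smORF, sample) pair the read count is Poisson with
#' mean `mean_depth`; each read's P-site sits on a uniformly drawn coding
#' codon, on frame 0 with the pair's planted periodicity p and otherwise
#' on frames 1/2 equally.  Transcript-wide uniform-frame background reads
#' (rate `background_per_nt` per transcript nt) cover untranslated ORFs
#' and intergenic candidates.  Read lengths are uniform over
#' `read_lengths`; reads are emitted as genomic intervals whose 5' end is
#' 12 nt upstream of the P-site, matching the default offset table.
#'
#' @param sim result of [simulate_genome_annotation()]
#' @param cfg [simulation_config()]
#' @return data.frame of reads (`chrom`, `start`, `end`, `strand`,
#'   `length`, `sample`)
#' @export
simulate_footprints <- function(sim, cfg) {
  set.seed(cfg$seed + 1L)
  truth <- sim$truth; ann <- sim$ann_asm
  pos_maps <- lapply(ann$transcripts, .tx_pos_map)
  rows <- list()
  emit <- function(tx, tpos, n, sample) {
    if (!n) return(invisible(NULL))
    gpos <- pos_maps[[tx$transcript_id]][tpos + 1L]
    len <- sample(cfg$read_lengths, n, replace = TRUE)
    if (tx$strand == "+") {
      start <- gpos - 12L; end <- start + len
    } else {
      end <- gpos + 12L + 1L; start <- end - len
    }
    ok <- start >= 0
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = tx$chrom, start = start[ok], end = end[ok],
      strand = tx$strand, length = len[ok], sample = sample,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (s in cfg$samples) {
    for (i in seq_len(nrow(truth$smorfs))) {
      if (!truth$translated[i, s]) next
      sm <- truth$smorfs[i, ]
      tx <- ann$transcripts[[sm$transcript_id]]
      n <- stats::rpois(1L, cfg$mean_depth)
      if (!n) next
      p <- truth$periodicity[i, s]
      codon <- sample(sm$length_codons - 1L, n, replace = TRUE) - 1L
      off <- ifelse(stats::runif(n) < p, 0L,
                    sample(c(1L, 2L), n, replace = TRUE))
      emit(tx, sm$tx_start + 3L * codon + off, n, s)
    }
    for (tx in ann$transcripts) {
      n <- stats::rpois(1L, cfg$background_per_nt * tx$tx_length)
      if (!n) next
      emit(tx, sample(tx$tx_length, n, replace = TRUE) - 1L, n, s)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), sample = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' `count_ij ~ NB(mean = s_j * mu_i * 2^(x_j beta_i), dispersion alpha)`;
#' features are the planted smORFs plus `n_extra_genes` null genes;
#' `de_fraction` of all features receive `beta = +/- beta_abs` (random
#' sign); `mu_i` is log-normal.
#'
#' @inheritParams simulate_footprints
#' @return list: `cm` ([count_matrix()]), `beta` (named planted log2
#'   fold-changes), `size_factors` (planted)
#' @export
simulate_counts <- function(sim, cfg) {
  set.seed(cfg$seed + 2L)
  feats <- c(sim$truth$smorfs$orf_id,
             sprintf("GENE%04d", seq_len(cfg$n_extra_genes)))
  n_f <- length(feats)
  samples <- paste0(rep(cfg$conditions, each = cfg$n_replicates), "_",
                    seq_len(cfg$n_replicates))
  design <- stats::setNames(rep(cfg$conditions, each = cfg$n_replicates),
                            samples)
  sf <- cfg$planted_size_factors
  if (is.null(sf)) sf <- rep(1, length(samples))
  x <- as.numeric(design == cfg$conditions[2])
  mu <- stats::rlnorm(n_f, cfg$mu_meanlog, cfg$mu_sdlog)
  beta <- stats::setNames(rep(0, n_f), feats)
  n_de <- round(cfg$de_fraction * n_f)
  if (n_de > 0) {
    de_i <- sample(n_f, n_de)
    beta[de_i] <- cfg$beta_abs * sample(c(-1, 1), n_de, replace = TRUE)
  }
  counts <- matrix(0L, n_f, length(samples),
                   dimnames = list(feats, samples))
  for (j in seq_along(samples)) {
    m <- sf[j] * mu * 2^(x[j] * beta)
    counts[, j] <- stats::rnbinom(n_f, mu = m, size = 1 / cfg$dispersion)
  }
  list(cm = count_matrix(counts, design), beta = beta,
       size_factors = stats::setNames(sf, samples))
}

# species embedded per planted tier
.tier_species <- function(tier, panel) {
  switch(tier,
         human_specific = character(0),
         primate_restricted = names(panel)[panel == "primate"],
         broad_mammal = names(panel)[panel != "rodent"],
         rodent_conserved = names(panel),
         stop("unknown tier: ", tier))
}

# mutate a peptide at per-site divergence d (substitutions to a random
# different amino acid)
.diverge_peptide <- function(aa, d) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < d
  if (any(hit))
    ch[hit] <- vapply(ch[hit],
                      function(a) sample(setdiff(AA20, a), 1L), "")
  paste(ch, collapse = "")
}

#' Simulate ortholog genomes for the conservation panel
#'
#' Each planted smORF is assigned a conservation tier (quotas from the
#' config); for every species whose clade the tier includes, the peptide
#' is mutated at amino-acid divergence `divergence`, back-translated with
#' the common-codon table, and embedded at a random position and strand in
#' that species' genome between random-sequence spacers.
#'
#' @inheritParams simulate_footprints
#' @return list: `genomes` (named list species -> named character genome),
#'   `tiers` (named character, planted tier per smORF)
#' @export
simulate_orthologs <- function(sim, cfg) {
  set.seed(cfg$seed + 3L)
  sm <- sim$truth$smorfs
  tiers <- sample(names(cfg$tier_quotas), nrow(sm), replace = TRUE,
                  prob = cfg$tier_quotas)
  names(tiers) <- sm$orf_id
  emb <- lapply(stats::setNames(nm = names(cfg$panel)),
                function(sp) character(0))
  for (i in seq_len(nrow(sm))) {
    for (sp in .tier_species(tiers[i], cfg$panel)) {
      pep <- .diverge_peptide(sm$aa_seq[i], cfg$divergence)
      nt <- paste0(back_translate(substr(pep, 1L, 1L), stop = FALSE),
                   back_translate(substr(pep, 2L, nchar(pep)), stop = TRUE))
      if (sample(c(TRUE, FALSE), 1L)) nt <- revcomp(nt)
      emb[[sp]] <- c(emb[[sp]], nt)
    }
  }
  genomes <- lapply(stats::setNames(nm = names(cfg$panel)), function(sp) {
    casettes <- sample(emb[[sp]])
    n_c <- length(casettes)
    spacer_total <- cfg$ortholog_background
    spacers <- vapply(seq_len(n_c + 1L),
                      function(i) .random_dna(max(50L,
                        stats::rpois(1L, spacer_total / (n_c + 1L)))), "")
    g <- paste0(paste0(spacers[seq_len(n_c)], casettes, collapse = ""),
                spacers[n_c + 1L])
    stats::setNames(g, "chr1")
  })
  list(genomes = genomes, tiers = tiers)
}
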