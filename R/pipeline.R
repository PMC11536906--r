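# End-to-end orchestration: simulate -> discover -> rescue -> classify ->
# DE -> conserve -> report, with a deterministic file bundle and a
# machine-readable manifest.

#' Pipeline configuration
#'
#' All thresholds default to the values the pipeline is built around:
#' calling score 0.7 with >= 10 P-sites, rescue count threshold 10,
#' |log2FC| >= 1 with FDR < 0.05, and conservation E-value <= 1e-3.
#'
#' @param seed integer seed driving the simulation block
#' @param out_dir output directory
#' @param sim [simulation_config()] (built from `seed` when omitted)
#' @param score_threshold,min_psites calling thresholds
#' @param rescue_threshold presence count threshold
#' @param lfc_min,fdr_max differential-expression thresholds
#' @param e_thresh conservation E-value threshold
#' @param conservation_subset number of smORFs searched against the
#'   ortholog panel (a deterministic subsample keeps the full Smith-
#'   Waterman search within minutes; set to `Inf` for all)
#' @param offsets [psite_offset_table()]
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed, out_dir, sim = NULL,
                            score_threshold = 0.7, min_psites = 10L,
                            rescue_threshold = 10L, lfc_min = 1,
                            fdr_max = 0.05, e_thresh = 1e-3,
                            conservation_subset = 40L,
                            offsets = psite_offset_table()) {
  stopifnot(score_threshold > 0, score_threshold <= 1,
            min_psites >= 0, rescue_threshold >= 0,
            lfc_min >= 0, fdr_max > 0, fdr_max < 1, e_thresh > 0)
  if (is.null(sim)) sim <- simulation_config(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 score_threshold = score_threshold,
                 min_psites = as.integer(min_psites),
                 rescue_threshold = as.integer(rescue_threshold),
                 lfc_min = lfc_min, fdr_max = fdr_max,
                 e_thresh = e_thresh,
                 conservation_subset = conservation_subset,
                 offsets = offsets),
            class = "pipeline_config")
}

.stage <- function(name, manifest, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[smorfreg] stage %-10s %6.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes simulate -> discover (enumerate, novelty-filter, per-sample
#' call) -> rescue -> classify -> DE -> conserve, writes per-stage outputs
#' plus `report.json` (filter-funnel counts and planted-truth recovery
#' metrics) and `manifest.json` (seed, config hash, per-stage record
#' counts) under `cfg$out_dir`.  Idempotent for a fixed seed: all outputs
#' are byte-identical across reruns.
#'
#' @param cfg [pipeline_config()]
#' @return the report, invisibly
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   config_hash = .config_hash(cfg), stages = list())
  on.exit(write_json_stable(manifest,
                            file.path(cfg$out_dir, "manifest.json")))

  sim <- .stage("simulate", manifest, {
    s <- simulate_genome_annotation(cfg$sim)
    write_fasta(s$genome, file.path(cfg$out_dir, "genome.fa"))
    write_gtf(s$ann_ref, file.path(cfg$out_dir, "annotation_ref.gtf"))
    write_gtf(s$ann_asm, file.path(cfg$out_dir, "annotation_asm.gtf"))
    s
  })
  reads <- .stage("footprints", manifest, {
    r <- simulate_footprints(sim, cfg$sim)
    write_footprints(r, file.path(cfg$out_dir, "footprints.bed"))
    r
  })
  tracks <- .stage("psites", manifest,
                   assign_psites(reads, sim$ann_asm, cfg$offsets))

  disc <- .stage("discover", manifest, {
    cands <- candidate_orfs(sim$genome, sim$ann_asm)
    reasons <- novelty_filter_all(cands, sim$ann_ref,
                                  sim$truth$known_proteins,
                                  e_thresh = cfg$e_thresh)
    novel <- cands[reasons == "kept"]
    tab <- smorf_score_table(novel, tracks, cfg$score_threshold,
                             cfg$min_psites)
    calls <- lapply(names(tracks), function(s)
      tab$orf_id[tab[[paste0("pass_", s)]]])
    names(calls) <- names(tracks)
    utils::write.table(tab, file.path(cfg$out_dir, "smorf_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(candidates = cands, novel = novel, calls = calls)
  })
  called_ids <- sort(unique(unlist(disc$calls)))
  master <- disc$novel[vapply(disc$novel, `[[`, "", "orf_id") %in%
                         called_ids]

  pm <- .stage("rescue", manifest, {
    if (!length(master)) stop("no smORF called in any sample")
    p <- build_presence_matrix(master, tracks, cfg$rescue_threshold,
                               calls = disc$calls)
    utils::write.table(data.frame(orf_id = rownames(p$counts), p$counts,
                                  check.names = FALSE),
                       file.path(cfg$out_dir, "presence_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn <- overlap_sets(p)
    write_json_stable(venn, file.path(cfg$out_dir, "venn.json"))
    p
  })

  ctx <- .stage("classify", manifest, {
    labs <- lapply(master, classify_context, ann = sim$ann_ref)
    d <- data.frame(orf_id = vapply(master, `[[`, "", "orf_id"),
                    context = vapply(labs, `[[`, "", "label"),
                    distance = vapply(labs, `[[`, 0, "distance"),
                    stringsAsFactors = FALSE)
    utils::write.table(d, file.path(cfg$out_dir, "context.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # scores for BED12 output: best per-sample score
    best <- vapply(master, function(sm) {
      max(vapply(tracks, function(tr)
        score_translation(sm, tr, cfg$score_threshold,
                          cfg$min_psites)$score, 0))
    }, 0)
    for (i in seq_along(master)) master[[i]]$score <- best[i]
    write_bed12(master, file.path(cfg$out_dir, "smorfs.bed"))
    write_fasta(stats::setNames(vapply(master, `[[`, "", "aa_seq"),
                                vapply(master, `[[`, "", "orf_id")),
                file.path(cfg$out_dir, "smorfs.faa"))
    summ <- summarize_smorfs(master)
    write_json_stable(summ[c("median_length", "decay_k", "aa_freq")],
                      file.path(cfg$out_dir, "summary.json"))
    d
  })

  dres <- .stage("de", manifest, {
    simc <- simulate_counts(sim, cfg$sim)
    utils::write.table(
      data.frame(feature = rownames(simc$cm$counts), simc$cm$counts,
                 check.names = FALSE),
      file.path(cfg$out_dir, "counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res <- nb_wald_de(simc$cm, cfg$sim$conditions[1],
                      cfg$sim$conditions[2], cfg$lfc_min, cfg$fdr_max)
    write_de_results(res, file.path(cfg$out_dir, "de_results.tsv"))
    list(res = res, beta = simc$beta)
  })

  cons <- .stage("conserve", manifest, {
    orth <- simulate_orthologs(sim, cfg$sim)
    sm <- sim$truth$smorfs
    eligible <- which(nchar(sm$aa_seq) >= 6L)  # search needs >= 6 aa
    use <- eligible[seq_len(min(length(eligible),
                                cfg$conservation_subset))]
    pars <- alignment_params()
    tg <- lapply(orth$genomes, translated_genome)
    tier_rows <- list()
    for (i in use) {
      hit_sp <- character(0)
      for (sp in names(orth$genomes)) {
        h <- conservation_search(sm$aa_seq[i], tg[[sp]], pars,
                                 cfg$e_thresh, max_hits_per_frame = 1L)
        if (nrow(h)) hit_sp <- c(hit_sp, sp)
      }
      tier_rows[[length(tier_rows) + 1L]] <- data.frame(
        orf_id = sm$orf_id[i],
        tier = assign_tier(hit_sp, cfg$sim$panel)$tier,
        planted_tier = unname(orth$tiers[sm$orf_id[i]]),
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, tier_rows)
    utils::write.table(d, file.path(cfg$out_dir, "tiers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })

  report <- .build_report(cfg, sim, disc, pm, ctx, dres, cons)
  write_json_stable(report, file.path(cfg$out_dir, "report.json"))
  manifest$stages <- list(
    candidates = length(disc$candidates), novel = length(disc$novel),
    called_any = length(called_ids), rescued_cells = sum(pm$present),
    contexts = nrow(ctx), de_features = nrow(dres$res),
    conservation_smorfs = nrow(cons))
  invisible(report)
}

.config_hash <- function(cfg) {
  # hash the scientific configuration only (not the output path)
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), c("offsets", "out_dir"))],
                        auto_unbox = TRUE, force = TRUE)
  # tiny stable string hash (djb2); avoids a digest dependency
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.build_report <- function(cfg, sim, disc, pm, ctx, dres, cons) {
  truth <- sim$truth
  planted <- truth$smorfs$orf_id
  called_ids <- sort(unique(unlist(disc$calls)))
  # per-(smORF, sample) calling vs rescue recovery over planted pairs
  pairs_total <- sum(truth$translated)
  call_hits <- sum(vapply(colnames(truth$translated), function(s)
    sum(truth$smorfs$orf_id[truth$translated[, s]] %in% disc$calls[[s]]),
    0))
  rescue_hits <- 0
  common <- intersect(planted, rownames(pm$present))
  if (length(common))
    rescue_hits <- sum(pm$present[common, , drop = FALSE] &
                         truth$translated[common, , drop = FALSE])
  # calling specificity over unplanted candidates
  unplanted_called <- setdiff(called_ids, planted)
  n_unplanted <- length(disc$novel) -
    sum(vapply(disc$novel, `[[`, "", "orf_id") %in% planted)
  # context accuracy on planted, called smORFs
  ctx_truth <- stats::setNames(truth$smorfs$context, truth$smorfs$orf_id)
  ctx_eval <- ctx[ctx$orf_id %in% planted, , drop = FALSE]
  ctx_acc <- if (nrow(ctx_eval))
    mean(ctx_eval$context == ctx_truth[ctx_eval$orf_id]) else NA_real_
  # DE recovery
  res <- dres$res; beta <- dres$beta[res$feature_id]
  de_sens <- if (any(beta != 0))
    mean(res$significant[beta != 0]) else NA_real_
  de_fdr <- if (any(res$significant))
    mean(beta[res$significant] == 0) else 0
  # tiers
  tier_acc <- if (nrow(cons)) mean(cons$tier == cons$planted_tier)
              else NA_real_
  list(
    thresholds = list(score = cfg$score_threshold,
                      min_psites = cfg$min_psites,
                      rescue = cfg$rescue_threshold,
                      lfc_min = cfg$lfc_min, fdr_max = cfg$fdr_max,
                      e_thresh = cfg$e_thresh),
    funnel = list(
      candidates = length(disc$candidates),
      novel = length(disc$novel),
      called_any_sample = length(called_ids),
      rescued_present_cells = sum(pm$present),
      per_context = as.list(table(ctx$context)),
      de_significant = sum(res$significant),
      per_tier = as.list(table(cons$tier))),
    recovery = list(
      call_sensitivity_pairs = call_hits / pairs_total,
      rescue_sensitivity_pairs = rescue_hits / pairs_total,
      call_false_positives = length(unplanted_called),
      n_unplanted_candidates = n_unplanted,
      context_accuracy = ctx_acc,
      de_sensitivity = de_sens, de_observed_fdr = de_fdr,
      tier_accuracy = tier_acc),
    venn = overlap_sets(pm)[c("n_present", "shared_fraction")])
}
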