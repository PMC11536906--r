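# Ground-truth generators: determinism, closure with the pipeline
# stages, and the statistical laws they claim to follow.

test_that("generators are deterministic per seed", {
  cfg <- small_sim_config(101)
  a <- simulate_genome_annotation(cfg)
  b <- simulate_genome_annotation(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_footprints(a, cfg), simulate_footprints(b, cfg))
  expect_identical(simulate_counts(a, cfg)$cm$counts,
                   simulate_counts(b, cfg)$cm$counts)
  oa <- simulate_orthologs(a, cfg); ob <- simulate_orthologs(b, cfg)
  expect_identical(oa$genomes, ob$genomes)
  expect_identical(oa$tiers, ob$tiers)
  # a different seed gives different data
  c2 <- simulate_genome_annotation(small_sim_config(102))
  expect_false(identical(a$genome, c2$genome))
})

test_that("planted smORFs are recovered by enumeration and classification", {
  cfg <- simulation_config(103, n_chrom = 2L, chrom_len = 250000L,
                           n_transcripts = 60L, n_smorfs = 40L,
                           context_quotas = c(uORF = 0.5, ncRNA = 0.25,
                                              dORF = 0.15,
                                              intergenic = 0.1))
  sim <- simulate_genome_annotation(cfg)
  expect_equal(nrow(sim$truth$smorfs), 40L)
  expect_setequal(unique(sim$truth$smorfs$context),
                  c("uORF", "ncRNA", "dORF", "intergenic"))
  cands <- candidate_orfs(sim$genome, sim$ann_asm)
  ids <- vapply(cands, `[[`, "", "orf_id")
  expect_true(all(sim$truth$smorfs$orf_id %in% ids))
  # the planted peptide is reproduced exactly
  byid <- stats::setNames(cands, ids)
  for (i in seq_len(nrow(sim$truth$smorfs))) {
    sm <- sim$truth$smorfs[i, ]
    expect_equal(byid[[sm$orf_id]]$aa_seq, sm$aa_seq)
    expect_equal(classify_context(byid[[sm$orf_id]], sim$ann_ref)$label,
                 sm$context)
  }
  # novel transcripts are absent from the reference annotation
  expect_gt(length(sim$ann_asm$transcripts),
            length(sim$ann_ref$transcripts))
})

test_that("generation errors name the violated constraint", {
  cfg <- simulation_config(104, n_transcripts = 4L, n_smorfs = 40L,
                           context_quotas = c(uORF = 1, ncRNA = 0,
                                              dORF = 0, intergenic = 0))
  expect_error(simulate_genome_annotation(cfg), "cannot fit")
  cfg2 <- small_sim_config(105, utr5_len = c(15L, 20L),
                           context_quotas = c(uORF = 1, ncRNA = 0,
                                              dORF = 0, intergenic = 0))
  expect_error(simulate_genome_annotation(cfg2), "aa_min|cannot fit")
})

test_that("footprints follow the planted periodicity and depth laws", {
  # p = 1, uniform codons, depth 300: f = 1 and pme close to 1
  cfg <- simulation_config(106, n_chrom = 1L, chrom_len = 60000L,
                           n_transcripts = 6L, n_smorfs = 3L,
                           samples = "S1", mean_depth = 300,
                           biotype_mix = c(protein_coding = 0.3,
                                           lncRNA = 0.7),
                           p_clean = 1, clean_extra_prob = 1,
                           background_per_nt = 0,
                           # pme ~ 1 - (k-1)/(2n log k): at depth 300 the
                           # 0.97 floor needs bounded ORF length
                           aa_max = 50L,
                           context_quotas = c(uORF = 0, ncRNA = 1,
                                              dORF = 0, intergenic = 0))
  sim <- simulate_genome_annotation(cfg)
  reads <- simulate_footprints(sim, cfg)
  tracks <- assign_psites(reads, sim$ann_asm)
  for (i in seq_len(nrow(sim$truth$smorfs))) {
    sm <- sim$truth$smorfs[i, ]
    sc <- score_translation(
      fake_orf(sm$orf_id, sm$transcript_id, sm$tx_start, sm$tx_end),
      tracks$S1)
    expect_equal(sc$f, 1)
    expect_gte(sc$pme, 0.97)
  }
  # p = 1/3: f within 3 Monte-Carlo standard errors of 1/3
  cfg2 <- simulation_config(107, n_chrom = 1L, chrom_len = 60000L,
                            n_transcripts = 6L, n_smorfs = 2L,
                            samples = "S1", mean_depth = 3000,
                            biotype_mix = c(protein_coding = 0.3,
                                            lncRNA = 0.7),
                            p_clean = 1 / 3, clean_extra_prob = 1,
                            background_per_nt = 0,
                            context_quotas = c(uORF = 0, ncRNA = 1,
                                               dORF = 0, intergenic = 0))
  sim2 <- simulate_genome_annotation(cfg2)
  tracks2 <- assign_psites(simulate_footprints(sim2, cfg2), sim2$ann_asm)
  sm <- sim2$truth$smorfs[1, ]
  sc2 <- score_translation(
    fake_orf(sm$orf_id, sm$transcript_id, sm$tx_start, sm$tx_end),
    tracks2$S1)
  mc_se <- sqrt((1 / 3) * (2 / 3) / sc2$n_psites)
  expect_lt(abs(sc2$f - 1 / 3), 3 * mc_se)
  # depth 0 and no background: empty read set
  cfg3 <- simulation_config(108, n_chrom = 1L, chrom_len = 60000L,
                            n_transcripts = 6L, n_smorfs = 2L,
                            samples = "S1", mean_depth = 0,
                            biotype_mix = c(protein_coding = 0.3,
                                            lncRNA = 0.7),
                            background_per_nt = 0,
                            context_quotas = c(uORF = 0, ncRNA = 1,
                                               dORF = 0, intergenic = 0))
  sim3 <- simulate_genome_annotation(cfg3)
  expect_equal(nrow(simulate_footprints(sim3, cfg3)), 0L)
})

test_that("counts follow the planted NB law and size factors", {
  # var ~ mu + alpha mu^2 across replicates
  cfg <- small_sim_config(109, n_replicates = 100L, de_fraction = 0,
                          dispersion = 0.05, n_extra_genes = 40L)
  sim <- simulate_genome_annotation(cfg)
  simc <- simulate_counts(sim, cfg)
  ctrl <- simc$cm$counts[, simc$cm$design == "control"]
  mu_hat <- rowMeans(ctrl)
  v_hat <- apply(ctrl, 1, stats::var)
  hi <- mu_hat > 200  # high-depth features: variance dominated by alpha
  ratio <- v_hat[hi] / (mu_hat[hi] + 0.05 * mu_hat[hi]^2)
  expect_lt(abs(mean(ratio) - 1), 0.15)
  # planted size factors are recovered within 5% (relative)
  cfg2 <- small_sim_config(110, n_replicates = 2L, de_fraction = 0,
                           planted_size_factors = c(1, 1, 2, 2),
                           n_extra_genes = 400L)
  sim2 <- simulate_genome_annotation(cfg2)
  simc2 <- simulate_counts(sim2, cfg2)
  sf <- size_factors(simc2$cm)
  rel <- sf / sf[1]
  expect_equal(unname(rel), c(1, 1, 2, 2), tolerance = 0.05)
})

test_that("null counts give calibrated type-I error through nb_wald_de", {
  cfg <- small_sim_config(111, de_fraction = 0, n_extra_genes = 900L,
                          dispersion = 0.05)
  sim <- simulate_genome_annotation(cfg)
  simc <- simulate_counts(sim, cfg)
  res <- nb_wald_de(simc$cm, "control", "treatment")
  n <- sum(!is.na(res$p_value))
  typeI <- mean(res$p_value < 0.05, na.rm = TRUE)
  env <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_lt(typeI, 0.05 + env)
  expect_gt(typeI, 0.05 - env)
})

test_that("ortholog genomes realize the planted tiers", {
  cfg <- simulation_config(112, n_chrom = 1L, chrom_len = 120000L,
                           n_transcripts = 16L, n_smorfs = 8L,
                           ortholog_background = 15000L,
                           biotype_mix = c(protein_coding = 0.3,
                                           lncRNA = 0.7),
                           context_quotas = c(uORF = 0, ncRNA = 1,
                                              dORF = 0, intergenic = 0))
  sim <- simulate_genome_annotation(cfg)
  orth <- simulate_orthologs(sim, cfg)
  # embedding pattern per tier
  for (i in seq_len(nrow(sim$truth$smorfs))) {
    id <- sim$truth$smorfs$orf_id[i]
    tier <- unname(orth$tiers[id])
    if (tier == "human_specific") next
    sp_expected <- smorfreg:::.tier_species(tier, cfg$panel)
    expect_true("chimp" %in% sp_expected)
    if (tier == "broad_mammal")
      expect_false(any(c("mouse", "rat") %in% sp_expected))
  }
  # closure at zero divergence: search + tiering returns the planted tier
  cfg0 <- simulation_config(112, n_chrom = 1L, chrom_len = 120000L,
                            n_transcripts = 16L, n_smorfs = 8L,
                            ortholog_background = 15000L,
                            biotype_mix = c(protein_coding = 0.3,
                                            lncRNA = 0.7),
                            divergence = 0,
                            context_quotas = c(uORF = 0, ncRNA = 1,
                                               dORF = 0, intergenic = 0))
  sim0 <- simulate_genome_annotation(cfg0)
  orth0 <- simulate_orthologs(sim0, cfg0)
  tg <- lapply(orth0$genomes, translated_genome)
  use <- which(nchar(sim0$truth$smorfs$aa_seq) >= 6)[1:4]
  for (i in use) {
    hit_sp <- names(tg)[vapply(names(tg), function(sp)
      nrow(conservation_search(sim0$truth$smorfs$aa_seq[i],
                               tg[[sp]])) > 0, TRUE)]
    expect_equal(assign_tier(hit_sp)$tier,
                 unname(orth0$tiers[sim0$truth$smorfs$orf_id[i]]))
  }
})
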