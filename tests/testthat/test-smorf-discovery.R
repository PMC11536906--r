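# ORF enumeration, novelty filtering and the translation score.

test_that("enumerate_candidate_orfs handles the worked examples", {
  one <- enumerate_candidate_orfs("ATGAAATAG", min_codons = 2)
  expect_length(one, 1L)
  expect_equal(one[[1]]$aa_seq, "MK")
  expect_equal(one[[1]]$length_codons, 3L)
  expect_equal(one[[1]]$tx_start, 0L)
  expect_equal(one[[1]]$tx_end, 9L)

  expect_length(enumerate_candidate_orfs("CCCCCC", min_codons = 2), 0L)

  two <- enumerate_candidate_orfs("AAATGGCCTGAATGTAA", min_codons = 2)
  expect_length(two, 2L)
  expect_setequal(vapply(two, `[[`, "", "aa_seq"), c("MA", "M"))
  expect_setequal(vapply(two, `[[`, 0L, "tx_start"), c(2L, 11L))

  expect_error(enumerate_candidate_orfs("ATGQQQ"), "A,C,G,T,N")
})

test_that("N-containing codons translate to X and exclude the peptide", {
  # ATG ANA TAA: middle codon ambiguous -> peptide contains X -> excluded
  expect_length(enumerate_candidate_orfs("ATGANATAA", min_codons = 2), 0L)
  # N that still resolves (CTN -> L) is kept
  kept <- enumerate_candidate_orfs("ATGCTNTAA", min_codons = 2)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$aa_seq, "ML")
})

test_that("all_starts mode adds internal-ATG variants", {
  # ATG AAA ATG TAA: default reports only the 5'-most start
  d <- enumerate_candidate_orfs("ATGAAAATGTAA", min_codons = 2)
  expect_length(d, 1L)
  a <- enumerate_candidate_orfs("ATGAAAATGTAA", min_codons = 2,
                                all_starts = TRUE)
  expect_length(a, 2L)
  expect_setequal(vapply(a, `[[`, "", "aa_seq"), c("MKM", "M"))
})

test_that("enumeration equals the brute-force (frame, ATG, stop) oracle", {
  set.seed(13)
  for (rep in 1:60) {
    seqlen <- sample(60:600, 1)
    s <- random_dna(seqlen)
    got <- enumerate_candidate_orfs(s, min_codons = 2, max_codons = 151)
    want <- brute_force_orfs(s, 2, 151)
    key <- function(l) vapply(l, function(o)
      paste(o$frame, o$tx_start, o$tx_end, o$aa_seq), "")
    expect_setequal(key(got), key(want))
  }
})

test_that("novelty_filter applies its precedence rules", {
  genome <- NULL  # not needed; blocks supplied directly
  cds_tx <- transcript_model(
    "coding", "gc", "chr1", "+",
    data.frame(start = 0, end = 1000),
    biotype = "protein_coding",
    cds = data.frame(start = 200, end = 800))
  lnc_tx <- transcript_model("lnc", "gl", "chr1", "+",
                             data.frame(start = 2000, end = 3000),
                             biotype = "lncRNA")
  ann <- annotation_set(list(cds_tx, lnc_tx))
  mk_cand <- function(start, end, aa, strand = "+") {
    list(orf_id = "c", chrom = "chr1", strand = strand,
         blocks = data.frame(start = start, end = end),
         aa_seq = aa, length_codons = nchar(aa) + 1L)
  }
  # inside the lncRNA exon, no CDS overlap, no protein match -> kept
  kept <- novelty_filter(mk_cand(2100, 2160, random_peptide(19)), ann)
  expect_true(kept$keep)
  expect_equal(kept$reason, "kept")
  # same-strand CDS overlap by >= 1 nt
  expect_equal(novelty_filter(mk_cand(780, 840, random_peptide(19)),
                              ann)$reason, "cds_overlap")
  # opposite strand does not trigger CDS overlap
  expect_equal(novelty_filter(mk_cand(780, 840, random_peptide(19),
                                      strand = "-"), ann)$reason, "kept")
  # a 30-aa peptide equal to a known protein's subsequence: E-value from
  # the closed form with the exact-match raw score
  set.seed(5)
  prot <- random_peptide(200)
  sub30 <- substr(prot, 50, 79)
  s_exact <- sum(diag(blosum62)[strsplit(sub30, "")[[1]]])
  e_exact <- evalue_from_score(s_exact, 30, 200)
  expect_lt(e_exact, 1e-3)  # confirms the example premise
  v <- novelty_filter(mk_cand(2100, 2190, sub30), ann,
                      known_proteins = prot, e_thresh = 1e-3)
  expect_equal(v$reason, "known_protein_match")
  # length bounds come after the overlap/match checks
  expect_equal(novelty_filter(mk_cand(2100, 2160, random_peptide(200)),
                              ann, max_codons = 151)$reason, "too_long")
  expect_equal(novelty_filter(mk_cand(2100, 2109, "MK"), ann,
                              min_codons = 6)$reason, "too_short")
})

test_that("batch novelty filter agrees with the per-candidate filter", {
  set.seed(17)
  cds_tx <- transcript_model(
    "coding", "gc", "chr1", "+", data.frame(start = 0, end = 1000),
    biotype = "protein_coding", cds = data.frame(start = 200, end = 800))
  ann <- annotation_set(list(cds_tx))
  prots <- c(random_peptide(120), random_peptide(150))
  cands <- lapply(1:40, function(i) {
    start <- sample(0:3000, 1)
    aa <- if (i <= 5) substr(prots[1], 10, 45) else random_peptide(25)
    list(orf_id = paste0("c", i), chrom = "chr1",
         strand = sample(c("+", "-"), 1),
         blocks = data.frame(start = start, end = start + 78),
         aa_seq = aa, length_codons = nchar(aa) + 1L)
  })
  single <- vapply(cands, function(cd)
    novelty_filter(cd, ann, prots)$reason, "")
  batch <- novelty_filter_all(cands, ann, prots)
  expect_equal(batch, single)
})

# -- translation score -------------------------------------------------------

# ORF of 4 codons (3 coding + stop) on a 12 nt span starting at tx pos 0
score_fixture <- function(v) {
  orf <- fake_orf("o", "t1", 0L, 12L)
  track <- fake_track(list(t1 = as.integer(v)))
  score_translation(orf, track, threshold = 0.7, min_psites = 1L)
}

test_that("score_translation matches the hand-computed vectors", {
  # perfect periodic uniform: in-frame [4,4,4], nothing off-frame
  v <- rep(0L, 12); v[c(1, 4, 7)] <- 4L
  s <- score_fixture(v)
  expect_equal(s$f, 1); expect_equal(s$pme, 1); expect_equal(s$score, 1)

  # counts spread equally over all 3 frame positions of every codon
  s2 <- score_fixture(rep(2L, 12))
  expect_equal(s2$f, 1 / 3, tolerance = 1e-12)
  expect_false(score_translation(fake_orf("o", "t1", 0L, 12L),
                                 fake_track(list(t1 = rep(2L, 12))),
                                 threshold = 0.7,
                                 min_psites = 1L)$passes)

  # in-frame codons [3,3,6], off-frame total 3
  v3 <- rep(0L, 12); v3[c(1, 4, 7)] <- c(3L, 3L, 6L); v3[2] <- 3L
  s3 <- score_fixture(v3)
  expect_equal(s3$f, 0.8, tolerance = 1e-12)
  pme_expect <- -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)) / log(3)
  expect_equal(s3$pme, pme_expect, tolerance = 1e-12)
  expect_equal(s3$score, 0.8 * pme_expect, tolerance = 1e-12)
})

test_that("score edge cases and invariances hold", {
  orf <- fake_orf("o", "t1", 0L, 12L)
  # no P-sites: score 0, not an error
  s0 <- score_translation(orf, fake_track(list(t1 = rep(0L, 12))))
  expect_equal(s0$score, 0); expect_false(s0$passes)
  # zero-length ORF is an error
  expect_error(score_translation(fake_orf("o", "t1", 5L, 5L),
                                 fake_track(list(t1 = rep(1L, 12)))),
               "zero-length")
  # single coding codon: pme defined as 1
  v <- rep(0L, 6); v[1] <- 7L
  s1 <- score_translation(fake_orf("o", "t1", 0L, 6L),
                          fake_track(list(t1 = v)), min_psites = 1L)
  expect_equal(s1$pme, 1)

  # scale invariance and range, over random count vectors
  set.seed(23)
  for (rep in 1:40) {
    v <- as.integer(rpois(30, 3))
    orf30 <- fake_orf("o", "t1", 0L, 30L)
    a <- score_translation(orf30, fake_track(list(t1 = v)))
    b <- score_translation(orf30, fake_track(list(t1 = v * 7L)))
    expect_equal(a$f, b$f); expect_equal(a$pme, b$pme)
    expect_gte(a$score, 0); expect_lte(a$score, 1)
    expect_gte(a$pme, 0); expect_lte(a$pme, 1)
  }
})

test_that("expected in-frame fraction converges to the planted periodicity", {
  set.seed(31)
  p <- 0.8; depth <- 10000
  n_codons <- 50
  v <- rep(0L, 3 * (n_codons + 1))
  codon <- sample(n_codons, depth, replace = TRUE) - 1L
  off <- ifelse(runif(depth) < p, 0L, sample(1:2, depth, replace = TRUE))
  pos <- 3L * codon + off
  v[seq_along(v)] <- tabulate(pos + 1L, nbins = length(v))
  s <- score_translation(fake_orf("o", "t1", 0L, length(v)),
                         fake_track(list(t1 = v)))
  mc_se <- sqrt(p * (1 - p) / depth)
  expect_lt(abs(s$f - p), 3 * mc_se)
})

test_that("call_smorfs is per-sample, deterministic, warns on empty track", {
  v_pass <- rep(0L, 12); v_pass[c(1, 4, 7)] <- 5L   # score 1, n = 15
  v_fail <- rep(1L, 12)
  orf <- fake_orf("orf1", "t1", 0L, 12L)
  tracks <- list(A = fake_track(list(t1 = v_pass), "A"),
                 B = fake_track(list(t1 = v_fail), "B"))
  calls <- call_smorfs(list(orf), tracks)
  expect_equal(calls$A, "orf1")
  expect_length(calls$B, 0L)
  # identical tracks give identical call sets
  tracks2 <- list(A = tracks$A, B = fake_track(list(t1 = v_pass), "B"))
  calls2 <- call_smorfs(list(orf), tracks2)
  expect_equal(unname(calls2$A), unname(calls2$B))
  empty <- list(E = fake_track(list(t1 = rep(0L, 12)), "E"))
  expect_warning(call_smorfs(list(orf), empty), "empty track")
})
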