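test_that("single-sequence profile reproduces the add-one formula", {
  h <- build_profile(c("MK"), "toy")
  expect_equal(h$n_match, 2L)
  expect_equal(unname(h$match_emissions[1, "M"]), 2 / 21)
  expect_equal(unname(h$match_emissions[2, "K"]), 2 / 21)
  expect_equal(unname(rowSums(h$match_emissions)), c(1, 1))
})

test_that("majority-gap columns are excluded from match states", {
  msa <- c("MKV-", "M-VA", "MKV-", "MKV-")  # col4: 75% gaps
  h <- build_profile(msa, "gapfam")
  expect_equal(h$n_match, 3L)
})

test_that("three-sequence toy MSA yields the hand-computed parameter table", {
  h <- build_profile(toy_msa3, "toy3")  # c("MKV", "M-V", "MRV")
  expect_equal(h$n_match, 3L)
  # emissions: col1 MMM, col2 {K, R} + one gap, col3 VVV
  expect_equal(unname(h$match_emissions[1, "M"]), 4 / 23)
  expect_equal(unname(h$match_emissions[1, "A"]), 1 / 23)
  expect_equal(unname(h$match_emissions[2, "K"]), 2 / 22)
  expect_equal(unname(h$match_emissions[2, "R"]), 2 / 22)
  expect_equal(unname(h$match_emissions[2, "M"]), 1 / 22)
  expect_equal(unname(h$match_emissions[3, "V"]), 4 / 23)
  # transitions: paths M1M2M3 / M1D2M3 / M1M2M3
  tr <- h$transitions
  expect_equal(tr$mm[1], 4 / 6)   # begin -> M1 three times, add-one over 3
  expect_equal(tr$mi[1], 1 / 6)
  expect_equal(tr$md[1], 1 / 6)
  expect_equal(tr$mm[2], 3 / 6)   # M1: 2x to M2, 1x to D2
  expect_equal(tr$md[2], 2 / 6)
  expect_equal(tr$mi[2], 1 / 6)
  expect_equal(tr$mm[3], 3 / 5)   # M2: 2x to M3
  expect_equal(tr$mm[4], 4 / 5)   # M3 -> End three times, add-one over 2
  expect_equal(tr$mi[4], 1 / 5)
  expect_equal(tr$dm[3], 2 / 3)   # D2 -> M3 once
  expect_equal(tr$dd[3], 1 / 3)
  expect_equal(tr$im[1], 1 / 2)   # no insert observations anywhere
  expect_equal(tr$dm[4], 1)       # terminal delete must exit
})

test_that("build errors: empty MSA, all-gap threshold, unequal lengths", {
  expect_error(build_profile(character(0), "x"), "empty")
  expect_error(build_profile(c("--", "--"), "x"), "no match columns")
  expect_error(build_profile(c("MK", "MKV"), "x"), "equal length")
})

test_that("build_profile is invariant to input sequence order", {
  set.seed(41)
  msa <- vapply(1:6, function(i) rand_protein(12), character(1))
  h1 <- build_profile(msa, "f")
  h2 <- build_profile(rev(msa), "f")
  expect_equal(h1$match_emissions, h2$match_emissions)
  expect_equal(h1$transitions, h2$transitions)
})

test_that("Forward and Viterbi equal exhaustive path enumeration", {
  set.seed(42)
  profiles <- list(
    build_profile(c("A", "C", "D"), "n1"),
    build_profile(c("MK", "M-", "AK"), "n2"),
    build_profile(toy_msa3, "n3")
  )
  alphabet <- c("A", "C", "D")
  seqs <- unlist(lapply(1:4, function(len) {
    apply(expand.grid(rep(list(alphabet), len)), 1, paste, collapse = "")
  }))
  for (h in profiles) {
    for (s in seqs) {
      fwd <- score_forward(h, s)
      vit <- score_viterbi(h, s)
      expect_lt(abs(fwd - oracle_hmm_score(h, s, "forward")), 1e-9)
      expect_lt(abs(vit$bit_score - oracle_hmm_score(h, s, "viterbi")), 1e-9)
      expect_gte(fwd, vit$bit_score - 1e-12)
    }
  }
})

test_that("Viterbi path re-scores to its own bit score; self-hit is all-match", {
  set.seed(43)
  for (rep in 1:10) {
    seqlen <- sample(5:15, 1)
    anchor <- rand_protein(seqlen)
    h <- build_profile(anchor, "self")
    v <- score_viterbi(h, anchor)
    expect_equal(score_path(h, anchor, v$path), v$bit_score)
    expect_equal(v$path, paste0("M", seq_len(seqlen)))
    other <- rand_protein(sample(4:20, 1))
    v2 <- score_viterbi(h, other)
    expect_equal(score_path(h, other, v2$path), v2$bit_score)
  }
})

test_that("Forward dominates Viterbi on random profile/sequence pairs", {
  set.seed(44)
  for (rep in 1:100) {
    msa <- vapply(1:3, function(i) rand_protein(8), character(1))
    h <- build_profile(msa, "r")
    s <- rand_protein(sample(3:20, 1))
    expect_gte(score_forward(h, s), score_viterbi(h, s)$bit_score - 1e-12)
  }
})

test_that("log-space scoring stays finite for very long proteins", {
  set.seed(45)
  h <- build_profile(vapply(1:4, function(i) rand_protein(50), character(1)), "f")
  long <- rand_protein(2000)
  expect_true(is.finite(score_forward(h, long)))
  expect_true(is.finite(score_viterbi(h, long)$bit_score))
})

test_that("non-standard residues are score-neutral", {
  h <- build_profile(c("MKVA", "MKVA", "MRVA"), "f")
  base <- score_forward(h, "MKVA")
  # X emits background everywhere: replacing a residue changes the score but
  # stays finite, and an all-X protein scores like pure transition cost
  expect_true(is.finite(score_forward(h, "MKXA")))
  expect_true(is.finite(score_forward(h, "XXXX")))
  expect_true(base > score_forward(h, "XXXX"))
})

test_that("library search separates planted families and labels the best hit", {
  fam_a <- synth_family_msa(61, "famA", n_seqs = 8, mutation_rate = 0.1,
                            length_aa = 120L, hepn_offsets = c(10L, 80L))
  fam_b <- synth_family_msa(62, "famB", n_seqs = 8, mutation_rate = 0.1,
                            length_aa = 120L, hepn_offsets = c(10L, 80L))
  lib <- list(build_profile(fam_a$msa, "famA"), build_profile(fam_b$msa, "famB"))
  member <- synth_family_member(63, fam_a$ancestor, 0.1, c(10L, 80L))
  hits <- search_library(tibble::tibble(protein_id = "m", protein = member), lib)
  expect_true("famA" %in% hits$family)
  best <- hits[hits$best, ]
  expect_equal(nrow(best), 1L)
  expect_equal(best$family, "famA")
  a_score <- hits$bit_score[hits$family == "famA"]
  b_score <- score_forward(lib[[2]], member)
  expect_gt(a_score, b_score)

  shuf <- shuffle_protein(member, 64)
  hits_s <- search_library(tibble::tibble(protein_id = "s", protein = shuf), lib)
  expect_equal(nrow(hits_s), 0L)

  expect_equal(nrow(search_library(tibble::tibble(protein_id = character(),
                                                  protein = character()), lib)), 0L)
  expect_error(search_library(tibble::tibble(protein_id = "m", protein = member),
                              list()), "empty")
})

test_that("planted homologs always outscore shuffled decoys (separation)", {
  set.seed(65)
  fams <- lapply(1:3, function(i) {
    synth_family_msa(650 + i, paste0("f", i), n_seqs = 8, mutation_rate = 0.1,
                     length_aa = 150L, hepn_offsets = c(12L, 100L))
  })
  for (fam in fams) {
    h <- build_profile(fam$msa, fam$family)
    homs <- vapply(1:3, function(k) {
      synth_family_member(700 + k, fam$ancestor, 0.1, fam$hepn_offsets)
    }, character(1))
    hom_scores <- vapply(homs, function(p) score_forward(h, p), numeric(1))
    decoys <- vapply(1:30, function(k) shuffle_protein(homs[1], 800 + k),
                     character(1))
    dec_scores <- vapply(decoys, function(p) score_forward(h, p), numeric(1))
    expect_gt(min(hom_scores), max(dec_scores))
  }
})

test_that("adaptation-gene flags respond to planted Cas1-like genes", {
  cas1 <- synth_family_msa(66, "cas1f", n_seqs = 6, mutation_rate = 0.1,
                           length_aa = 150L, hepn_offsets = integer())
  cas2 <- synth_family_msa(67, "cas2f", n_seqs = 6, mutation_rate = 0.1,
                           length_aa = 90L, hepn_offsets = integer())
  p1 <- build_profile(cas1$msa, "cas1f")
  p2 <- build_profile(cas2$msa, "cas2f")
  orfs <- tibble::tibble(
    protein_id = "x",
    protein = synth_family_member(68, cas1$ancestor, 0.1)
  )
  flags <- detect_adaptation_genes(orfs, p1, p2, bit_threshold = 20)
  expect_true(flags$cas1_present)
  expect_false(flags$cas2_present)
  flags0 <- detect_adaptation_genes(orfs[0, ], p1, p2)
  expect_false(flags0$cas1_present)
  expect_false(flags0$cas2_present)
})

test_that("profile library serialisation round-trips scores exactly", {
  fam <- synth_family_msa(69, "rt", n_seqs = 5, mutation_rate = 0.1,
                          length_aa = 60L, hepn_offsets = c(5L, 40L))
  h <- build_profile(fam$msa, "rt")
  f <- withr::local_tempfile(fileext = ".txt")
  write_profile_library(list(h), f)
  back <- read_profile_library(f)[["rt"]]
  p <- synth_family_member(70, fam$ancestor, 0.2)
  expect_equal(score_forward(back, p), score_forward(h, p), tolerance = 1e-12)
  expect_equal(back$n_match, h$n_match)
})
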