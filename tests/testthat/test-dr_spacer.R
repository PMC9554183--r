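test_that("DR consensus handles identical, tied and mutated repeat sets", {
  five <- rep("ACGTACGTACGTACGTACGT", 5)
  p <- dr_consensus(five)
  expect_true(all(p$per_column_conservation == 1))
  expect_equal(p$consensus, chartr("T", "U", five[1]))
  expect_false(p$length_flagged)

  # 2/2 tie in one column resolves by base order A < C < G < T
  tied <- c("AAAA", "AAAA", "ACAA", "ACAA")
  pt <- dr_consensus(tied)
  expect_equal(substr(pt$consensus_dna, 2, 2), "A")
  expect_equal(pt$per_column_conservation[2], 0.5)

  expect_error(dr_consensus(character(0)), "no repeats")
})

test_that("consensus conservation equals direct column counts", {
  set.seed(91)
  base <- rand_dna(36)
  reps <- vapply(1:8, function(i) {
    chars <- strsplit(base, "", fixed = TRUE)[[1]]
    mut <- which(runif(36) < 0.1)
    for (m in mut) chars[m] <- sample(setdiff(BASES_T, chars[m]), 1)
    paste(chars, collapse = "")
  }, character(1))
  p <- dr_consensus(reps)
  mat <- do.call(rbind, strsplit(reps, ""))
  for (col in 1:36) {
    expect_equal(p$per_column_conservation[col],
                 max(table(mat[, col])) / 8)
  }
})

test_that("length-discordant repeats are end-padded and flagged", {
  p <- dr_consensus(c("ACGTACGTAC", "ACGTACGT"))
  expect_true(p$length_flagged)
  expect_equal(nchar(p$consensus), 10L)
})

test_that("Nussinov folding reproduces the hand cases", {
  f0 <- nussinov_fold("AAAA")
  expect_equal(f0$n_pairs, 0L)
  expect_equal(f0$structure, "....")

  f3 <- nussinov_fold("GGGAAAACCC")
  expect_equal(f3$n_pairs, 3L)
  expect_equal(f3$n_pairs, oracle_max_pairs("GGGAAAACCC"))

  # min_loop forbids the tight hairpin
  expect_equal(nussinov_fold("GCGC", min_loop = 3)$n_pairs, 0L)
  expect_error(nussinov_fold("ACGX"), "A,C,G,U")
})

test_that("folding equals brute-force enumeration for short sequences", {
  set.seed(92)
  for (rep in 1:80) {
    s <- rand_rna(sample(4:12, 1))
    f <- nussinov_fold(s)
    expect_equal(f$n_pairs, oracle_max_pairs(s), info = s)
    # emitted structure is a valid realisation: nested, paired bases legal
    if (f$n_pairs > 0) {
      prs <- f$pairs
      expect_true(all(prs$j - prs$i > 3))
      chars <- strsplit(chartr("T", "U", s), "")[[1]]
      expect_true(all(mapply(function(i, j) oracle_can_pair(chars[i], chars[j]),
                             prs$i, prs$j)))
      # no crossing pairs
      if (nrow(prs) > 1) {
        for (u in 1:(nrow(prs) - 1)) for (v in (u + 1):nrow(prs)) {
          a <- prs[u, ]; b <- prs[v, ]
          crossing <- (a$i < b$i & b$i < a$j & a$j < b$j) ||
            (b$i < a$i & a$i < b$j & b$j < a$j)
          expect_false(crossing)
        }
      }
    }
  }
})

test_that("GU-symmetric pairing gives the same count on reversed sequences", {
  set.seed(93)
  for (rep in 1:50) {
    s <- rand_rna(sample(6:12, 1))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(nussinov_fold(s)$n_pairs, nussinov_fold(rev_s)$n_pairs,
                 info = s)
  }
})

test_that("both DR orientations are folded and the denser one reported", {
  p <- dr_consensus(rep("GGGGACGTAAAACGTACGTCCCCAAGGGACCTTAAA", 4))
  both <- fold_dr_orientations(p)
  expect_true(both$heuristic)
  expect_true(both$orientation %in% c("forward", "reverse"))
  winner <- if (both$orientation == "forward") both$forward else both$reverse
  loser <- if (both$orientation == "forward") both$reverse else both$forward
  expect_gte(winner$n_pairs, loser$n_pairs)
})

test_that("spacer matching finds planted protospacers on both strands", {
  set.seed(94)
  spacers <- tibble::tibble(
    spacer_id = c("sp1", "sp2"),
    seq = c(rand_dna(30), rand_dna(28))
  )
  tdb <- synth_target_db(941, n_targets = 2, target_len = 5000,
                         planted_spacers = dplyr::mutate(spacers,
                                                         strand = c("+", "-")))
  hits <- match_spacers(spacers, tdb$targets, max_mismatches = 0)
  for (i in 1:2) {
    pl <- tdb$placements[i, ]
    hit <- hits[hits$spacer_id == pl$spacer_id & hits$strand == pl$strand, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, pl$start)
    expect_equal(hit$end, pl$end)
    expect_equal(hit$target_id, pl$target_id)
    expect_equal(hit$mismatches, 0L)
  }
})

test_that("spacer matching equals the sliding Hamming oracle", {
  set.seed(95)
  target <- rand_dna(2000)
  for (mm_max in c(0L, 3L)) {
    for (rep in 1:4) {
      sp <- rand_dna(16)
      got <- match_spacers(tibble::tibble(spacer_id = "s", seq = sp),
                           tibble::tibble(id = "t", seq = target),
                           max_mismatches = mm_max)
      want <- oracle_spacer_hits(sp, target, mm_max)
      want <- want[order(want$start, want$strand), ]
      got <- got[order(got$start, got$strand), ]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("short spacers are rejected; empty inputs return empty tables", {
  expect_error(match_spacers(tibble::tibble(spacer_id = "s", seq = "ACGTACGT"),
                             tibble::tibble(id = "t", seq = "ACGT")),
               "15")
  empty <- match_spacers(tibble::tibble(spacer_id = character(),
                                        seq = character()),
                         tibble::tibble(id = "t", seq = "ACGTACGTACGTACGTACGT"))
  expect_equal(nrow(empty), 0L)
})
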