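test_that("contig synthesis is a pure function of its seed", {
  spec <- locus_spec(501, 8000,
                     array = list(repeat_seq = with_seed_dna(502, 36),
                                  spacer_len = 30L, n_units = 4L,
                                  mutation_rate = 0.05, pos = 3000L))
  a <- synth_contig(spec)
  b <- synth_contig(spec)
  expect_identical(a$contig$seq, b$contig$seq)
  expect_identical(a$truth, b$truth)

  spec2 <- locus_spec(503, 8000, array = spec$array)
  expect_false(identical(synth_contig(spec2)$contig$seq, a$contig$seq))
})

test_that("planted ground truth is self-validating by re-extraction", {
  fx <- synth_array_fixture(504)
  tr <- fx$truth$array
  seq <- fx$contig$seq
  units <- tr$repeat_units[[1]]
  expect_equal(substring(seq, units$start + 1, units$end), units$seq)
  spac <- tr$spacers[[1]]
  expect_equal(substring(seq, spac$start + 1, spac$end), spac$seq)
  # column-majority consensus of the planted units equals the planted repeat
  mat <- do.call(rbind, strsplit(units$seq, ""))
  cons <- apply(mat, 2, function(col) names(which.max(table(factor(col,
    levels = BASES_T)))))
  expect_equal(paste(cons, collapse = ""), tr$repeat_consensus)
})

test_that("planted genes re-translate exactly from the emitted contig", {
  # compact-effector scale: 767 aa with the first HEPN motif at offset 20
  prot <- with_seed_protein(505, 767, hepn = c(20L, 640L))
  spec <- locus_spec(506, 6000,
                     genes = list(list(id = "g", protein = prot,
                                       strand = "+", pos = 2000L),
                                  list(id = "gm", protein = prot,
                                       strand = "-", pos = 500L)))
  expect_error(synth_contig(spec), "overlaps")  # cassettes collide

  spec <- locus_spec(506, 8000,
                     genes = list(list(id = "g", protein = prot,
                                       strand = "+", pos = 4000L),
                                  list(id = "gm", protein = prot,
                                       strand = "-", pos = 100L)))
  fx <- synth_contig(spec)
  for (i in 1:2) {
    g <- fx$truth$genes[i, ]
    expect_equal(g$length_aa, 767L)
    expect_equal(translate_interval(fx$contig$seq, g$start, g$end, g$strand),
                 prot)
  }
  chars <- strsplit(prot, "")[[1]]
  expect_equal(chars[21], "R")
  expect_equal(chars[26], "H")
})

test_that("family MSAs hold anchors invariant and match the identity closed form", {
  m <- 0.2
  fam <- synth_family_msa(507, "closed", n_seqs = 30, mutation_rate = m,
                          length_aa = 400L, hepn_offsets = c(30L, 300L))
  for (s in fam$msa$seq) {
    ch <- strsplit(s, "")[[1]]
    expect_equal(ch[31], "R")
    expect_equal(ch[36], "H")
    expect_equal(ch[301], "R")
    expect_equal(ch[306], "H")
  }
  # pairwise identity ~ (1-m)^2 + m^2/19 over random member pairs
  expected <- (1 - m)^2 + m^2 / 19
  set.seed(508)
  idents <- vapply(1:30, function(k) {
    ij <- sample(30, 2)
    a <- strsplit(fam$msa$seq[ij[1]], "")[[1]]
    b <- strsplit(fam$msa$seq[ij[2]], "")[[1]]
    mean(a == b)
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / 400)
  expect_lt(abs(mean(idents) - expected), 3 * se)
})

test_that("zero mutation rate reproduces the ancestor; gaps obey the threshold", {
  fam0 <- synth_family_msa(509, "clonal", n_seqs = 5, mutation_rate = 0,
                           length_aa = 60L, hepn_offsets = c(5L, 40L))
  expect_true(all(fam0$msa$seq == fam0$ancestor))

  famg <- synth_family_msa(510, "gappy", n_seqs = 12, mutation_rate = 0.1,
                           length_aa = 120L, hepn_offsets = c(10L, 80L),
                           gap_rate = 0.2)
  expect_true(any(grepl("-", famg$msa$seq, fixed = TRUE)))
  h <- build_profile(famg$msa, "gappy")
  expect_lt(h$n_match, 120L)  # majority-gap columns dropped
})

test_that("decoy proteins have their designed elimination property", {
  fam <- synth_family_msa(511, "base", n_seqs = 6, mutation_rate = 0.1,
                          length_aa = 500L, hepn_offsets = c(30L, 420L))
  short <- decoy_protein(512, "short", fam$ancestor, c(30L, 420L))
  expect_equal(nchar(short), 350L)

  single <- decoy_protein(513, "single_hepn", fam$ancestor, c(30L, 420L))
  hits <- scan_rx4h(single)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 30L)

  nohepn <- decoy_protein(514, "no_hepn")
  expect_equal(nrow(scan_rx4h(nohepn)), 0L)
  expect_equal(nchar(nohepn), 500L)

  shuf <- decoy_protein(515, "shuffled", fam$ancestor, c(30L, 420L))
  expect_equal(nchar(shuf), 500L)
})

test_that("target databases plant spacers verbatim at recorded coordinates", {
  set.seed(516)
  sp <- tibble::tibble(spacer_id = c("a", "b", "c"),
                       seq = vapply(c(30, 30, 28), rand_dna, character(1)),
                       strand = c("+", "+", "-"))
  t1 <- synth_target_db(517, n_targets = 2, target_len = 4000,
                        planted_spacers = sp)
  t2 <- synth_target_db(517, n_targets = 2, target_len = 4000,
                        planted_spacers = sp)
  expect_identical(t1$targets$seq, t2$targets$seq)
  for (i in seq_len(nrow(t1$placements))) {
    pl <- t1$placements[i, ]
    tgt <- t1$targets$seq[t1$targets$id == pl$target_id]
    segment <- substring(tgt, pl$start + 1, pl$end)
    planted <- sp$seq[sp$spacer_id == pl$spacer_id]
    if (pl$strand == "-") planted <- oracle_revcomp(planted)
    expect_equal(segment, planted)
  }
  # empty plant: database still deterministic, nothing to find exactly
  t0 <- synth_target_db(518, n_targets = 1, target_len = 3000)
  expect_equal(nrow(t0$placements), 0L)
  probe <- tibble::tibble(spacer_id = "q", seq = with_seed_dna(519, 30))
  expect_equal(nrow(match_spacers(probe, t0$targets, max_mismatches = 0)), 0L)
})

test_that("dinucleotide shuffles preserve composition and endpoints", {
  set.seed(520)
  for (rep in 1:5) {
    s <- rand_dna(500)
    sh <- dinucleotide_shuffle(s, 520 + rep)
    expect_equal(nchar(sh), nchar(s))
    di <- function(z) {
      ch <- strsplit(z, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1]))
    }
    expect_equal(di(sh), di(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 500, 500), substr(s, 500, 500))
  }
  expect_identical(dinucleotide_shuffle("ACGTACGT", 1),
                   dinucleotide_shuffle("ACGTACGT", 1))
})

test_that("the canonical metagenome is deterministic and internally consistent", {
  mg1 <- synth_metagenome(7)
  mg2 <- synth_metagenome(7)
  expect_identical(mg1$contigs$seq, mg2$contigs$seq)
  expect_identical(mg1$references, mg2$references)
  expect_equal(nrow(mg1$candidates), 3L)
  # planted candidate CDSs re-translate from their contigs
  for (i in seq_len(nrow(mg1$candidates))) {
    g <- mg1$candidates[i, ]
    ctg <- mg1$contigs$seq[mg1$contigs$id == g$contig_id]
    expect_equal(translate_interval(ctg, g$start, g$end, g$strand), g$protein)
  }
  # architecture fixtures cover both orientation classes
  archs <- cas13_architectures()
  expect_setequal(unique(archs$dr_side), c("5prime", "3prime"))
  expect_equal(sum(archs$ntd), 3L)  # a, c, d
})
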