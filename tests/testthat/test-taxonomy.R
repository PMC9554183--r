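test_that("global identity matches hand and brute-force alignment oracles", {
  expect_equal(global_identity("MKV", "MKV"), 1.0)
  o <- oracle_global_alignments("MKV", "MRV")
  expect_true(global_identity("MKV", "MRV") %in% o$identities)
  expect_equal(global_identity("MKV", "MRV"), 2 / 3)

  set.seed(81)
  for (rep in 1:15) {
    a <- rand_protein(sample(2:6, 1))
    b <- rand_protein(sample(2:6, 1))
    o <- oracle_global_alignments(a, b)
    expect_true(global_identity(a, b) %in% o$identities,
                info = paste(a, b))
  }
  expect_error(global_identity("", "MK"), "non-empty")
})

test_that("identity is exactly symmetric", {
  set.seed(82)
  for (rep in 1:50) {
    a <- rand_protein(sample(3:30, 1))
    b <- rand_protein(sample(3:30, 1))
    expect_identical(global_identity(a, b), global_identity(b, a))
  }
})

test_that("distance matrices satisfy their invariants and equivariance", {
  prot <- tibble::tibble(protein_id = c("x", "y"), protein = c("MKVAA", "MKVAA"))
  d <- build_distance_matrix(prot)
  expect_equal(d["x", "y"], 0)

  set.seed(83)
  trio <- tibble::tibble(protein_id = c("a", "b", "c"),
                         protein = vapply(1:3, function(i) rand_protein(20),
                                          character(1)))
  d3 <- build_distance_matrix(trio)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d3[i, j],
                 1 - global_identity(trio$protein[i], trio$protein[j]))
  }
  expect_equal(d3, t(d3))
  expect_true(all(diag(d3) == 0))
  perm <- trio[c(3, 1, 2), ]
  dperm <- build_distance_matrix(perm)
  expect_equal(dperm[rownames(d3), colnames(d3)], d3)

  expect_error(build_distance_matrix(trio[1, ]), "at least 2")
  dup <- trio; dup$protein_id <- c("a", "a", "c")
  expect_error(build_distance_matrix(dup), "duplicate")
})

test_that("UPGMA reproduces the hand-worked cases", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$root_height, 0.2)

  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$root_height, 0.3)
  expect_equal(t3$merges$left_label[1], "A")
  expect_equal(t3$merges$right_label[1], "B")
  expect_equal(t3$merges$height[1], 0.1)
})

test_that("UPGMA equals the naive re-implementation on random matrices", {
  set.seed(84)
  for (rep in 1:20) {
    n <- 6
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    vals <- runif(n * (n - 1) / 2, 0.05, 1)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    tree <- upgma(m)
    expect_equal(cophenetic_distances(tree), oracle_upgma_cophenetic(m),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with hclust average linkage (cross-check)", {
  set.seed(85)
  for (rep in 1:5) {
    n <- 7
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
    m <- m + t(m)
    tree <- upgma(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(cophenetic_distances(tree)[letters[1:n], letters[1:n]],
                 as.matrix(stats::cophenetic(hc))[letters[1:n], letters[1:n]],
                 tolerance = 1e-12)
  }
})

test_that("heights are monotone and ultrametric inputs are reproduced", {
  set.seed(86)
  for (rep in 1:10) {
    n <- 6
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
    m <- m + t(m)
    tree <- upgma(m)
    expect_true(all(diff(tree$merges$height) >= -1e-12))  # merge order
  }
  # constructed ultrametric matrix: nested merges at increasing distances
  um <- matrix(0.9, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  um["a", "b"] <- um["b", "a"] <- 0.1
  um["c", "d"] <- um["d", "c"] <- 0.2
  for (x in c("a", "b")) for (y in c("c", "d")) um[x, y] <- um[y, x] <- 0.5
  diag(um) <- 0
  tree <- upgma(um)
  expect_equal(cophenetic_distances(tree), um)
  # ultrametric: all leaves equidistant from root
  expect_equal(max(cophenetic_distances(tree)) / 2, tree$root_height)
})

test_that("Newick export parses and preserves the cophenetic structure", {
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d3)
  ph <- as_phylo(tree)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  cp <- ape::cophenetic.phylo(ph)
  expect_equal(cp["A", "B"], 0.2, tolerance = 1e-9)
  expect_equal(cp["A", "C"], 0.6, tolerance = 1e-9)
})

test_that("subtype assignment anchors references and numbers novel clades", {
  set.seed(87)
  fam <- synth_family_msa(871, "famX", n_seqs = 4, mutation_rate = 0.05,
                          length_aa = 80L, hepn_offsets = integer())
  near <- synth_family_member(872, fam$ancestor, 0.10)
  unrelated1 <- rand_protein(80)
  unrelated2 <- rand_protein(90)
  prot <- tibble::tibble(
    protein_id = c("cand_near", "cand_far1", "cand_far2",
                   sprintf("famX_ref%d", 1:2)),
    protein = c(near, unrelated1, unrelated2, fam$msa$seq[1:2])
  )
  refs <- stats::setNames(rep("famX", 2), sprintf("famX_ref%d", 1:2))
  tree <- upgma(build_distance_matrix(prot))
  asg <- assign_subtypes(tree, refs, cut_height = 0.35)
  expect_equal(asg$subtype[asg$protein_id == "cand_near"], "famX")
  expect_false(asg$novel[asg$protein_id == "cand_near"])
  far <- asg[asg$protein_id %in% c("cand_far1", "cand_far2"), ]
  expect_true(all(far$novel))
  expect_true(all(grepl("^novel_", far$subtype)))
  # novel numbering follows the smallest member id
  expect_equal(asg$subtype[asg$protein_id == "cand_far1"], "novel_1")

  # all identical to a reference: one cluster, that family
  same <- tibble::tibble(protein_id = c("p1", "p2", "famX_ref1"),
                         protein = rep(fam$msa$seq[1], 3))
  tr2 <- upgma(build_distance_matrix(same))
  asg2 <- assign_subtypes(tr2, c(famX_ref1 = "famX"))
  expect_true(all(asg2$subtype == "famX"))
})

test_that("subtype assignment is invariant to input order", {
  set.seed(88)
  prot <- tibble::tibble(
    protein_id = c("a1", "a2", "r1", "z9"),
    protein = c(rand_protein(40), rand_protein(40), rand_protein(40),
                rand_protein(40))
  )
  refs <- c(r1 = "famR")
  t1 <- upgma(build_distance_matrix(prot))
  t2 <- upgma(build_distance_matrix(prot[c(4, 2, 1, 3), ]))
  expect_equal(assign_subtypes(t1, refs), assign_subtypes(t2, refs))
})

test_that("length profiles aggregate per subtype and conserve totals", {
  asg <- tibble::tibble(protein_id = c("p1", "p2", "p3", "p4"),
                        subtype = c("s1", "s1", "s1", "s2"),
                        novel = FALSE, ambiguous = FALSE)
  prot <- tibble::tibble(protein_id = sprintf("p%d", 1:4),
                         length_aa = c(760L, 800L, 840L, 1100L))
  prof <- subtype_length_profile(asg, prot)
  expect_equal(prof$mean_aa[prof$subtype == "s1"], 800)
  expect_equal(sum(prof$n), nrow(asg))
  expect_equal(prof$min_aa[prof$subtype == "s1"], 760L)
  expect_equal(prof$max_aa[prof$subtype == "s1"], 840L)
})
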