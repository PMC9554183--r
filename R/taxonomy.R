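# Subtype classification: pairwise global-alignment identity, UPGMA
# dendrogram, reference-anchored labelling and novel-clade calling.

#' Global-alignment identity between two proteins
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap -1; identity is the number of identical aligned positions divided by
#' the alignment length. The pair is ordered canonically before aligning so
#' the result is exactly symmetric.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param match,mismatch,gap Alignment scores.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  check_string(a, "a")
  check_string(b, "b")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  letters_ab <- sort(unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]]))
  sm <- matrix(mismatch, length(letters_ab), length(letters_ab),
               dimnames = list(letters_ab, letters_ab))
  diag(sm) <- match
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = -gap
  )
  pc <- strsplit(as.character(Biostrings::alignedPattern(al)), "", fixed = TRUE)[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(al)), "", fixed = TRUE)[[1]]
  sum(pc == sc & pc != "-") / length(pc)
}

#' Pairwise identity distance matrix
#'
#' Distance is `1 - global identity` for every protein pair.
#'
#' @param proteins Tibble with columns `protein_id` (unique) and `protein`.
#' @return A symmetric numeric matrix with zero diagonal and the ids as
#'   dimnames.
#' @export
build_distance_matrix <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "protein") %in% names(proteins)))
  if (nrow(proteins) < 2L) abort("need at least 2 proteins")
  if (anyDuplicated(proteins$protein_id)) abort("duplicate protein ids")
  n <- nrow(proteins)
  d <- matrix(0, n, n, dimnames = list(proteins$protein_id, proteins$protein_id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- 1 - global_identity(proteins$protein[i], proteins$protein[j])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted arithmetic mean of its
#' parts. Ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member id), which makes the
#' tree deterministic. Node height is half the merge distance, so the tree
#' is ultrametric and cophenetic distances equal merge distances.
#'
#' @param dm Symmetric distance matrix with dimnames (as from
#'   [build_distance_matrix()]).
#' @return An object of class `cas13_upgma`: `ids`, a `merges` tibble (one
#'   row per internal node: `node`, `left`, `right`, `height`, `label`,
#'   `members`), and `root_height`.
#' @export
upgma <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 2L)
  ids <- rownames(dm)
  if (is.null(ids)) abort("distance matrix must carry ids as dimnames")
  if (any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  n <- length(ids)
  # active clusters: negative index = leaf, positive = internal node number
  act <- lapply(seq_len(n), function(i) {
    list(node = -i, label = ids[i], size = 1L, members = ids[i], height = 0)
  })
  d <- dm
  merges <- list()
  node_counter <- 0L
  while (length(act) > 1L) {
    m <- length(act)
    # closest pair, ties by lexicographically smallest (label_i, label_j)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        lab <- sort(c(act[[i]]$label, act[[j]]$label))
        if (is.null(best) || d[i, j] < best$d - 1e-15 ||
            (abs(d[i, j] - best$d) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d[i, j], lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    node_counter <- node_counter + 1L
    new_cl <- list(
      node = node_counter,
      label = min(act[[i]]$label, act[[j]]$label),
      size = act[[i]]$size + act[[j]]$size,
      members = sort(c(act[[i]]$members, act[[j]]$members)),
      height = best$d / 2
    )
    merges[[node_counter]] <- tibble(
      node = node_counter,
      left = act[[i]]$node, right = act[[j]]$node,
      left_label = act[[i]]$label, right_label = act[[j]]$label,
      height = best$d / 2,
      label = new_cl$label,
      members = list(new_cl$members)
    )
    # size-weighted mean distance to remaining clusters
    keep <- setdiff(seq_len(m), c(i, j))
    if (length(keep) > 0L) {
      new_d <- (act[[i]]$size * d[i, keep] + act[[j]]$size * d[j, keep]) /
        new_cl$size
      d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
                 c(new_d, 0))
    } else {
      d <- matrix(0, 1, 1)
    }
    act <- c(act[keep], list(new_cl))
  }
  structure(list(
    ids = ids,
    merges = bind_rows(merges),
    root_height = act[[1]]$height
  ), class = "cas13_upgma")
}

#' @export
print.cas13_upgma <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$ids), x$root_height))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of the
#' node at which they first co-cluster (i.e. the merge distance).
#'
#' @param tree A `cas13_upgma` object.
#' @return Symmetric matrix over the tree's leaf ids.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "cas13_upgma"))
  n <- length(tree$ids)
  cm <- matrix(0, n, n, dimnames = list(tree$ids, tree$ids))
  # children membership before each merge
  node_members <- list()
  for (k in seq_len(nrow(tree$merges))) {
    row <- tree$merges[k, ]
    left_m <- if (row$left < 0) tree$ids[-row$left] else node_members[[row$left]]
    right_m <- if (row$right < 0) tree$ids[-row$right] else node_members[[row$right]]
    cm[left_m, right_m] <- 2 * row$height
    cm[right_m, left_m] <- 2 * row$height
    node_members[[row$node]] <- c(left_m, right_m)
  }
  cm
}

upgma_newick_string <- function(tree) {
  stopifnot(inherits(tree, "cas13_upgma"))
  heights <- c(setNames(rep(0, length(tree$ids)), paste0("L", seq_along(tree$ids))),
               setNames(tree$merges$height, paste0("N", tree$merges$node)))
  node_str <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.10g", tree$ids[-node], parent_height)
    } else {
      row <- tree$merges[tree$merges$node == node, ]
      sprintf("(%s,%s):%.10g",
              node_str(row$left, row$height),
              node_str(row$right, row$height),
              parent_height - row$height)
    }
  }
  root <- tree$merges[nrow(tree$merges), ]
  sprintf("(%s,%s);",
          node_str(root$left, root$height),
          node_str(root$right, root$height))
}

#' Write a UPGMA tree as Newick
#'
#' Branch lengths are height differences (ultrametric; leaf depth equals the
#' root height).
#'
#' @param tree A `cas13_upgma` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(upgma_newick_string(tree), path)
  invisible(path)
}

#' Convert a UPGMA tree to an `ape::phylo`
#'
#' @param tree A `cas13_upgma` object.
#' @return A rooted `phylo` object with branch lengths.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = upgma_newick_string(tree))
}

cut_tree_clusters <- function(tree, cut_height) {
  # union-find over merges with height <= cut_height
  parent <- seq_along(tree$ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  leaf_idx <- setNames(seq_along(tree$ids), tree$ids)
  node_rep <- list()  # representative leaf index per internal node
  for (k in seq_len(nrow(tree$merges))) {
    row <- tree$merges[k, ]
    lrep <- if (row$left < 0) -row$left else node_rep[[row$left]]
    rrep <- if (row$right < 0) -row$right else node_rep[[row$right]]
    if (row$height <= cut_height) {
      parent[find(rrep)] <- find(lrep)
    }
    node_rep[[row$node]] <- lrep
  }
  roots <- vapply(seq_along(tree$ids), find, integer(1))
  split(tree$ids, roots)
}

#' Assign subtype labels by cutting the UPGMA tree
#'
#' The tree is cut at `cut_height`; a cluster containing references of
#' exactly one family inherits that family, a reference-free cluster becomes
#' `novel_k` (numbered by its lexicographically smallest member id), and a
#' cluster mixing reference families is flagged ambiguous.
#'
#' @param tree A `cas13_upgma` object.
#' @param references Named character vector `protein_id -> family` (or a
#'   tibble with `protein_id`, `family`); non-empty.
#' @param cut_height Height cut; the default 0.35 corresponds to 70%
#'   sequence divergence under the half-distance height convention.
#' @return A tibble `protein_id`, `subtype`, `novel`, `ambiguous`, sorted by
#'   `protein_id`.
#' @export
assign_subtypes <- function(tree, references, cut_height = 0.7 / 2) {
  stopifnot(inherits(tree, "cas13_upgma"))
  if (is.data.frame(references)) {
    references <- setNames(references$family, references$protein_id)
  }
  if (length(references) == 0L) abort("references must be non-empty")
  clusters <- cut_tree_clusters(tree, cut_height)
  novel_clusters <- clusters[vapply(clusters, function(ms) {
    !any(ms %in% names(references))
  }, logical(1))]
  novel_order <- order(vapply(novel_clusters, min, character(1)))
  novel_label <- setNames(paste0("novel_", seq_along(novel_order)),
                          vapply(novel_clusters[novel_order], min, character(1)))
  rows <- lapply(clusters, function(ms) {
    fams <- unique(unname(references[ms[ms %in% names(references)]]))
    if (length(fams) == 0L) {
      tibble(protein_id = ms, subtype = unname(novel_label[min(ms)]),
             novel = TRUE, ambiguous = FALSE)
    } else if (length(fams) == 1L) {
      tibble(protein_id = ms, subtype = fams, novel = FALSE, ambiguous = FALSE)
    } else {
      tibble(protein_id = ms, subtype = "ambiguous", novel = FALSE,
             ambiguous = TRUE)
    }
  })
  arrange(bind_rows(rows), .data$protein_id)
}

#' Per-subtype protein length profile
#'
#' @param assignments Tibble from [assign_subtypes()].
#' @param proteins Tibble with `protein_id` and `protein` (or `length_aa`).
#' @return A tibble `subtype`, `n`, `mean_aa`, `min_aa`, `max_aa`; empty
#'   subtypes are absent by construction.
#' @export
subtype_length_profile <- function(assignments, proteins) {
  stopifnot(is.data.frame(assignments), is.data.frame(proteins))
  if (!"length_aa" %in% names(proteins)) {
    proteins <- mutate(proteins, length_aa = nchar(.data$protein))
  }
  assignments |>
    dplyr::inner_join(select(proteins, "protein_id", "length_aa"),
                      by = "protein_id") |>
    group_by(.data$subtype) |>
    summarise(n = dplyr::n(),
              mean_aa = mean(.data$length_aa),
              min_aa = min(.data$length_aa),
              max_aa = max(.data$length_aa),
              .groups = "drop") |>
    arrange(.data$subtype)
}

#' @describeIn upgma Tidy the merge table of a UPGMA tree.
#' @param x A `cas13_upgma` object.
#' @param ... Unused.
#' @method tidy cas13_upgma
#' @export
tidy.cas13_upgma <- function(x, ...) {
  select(x$merges, "node", "left_label", "right_label", "height")
}

#' @describeIn upgma One-row summary of a UPGMA tree.
#' @method glance cas13_upgma
#' @export
glance.cas13_upgma <- function(x, ...) {
  tibble(n_leaves = length(x$ids),
         n_merges = nrow(x$merges),
         root_height = x$root_height)
}
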