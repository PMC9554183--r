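# Direct-repeat and spacer characterisation: DR consensus and conservation,
# secondary structure by Nussinov base-pair maximisation, and ungapped
# spacer-to-target (protospacer) matching.

#' Direct-repeat consensus and per-column conservation
#'
#' Column-majority consensus over the repeat units of an array (ties broken
#' deterministically by base order A < C < G < T), transcribed to RNA.
#' Length-discordant repeats are end-padded and flagged; pad positions count
#' against conservation.
#'
#' @param repeats Character vector of DNA repeat units (at least one).
#' @return A list of class `dr_profile`: `consensus` (RNA), `consensus_dna`,
#'   `per_column_conservation`, `n_repeats`, `length_flagged`.
#' @export
dr_consensus <- function(repeats) {
  if (length(repeats) == 0L) abort("no repeats")
  repeats <- toupper(repeats)
  lens <- nchar(repeats)
  flagged <- length(unique(lens)) > 1L
  width <- max(lens)
  padded <- vapply(repeats, function(r) {
    paste0(r, strrep("-", width - nchar(r)))
  }, character(1), USE.NAMES = FALSE)
  m <- seq_matrix(padded)
  cons <- character(width)
  conserv <- numeric(width)
  for (col in seq_len(width)) {
    counts <- tabulate(factor(m[, col], levels = DNA_BASES), nbins = 4L)
    cons[col] <- DNA_BASES[which.max(counts)]
    conserv[col] <- max(counts) / length(repeats)
  }
  consensus_dna <- paste(cons, collapse = "")
  structure(list(
    consensus = chartr("T", "U", consensus_dna),
    consensus_dna = consensus_dna,
    per_column_conservation = conserv,
    n_repeats = length(repeats),
    length_flagged = flagged
  ), class = "dr_profile")
}

#' @export
print.dr_profile <- function(x, ...) {
  cat(sprintf("DR profile over %d repeats%s\n  consensus: %s\n  mean conservation: %.3f\n",
              x$n_repeats,
              if (x$length_flagged) " (length-discordant, end-padded)" else "",
              x$consensus, mean(x$per_column_conservation)))
  invisible(x)
}

rna_can_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) {
    wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  } else {
    wc
  }
}

#' Nussinov base-pair maximisation
#'
#' Dynamic-programming maximisation of the number of nested base pairs
#' (Watson-Crick, plus G-U wobble when `allow_gu`), with a minimum hairpin
#' loop of `min_loop` unpaired bases (a pair `(i, j)` requires
#' `j - i > min_loop`). The traceback is deterministic: pairing `(i, j)` is
#' preferred, then leaving `i` unpaired, then leaving `j` unpaired, then the
#' bifurcation with the smallest split point.
#'
#' @param rna RNA string over `{A,C,G,U}` (a DNA string is transcribed).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @param allow_gu Allow G-U wobble pairs.
#' @return A list of class `fold_result`: `structure` (dot-bracket),
#'   `n_pairs`, `pairs` (tibble of 1-based `i < j`).
#' @export
nussinov_fold <- function(rna, min_loop = 3L, allow_gu = TRUE) {
  check_string(rna, "rna")
  rna <- chartr("T", "U", toupper(rna))
  if (grepl("[^ACGU]", rna)) abort("RNA sequence must be over {A,C,G,U}")
  s <- strsplit(rna, "", fixed = TRUE)[[1]]
  L <- length(s)
  empty <- function() {
    structure(list(structure = strrep(".", L), n_pairs = 0L,
                   pairs = tibble(i = integer(), j = integer())),
              class = "fold_result")
  }
  if (L <= min_loop) return(empty())
  N <- matrix(0L, L, L)
  for (span in (min_loop + 1L):(L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      best <- max(N[i + 1L, j], N[i, j - 1L])
      if (rna_can_pair(s[i], s[j], allow_gu)) {
        paired <- (if (j - 1L >= i + 1L) N[i + 1L, j - 1L] else 0L) + 1L
        best <- max(best, paired)
      }
      if (j - i >= 3L) {
        for (k in (i + 1L):(j - 2L)) {
          best <- max(best, N[i, k] + N[k + 1L, j])
        }
      }
      N[i, j] <- best
    }
  }
  pairs <- list()
  stack <- list(c(1L, L))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j || j - i <= min_loop) next
    target <- N[i, j]
    if (target == 0L) next
    if (rna_can_pair(s[i], s[j], allow_gu) &&
        target == (if (j - 1L >= i + 1L) N[i + 1L, j - 1L] else 0L) + 1L) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (target == N[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (target == N[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else if (j - i >= 3L) {
      for (k in (i + 1L):(j - 2L)) {
        if (target == N[i, k] + N[k + 1L, j]) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  if (length(pairs) == 0L) return(empty())
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  db <- rep(".", L)
  db[pm[, 1]] <- "("
  db[pm[, 2]] <- ")"
  structure(list(
    structure = paste(db, collapse = ""),
    n_pairs = nrow(pm),
    pairs = tibble(i = pm[, 1], j = pm[, 2])
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("%s\n%d base pairs\n", x$structure, x$n_pairs))
  invisible(x)
}

#' Fold a DR consensus in both orientations
#'
#' Folds the consensus and its reverse complement; the orientation with more
#' base pairs is reported as the putative functional DR orientation. This is
#' a heuristic and flagged as such.
#'
#' @param dr_profile A `dr_profile` from [dr_consensus()], or a DNA/RNA
#'   string.
#' @param ... Passed to [nussinov_fold()].
#' @return A list: `forward`, `reverse` (both `fold_result`), `orientation`
#'   (`"forward"`/`"reverse"`), `heuristic = TRUE`.
#' @export
fold_dr_orientations <- function(dr_profile, ...) {
  seq_dna <- if (inherits(dr_profile, "dr_profile")) dr_profile$consensus_dna
             else chartr("U", "T", toupper(dr_profile))
  fwd <- nussinov_fold(seq_dna, ...)
  rev <- nussinov_fold(revcomp(seq_dna), ...)
  list(forward = fwd, reverse = rev,
       orientation = if (rev$n_pairs > fwd$n_pairs) "reverse" else "forward",
       heuristic = TRUE)
}

#' Match spacers against a target database
#'
#' Reports every ungapped alignment of each spacer (both strands) with
#' Hamming distance at most `max_mismatches`; coordinates are on the target
#' forward strand, 0-based half-open.
#'
#' @param spacers Tibble with `spacer_id`, `seq` (each at least 15 nt).
#' @param targets Tibble with `id`, `seq` (e.g. phage/plasmid surrogate
#'   contigs, as from [read_fasta()]).
#' @param max_mismatches Maximum Hamming distance.
#' @return A tibble `spacer_id`, `target_id`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @export
match_spacers <- function(spacers, targets, max_mismatches = 3L) {
  stopifnot(is.data.frame(spacers), is.data.frame(targets))
  max_mismatches <- check_count(max_mismatches, "max_mismatches", 0L)
  if (nrow(spacers) > 0L && any(nchar(spacers$seq) < 15L)) {
    abort("spacers must be at least 15 nt")
  }
  empty <- tibble(spacer_id = character(), target_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer())
  if (nrow(spacers) == 0L || nrow(targets) == 0L) return(empty)
  rows <- list()
  for (ti in seq_len(nrow(targets))) {
    subject <- Biostrings::DNAString(targets$seq[ti])
    for (si in seq_len(nrow(spacers))) {
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") spacers$seq[si] else revcomp(spacers$seq[si])
        hits <- Biostrings::matchPattern(qry, subject,
                                         max.mismatch = max_mismatches,
                                         with.indels = FALSE)
        if (length(hits) == 0L) next
        mm <- vapply(seq_along(hits), function(h) {
          sum(strsplit(as.character(hits[[h]]), "", fixed = TRUE)[[1]] !=
              strsplit(qry, "", fixed = TRUE)[[1]])
        }, integer(1))
        rows[[length(rows) + 1L]] <- tibble(
          spacer_id = spacers$spacer_id[si],
          target_id = targets$id[ti],
          start = Biostrings::start(hits) - 1L,
          end = Biostrings::end(hits),
          strand = strand,
          mismatches = mm
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  arrange(bind_rows(rows), .data$spacer_id, .data$target_id, .data$start,
          .data$strand)
}
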