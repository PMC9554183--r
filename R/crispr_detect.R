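# De novo CRISPR array detection: CRT/MinCED-style seed-and-extend.
#
# An array is a run of >= min_units near-identical direct repeats (DRs)
# separated by spacers. Detection seeds on exact k-mers recurring at
# array-compatible distances, extends each seed column-wise across all
# occurrences while the column majority stays >= 50%, and validates the
# result against repeat/spacer length and per-unit mismatch bounds.

#' Parameters for CRISPR array detection
#'
#' Defaults bracket the direct-repeat (~36 nt) and spacer (~30 nt) lengths
#' typical of type VI (Cas13) loci with generous margin.
#'
#' @param seed_k Exact k-mer seed length (nt).
#' @param repeat_len_min,repeat_len_max Admissible repeat-unit length (nt).
#' @param spacer_len_min,spacer_len_max Admissible spacer length (nt).
#' @param min_units Minimum number of repeat units per array.
#' @param max_repeat_mismatch_frac Maximum Hamming distance of any unit from
#'   the column-majority consensus, as a fraction of repeat length.
#' @return An object of class `array_params`.
#' @export
array_params <- function(seed_k = 8L,
                         repeat_len_min = 23L, repeat_len_max = 50L,
                         spacer_len_min = 20L, spacer_len_max = 60L,
                         min_units = 3L,
                         max_repeat_mismatch_frac = 0.2) {
  p <- list(
    seed_k = check_count(seed_k, "seed_k", 4L),
    repeat_len_min = check_count(repeat_len_min, "repeat_len_min", 1L),
    repeat_len_max = check_count(repeat_len_max, "repeat_len_max", 1L),
    spacer_len_min = check_count(spacer_len_min, "spacer_len_min", 1L),
    spacer_len_max = check_count(spacer_len_max, "spacer_len_max", 1L),
    min_units = check_count(min_units, "min_units", 2L),
    max_repeat_mismatch_frac = max_repeat_mismatch_frac
  )
  if (p$repeat_len_min > p$repeat_len_max) abort("repeat_len_min > repeat_len_max")
  if (p$spacer_len_min > p$spacer_len_max) abort("spacer_len_min > spacer_len_max")
  if (!is.numeric(max_repeat_mismatch_frac) || max_repeat_mismatch_frac < 0 ||
      max_repeat_mismatch_frac >= 1) {
    abort("max_repeat_mismatch_frac must be in [0, 1)")
  }
  structure(p, class = "array_params")
}

seed_gap_bounds <- function(params) {
  c(params$repeat_len_min + params$spacer_len_min - params$seed_k,
    params$repeat_len_max + params$spacer_len_max)
}

# All k-mer start positions (0-based), N-free, as a named list keyed by k-mer,
# restricted to k-mers occurring >= min_count times.
kmer_positions <- function(seq, k, min_count) {
  L <- nchar(seq)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  tab <- table(kmers[ok])
  cand <- names(tab)[tab >= min_count]
  if (length(cand) == 0L) return(list())
  idx <- which(ok & kmers %in% cand)
  lapply(split(idx - 1L, kmers[idx]), unname)
}

#' Find exact k-mer seeds compatible with a CRISPR array
#'
#' Returns every k-mer occurring at least `min_units` times in the contig
#' whose consecutive occurrence gaps all lie within the admissible
#' repeat-plus-spacer period. k-mers containing `N` are never seeds.
#'
#' @param seq A single DNA sequence (uppercase string).
#' @param params An [array_params()] object.
#' @return A tibble with columns `kmer`, `positions` (list of 0-based starts),
#'   `n`.
#' @export
find_seed_repeats <- function(seq, params = array_params()) {
  check_string(seq, "seq")
  pos <- kmer_positions(seq, params$seed_k, params$min_units)
  if (length(pos) == 0L) {
    return(tibble(kmer = character(), positions = list(), n = integer()))
  }
  gb <- seed_gap_bounds(params)
  keep <- vapply(pos, function(p) {
    g <- diff(p)
    all(g >= gb[1] & g <= gb[2])
  }, logical(1))
  pos <- pos[keep]
  tibble(kmer = names(pos), positions = unname(pos),
         n = vapply(pos, length, integer(1))) |>
    arrange(.data$kmer)
}

# Maximal runs of in-range consecutive gaps within one k-mer's occurrence
# list. Used by detect_arrays() so that a repeat k-mer with a stray distant
# occurrence still seeds on its array-local run.
split_gap_runs <- function(p, gb, min_units) {
  if (length(p) < min_units) return(list())
  ok <- diff(p) >= gb[1] & diff(p) <= gb[2]
  runs <- list()
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      run <- p[i:(j + 1L)]
      if (length(run) >= min_units) runs[[length(runs) + 1L]] <- run
      i <- j + 1L
    }
    i <- i + 1L
  }
  runs
}

# Fraction of units agreeing with the column majority at a fixed offset from
# each occurrence start.
column_identity <- function(chars_mat, col) {
  counts <- tabulate(factor(chars_mat[, col], levels = DNA_BASES), nbins = 4L)
  max(counts) / nrow(chars_mat)
}

#' Extend a k-mer seed into a full CRISPR array
#'
#' Greedy bidirectional column-wise extension of the seed occurrences into
#' full repeat units: a boundary column is absorbed while its across-unit
#' majority identity stays at or above 50%, the unit length stays within
#' bounds, and units do not collide. The extended candidate is then validated
#' (unit count, repeat/spacer length windows, per-unit mismatch against the
#' column-majority consensus).
#'
#' @param seq Contig sequence (uppercase string).
#' @param positions 0-based occurrence starts of one seed k-mer.
#' @param params An [array_params()] object.
#' @return A one-row array tibble (see [detect_arrays()]) or `NULL` when the
#'   extension violates any bound.
#' @export
extend_seed_to_array <- function(seq, positions, params = array_params()) {
  p <- sort(as.integer(positions))
  n <- length(p)
  if (n < params$min_units) return(NULL)
  k <- params$seed_k
  L <- nchar(seq)
  min_gap <- min(diff(p))

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  col_at <- function(off) chars[p + off + 1L]  # off relative to occurrence start
  col_ident <- function(off) {
    cc <- col_at(off)
    counts <- tabulate(factor(cc, levels = DNA_BASES), nbins = 4L)
    max(counts) / n
  }

  ext_l <- 0L
  repeat {
    off <- -ext_l - 1L
    total <- k + ext_l + 1L
    if (p[1] + off < 0L) break
    if (total > params$repeat_len_max) break
    if (min_gap - total < 0L) break
    if (col_ident(off) < 0.5) break
    ext_l <- ext_l + 1L
  }
  ext_r <- 0L
  repeat {
    off <- k + ext_r
    total <- k + ext_l + ext_r + 1L
    if (p[n] + off >= L) break
    if (total > params$repeat_len_max) break
    if (min_gap - total < 0L) break
    if (col_ident(off) < 0.5) break
    ext_r <- ext_r + 1L
  }

  rep_len <- k + ext_l + ext_r
  if (rep_len < params$repeat_len_min || rep_len > params$repeat_len_max) return(NULL)
  unit_starts <- p - ext_l
  unit_ends <- unit_starts + rep_len
  spacer_lens <- unit_starts[-1] - unit_ends[-n]
  if (any(spacer_lens < params$spacer_len_min | spacer_lens > params$spacer_len_max)) {
    return(NULL)
  }

  units <- substring(seq, unit_starts + 1L, unit_ends)
  um <- seq_matrix(units)
  consensus <- paste(apply(um, 2L, majority_base), collapse = "")
  cons_chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mism <- apply(um, 1L, function(r) sum(r != cons_chars)) / rep_len
  if (any(mism > params$max_repeat_mismatch_frac)) return(NULL)

  spacer_starts <- unit_ends[-n]
  spacer_ends <- unit_starts[-1]
  tibble(
    start = unit_starts[1],
    end = unit_ends[n],
    strand = "+",
    n_units = n,
    repeat_len = rep_len,
    repeat_consensus = consensus,
    mean_spacer_len = mean(spacer_lens),
    repeat_units = list(tibble(start = unit_starts, end = unit_ends, seq = units)),
    spacers = list(tibble(start = spacer_starts, end = spacer_ends,
                          seq = substring(seq, spacer_starts + 1L, spacer_ends)))
  )
}

detect_arrays_one <- function(id, seq, params) {
  empty <- tibble(
    contig_id = character(), start = integer(), end = integer(),
    strand = character(), n_units = integer(), repeat_len = integer(),
    repeat_consensus = character(), mean_spacer_len = double(),
    repeat_units = list(), spacers = list()
  )
  if (nchar(seq) < params$seed_k) return(empty)
  pos <- kmer_positions(seq, params$seed_k, params$min_units)
  if (length(pos) == 0L) return(empty)
  gb <- seed_gap_bounds(params)
  cands <- list()
  for (km in sort(names(pos))) {
    for (run in split_gap_runs(pos[[km]], gb, params$min_units)) {
      arr <- extend_seed_to_array(seq, run, params)
      if (!is.null(arr)) cands[[length(cands) + 1L]] <- arr
    }
  }
  if (length(cands) == 0L) return(empty)
  cand <- distinct(bind_rows(cands))
  # overlap resolution: more units > longer span > smaller start
  cand <- arrange(cand, desc(.data$n_units), desc(.data$end - .data$start), .data$start)
  kept <- integer()
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[kept] < cand$end[i] & cand$start[i] < cand$end[kept])
    if (!overlaps) kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]
  mutate(arrange(cand, .data$start), contig_id = id, .before = 1L)
}

#' Detect CRISPR arrays in contigs
#'
#' Runs the seed-and-extend detector over every contig. Overlapping candidate
#' arrays are resolved deterministically (more units, then longer span, then
#' smaller start) and results are sorted by contig and start.
#'
#' @param contigs A contig tibble as from [read_fasta()] (columns `id`, `seq`),
#'   or a single DNA string.
#' @param params An [array_params()] object.
#' @return A tibble with one row per array: `contig_id`, `start`, `end`,
#'   `strand`, `n_units`, `repeat_len`, `repeat_consensus`, `mean_spacer_len`,
#'   and list-columns `repeat_units`, `spacers` (each a tibble of 0-based
#'   intervals plus sequence).
#' @export
detect_arrays <- function(contigs, params = array_params()) {
  if (is.character(contigs)) {
    contigs <- tibble(id = paste0("contig", seq_along(contigs)), seq = contigs)
  }
  stopifnot(is.data.frame(contigs), all(c("id", "seq") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) abort("duplicate contig ids")
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    detect_arrays_one(contigs$id[i], contigs$seq[i], params)
  })
  bind_rows(out)
}

#' Summarise repeat and spacer features across arrays
#'
#' Pools every repeat unit and spacer across the input arrays and reports
#' mean and standard deviation of their lengths, together with a per-array
#' table.
#'
#' @param arrays An array tibble from [detect_arrays()].
#' @return A list of class `cas13_array_stats` with elements `summary`
#'   (tibble: `feature`, `n`, `mean_len`, `sd_len`) and `per_array`.
#' @export
array_feature_stats <- function(arrays) {
  if (!is.data.frame(arrays) || nrow(arrays) == 0L) abort("no arrays")
  rep_lens <- unlist(lapply(arrays$repeat_units, function(u) u$end - u$start))
  sp_lens <- unlist(lapply(arrays$spacers, function(s) s$end - s$start))
  summary <- tibble(
    feature = c("repeat", "spacer"),
    n = c(length(rep_lens), length(sp_lens)),
    mean_len = c(mean(rep_lens), mean(sp_lens)),
    sd_len = c(if (length(rep_lens) > 1L) stats::sd(rep_lens) else 0,
               if (length(sp_lens) > 1L) stats::sd(sp_lens) else 0)
  )
  per_array <- arrays |>
    mutate(mean_repeat_len = map_dbl(.data$repeat_units, ~ mean(.x$end - .x$start)),
           mean_spacer_len = map_dbl(.data$spacers, ~ mean(.x$end - .x$start))) |>
    select("contig_id", "start", "end", "n_units",
           "mean_repeat_len", "mean_spacer_len")
  structure(list(summary = summary, per_array = per_array),
            class = "cas13_array_stats")
}

#' @export
print.cas13_array_stats <- function(x, ...) {
  cat("CRISPR array feature summary\n")
  print(x$summary)
  invisible(x)
}

#' Export arrays as GFF3 (array plus child repeat/spacer features)
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param path Output path.
#' @param contig_lengths Optional named vector for bound validation.
#' @return `path`, invisibly.
#' @export
arrays_to_gff3 <- function(arrays, path, contig_lengths = NULL) {
  if (nrow(arrays) == 0L) return(write_gff3(arrays, path))
  feats <- lapply(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    aid <- sprintf("array_%s_%d", a$contig_id, a$start)
    bind_rows(
      tibble(contig_id = a$contig_id, start = a$start, end = a$end,
             strand = a$strand, type = "CRISPR_array", ID = aid,
             n_units = as.character(a$n_units),
             repeat_consensus = a$repeat_consensus),
      tibble(contig_id = a$contig_id, start = a$repeat_units[[1]]$start,
             end = a$repeat_units[[1]]$end, strand = a$strand,
             type = "repeat_unit", Parent = aid),
      tibble(contig_id = a$contig_id, start = a$spacers[[1]]$start,
             end = a$spacers[[1]]$end, strand = a$strand,
             type = "spacer", Parent = aid)
    )
  })
  write_gff3(bind_rows(feats), path, contig_lengths)
}
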