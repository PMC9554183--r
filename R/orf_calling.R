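# Flank extraction and six-frame ORF calling under the bacterial genetic
# code (translation table 11: starts ATG/GTG/TTG, all translated as M at the
# start position).

# codon -> amino acid map (standard code; table 11 shares all internal codons)
codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

STOP_SYMBOL <- "*"

#' Extract the flanking region around a CRISPR array
#'
#' Returns the region `[array_start - flank_nt, array_end + flank_nt)` clipped
#' to the contig bounds. The array span itself is retained inside the region;
#' ORFs overlapping the array are permitted downstream and flagged.
#'
#' @param contig One contig row (tibble with `id`, `seq`) or a list with those
#'   fields.
#' @param array One array row from [detect_arrays()] (needs `start`, `end`).
#' @param flank_nt Flank width on each side, in nucleotides (default 20 kb).
#' @return A one-row tibble: `contig_id`, `start`, `end`, `seq`,
#'   `array_start`, `array_end`.
#' @export
extract_flanks <- function(contig, array, flank_nt = 20000L) {
  flank_nt <- check_count(flank_nt, "flank_nt", 0L)
  L <- nchar(contig$seq)
  start <- max(0L, array$start - flank_nt)
  end <- min(L, array$end + flank_nt)
  tibble(
    contig_id = contig$id,
    start = as.integer(start),
    end = as.integer(end),
    seq = substring(contig$seq, start + 1L, end),
    array_start = as.integer(array$start),
    array_end = as.integer(array$end)
  )
}

translate_codons <- function(codons) {
  aa <- codon_table[codons]
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  unname(aa)
}

orfs_one_strand <- function(seq, min_len_aa, starts) {
  L <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 2L) next
    cs <- substring(seq, f + 1L + 3L * (0:(n_cod - 1L)), f + 3L * (1:n_cod))
    aa <- translate_codons(cs)
    stop_idx <- which(aa == STOP_SYMBOL)
    is_start <- cs %in% starts
    prev <- 0L
    for (t in stop_idx) {
      seg <- if (prev + 1L <= t - 1L) (prev + 1L):(t - 1L) else integer()
      s0 <- seg[is_start[seg]][1]
      if (!is.na(s0)) {
        len_aa <- t - s0
        if (len_aa >= min_len_aa) {
          prot <- aa[s0:(t - 1L)]
          prot[1] <- "M"
          rows[[length(rows) + 1L]] <- list(
            start = f + 3L * (s0 - 1L),        # 0-based, includes start codon
            end = f + 3L * t,                  # exclusive, includes stop codon
            frame = f,
            protein = paste(prot, collapse = "")
          )
        }
      }
      prev <- t
    }
  }
  rows
}

#' Six-frame ORF prediction
#'
#' For each of the six reading frames, every maximal start-to-in-frame-stop
#' span of at least `min_len_aa` residues is reported; nested starts within
#' one stop-bounded region yield only the longest ORF (the first start).
#' Codons containing `N` never act as start or stop and translate as `X`.
#' Reverse-strand ORFs are reported in forward genomic coordinates.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param min_len_aa Minimum protein length (residues, excluding the stop).
#' @param starts Permitted start codons (translation table 11 default).
#' @return A tibble: `start`, `end` (0-based half-open, CDS including stop
#'   codon), `strand`, `frame`, `protein`, `length_aa`.
#' @export
find_orfs <- function(seq, min_len_aa = 1L, starts = c("ATG", "GTG", "TTG")) {
  check_string(seq, "seq")
  min_len_aa <- check_count(min_len_aa, "min_len_aa", 1L)
  L <- nchar(seq)
  fwd <- orfs_one_strand(seq, min_len_aa, starts)
  rev <- orfs_one_strand(revcomp(seq), min_len_aa, starts)
  rows <- c(
    lapply(fwd, function(r) tibble(start = r$start, end = r$end, strand = "+",
                                   frame = r$frame, protein = r$protein)),
    lapply(rev, function(r) tibble(start = L - r$end, end = L - r$start,
                                   strand = "-", frame = r$frame,
                                   protein = r$protein))
  )
  out <- if (length(rows) == 0L) {
    tibble(start = integer(), end = integer(), strand = character(),
           frame = integer(), protein = character())
  } else {
    bind_rows(rows)
  }
  out |>
    mutate(length_aa = nchar(.data$protein)) |>
    arrange(.data$start, .data$end, .data$strand)
}

#' Translate a genomic CDS interval back to its protein
#'
#' Utility used to verify that an emitted ORF's coordinates reproduce its
#' stored protein (start codon forced to `M`, stop codon dropped).
#'
#' @param seq Contig/flank DNA string.
#' @param start,end 0-based half-open CDS interval including the stop codon.
#' @param strand `"+"` or `"-"`.
#' @return Protein string.
#' @export
translate_interval <- function(seq, start, end, strand = "+") {
  cds <- substring(seq, start + 1L, end)
  if (strand == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L) abort("CDS length not divisible by 3")
  n_cod <- nchar(cds) %/% 3L
  aa <- translate_codons(substring(cds, 3L * (0:(n_cod - 1L)) + 1L, 3L * (1:n_cod)))
  if (aa[n_cod] != STOP_SYMBOL) abort("interval does not end at a stop codon")
  aa <- aa[-n_cod]
  aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Apply the candidate-protein length filter
#'
#' Keeps ORFs whose protein is strictly longer than `min_aa` residues
#' ("more than 400 residues": a 400-aa protein is excluded, a 401-aa protein
#' kept).
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param min_aa Length threshold (default 400).
#' @return The filtered tibble.
#' @export
filter_candidate_proteins <- function(orfs, min_aa = 400L) {
  stopifnot(is.data.frame(orfs))
  if (nrow(orfs) == 0L) return(orfs)
  filter(orfs, .data$length_aa > min_aa)
}

#' Call ORFs in the flanks of every array
#'
#' Convenience wrapper joining [extract_flanks()] and [find_orfs()] over an
#' array table; ORF coordinates are lifted to contig coordinates, duplicates
#' from overlapping flanks are removed, and ORFs overlapping their source
#' array are flagged.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param arrays Array tibble from [detect_arrays()].
#' @param flank_nt Flank width per side (nt).
#' @param min_len_aa Minimum protein length to report.
#' @return A tibble of ORFs with `contig_id`, contig-level `start`/`end`,
#'   `strand`, `frame`, `protein`, `length_aa`, `overlaps_array`,
#'   `array_start`, `array_end`, `protein_id`.
#' @export
call_flank_orfs <- function(contigs, arrays, flank_nt = 20000L, min_len_aa = 100L) {
  if (nrow(arrays) == 0L) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(), protein = character(),
                  length_aa = integer(), overlaps_array = logical(),
                  array_start = integer(), array_end = integer(),
                  protein_id = character()))
  }
  out <- lapply(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    ctg <- contigs[contigs$id == a$contig_id, ]
    if (nrow(ctg) != 1L) abort(sprintf("array references unknown contig %s", a$contig_id))
    fl <- extract_flanks(ctg, a, flank_nt)
    orfs <- find_orfs(fl$seq, min_len_aa = min_len_aa)
    if (nrow(orfs) == 0L) return(NULL)
    orfs |>
      mutate(contig_id = a$contig_id,
             start = .data$start + fl$start,
             end = .data$end + fl$start,
             overlaps_array = .data$start < a$end & a$start < .data$end,
             array_start = a$start,
             array_end = a$end)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(call_flank_orfs(contigs, arrays[0, ], flank_nt, min_len_aa))
  res |>
    distinct(.data$contig_id, .data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    mutate(protein_id = sprintf("%s|%d|%d|%s", .data$contig_id, .data$start,
                                .data$end, .data$strand)) |>
    arrange(.data$contig_id, .data$start, .data$end)
}
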