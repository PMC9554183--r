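# HEPN (higher eukaryotes and prokaryotes nucleotide-binding) domain rules.
#
# Cas13 effectors carry two HEPN RNase domains, each anchored by the
# catalytic R-X4-H motif. The scanner is motif-anchored: every R...H window
# of width six is a hit, overlaps allowed. Downstream rules derive the
# dual-HEPN completeness filter, the RNXXXH variant statistics, the
# N-terminal-domain (NTD) call, and the predicted crRNA DR orientation
# (NTD-present families load crRNAs with a 5'-DR handle, NTD-absent ones
# with a 3'-DR handle).

#' Scan a protein for R-X4-H (HEPN catalytic) motifs
#'
#' Every position `i` with `R` at `i` and `H` at `i + 5` yields a hit;
#' overlapping hits are all reported, in ascending order.
#'
#' @param protein Amino-acid string.
#' @return A tibble `start` (0-based), `motif_seq` (6 residues), `is_rn`
#'   (`TRUE` when the second residue is `N`, the RNXXXH variant).
#' @export
scan_rx4h <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  empty <- tibble(start = integer(), motif_seq = character(), is_rn = logical())
  if (is.na(protein) || nchar(protein) < 6L) return(empty)
  m <- gregexpr("(?=R.{4}H)", protein, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  motifs <- substring(protein, starts, starts + 5L)
  tibble(start = starts - 1L, motif_seq = motifs,
         is_rn = substring(motifs, 2L, 2L) == "N")
}

#' Dual-HEPN completeness filter
#'
#' A candidate counts as carrying two HEPN domains when two motif hits are at
#' least `min_separation_aa` residues apart (two motifs within one domain do
#' not qualify). Candidates failing this are considered incomplete effectors.
#'
#' @param hits Motif tibble from [scan_rx4h()] (sorted ascending by `start`).
#' @param min_separation_aa Minimum start separation defining two distinct
#'   domains.
#' @return Logical flag.
#' @export
dual_hepn_filter <- function(hits, min_separation_aa = 100L) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) < 2L) return(FALSE)
  (max(hits$start) - min(hits$start)) >= min_separation_aa
}

#' Pooled fraction of RNXXXH among all RXXXXH motifs
#'
#' @param annotations A HEPN annotation tibble from [annotate_hepn()], or any
#'   tibble with a `hits` list-column of motif tibbles.
#' @return Fraction in `[0, 1]`.
#' @export
rnxxxh_fraction <- function(annotations) {
  stopifnot(is.data.frame(annotations), "hits" %in% names(annotations))
  all_hits <- bind_rows(annotations$hits)
  if (nrow(all_hits) == 0L) abort("no RXXXXH motifs across inputs")
  mean(all_hits$is_rn)
}

#' Call an elongated N-terminal domain from motif architecture
#'
#' A long HEPN-free N-terminal stretch implies an NTD: the call is `TRUE`
#' when the first motif starts at or beyond `ntd_offset_aa`.
#'
#' @param protein_len Protein length in residues.
#' @param hits Motif tibble from [scan_rx4h()] (non-empty).
#' @param ntd_offset_aa Offset convention (default 250; a first hit exactly
#'   at the offset counts as NTD-present).
#' @return Logical flag.
#' @export
detect_ntd <- function(protein_len, hits, ntd_offset_aa = 250L) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) abort("no HEPN anchor")
  if (any(hits$start >= protein_len)) abort("motif beyond protein length")
  min(hits$start) >= ntd_offset_aa
}

#' Predict the functional crRNA DR orientation from protein architecture
#'
#' NTD-present architectures (Cas13a/c/d-like) use mature crRNAs with a
#' 5'-DR handle; NTD-absent architectures (Cas13b/X/Bt/e/f-like) use a 3'-DR
#' handle; proteins without any HEPN anchor are undetermined.
#'
#' @param ntd_present Logical or `NA` (no HEPN hits).
#' @return One of `"5prime"`, `"3prime"`, `"undetermined"`.
#' @export
predict_crrna_orientation <- function(ntd_present) {
  if (is.na(ntd_present)) return("undetermined")
  if (ntd_present) "5prime" else "3prime"
}

#' Annotate proteins with HEPN motifs, domain flags and DR orientation
#'
#' Runs [scan_rx4h()], the dual-HEPN filter, the NTD call and the crRNA
#' orientation rule over a protein table.
#'
#' @param proteins Tibble with columns `protein_id`, `protein`.
#' @param min_separation_aa Separation defining two HEPN domains.
#' @param ntd_offset_aa NTD offset convention (see [detect_ntd()]).
#' @return A tibble `protein_id`, `n_motifs`, `hits` (list-column),
#'   `dual_hepn`, `ntd_present` (`NA` when no hits), `predicted_dr_side`.
#' @export
annotate_hepn <- function(proteins, min_separation_aa = 100L, ntd_offset_aa = 250L) {
  stopifnot(is.data.frame(proteins), all(c("protein_id", "protein") %in% names(proteins)))
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    hits <- scan_rx4h(proteins$protein[i])
    ntd <- if (nrow(hits) == 0L) NA else {
      detect_ntd(nchar(proteins$protein[i]), hits, ntd_offset_aa)
    }
    dual <- dual_hepn_filter(hits, min_separation_aa)
    tibble(
      protein_id = proteins$protein_id[i],
      protein_len = nchar(proteins$protein[i]),
      n_motifs = nrow(hits),
      hits = list(hits),
      dual_hepn = dual,
      ntd_present = ntd,
      predicted_dr_side = predict_crrna_orientation(ntd)
    )
  })
  if (length(rows) == 0L) {
    return(tibble(protein_id = character(), protein_len = integer(),
                  n_motifs = integer(), hits = list(),
                  dual_hepn = logical(), ntd_present = logical(),
                  predicted_dr_side = character()))
  }
  bind_rows(rows)
}

#' Flatten a HEPN annotation table for TSV export
#'
#' @param annotations Tibble from [annotate_hepn()].
#' @return A plain tibble with motif positions collapsed to a comma list.
#' @export
hepn_report <- function(annotations) {
  annotations |>
    mutate(motif_positions = map_chr(.data$hits, ~ paste(.x$start, collapse = ","))) |>
    select("protein_id", "n_motifs", "motif_positions", "dual_hepn",
           "ntd_present", "predicted_dr_side")
}
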