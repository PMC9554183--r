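# Deterministic synthetic-data generators with machine-readable ground
# truth: contigs with planted CRISPR arrays and Cas13-like genes, family
# MSAs for profile building, decoy proteins, and target databases for
# protospacer matching. Every generator is a pure function of its seed.
#
# Ground-truth identifiability for planted arrays is engineered, not left
# to chance:
#  * repeat-unit mutations never touch the first PROTECTED_SEED_NT columns,
#    so an exact seed k-mer survives in every unit;
#  * per column, strictly fewer than half the units are mutated, so the
#    column-majority consensus equals the planted repeat;
#  * the two columns flanking each repeat boundary are resampled to below
#    50% across-unit identity, so column-wise extension stops exactly at
#    the planted boundary.

PROTECTED_SEED_NT <- 12L

random_dna_chars <- function(n, gc = 0.5) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_protein_chars <- function(n) {
  out <- sample(AA20, n, replace = TRUE)
  out[1] <- "M"
  out
}

# Break every R-X4-H motif whose start is not in keep_offsets (0-based) by
# replacing its histidine with leucine. Substitution-only, so alignments
# remain columnar.
scrub_hepn <- function(protein, keep_offsets = integer()) {
  repeat {
    hits <- scan_rx4h(protein)
    bad <- hits$start[!hits$start %in% keep_offsets]
    if (length(bad) == 0L) return(protein)
    chars <- strsplit(protein, "", fixed = TRUE)[[1]]
    chars[bad[1] + 6L] <- "L"
    protein <- paste(chars, collapse = "")
  }
}

set_hepn_anchors <- function(chars, hepn_offsets, is_rn) {
  for (k in seq_along(hepn_offsets)) {
    off <- hepn_offsets[k]  # 0-based
    chars[off + 1L] <- "R"
    chars[off + 2L] <- if (is_rn[k]) "N" else "A"
    chars[off + 6L] <- "H"
  }
  chars
}

anchor_positions <- function(hepn_offsets) {
  # protected 0-based protein positions: R, second residue, H of each motif
  as.integer(c(0L, outer(c(0L, 1L, 5L), hepn_offsets, "+")))
}

mutate_protein_chars <- function(chars, rate, protected = integer()) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protected + 1L)
  for (i in hit) {
    alt <- AA20[AA20 != chars[i]]
    chars[i] <- alt[sample.int(19L, 1L)]
  }
  chars
}

#' Reference Cas13 family architectures used by the fixture generators
#'
#' One row per family-like architecture: protein length, 0-based offsets of
#' the two HEPN R-X4-H motifs, whether the motifs are of the RNXXXH variant,
#' whether the architecture carries an elongated N-terminal domain (NTD),
#' and the experimentally established crRNA DR side for that architecture
#' class. Lengths and motif placements follow the published family scales
#' (compact ~770-800 aa effectors through ~1200 aa Cas13a-like proteins).
#'
#' @return A tibble `family`, `length_aa`, `hepn1`, `hepn2`, `is_rn`,
#'   `ntd`, `dr_side`.
#' @export
cas13_architectures <- function() {
  tibble(
    family = c("cas13a", "cas13b", "cas13c", "cas13d",
               "cas13x", "cas13bt", "cas13e", "cas13f"),
    length_aa = c(1200L, 1150L, 1120L, 950L, 775L, 800L, 767L, 1100L),
    hepn1 = c(425L, 30L, 380L, 300L, 25L, 35L, 28L, 45L),
    hepn2 = c(1050L, 980L, 990L, 850L, 630L, 660L, 640L, 950L),
    is_rn = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    ntd = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    dr_side = c("5prime", "3prime", "5prime", "5prime",
                "3prime", "3prime", "3prime", "3prime")
  )
}

resolve_architecture <- function(family, length_aa, hepn_offsets, is_rn) {
  arch <- cas13_architectures()
  row <- arch[arch$family == family, ]
  if (nrow(row) == 1L) {
    length_aa <- length_aa %||% row$length_aa
    hepn_offsets <- hepn_offsets %||% c(row$hepn1, row$hepn2)
    is_rn <- is_rn %||% rep(row$is_rn, length(hepn_offsets))
  }
  if (is.null(length_aa)) abort("length_aa required for a family without a built-in architecture")
  hepn_offsets <- as.integer(hepn_offsets %||% integer())
  if (length(hepn_offsets) > 0L) {
    if (is.null(is_rn)) is_rn <- rep(TRUE, length(hepn_offsets))
    if (any(hepn_offsets + 6L > length_aa)) abort("HEPN offset beyond protein length")
  }
  list(length_aa = as.integer(length_aa), hepn_offsets = hepn_offsets,
       is_rn = is_rn %||% logical())
}

#' Generate a synthetic family multiple sequence alignment
#'
#' Members are independent per-site mutants of a seeded ancestor (mutations
#' uniform over the 19 alternative residues); the HEPN R/H anchors, the
#' motif's second residue, and the initial methionine are held invariant.
#' Accidental R-X4-H motifs outside the planted offsets are scrubbed from
#' every emitted sequence so motif architecture is exactly the planted one.
#' With `gap_rate > 0`, a fraction of columns receive gap characters in 75%
#' of members (exercising the match-column threshold); by default there are
#' no gaps.
#'
#' @param rng_seed Integer seed.
#' @param family Family label; members of [cas13_architectures()] supply
#'   length/offset defaults.
#' @param n_seqs Number of aligned members.
#' @param mutation_rate Per-site mutation probability in `[0, 0.5]`.
#' @param length_aa,hepn_offsets,is_rn Architecture overrides (required for
#'   families without a built-in architecture; `hepn_offsets = integer()`
#'   builds a motif-free family such as Cas1/Cas2).
#' @param gap_rate Fraction of columns converted to majority-gap columns.
#' @return A list: `msa` (tibble `id`, `seq`), `ancestor`, `family`,
#'   `hepn_offsets`, `is_rn`.
#' @export
synth_family_msa <- function(rng_seed, family, n_seqs = 10L,
                             mutation_rate = 0.1, length_aa = NULL,
                             hepn_offsets = NULL, is_rn = NULL,
                             gap_rate = 0) {
  if (mutation_rate < 0 || mutation_rate > 0.5) abort("mutation_rate must be in [0, 0.5]")
  ar <- resolve_architecture(family, length_aa, hepn_offsets, is_rn)
  with_rng_seed(rng_seed, {
    anc_chars <- random_protein_chars(ar$length_aa)
    anc_chars <- set_hepn_anchors(anc_chars, ar$hepn_offsets, ar$is_rn)
    ancestor <- scrub_hepn(paste(anc_chars, collapse = ""), ar$hepn_offsets)
    anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    protected <- anchor_positions(ar$hepn_offsets)
    members <- vapply(seq_len(n_seqs), function(i) {
      m <- mutate_protein_chars(anc_chars, mutation_rate, protected)
      scrub_hepn(paste(m, collapse = ""), ar$hepn_offsets)
    }, character(1))
    if (gap_rate > 0) {
      gap_cols <- which(stats::runif(ar$length_aa) < gap_rate)
      gap_cols <- setdiff(gap_cols, protected + 1L)
      if (length(gap_cols) > 0L) {
        mm <- seq_matrix(members)
        for (col in gap_cols) {
          gapped <- which(stats::runif(n_seqs) < 0.75)
          mm[gapped, col] <- "-"
        }
        members <- apply(mm, 1L, paste, collapse = "")
      }
    }
    list(
      msa = tibble(id = sprintf("%s_ref%d", family, seq_len(n_seqs)),
                   seq = members),
      ancestor = ancestor,
      family = family,
      hepn_offsets = ar$hepn_offsets,
      is_rn = ar$is_rn
    )
  })
}

#' Generate one family member (per-site mutant of an ancestor)
#'
#' @param rng_seed Integer seed.
#' @param ancestor Ancestor protein string.
#' @param mutation_rate Per-site mutation probability.
#' @param hepn_offsets 0-based planted motif offsets held invariant (and the
#'   only motifs retained after scrubbing).
#' @return Protein string.
#' @export
synth_family_member <- function(rng_seed, ancestor, mutation_rate = 0.1,
                                hepn_offsets = integer()) {
  with_rng_seed(rng_seed, {
    chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    m <- mutate_protein_chars(chars, mutation_rate, anchor_positions(hepn_offsets))
    scrub_hepn(paste(m, collapse = ""), hepn_offsets)
  })
}

#' Generate a decoy protein of a designed elimination class
#'
#' * `short`: family-derived homolog truncated to `length_aa` residues
#'   (eliminated by the >400-aa filter);
#' * `single_hepn`: family-derived homolog with the C-terminal motif
#'   ablated (passes the HMM search, fails the dual-HEPN filter);
#' * `no_hepn`: random motif-free protein (eliminated at the HMM search);
#' * `shuffled`: residue-shuffled family homolog (eliminated at the HMM
#'   search).
#'
#' @param rng_seed Integer seed.
#' @param kind One of `"short"`, `"single_hepn"`, `"no_hepn"`, `"shuffled"`.
#' @param ancestor Family ancestor (required for all kinds except
#'   `no_hepn`).
#' @param hepn_offsets Planted motif offsets of the ancestor.
#' @param mutation_rate Divergence of the underlying homolog.
#' @param length_aa Length for `short` (350) and `no_hepn` (500) kinds.
#' @return Protein string.
#' @export
decoy_protein <- function(rng_seed, kind, ancestor = NULL,
                          hepn_offsets = integer(), mutation_rate = 0.1,
                          length_aa = NULL) {
  kind <- match.arg(kind, c("short", "single_hepn", "no_hepn", "shuffled"))
  with_rng_seed(rng_seed, {
    if (kind == "no_hepn") {
      len <- length_aa %||% 500L
      return(scrub_hepn(paste(random_protein_chars(len), collapse = "")))
    }
    if (is.null(ancestor)) abort("ancestor required for family-derived decoys")
    chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    hom <- mutate_protein_chars(chars, mutation_rate, anchor_positions(hepn_offsets))
    hom <- scrub_hepn(paste(hom, collapse = ""), hepn_offsets)
    if (kind == "short") {
      len <- length_aa %||% 350L
      scrub_hepn(substr(hom, 1L, len), hepn_offsets[hepn_offsets + 6L <= len])
    } else if (kind == "single_hepn") {
      if (length(hepn_offsets) < 2L) abort("single_hepn decoy needs two planted motifs")
      chars <- strsplit(hom, "", fixed = TRUE)[[1]]
      chars[max(hepn_offsets) + 1L] <- "A"  # ablate the C-terminal R
      scrub_hepn(paste(chars, collapse = ""), hepn_offsets)
    } else {  # shuffled
      chars <- strsplit(hom, "", fixed = TRUE)[[1]]
      shuf <- c(chars[1], sample(chars[-1]))
      scrub_hepn(paste(shuf, collapse = ""))
    }
  })
}

#' Residue-shuffle a protein (first residue fixed)
#'
#' @param protein Protein string.
#' @param rng_seed Integer seed.
#' @return Shuffled protein of identical composition.
#' @export
shuffle_protein <- function(protein, rng_seed) {
  with_rng_seed(rng_seed, {
    chars <- strsplit(protein, "", fixed = TRUE)[[1]]
    paste(c(chars[1], sample(chars[-1])), collapse = "")
  })
}

# codon choices per amino acid under the standard/bacterial code
codon_choices <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Uniform synonymous back-translation; the initial residue always becomes
# ATG. Returns the CDS (codons + one stop), no guard.
back_translate_cds <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    ch <- codon_choices[[a]]
    if (is.null(ch)) abort(sprintf("cannot back-translate residue %s", a))
    ch[sample.int(length(ch), 1L)]
  }, character(1), USE.NAMES = FALSE)
  codons[1] <- "ATG"
  paste(c(codons, STOP_CODONS[sample.int(3L, 1L)]), collapse = "")
}

#' Specify a synthetic locus
#'
#' @param rng_seed Integer seed driving background, array mutations, codon
#'   choices and boundary resampling.
#' @param contig_len Contig length (nt).
#' @param array `NULL` or a list: `repeat_seq` (23-50 nt DNA), `spacer_len`,
#'   `n_units`, `mutation_rate` (per-unit fraction of mutated positions),
#'   `pos` (0-based array start).
#' @param genes List of gene plants, each a list: `id`, `protein` (string,
#'   starting with `M`), `strand`, `pos` (0-based cassette start), and
#'   optional metadata `family`, `kind`, `hepn_offsets`.
#' @param gc Background GC content.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(rng_seed, contig_len, array = NULL, genes = list(),
                       gc = 0.5) {
  structure(list(rng_seed = rng_seed, contig_len = check_count(contig_len, "contig_len", 100L),
                 array = array, genes = genes, gc = gc),
            class = "locus_spec")
}

resample_low_identity_column <- function(n) {
  # bases whose maximum count is strictly below n/2 across the n units
  if (n <= 4L) return(sample(DNA_BASES, n))
  repeat {
    b <- sample(DNA_BASES, n, replace = TRUE)
    if (2L * max(tabulate(factor(b, levels = DNA_BASES), 4L)) < n) return(b)
  }
}

#' Synthesise a contig from a locus specification
#'
#' Background is drawn base-by-base from the seeded generator; the planted
#' array and gene cassettes are inserted at their recorded coordinates.
#' Each gene cassette is an in-frame stop guard, an ATG-initiated uniformly
#' codon-randomised back-translation of the protein, and a stop codon, so
#' the ORF caller must recover exactly the planted protein. The same seed
#' yields byte-identical output.
#'
#' @param spec A [locus_spec()].
#' @return A list: `contig` (tibble `id`, `seq`, `length`; id from the seed)
#'   and `truth` (list with `array` - same schema as [detect_arrays()] rows -
#'   and `genes`, a tibble of planted CDS coordinates and proteins).
#' @export
synth_contig <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  with_rng_seed(spec$rng_seed, {
    L <- spec$contig_len
    chars <- random_dna_chars(L, spec$gc)
    occupied <- list()
    claim <- function(start, end, what) {
      for (iv in occupied) {
        if (start < iv[2] && iv[1] < end) {
          abort(sprintf("planted %s [%d,%d) overlaps an earlier feature", what, start, end))
        }
      }
      if (start < 0L || end > L) abort(sprintf("planted %s outside contig", what))
      occupied[[length(occupied) + 1L]] <<- c(start, end)
    }

    arr_truth <- NULL
    if (!is.null(spec$array)) {
      a <- spec$array
      rep_len <- nchar(a$repeat_seq)
      n <- a$n_units
      if (n < 2L) abort("array needs at least 2 units")
      if (rep_len <= PROTECTED_SEED_NT) abort("repeat shorter than the protected seed window")
      period <- rep_len + a$spacer_len
      unit_starts <- a$pos + (0:(n - 1L)) * period
      arr_end <- unit_starts[n] + rep_len
      claim(a$pos - 2L, arr_end + 2L, "array")

      rep_chars <- strsplit(toupper(a$repeat_seq), "", fixed = TRUE)[[1]]
      units <- matrix(rep(rep_chars, each = n), nrow = n)
      n_mut <- floor((a$mutation_rate %||% 0) * rep_len)
      if (n_mut > 0L) {
        cap <- ceiling(n / 2) - 1L  # strict minority of units per column
        col_used <- integer(rep_len)
        for (i in seq_len(n)) {
          avail <- which(seq_len(rep_len) > PROTECTED_SEED_NT & col_used < cap)
          if (length(avail) < n_mut) {
            abort("mutation rate too high for identifiable ground truth")
          }
          cols <- avail[sample.int(length(avail), n_mut)]
          col_used[cols] <- col_used[cols] + 1L
          for (col in cols) {
            alt <- DNA_BASES[DNA_BASES != units[i, col]]
            units[i, col] <- alt[sample.int(3L, 1L)]
          }
        }
      }
      for (i in seq_len(n)) {
        chars[(unit_starts[i] + 1L):(unit_starts[i] + rep_len)] <- units[i, ]
        if (i < n) {
          sp0 <- unit_starts[i] + rep_len
          chars[(sp0 + 1L):(sp0 + a$spacer_len)] <- random_dna_chars(a$spacer_len, spec$gc)
        }
      }
      # boundary columns: force across-unit identity below 50%
      for (off in c(-2L, -1L, rep_len, rep_len + 1L)) {
        chars[unit_starts + off + 1L] <- resample_low_identity_column(n)
      }
      spacer_starts <- unit_starts[-n] + rep_len
      spacer_ends <- unit_starts[-1]
      arr_truth <- tibble(
        start = unit_starts[1], end = arr_end, strand = "+",
        n_units = n, repeat_len = rep_len,
        repeat_consensus = paste(rep_chars, collapse = ""),
        mean_spacer_len = mean(spacer_ends - spacer_starts),
        repeat_units = list(tibble(
          start = unit_starts, end = unit_starts + rep_len,
          seq = substring(paste(chars, collapse = ""), unit_starts + 1L,
                          unit_starts + rep_len))),
        spacers = list(tibble(
          start = spacer_starts, end = spacer_ends,
          seq = substring(paste(chars, collapse = ""), spacer_starts + 1L,
                          spacer_ends)))
      )
    }

    gene_rows <- list()
    for (g in spec$genes) {
      cds <- back_translate_cds(g$protein)
      cassette <- paste0("TAA", cds)
      clen <- nchar(cassette)
      claim(g$pos, g$pos + clen, sprintf("gene %s", g$id %||% "?"))
      ins <- if (g$strand == "-") revcomp(cassette) else cassette
      chars[(g$pos + 1L):(g$pos + clen)] <- strsplit(ins, "", fixed = TRUE)[[1]]
      if (g$strand == "+") {
        cds_start <- g$pos + 3L
        cds_end <- g$pos + clen
      } else {
        cds_start <- g$pos
        cds_end <- g$pos + clen - 3L
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        id = g$id %||% sprintf("gene%d", length(gene_rows) + 1L),
        family = g$family %||% NA_character_,
        kind = g$kind %||% "candidate",
        start = cds_start, end = cds_end, strand = g$strand,
        protein = g$protein, length_aa = nchar(g$protein),
        hepn1 = (g$hepn_offsets %||% c(NA_integer_, NA_integer_))[1],
        hepn2 = (g$hepn_offsets %||% c(NA_integer_, NA_integer_))[2]
      )
    }

    seq <- paste(chars, collapse = "")
    if (!is.null(arr_truth)) {
      # re-extract planted sequences from the final contig
      arr_truth$repeat_units[[1]]$seq <-
        substring(seq, arr_truth$repeat_units[[1]]$start + 1L,
                  arr_truth$repeat_units[[1]]$end)
      if (nrow(arr_truth$spacers[[1]]) > 0L) {
        arr_truth$spacers[[1]]$seq <-
          substring(seq, arr_truth$spacers[[1]]$start + 1L,
                    arr_truth$spacers[[1]]$end)
      }
    }
    contig_id <- sprintf("synth_%d", spec$rng_seed)
    list(
      contig = tibble(id = contig_id, seq = seq, length = nchar(seq)),
      truth = list(
        array = if (is.null(arr_truth)) NULL else
          mutate(arr_truth, contig_id = contig_id, .before = 1L),
        genes = if (length(gene_rows) == 0L) NULL else
          mutate(bind_rows(gene_rows), contig_id = contig_id, .before = 1L)
      )
    )
  })
}

#' Random planted-array contig (detector stress fixture)
#'
#' Draws array parameters uniformly from the stated ranges (repeat 23-47 nt,
#' spacer 20-50 nt, 3-8 units, per-unit mutation up to `max_mutation_rate`),
#' plants one array at a random position in a random background contig of
#' 20-50 kb, and returns contig plus ground truth.
#'
#' @param rng_seed Integer seed.
#' @param contig_len Contig length; random in 20-50 kb when `NULL`.
#' @param max_mutation_rate Upper bound of the per-unit mutation fraction.
#' @return As [synth_contig()].
#' @export
synth_array_fixture <- function(rng_seed, contig_len = NULL,
                                max_mutation_rate = 0.1) {
  draws <- with_rng_seed(rng_seed, {
    list(
      contig_len = contig_len %||% sample(20000:50000, 1L),
      rep_len = sample(23:47, 1L),
      spacer_len = sample(20:50, 1L),
      n_units = sample(3:8, 1L),
      mutation_rate = stats::runif(1L, 0, max_mutation_rate),
      repeat_seq = paste(random_dna_chars(47L), collapse = ""),
      posfrac = stats::runif(1L, 0.1, 0.7)
    )
  })
  span <- draws$n_units * draws$rep_len + (draws$n_units - 1L) * draws$spacer_len
  pos <- floor(draws$posfrac * (draws$contig_len - span - 10L)) + 5L
  spec <- locus_spec(
    rng_seed = as.integer((as.numeric(rng_seed) * 31) %% 2000000000),
    contig_len = draws$contig_len,
    array = list(repeat_seq = substr(draws$repeat_seq, 1L, draws$rep_len),
                 spacer_len = draws$spacer_len, n_units = draws$n_units,
                 mutation_rate = draws$mutation_rate, pos = pos)
  )
  synth_contig(spec)
}

#' Exact dinucleotide shuffle of a DNA sequence
#'
#' Altschul-Erickson shuffle: generates a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) counts, the same first and
#' last base, by sampling a random Eulerian path through the dinucleotide
#' multigraph.
#'
#' @param seq DNA string.
#' @param rng_seed Integer seed.
#' @return Shuffled sequence of identical dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq, rng_seed) {
  with_rng_seed(rng_seed, {
    s <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(s)
    if (n < 3L) return(seq)
    verts <- sort(unique(s))
    vi <- match(s, verts)
    nv <- length(verts)
    first <- vi[1]; last <- vi[n]
    succ <- split(vi[-1], vi[-n])  # successor lists keyed by vertex index
    keys <- as.integer(names(succ))
    succ_full <- vector("list", nv)
    succ_full[keys] <- succ
    # choose a random last edge per vertex (except the terminal vertex) such
    # that following last edges always reaches the terminal vertex
    repeat {
      last_edge <- rep(NA_integer_, nv)
      for (v in seq_len(nv)) {
        if (v == last) next
        out <- succ_full[[v]]
        if (is.null(out) || length(out) == 0L) next
        last_edge[v] <- out[sample.int(length(out), 1L)]
      }
      ok <- TRUE
      for (v in seq_len(nv)) {
        if (v == last || is.na(last_edge[v])) next
        cur <- v
        for (step in seq_len(nv)) {
          cur <- last_edge[cur]
          if (is.na(cur) || cur == last) break
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # per-vertex edge order: shuffled non-last edges, then the last edge
    ordered <- vector("list", nv)
    for (v in seq_len(nv)) {
      out <- succ_full[[v]]
      if (is.null(out) || length(out) == 0L) next
      if (is.na(last_edge[v])) {
        ordered[[v]] <- out[sample.int(length(out))]
      } else {
        pool <- out
        drop1 <- match(last_edge[v], pool)
        pool <- pool[-drop1]
        ordered[[v]] <- c(if (length(pool) > 0L) pool[sample.int(length(pool))],
                          last_edge[v])
      }
    }
    ptr <- rep(1L, nv)
    out <- integer(n)
    out[1] <- first
    cur <- first
    for (i in 2:n) {
      nxt <- ordered[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(verts[out], collapse = "")
  })
}

#' Synthesise a target database with planted protospacers
#'
#' @param rng_seed Integer seed.
#' @param n_targets Number of target sequences (phage/plasmid surrogates).
#' @param target_len Length of each target (nt).
#' @param planted_spacers `NULL`, or a tibble with `spacer_id`, `seq` and
#'   optionally `strand` (default `+`); spacer `i` is planted in target
#'   `((i - 1) %% n_targets) + 1` at a recorded position.
#' @return A list: `targets` (tibble `id`, `seq`, `length`) and `placements`
#'   (tibble `spacer_id`, `target_id`, `start`, `end`, `strand`).
#' @export
synth_target_db <- function(rng_seed, n_targets = 2L, target_len = 8000L,
                            planted_spacers = NULL) {
  with_rng_seed(rng_seed, {
    seqs <- vapply(seq_len(n_targets), function(i) {
      paste(random_dna_chars(target_len), collapse = "")
    }, character(1))
    ids <- sprintf("target%d", seq_len(n_targets))
    placements <- tibble(spacer_id = character(), target_id = character(),
                         start = integer(), end = integer(), strand = character())
    if (!is.null(planted_spacers) && nrow(planted_spacers) > 0L) {
      if (!"strand" %in% names(planted_spacers)) planted_spacers$strand <- "+"
      used <- vector("list", n_targets)
      for (i in seq_len(nrow(planted_spacers))) {
        ti <- ((i - 1L) %% n_targets) + 1L
        sp <- planted_spacers$seq[i]
        w <- nchar(sp)
        repeat {
          pos <- sample.int(target_len - w, 1L) - 1L
          clash <- any(vapply(used[[ti]], function(iv) pos < iv[2] && iv[1] < pos + w,
                              logical(1)))
          if (!clash) break
        }
        used[[ti]] <- c(used[[ti]], list(c(pos, pos + w)))
        ins <- if (planted_spacers$strand[i] == "-") revcomp(sp) else sp
        seqs[ti] <- paste0(substr(seqs[ti], 1L, pos), ins,
                           substr(seqs[ti], pos + w + 1L, target_len))
        placements <- bind_rows(placements, tibble(
          spacer_id = planted_spacers$spacer_id[i], target_id = ids[ti],
          start = pos, end = pos + w, strand = planted_spacers$strand[i]
        ))
      }
    }
    list(targets = tibble(id = ids, seq = seqs, length = nchar(seqs)),
         placements = placements)
  })
}

#' Canonical fixture metagenome for the end-to-end pipeline
#'
#' Builds a small synthetic metagenome with three planted Cas13-like loci
#' (a Cas13a-like and a Cas13b-like candidate at 10% divergence from their
#' reference families, and one candidate from a novel family at ~65%
#' divergence from Cas13a), one locus with adjacent Cas1/Cas2 adaptation
#' genes, four decoys (short, single-HEPN, HEPN-free, shuffled) on separate
#' decoy loci, reference MSAs for the four known Cas13 families plus
#' Cas1/Cas2, and a target database with two of the Cas13a-locus spacers
#' planted (one per strand).
#'
#' @param rng_seed Integer seed.
#' @return A list: `contigs`, `truth` (per-contig list), `msas`,
#'   `cas1_msa`, `cas2_msa`, `references` (tibble `protein_id`, `family`,
#'   `protein`), `candidates` (expected-truth tibble), `targets`,
#'   `target_placements`.
#' @export
synth_metagenome <- function(rng_seed) {
  seeds <- with_rng_seed(rng_seed, sample.int(1000000000L, 40L))
  arch <- cas13_architectures()
  fams <- c("cas13a", "cas13b", "cas13c", "cas13d")
  msas <- lapply(seq_along(fams), function(i) {
    synth_family_msa(seeds[i], fams[i], n_seqs = 10L, mutation_rate = 0.1)
  })
  names(msas) <- fams
  cas1_msa <- synth_family_msa(seeds[5], "cas1", n_seqs = 8L, mutation_rate = 0.1,
                               length_aa = 300L, hepn_offsets = integer())
  cas2_msa <- synth_family_msa(seeds[6], "cas2", n_seqs = 8L, mutation_rate = 0.1,
                               length_aa = 90L, hepn_offsets = integer())

  references <- bind_rows(lapply(fams, function(f) {
    tibble(protein_id = sprintf("%s_ref%d", f, 1:3), family = f,
           protein = msas[[f]]$msa$seq[1:3])
  }))

  off <- function(f) {
    r <- arch[arch$family == f, ]
    c(r$hepn1, r$hepn2)
  }
  cand_a <- synth_family_member(seeds[7], msas$cas13a$ancestor, 0.10, off("cas13a"))
  cand_b <- synth_family_member(seeds[8], msas$cas13b$ancestor, 0.10, off("cas13b"))
  novel_anc <- synth_family_member(seeds[9], msas$cas13a$ancestor, 0.65, off("cas13a"))
  cand_n <- synth_family_member(seeds[10], novel_anc, 0.05, off("cas13a"))
  cas1_gene <- synth_family_member(seeds[11], cas1_msa$ancestor, 0.10)
  cas2_gene <- synth_family_member(seeds[12], cas2_msa$ancestor, 0.10)
  d_short <- decoy_protein(seeds[13], "short", msas$cas13a$ancestor, off("cas13a"))
  d_single <- decoy_protein(seeds[14], "single_hepn", msas$cas13b$ancestor, off("cas13b"))
  d_nohepn <- decoy_protein(seeds[15], "no_hepn")
  d_shuffled <- decoy_protein(seeds[16], "shuffled", msas$cas13a$ancestor, off("cas13a"))

  dr36 <- function(seed) with_rng_seed(seed, paste(random_dna_chars(36L), collapse = ""))

  loci <- list(
    ctg_a = locus_spec(seeds[21], 48000L,
      array = list(repeat_seq = dr36(seeds[26]), spacer_len = 30L, n_units = 5L,
                   mutation_rate = 0.03, pos = 24000L),
      genes = list(
        list(id = "cand_a", family = "cas13a", kind = "candidate",
             protein = cand_a, strand = "+", pos = 16000L,
             hepn_offsets = off("cas13a")),
        list(id = "cas1_a", family = "cas1", kind = "adaptation",
             protein = cas1_gene, strand = "+", pos = 30000L),
        list(id = "cas2_a", family = "cas2", kind = "adaptation",
             protein = cas2_gene, strand = "+", pos = 31500L)
      )),
    ctg_b = locus_spec(seeds[22], 40000L,
      array = list(repeat_seq = dr36(seeds[27]), spacer_len = 30L, n_units = 4L,
                   mutation_rate = 0.05, pos = 20000L),
      genes = list(
        list(id = "cand_b", family = "cas13b", kind = "candidate",
             protein = cand_b, strand = "-", pos = 12000L,
             hepn_offsets = off("cas13b"))
      )),
    ctg_n = locus_spec(seeds[23], 40000L,
      array = list(repeat_seq = dr36(seeds[28]), spacer_len = 30L, n_units = 6L,
                   mutation_rate = 0, pos = 18000L),
      genes = list(
        list(id = "cand_n", family = "novel", kind = "candidate",
             protein = cand_n, strand = "+", pos = 26000L,
             hepn_offsets = off("cas13a"))
      )),
    ctg_d1 = locus_spec(seeds[24], 30000L,
      array = list(repeat_seq = dr36(seeds[29]), spacer_len = 30L, n_units = 3L,
                   mutation_rate = 0, pos = 15000L),
      genes = list(
        list(id = "decoy_short", kind = "decoy_short", protein = d_short,
             strand = "+", pos = 8000L),
        list(id = "decoy_single_hepn", kind = "decoy_single_hepn",
             protein = d_single, strand = "+", pos = 20000L)
      )),
    ctg_d2 = locus_spec(seeds[25], 30000L,
      array = list(repeat_seq = dr36(seeds[30]), spacer_len = 30L, n_units = 3L,
                   mutation_rate = 0, pos = 15000L),
      genes = list(
        list(id = "decoy_no_hepn", kind = "decoy_no_hepn", protein = d_nohepn,
             strand = "+", pos = 9000L),
        list(id = "decoy_shuffled", kind = "decoy_shuffled", protein = d_shuffled,
             strand = "-", pos = 20000L)
      ))
  )
  built <- lapply(loci, synth_contig)
  contigs <- bind_rows(lapply(built, `[[`, "contig"))
  contigs$id <- names(loci)  # stable, human-readable contig ids
  truth <- lapply(built, `[[`, "truth")
  for (nm in names(truth)) {
    if (!is.null(truth[[nm]]$array)) truth[[nm]]$array$contig_id <- nm
    if (!is.null(truth[[nm]]$genes)) truth[[nm]]$genes$contig_id <- nm
  }

  sp_a <- truth$ctg_a$array$spacers[[1]]
  tdb <- synth_target_db(seeds[31], n_targets = 2L, target_len = 8000L,
                         planted_spacers = tibble(
                           spacer_id = sprintf("ctg_a_spacer%d", 1:2),
                           seq = sp_a$seq[1:2],
                           strand = c("+", "-")))

  candidates <- bind_rows(lapply(truth, function(tr) {
    if (is.null(tr$genes)) return(NULL)
    filter(tr$genes, .data$kind == "candidate")
  }))

  list(contigs = contigs, truth = truth, msas = msas,
       cas1_msa = cas1_msa, cas2_msa = cas2_msa,
       references = references, candidates = candidates,
       targets = tdb$targets, target_placements = tdb$placements)
}
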