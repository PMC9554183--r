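# Independent brute-force oracles used across the suite. Each oracle is a
# deliberately naive re-derivation from first principles, sharing no code
# path with the implementation it checks.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES_T <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES_T, n, replace = TRUE), collapse = "")
rand_protein <- function(n) paste(sample(AA20_T, n, replace = TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# --- k-mer census oracle ----------------------------------------------------
oracle_seed_kmers <- function(seq, k, min_units, gap_min, gap_max) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- list()
  if (L < k) return(out)
  kmers <- vapply(1:(L - k + 1), function(i) {
    paste(chars[i:(i + k - 1)], collapse = "")
  }, character(1))
  for (km in unique(kmers)) {
    if (grepl("N", km, fixed = TRUE)) next
    pos <- which(kmers == km) - 1L
    if (length(pos) < min_units) next
    gaps <- diff(pos)
    if (all(gaps >= gap_min & gaps <= gap_max)) out[[km]] <- pos
  }
  out
}

# --- six-frame ORF oracle ---------------------------------------------------
oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

oracle_codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  function(codon) {
    aa <- unname(gc[codon])
    if (is.na(aa)) "X" else aa
  }
})

oracle_orfs <- function(seq, min_len_aa, starts = c("ATG", "GTG", "TTG")) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3
      if (n_cod < 2) next
      codons <- vapply(0:(n_cod - 1), function(c0) {
        substr(s, f + 3 * c0 + 1, f + 3 * c0 + 3)
      }, character(1))
      aas <- vapply(codons, oracle_codon_aa, character(1))
      stop_at <- which(aas == "*")
      for (t in stop_at) {
        prev_stops <- stop_at[stop_at < t]
        lo <- if (length(prev_stops) == 0) 1 else max(prev_stops) + 1
        cand <- lo:(t - 1)
        cand <- cand[cand <= t - 1 & cand >= lo]
        cand <- cand[codons[cand] %in% starts]
        if (length(cand) == 0) next
        s0 <- min(cand)  # longest ORF for this stop
        if (t - s0 < min_len_aa) next
        prot <- aas[s0:(t - 1)]
        prot[1] <- "M"
        start_local <- f + 3 * (s0 - 1)
        end_local <- f + 3 * t
        rows[[length(rows) + 1L]] <- data.frame(
          start = if (strand == "+") start_local else L - end_local,
          end = if (strand == "+") end_local else L - start_local,
          strand = strand, frame = f,
          protein = paste(prot, collapse = ""),
          length_aa = t - s0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), protein = character(), length_aa = integer())
  } else {
    do.call(rbind, rows)
  }
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# --- profile-HMM path enumeration ------------------------------------------
# Total (or maximum) probability over all global state paths, by recursion on
# (state type, state index, residues emitted). Probability space, not logs.
oracle_hmm_score <- function(hmm, protein, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  x <- match(strsplit(protein, "", fixed = TRUE)[[1]], AA20_T)
  T_ <- length(x)
  n <- hmm$n_match
  tr <- hmm$transitions
  me <- hmm$match_emissions
  ie <- hmm$insert_emissions
  comb <- if (mode == "forward") sum else max
  # value of being IN state (type, j) with i residues already emitted
  # (the arriving emission has been paid), continuing to the end state
  rec <- function(type, j, i) {
    opts <- numeric(0)
    if (type == "M" || type == "I") {
      p_m <- if (type == "M") tr$mm[j + 1] else tr$im[j + 1]
      p_i <- if (type == "M") tr$mi[j + 1] else tr$ii[j + 1]
      # to M_{j+1} (or End)
      if (j + 1 <= n) {
        if (i + 1 <= T_) {
          opts <- c(opts, p_m * me[j + 1, x[i + 1]] * rec("M", j + 1, i + 1))
        }
      } else {
        if (i == T_) opts <- c(opts, p_m)
      }
      # to I_j
      if (i + 1 <= T_) {
        opts <- c(opts, p_i * ie[j + 1, x[i + 1]] * rec("I", j, i + 1))
      }
      # to D_{j+1}
      if (type == "M" && j + 1 <= n) {
        opts <- c(opts, tr$md[j + 1] * rec("D", j + 1, i))
      }
    } else {  # D_j
      if (j + 1 <= n) {
        if (i + 1 <= T_) {
          opts <- c(opts, tr$dm[j + 1] * me[j + 1, x[i + 1]] * rec("M", j + 1, i + 1))
        }
        opts <- c(opts, tr$dd[j + 1] * rec("D", j + 1, i))
      } else {
        if (i == T_) opts <- c(opts, tr$dm[j + 1])
      }
    }
    if (length(opts) == 0) 0 else comb(opts)
  }
  p <- rec("M", 0, 0)
  log2(p) - T_ * log2(1 / 20)
}

# --- brute-force global alignment ------------------------------------------
# All optimal global alignments under match/mismatch/linear-gap scoring;
# returns the best score and the set of identities realised by optimal
# alignments (identical columns / alignment length).
oracle_global_alignments <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric(0)
  rec <- function(i, j, score, ident, len) {
    if (i > length(ac) && j > length(bc)) {
      if (score > best$score + 1e-12) {
        best$score <- score
        best$idents <- ident / len
      } else if (abs(score - best$score) <= 1e-12) {
        best$idents <- unique(c(best$idents, ident / len))
      }
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      rec(i + 1, j + 1, score + s, ident + (ac[i] == bc[j]), len + 1)
    }
    if (i <= length(ac)) rec(i + 1, j, score + gap, ident, len + 1)
    if (j <= length(bc)) rec(i, j + 1, score + gap, ident, len + 1)
  }
  rec(1, 1, 0, 0, 0)
  list(score = best$score, identities = best$idents)
}

# --- naive UPGMA ------------------------------------------------------------
# Cluster distances recomputed from the ORIGINAL matrix as the plain mean
# over all cross-cluster leaf pairs (the defining property), rather than the
# incremental update rule.
oracle_upgma_cophenetic <- function(dm) {
  ids <- rownames(dm)
  clusters <- lapply(ids, identity)
  coph <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  while (length(clusters) > 1) {
    m <- length(clusters)
    bi <- bj <- 1; bd <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        dd <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dd < bd - 1e-15) { bd <- dd; bi <- i; bj <- j }
      }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- bd
    coph[clusters[[bj]], clusters[[bi]]] <- bd
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# --- Nussinov brute force ---------------------------------------------------
oracle_can_pair <- function(a, b, allow_gu = TRUE) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "GC", "CG") || (allow_gu && p %in% c("GU", "UG"))
}

oracle_max_pairs <- function(rna, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(chartr("T", "U", rna), "", fixed = TRUE)[[1]]
  memo <- new.env()
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (oracle_can_pair(s[i], s[k], allow_gu)) {
        left <- if (k - 1 >= i + 1) f(i + 1, k - 1) else 0L
        right <- if (k < j) f(k + 1, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    memo[[key]] <- best
    best
  }
  if (length(s) <= min_loop + 1) return(0L)
  f(1L, length(s))
}

# --- sliding-window oracles -------------------------------------------------
oracle_rx4h <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 6) return(integer(0))
  which(chars[1:(n - 5)] == "R" & chars[6:n] == "H") - 1L
}

oracle_spacer_hits <- function(spacer, target, max_mm) {
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else oracle_revcomp(spacer)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    w <- length(qc)
    if (w > length(tc)) next
    for (p in 0:(length(tc) - w)) {
      mm <- sum(tc[(p + 1):(p + w)] != qc)
      if (mm <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = p, end = p + w, strand = strand, mismatches = mm)
      }
    }
  }
  if (length(hits) == 0) {
    data.frame(start = integer(), end = integer(), strand = character(),
               mismatches = integer())
  } else {
    do.call(rbind, hits)
  }
}

# small aligned-MSA profile fixtures used in several files
toy_msa3 <- c("MKV", "M-V", "MRV")

with_seed_dna <- function(seed, n) {
  set.seed(seed)
  rand_dna(n)
}

# Hand-assemble an array contig with identifiable boundaries: the column of
# bases immediately before each repeat unit and immediately after each unit
# is forced to all-distinct bases so column-wise extension stops exactly at
# the planted repeat.
make_array_contig <- function(R, spacers, bg_len = 300) {
  n <- length(spacers) + 1
  stopifnot(n <= 4)
  pre <- vapply(seq_along(spacers), function(i) {
    sp <- spacers[[i]]
    substr(sp, nchar(sp), nchar(sp)) <- BASES_T[i + 1]
    substr(sp, 1, 1) <- BASES_T[i]
    sp
  }, character(1))
  left_bg <- rand_dna(bg_len)
  right_bg <- rand_dna(bg_len)
  substr(left_bg, bg_len, bg_len) <- BASES_T[1]
  substr(right_bg, 1, 1) <- BASES_T[n]
  # boundary columns: before units = {T1..}, after units = {..}
  body <- R
  for (i in seq_along(pre)) body <- paste0(body, pre[i], R)
  list(seq = paste0(left_bg, body, right_bg),
       start = bg_len, end = bg_len + nchar(body))
}

with_seed_protein <- function(seed, len, hepn = integer()) {
  synth_family_msa(seed, "tmp", n_seqs = 1, mutation_rate = 0,
                   length_aa = len, hepn_offsets = hepn)$ancestor
}
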