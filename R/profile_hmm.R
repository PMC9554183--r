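# Profile hidden Markov models of Cas protein families.
#
# Minimal Krogh-style architecture: match states from alignment columns with
# gap fraction below a threshold, insert/delete states around them, add-one
# pseudocounts on emissions and transitions, uniform 1/20 background, global
# alignment of the whole protein to the profile. Scores are log-odds in bits.
# The DP kernels live in compiled code; tests compare them against exhaustive
# path enumeration.

aa_index <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20) - 1L
  idx[is.na(idx)] <- -1L  # non-standard residue: background emission
  idx
}

#' Build a profile HMM from a family multiple sequence alignment
#'
#' Alignment columns with gap fraction strictly below `gap_frac_threshold`
#' become match states; residues in the remaining columns are assigned to the
#' flanking insert state. Emissions are `(count + 1) / (total + 20)` (add-one
#' pseudocounts over the 20 standard amino acids); transitions are estimated
#' from the observed per-sequence state paths with add-one pseudocounts over
#' each state's admissible moves.
#'
#' @param msa Aligned sequences: a tibble with columns `id`, `seq`, or a
#'   (optionally named) character vector. Gap characters are `-` and `.`.
#' @param family Family label stored on the profile.
#' @param gap_frac_threshold Columns with gap fraction below this become
#'   match states.
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(msa, family, gap_frac_threshold = 0.5) {
  check_string(family, "family")
  if (is.data.frame(msa)) msa <- setNames(msa$seq, msa$id)
  msa <- as.character(msa)
  if (length(msa) == 0L) abort("empty MSA")
  msa <- toupper(msa)
  if (length(unique(nchar(msa))) != 1L) abort("aligned sequences must have equal length")
  msa <- gsub(".", "-", msa, fixed = TRUE)
  bad <- grepl(sprintf("[^%s-]", paste(AA20, collapse = "")), msa)
  if (any(bad)) abort("MSA contains characters outside the 20 amino acids + gap")

  m <- seq_matrix(msa)
  nseq <- nrow(m)
  gap_frac <- colMeans(m == "-")
  is_match <- gap_frac < gap_frac_threshold
  n <- sum(is_match)
  if (n == 0L) abort("no match columns at this gap threshold")

  # emissions
  match_cols <- which(is_match)
  me <- matrix(0, nrow = n, ncol = 20L, dimnames = list(NULL, AA20))
  for (s in seq_len(n)) {
    res <- m[, match_cols[s]]
    res <- res[res != "-"]
    cnt <- table(factor(res, levels = AA20))
    me[s, ] <- (as.numeric(cnt) + 1) / (length(res) + 20)
  }
  # insert state of each column: number of match columns strictly before it
  ins_state <- cumsum(is_match)  # for non-match column c, state = ins_state[c]
  ie <- matrix(0, nrow = n + 1L, ncol = 20L, dimnames = list(NULL, AA20))
  for (j in 0:n) {
    cols <- which(!is_match & ins_state == j)
    res <- as.vector(m[, cols, drop = FALSE])
    res <- res[res != "-"]
    cnt <- table(factor(res, levels = AA20))
    ie[j + 1L, ] <- (as.numeric(cnt) + 1) / (length(res) + 20)
  }

  # transition counts from per-sequence state paths
  cnt0 <- function() numeric(n + 1L)
  cmm <- cnt0(); cmi <- cnt0(); cmd <- cnt0()
  cim <- cnt0(); cii <- cnt0()
  cdm <- cnt0(); cdd <- cnt0()
  for (r in seq_len(nseq)) {
    states <- list(c("M", 0L))  # begin
    j <- 0L
    for (col in seq_len(ncol(m))) {
      ch <- m[r, col]
      if (is_match[col]) {
        j <- j + 1L
        states[[length(states) + 1L]] <- c(if (ch == "-") "D" else "M", j)
      } else if (ch != "-") {
        states[[length(states) + 1L]] <- c("I", j)
      }
    }
    states[[length(states) + 1L]] <- c("M", n + 1L)  # end, counts as M move
    for (t in seq_len(length(states) - 1L)) {
      a <- states[[t]]; b <- states[[t + 1L]]
      ja <- as.integer(a[2]) + 1L  # index into length-(n+1) vectors
      key <- paste0(a[1], b[1])
      switch(key,
        MM = cmm[ja] <- cmm[ja] + 1,
        MI = cmi[ja] <- cmi[ja] + 1,
        MD = cmd[ja] <- cmd[ja] + 1,
        IM = cim[ja] <- cim[ja] + 1,
        II = cii[ja] <- cii[ja] + 1,
        DM = cdm[ja] <- cdm[ja] + 1,
        DD = cdd[ja] <- cdd[ja] + 1,
        # the reduced architecture has no D->I / I->D edges; such adjacencies
        # (gap beside an occupied insert column) are not counted
        DI = NULL,
        ID = NULL,
        abort(sprintf("impossible state transition %s", key))
      )
    }
  }
  # add-one over each state's admissible moves; at j = n the moves M->D and
  # D->D do not exist and D_n -> M(end) is certain
  tmm <- numeric(n + 1L); tmi <- numeric(n + 1L); tmd <- numeric(n + 1L)
  tim <- numeric(n + 1L); tii <- numeric(n + 1L)
  tdm <- numeric(n + 1L); tdd <- numeric(n + 1L)
  for (jj in 1:(n + 1L)) {
    interior <- jj <= n
    if (interior) {
      tot <- cmm[jj] + cmi[jj] + cmd[jj] + 3
      tmm[jj] <- (cmm[jj] + 1) / tot
      tmi[jj] <- (cmi[jj] + 1) / tot
      tmd[jj] <- (cmd[jj] + 1) / tot
    } else {
      tot <- cmm[jj] + cmi[jj] + 2
      tmm[jj] <- (cmm[jj] + 1) / tot
      tmi[jj] <- (cmi[jj] + 1) / tot
      tmd[jj] <- 0
    }
    toti <- cim[jj] + cii[jj] + 2
    tim[jj] <- (cim[jj] + 1) / toti
    tii[jj] <- (cii[jj] + 1) / toti
    if (jj >= 2L) {
      if (interior) {
        totd <- cdm[jj] + cdd[jj] + 2
        tdm[jj] <- (cdm[jj] + 1) / totd
        tdd[jj] <- (cdd[jj] + 1) / totd
      } else {
        tdm[jj] <- 1
        tdd[jj] <- 0
      }
    }
  }

  hmm <- structure(list(
    family = family,
    n_match = n,
    match_emissions = me,
    insert_emissions = ie,
    transitions = list(mm = tmm, mi = tmi, md = tmd,
                       im = tim, ii = tii, dm = tdm, dd = tdd),
    background = setNames(rep(1 / 20, 20L), AA20),
    consensus = paste(AA20[apply(me, 1L, which.max)], collapse = "")
  ), class = "profile_hmm")
  validate_profile(hmm)
  hmm
}

validate_profile <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  n <- hmm$n_match
  if (n < 1L) abort("profile must have at least one match state")
  rows_ok <- function(mat) all(abs(rowSums(mat) - 1) < 1e-9) && all(mat > 0)
  if (!rows_ok(hmm$match_emissions) || !rows_ok(hmm$insert_emissions)) {
    abort("emission rows must be positive and sum to 1")
  }
  tr <- hmm$transitions
  for (jj in 1:(n + 1L)) {
    m_sum <- tr$mm[jj] + tr$mi[jj] + tr$md[jj]
    i_sum <- tr$im[jj] + tr$ii[jj]
    if (abs(m_sum - 1) > 1e-9 || abs(i_sum - 1) > 1e-9) {
      abort("transition rows must sum to 1")
    }
    if (jj >= 2L && abs(tr$dm[jj] + tr$dd[jj] - 1) > 1e-9) {
      abort("transition rows must sum to 1")
    }
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match states, consensus %s\n",
              x$family, x$n_match,
              if (nchar(x$consensus) > 40) paste0(substr(x$consensus, 1, 40), "...")
              else x$consensus))
  invisible(x)
}

hmm_log_pieces <- function(hmm) {
  lg <- function(v) ifelse(v > 0, log(v), -Inf)
  tr <- hmm$transitions
  list(
    log_me = lg(hmm$match_emissions),
    log_ie = lg(hmm$insert_emissions),
    log_bg = lg(unname(hmm$background)),
    t_mm = lg(tr$mm), t_mi = lg(tr$mi), t_md = lg(tr$md),
    t_im = lg(tr$im), t_ii = lg(tr$ii),
    t_dm = c(-Inf, lg(tr$dm[-1])), t_dd = c(-Inf, lg(tr$dd[-1]))
  )
}

#' Forward log-odds score of a protein against a profile
#'
#' Sums over all global state paths; returns
#' `log2(P(seq | profile) / P(seq | background))` in bits. Non-standard
#' residues (B, J, O, U, X, Z) emit the background probability and are
#' score-neutral.
#'
#' @param hmm A `profile_hmm`.
#' @param protein Amino-acid string (non-empty).
#' @return Bit score (finite double).
#' @export
score_forward <- function(hmm, protein) {
  validate_profile(hmm)
  check_string(protein, "protein")
  x <- aa_index(toupper(protein))
  p <- hmm_log_pieces(hmm)
  logp <- .phmm_forward(x, hmm$n_match, p$log_me, p$log_ie, p$log_bg,
                        p$t_mm, p$t_mi, p$t_md, p$t_im, p$t_ii, p$t_dm, p$t_dd)
  (logp - length(x) * log(1 / 20)) / log(2)
}

#' Viterbi score and state path of a protein against a profile
#'
#' As [score_forward()] but maximising over state paths. The returned path
#' (e.g. `c("M1", "M2", "I2", "D3")`) re-evaluates to the returned score via
#' [score_path()].
#'
#' @inheritParams score_forward
#' @return A list with `bit_score` and `path` (character vector of states).
#' @export
score_viterbi <- function(hmm, protein) {
  validate_profile(hmm)
  check_string(protein, "protein")
  x <- aa_index(toupper(protein))
  p <- hmm_log_pieces(hmm)
  v <- .phmm_viterbi(x, hmm$n_match, p$log_me, p$log_ie, p$log_bg,
                     p$t_mm, p$t_mi, p$t_md, p$t_im, p$t_ii, p$t_dm, p$t_dd)
  list(bit_score = (v$logp - length(x) * log(1 / 20)) / log(2),
       path = v$path)
}

#' Log-odds score of one explicit state path
#'
#' @inheritParams score_forward
#' @param path Character vector of states as returned by [score_viterbi()].
#' @return Bit score of that single path.
#' @export
score_path <- function(hmm, protein, path) {
  validate_profile(hmm)
  x <- aa_index(toupper(protein))
  p <- hmm_log_pieces(hmm)
  state <- sub("[0-9]+$", "", path)
  jj <- as.integer(sub("^[A-Z]", "", path))
  logp <- 0
  prev <- c("M", 0L)
  i <- 0L
  trans_lp <- function(a, aj, b) {
    switch(paste0(a, b),
      MM = p$t_mm[aj + 1L], MI = p$t_mi[aj + 1L], MD = p$t_md[aj + 1L],
      IM = p$t_im[aj + 1L], II = p$t_ii[aj + 1L],
      DM = p$t_dm[aj + 1L], DD = p$t_dd[aj + 1L],
      abort("impossible transition in path"))
  }
  for (t in seq_along(path)) {
    logp <- logp + trans_lp(prev[1], as.integer(prev[2]), state[t])
    if (state[t] %in% c("M", "I")) {
      i <- i + 1L
      res <- x[i]
      emis <- if (state[t] == "M") p$log_me[jj[t], , drop = TRUE] else p$log_ie[jj[t] + 1L, , drop = TRUE]
      logp <- logp + if (res < 0) p$log_bg[1] else emis[res + 1L]
    }
    prev <- c(state[t], jj[t])
  }
  if (i != length(x)) abort("path does not emit the whole sequence")
  logp <- logp + trans_lp(prev[1], as.integer(prev[2]), "M")  # to end
  unname((logp - length(x) * log(1 / 20)) / log(2))
}

#' Search proteins against a profile library
#'
#' Every (protein, family) pair with forward bit score at or above
#' `bit_threshold` is reported as a hit; per protein the highest-scoring
#' family is flagged `best` (ties broken by family label order).
#'
#' @param proteins Tibble with columns `protein_id`, `protein`.
#' @param library A list of `profile_hmm` objects (non-empty).
#' @param bit_threshold Acceptance threshold in bits.
#' @return A tibble `protein_id`, `family`, `bit_score`, `best`.
#' @export
search_library <- function(proteins, library, bit_threshold = 20) {
  if (length(library) == 0L) abort("empty profile library")
  stopifnot(is.data.frame(proteins))
  fams <- vapply(library, function(h) h$family, character(1))
  if (anyDuplicated(fams)) abort("duplicate family labels in library")
  library <- library[order(fams)]
  fams <- sort(fams)
  empty <- tibble(protein_id = character(), family = character(),
                  bit_score = double(), best = logical())
  if (nrow(proteins) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    scores <- vapply(library, score_forward, numeric(1),
                     protein = proteins$protein[i])
    hit <- scores >= bit_threshold
    if (!any(hit)) next
    best_fam <- fams[which.max(scores)]  # which.max: first maximum, label order
    rows[[length(rows) + 1L]] <- tibble(
      protein_id = proteins$protein_id[i],
      family = fams[hit],
      bit_score = unname(scores[hit]),
      best = fams[hit] == best_fam
    )
  }
  if (length(rows) == 0L) return(empty)
  bind_rows(rows)
}

#' Flag Cas1/Cas2 adaptation genes among flanking ORFs
#'
#' @param flank_orfs ORF tibble with a `protein` column (may be empty).
#' @param cas1_profile,cas2_profile `profile_hmm` objects for the adaptation
#'   genes.
#' @param bit_threshold Acceptance threshold in bits.
#' @return A list with logical flags `cas1_present`, `cas2_present`.
#' @export
detect_adaptation_genes <- function(flank_orfs, cas1_profile, cas2_profile,
                                    bit_threshold = 20) {
  present <- function(profile) {
    if (is.null(profile) || nrow(flank_orfs) == 0L) return(FALSE)
    any(vapply(flank_orfs$protein, function(pr) {
      score_forward(profile, pr) >= bit_threshold
    }, logical(1)))
  }
  list(cas1_present = present(cas1_profile), cas2_present = present(cas2_profile))
}

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = "\t")

#' Serialise a profile library to a plain-text file
#'
#' One block per family: match/insert emissions and transition rows as
#' tab-separated natural-log probabilities, terminated by `//`.
#'
#' @param library List of `profile_hmm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cas13scout profile library v1", con)
  for (hmm in library) {
    validate_profile(hmm)
    writeLines(sprintf(">family\t%s\tn_match\t%d", hmm$family, hmm$n_match), con)
    writeLines("MATCH_EMISSIONS", con)
    for (s in seq_len(hmm$n_match)) writeLines(fmt_nums(log(hmm$match_emissions[s, ])), con)
    writeLines("INSERT_EMISSIONS", con)
    for (s in seq_len(hmm$n_match + 1L)) writeLines(fmt_nums(log(hmm$insert_emissions[s, ])), con)
    for (nm in c("mm", "mi", "md", "im", "ii", "dm", "dd")) {
      v <- hmm$transitions[[nm]]
      writeLines(sprintf("TRANS\t%s\t%s", nm, fmt_nums(ifelse(v > 0, log(v), -Inf))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a profile library written by [write_profile_library()]
#'
#' @param path Path to the library file.
#' @return A list of `profile_hmm` objects.
#' @export
read_profile_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  i <- 1L
  parse_nums <- function(s) as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]])
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (hdr[1] != ">family") abort(sprintf("bad library block header at line %d", i))
    family <- hdr[2]
    n <- as.integer(hdr[4])
    i <- i + 1L
    stopifnot(lines[i] == "MATCH_EMISSIONS")
    me <- t(vapply(lines[(i + 1L):(i + n)], parse_nums, numeric(20L)))
    i <- i + n + 1L
    stopifnot(lines[i] == "INSERT_EMISSIONS")
    ie <- t(vapply(lines[(i + 1L):(i + n + 1L)], parse_nums, numeric(20L)))
    i <- i + n + 2L
    tr <- list()
    for (k in 1:7) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      stopifnot(parts[1] == "TRANS")
      tr[[parts[2]]] <- exp(as.numeric(parts[-(1:2)]))
      i <- i + 1L
    }
    stopifnot(lines[i] == "//")
    i <- i + 1L
    dimnames(me) <- list(NULL, AA20)
    dimnames(ie) <- list(NULL, AA20)
    me <- exp(me)
    ie <- exp(ie)
    hmm <- structure(list(
      family = family, n_match = n,
      match_emissions = me, insert_emissions = ie,
      transitions = tr,
      background = setNames(rep(1 / 20, 20L), AA20),
      consensus = paste(AA20[apply(me, 1L, which.max)], collapse = "")
    ), class = "profile_hmm")
    validate_profile(hmm)
    out[[family]] <- hmm
  }
  out
}
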