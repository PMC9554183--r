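# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All fixture generators route their randomness through this so that a
# generator is a pure function of its seed.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`rng_seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Reverse complement of an uppercase DNA string (N-safe).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", what))
  }
  invisible(x)
}

check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(as.integer(x))
}

# Columns of equal-length strings as a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  n <- length(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) abort("sequences must have equal length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = len, byrow = TRUE)
}

# Majority base of a character vector with the deterministic A<C<G<T tie rule.
majority_base <- function(chars, alphabet = DNA_BASES) {
  counts <- table(factor(chars, levels = alphabet))
  alphabet[which.max(counts)]
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}
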