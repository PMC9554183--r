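# Sequence and annotation I/O.
#
# All coordinates inside the package are 0-based half-open on the contig
# forward strand; GFF3 output is 1-based inclusive. The conversion lives
# here and nowhere else.

#' Read a DNA FASTA file into a contig table
#'
#' Sequences are uppercased, `U` is converted to `T` (RNA-coded DNA input),
#' and record order is preserved. Only `A`, `C`, `G`, `T`, `N` are accepted
#' after normalisation.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A tibble with columns `id`, `seq`, `length`, one row per record.
#'   An empty file yields a zero-row tibble.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(tibble(id = character(), seq = character(), length = integer()))
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf("malformed FASTA: sequence line before any header at line %d", first))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) abort("malformed FASTA: empty record id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA record id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- unname(chartr("u", "t", toupper(as.character(set))))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("contig %s contains characters outside {A,C,G,T,N}", ids[which(bad)[1]]))
  }
  tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write contigs (or any named sequences) to FASTA
#'
#' @param x A tibble with columns `id` and `seq` (DNA or protein).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write genomic features as GFF3
#'
#' Features use the package's internal 0-based half-open convention and are
#' emitted 1-based inclusive per the GFF3 specification.
#'
#' @param features A tibble with columns `contig_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `type` (e.g. `CRISPR_array`,
#'   `CDS`, `HEPN_motif`); any further columns become GFF3 attributes.
#' @param path Output path.
#' @param contig_lengths Optional named integer vector; when given, every
#'   interval is validated against its contig bound.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, contig_lengths = NULL) {
  stopifnot(is.data.frame(features))
  req <- c("contig_id", "start", "end", "strand", "type")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols) > 0L && nrow(features) > 0L) {
    abort(sprintf("features is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(features$start < 0L) || any(features$end <= features$start)) {
    abort("invalid interval: need 0 <= start < end")
  }
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[features$contig_id]
    if (any(is.na(lim)) || any(features$end > lim)) {
      abort("interval outside contig bounds")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$source <- "cas13scout"
  extra <- setdiff(names(features), c(req, "source"))
  for (col in extra) {
    val <- features[[col]]
    if (is.list(val)) val <- vapply(val, function(v) paste(v, collapse = ","), character(1))
    S4Vectors::mcols(gr)[[col]] <- val
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into the internal feature convention
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with `contig_id`, `start` (0-based), `end` (exclusive),
#'   `strand`, `type` and one column per attribute.
#' @export
read_gff3 <- function(path) {
  check_string(path, "path")
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character(), type = character()))
  }
  out <- tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (col in setdiff(names(mc), c("type", "source", "score", "phase"))) {
    out[[col]] <- mc[[col]]
  }
  out
}

#' Write a tibble as a UTF-8, tab-delimited report
#'
#' @param x A data frame; list-columns are collapsed with commas.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], function(v) paste(unlist(v), collapse = ","), character(1))
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
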