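# End-to-end discovery pipeline: arrays -> flanks -> ORFs -> length filter
# -> profile-HMM search -> dual-HEPN filter -> subtype classification ->
# DR/spacer characterisation -> candidate report.

pipeline_defaults <- function() {
  list(
    seed_k = 8L, repeat_len_min = 23L, repeat_len_max = 50L,
    spacer_len_min = 20L, spacer_len_max = 60L, min_units = 3L,
    max_repeat_mismatch_frac = 0.2,
    flank_nt = 20000L, min_orf_aa = 80L, min_protein_aa = 400L,
    bit_threshold = 20, adaptation_bit_threshold = 20,
    hepn_min_separation_aa = 100L, ntd_offset_aa = 250L,
    taxonomy_cut_height = 0.35, max_spacer_mismatches = 3L
  )
}

#' Assemble a validated pipeline configuration
#'
#' @param ... Overrides of the default keys (see [validate_config()] for the
#'   key list). Unknown keys are rejected with a suggestion.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- pipeline_defaults()
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) {
      near <- agrep(key, names(cfg), max.distance = 0.3, value = TRUE)
      hint <- if (length(near) > 0L) sprintf(" (did you mean '%s'?)", near[1]) else ""
      abort(sprintf("unknown config key '%s'%s", key, hint))
    }
    cfg[[key]] <- overrides[[key]]
  }
  int_keys <- c("seed_k", "repeat_len_min", "repeat_len_max", "spacer_len_min",
                "spacer_len_max", "min_units", "flank_nt", "min_orf_aa",
                "min_protein_aa", "hepn_min_separation_aa", "ntd_offset_aa",
                "max_spacer_mismatches")
  for (key in int_keys) cfg[[key]] <- check_count(cfg[[key]], key, 0L)
  pos_keys <- c("seed_k", "repeat_len_min", "repeat_len_max", "spacer_len_min",
                "spacer_len_max", "min_units", "flank_nt", "min_orf_aa",
                "min_protein_aa", "bit_threshold", "hepn_min_separation_aa",
                "ntd_offset_aa", "taxonomy_cut_height")
  for (key in pos_keys) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      abort(sprintf("config key '%s' must be positive", key))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with any subset of the configuration keys; missing keys take
#' the package defaults (20 kb flanks, >400-aa protein filter, 20-bit HMM
#' threshold, 100-aa HEPN separation, 250-aa NTD offset, 0.35 taxonomy cut).
#' Unknown keys are rejected, naming the closest known key.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

array_params_from_config <- function(config) {
  array_params(
    seed_k = config$seed_k,
    repeat_len_min = config$repeat_len_min,
    repeat_len_max = config$repeat_len_max,
    spacer_len_min = config$spacer_len_min,
    spacer_len_max = config$spacer_len_max,
    min_units = config$min_units,
    max_repeat_mismatch_frac = config$max_repeat_mismatch_frac
  )
}

#' Run the Cas13 discovery pipeline end to end
#'
#' Executes array detection, flank extraction, six-frame ORF calling, the
#' strict `min_protein_aa` length filter, the profile-HMM library search, HEPN
#' annotation with the dual-HEPN completeness filter, Cas1/Cas2 adjacency
#' flags, UPGMA subtype classification against the references, DR
#' consensus/structure analysis, and optional spacer-to-target matching.
#' The run is fully deterministic for fixed inputs and configuration.
#'
#' @param config A `pipeline_config` (or `NULL` for defaults).
#' @param contigs Contig tibble (`id`, `seq`), e.g. from [read_fasta()].
#' @param library List of Cas13-family `profile_hmm` objects.
#' @param references Tibble `protein_id`, `family`, `protein` used to anchor
#'   subtype labels.
#' @param targets Optional target tibble (`id`, `seq`) for protospacer
#'   matching.
#' @param adaptation_profiles Optional list with `cas1` and/or `cas2`
#'   `profile_hmm` objects for adaptation-gene flags.
#' @param out_dir Optional directory; when given, GFF3/TSV/Newick/FASTA
#'   artifacts and a run log are written there.
#' @return An object of class `cas13_report`: `candidates` (one row per
#'   surviving protein), `counts` (stage funnel), plus the intermediate
#'   `arrays`, `orfs`, `hits`, `hepn`, `subtypes`, `dr_profiles`,
#'   `spacer_hits`, `tree` and the `config`.
#' @export
run_discovery <- function(config = NULL, contigs, library, references,
                          targets = NULL, adaptation_profiles = NULL,
                          out_dir = NULL) {
  config <- config %||% pipeline_config()
  stopifnot(inherits(config, "pipeline_config"))
  if (length(library) == 0L) abort("empty profile library")

  params <- array_params_from_config(config)
  arrays <- detect_arrays(contigs, params)
  orfs <- call_flank_orfs(contigs, arrays, flank_nt = config$flank_nt,
                          min_len_aa = config$min_orf_aa)
  long_orfs <- filter_candidate_proteins(orfs, config$min_protein_aa)
  hits <- search_library(
    select(long_orfs, "protein_id", "protein"),
    library, bit_threshold = config$bit_threshold
  )
  best_hits <- filter(hits, .data$best)
  hit_orfs <- filter(long_orfs, .data$protein_id %in% best_hits$protein_id)
  hepn <- annotate_hepn(select(hit_orfs, "protein_id", "protein"),
                        min_separation_aa = config$hepn_min_separation_aa,
                        ntd_offset_aa = config$ntd_offset_aa)
  survivors <- filter(hepn, .data$dual_hepn)
  surv_orfs <- filter(hit_orfs, .data$protein_id %in% survivors$protein_id)

  counts <- tibble(
    stage = c("arrays", "orfs", paste0("proteins_gt", config$min_protein_aa),
              "hmm_hits", "dual_hepn"),
    n = c(nrow(arrays), nrow(orfs), nrow(long_orfs),
          nrow(dplyr::distinct(hits, .data$protein_id)), nrow(survivors))
  )

  # subtype classification of survivors against the references
  subtypes <- NULL
  tree <- NULL
  if (nrow(surv_orfs) > 0L) {
    pool <- bind_rows(
      select(surv_orfs, "protein_id", "protein"),
      select(references, "protein_id", "protein")
    )
    dm <- build_distance_matrix(pool)
    tree <- upgma(dm)
    subtypes <- assign_subtypes(tree, references,
                                cut_height = config$taxonomy_cut_height)
  }

  # per-locus adaptation flags and DR/spacer analyses
  cand_rows <- list()
  dr_profiles <- list()
  spacer_hit_rows <- list()
  if (nrow(surv_orfs) > 0L) {
    for (i in seq_len(nrow(surv_orfs))) {
      orf <- surv_orfs[i, ]
      arr <- arrays |>
        filter(.data$contig_id == orf$contig_id,
               .data$start == orf$array_start, .data$end == orf$array_end)
      locus_orfs <- filter(orfs, .data$contig_id == orf$contig_id,
                           .data$array_start == orf$array_start)
      adapt <- detect_adaptation_genes(
        locus_orfs,
        adaptation_profiles$cas1, adaptation_profiles$cas2,
        bit_threshold = config$adaptation_bit_threshold
      )
      drp <- dr_consensus(arr$repeat_units[[1]]$seq)
      fold <- fold_dr_orientations(drp)
      dr_profiles[[orf$protein_id]] <- list(profile = drp, fold = fold)

      sp_hits <- NULL
      n_proto <- 0L
      if (!is.null(targets) && nrow(arr$spacers[[1]]) > 0L) {
        spac <- arr$spacers[[1]] |>
          mutate(spacer_id = sprintf("%s_array%d_sp%d", orf$contig_id,
                                     arr$start, row_number())) |>
          select("spacer_id", "seq")
        spac <- filter(spac, nchar(.data$seq) >= 15L)
        if (nrow(spac) > 0L) {
          sp_hits <- match_spacers(spac, targets,
                                   max_mismatches = config$max_spacer_mismatches)
          n_proto <- nrow(sp_hits)
          if (n_proto > 0L) {
            spacer_hit_rows[[orf$protein_id]] <-
              mutate(sp_hits, protein_id = orf$protein_id)
          }
        }
      }

      sub_row <- subtypes[subtypes$protein_id == orf$protein_id, ]
      hepn_row <- hepn[hepn$protein_id == orf$protein_id, ]
      best_row <- best_hits[best_hits$protein_id == orf$protein_id, ]
      cand_rows[[length(cand_rows) + 1L]] <- tibble(
        protein_id = orf$protein_id,
        contig_id = orf$contig_id,
        start = orf$start, end = orf$end, strand = orf$strand,
        length_aa = orf$length_aa,
        array_start = orf$array_start, array_end = orf$array_end,
        array_n_units = arr$n_units,
        repeat_consensus = arr$repeat_consensus,
        mean_spacer_len = arr$mean_spacer_len,
        best_family = best_row$family, bit_score = best_row$bit_score,
        n_hepn_motifs = hepn_row$n_motifs,
        dual_hepn = hepn_row$dual_hepn,
        ntd_present = hepn_row$ntd_present,
        predicted_dr_side = hepn_row$predicted_dr_side,
        subtype = sub_row$subtype, novel = sub_row$novel,
        cas1_present = adapt$cas1_present, cas2_present = adapt$cas2_present,
        n_protospacer_hits = n_proto,
        dr_fold_pairs = fold$forward$n_pairs,
        overlaps_array = orf$overlaps_array
      )
    }
  }
  candidates <- if (length(cand_rows) == 0L) {
    tibble(protein_id = character(), contig_id = character(),
           start = integer(), end = integer(), strand = character(),
           length_aa = integer(), array_start = integer(),
           array_end = integer(), array_n_units = integer(),
           repeat_consensus = character(), mean_spacer_len = double(),
           best_family = character(), bit_score = double(),
           n_hepn_motifs = integer(), dual_hepn = logical(),
           ntd_present = logical(), predicted_dr_side = character(),
           subtype = character(), novel = logical(),
           cas1_present = logical(), cas2_present = logical(),
           n_protospacer_hits = integer(), dr_fold_pairs = integer(),
           overlaps_array = logical())
  } else {
    arrange(bind_rows(cand_rows), .data$contig_id, .data$start)
  }

  # funnel conservation sanity check
  n <- setNames(counts$n, counts$stage)
  stopifnot(n["dual_hepn"] <= n["hmm_hits"],
            n["hmm_hits"] <= n[3L],
            n[3L] <= n["orfs"])

  report <- structure(list(
    candidates = candidates, counts = counts, config = config,
    arrays = arrays, orfs = orfs, hits = hits, hepn = hepn,
    subtypes = subtypes, tree = tree, dr_profiles = dr_profiles,
    spacer_hits = if (length(spacer_hit_rows) > 0L) bind_rows(spacer_hit_rows) else NULL
  ), class = "cas13_report")

  if (!is.null(out_dir)) write_report_artifacts(report, contigs, out_dir)
  report
}

#' @export
print.cas13_report <- function(x, ...) {
  cat("Cas13 discovery report\n")
  cat(sprintf("  %s\n", paste(sprintf("%s: %d", x$counts$stage, x$counts$n),
                              collapse = " -> ")))
  cat(sprintf("  surviving candidates: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates) > 0L) {
    print(select(x$candidates, "protein_id", "length_aa", "best_family",
                 "bit_score", "subtype", "novel", "predicted_dr_side"))
  }
  invisible(x)
}

#' @describeIn run_discovery Tidy the candidate table of a report.
#' @param x A `cas13_report`.
#' @param ... Unused.
#' @method tidy cas13_report
#' @export
tidy.cas13_report <- function(x, ...) x$candidates

#' @describeIn run_discovery One-row stage-count summary of a report.
#' @method glance cas13_report
#' @export
glance.cas13_report <- function(x, ...) {
  out <- as.list(setNames(x$counts$n, x$counts$stage))
  out$n_candidates <- nrow(x$candidates)
  out$n_novel <- sum(x$candidates$novel)
  as_tibble(out)
}

write_report_artifacts <- function(report, contigs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(contigs$length %||% nchar(contigs$seq), contigs$id)
  arrays_to_gff3(report$arrays, file.path(out_dir, "arrays.gff3"), lens)
  write_tsv_report(select(report$arrays, -"repeat_units", -"spacers"),
                   file.path(out_dir, "arrays.tsv"))
  if (nrow(report$orfs) > 0L) {
    write_gff3(report$orfs |>
                 mutate(type = "CDS", ID = .data$protein_id, phase = 0L) |>
                 select("contig_id", "start", "end", "strand", "type", "ID",
                        "phase"),
               file.path(out_dir, "orfs.gff3"), lens)
    write_fasta(report$orfs |> rename(id = "protein_id", seq = "protein"),
                file.path(out_dir, "proteins.faa"))
  }
  if (nrow(report$hits) > 0L) {
    write_tsv_report(report$hits, file.path(out_dir, "hmm_hits.tsv"))
  }
  if (nrow(report$hepn) > 0L) {
    write_tsv_report(hepn_report(report$hepn), file.path(out_dir, "hepn.tsv"))
  }
  if (!is.null(report$tree)) {
    write_newick(report$tree, file.path(out_dir, "subtypes.nwk"))
    write_tsv_report(report$subtypes, file.path(out_dir, "subtypes.tsv"))
  }
  if (!is.null(report$spacer_hits)) {
    write_tsv_report(report$spacer_hits, file.path(out_dir, "protospacer_hits.tsv"))
  }
  write_tsv_report(report$candidates, file.path(out_dir, "candidates.tsv"))
  write_tsv_report(report$counts, file.path(out_dir, "stage_counts.tsv"))
  cfg <- unclass(report$config)
  log_lines <- c(
    sprintf("cas13scout %s", as.character(utils::packageVersion("cas13scout"))),
    sprintf("config_hash\t%s", config_hash(report$config)),
    sprintf("config\t%s", paste(sprintf("%s=%s", names(cfg), unlist(cfg)),
                                collapse = " ")),
    sprintf("input_checksum\t%s\t%s", contigs$id,
            vapply(contigs$seq, function(s) {
              as.character(tools::md5sum(textfile(s)))
            }, character(1))),
    sprintf("stage\t%s\t%d", report$counts$stage, report$counts$n)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

textfile <- function(s) {
  f <- tempfile()
  writeLines(s, f)
  f
}

config_hash <- function(config) {
  cfg <- unclass(config)
  as.character(tools::md5sum(textfile(paste(names(cfg), unlist(cfg),
                                            collapse = ";"))))
}
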