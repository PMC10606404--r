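#' Run the four-phase gap-recall pipeline
#'
#' Phase 1 scans the chromosome-level assembly and the merged contig set
#' for single-copy markers and takes the set difference to find fillable
#' genes; phase 2 locates each fillable gene's host contig and anchors that
#' contig to a chromosome interval via whole-genome alignment; phase 3
#' recalls the reads aligned to the lost contig and to the anchor's
#' chromosome neighborhood, reassembles them and selects the candidate
#' carrying the intact gene; phase 4 aligns each candidate back to the
#' chromosomes, validates gene placement and coverage, splices candidates
#' in positional order with offset bookkeeping, and re-scans the edited
#' assembly to verify that completeness did not regress. The edited
#' assembly is written to `config$out_dir` only when the regression check
#' passes (or `force = TRUE`).
#'
#' @param config A `pipeline_config` (see [pipeline_config()],
#'   [load_config()]). Inputs may be file paths or in-memory objects.
#' @param verbose Emit per-phase progress messages.
#' @return Invisibly, a list: `assembly` (edited DNAStringSet), `ledger`
#'   (`edit_ledger`), `summary` (named list of counts and per-gene
#'   outcomes), `before_table`, `after_table`, `regions`, `verification`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  op <- options(contigrecall.verbose = verbose)
  on.exit(options(op))
  t0 <- proc.time()[["elapsed"]]
  phase_times <- c()
  tick <- function(phase) {
    t1 <- proc.time()[["elapsed"]]
    phase_times[[phase]] <<- round(t1 - t0, 2)
    t0 <<- t1
    log_msg("finished ", phase, " (", phase_times[[phase]], "s)")
  }

  chrom_asm <- load_sequences(config$chrom_assembly)
  contig_sets <- lapply(config$contig_sets, load_sequences)
  reads <- load_sequences(config$reads)
  catalog <- if (is.character(config$catalog)) {
    read_marker_catalog(config$catalog, config$min_fragment_fraction)
  } else config$catalog
  adapters <- resolve_adapters(config, catalog)
  tick("load")

  # Phase 1: completeness scans and fillable-gene set difference
  merged_contigs <- merge_contig_sets(contig_sets)
  chrom_table <- adapters$assessor(chrom_asm)
  contig_table <- adapters$assessor(merged_contigs)
  fillable <- fillable_genes(chrom_table, contig_table,
                             include_fragmented = config$include_fragmented)
  tick("phase1_prepare")

  # Phase 2: locate host contigs and anchor them to the chromosomes
  aln_ctg_chrom <- if (length(fillable) > 0) {
    adapters$aligner(merged_contigs, chrom_asm)
  } else alignment_table()
  regions <- build_missing_regions(fillable, contig_table, merged_contigs,
                                   aln_ctg_chrom, config$min_anchor_matches)
  tick("phase2_locate")

  # Phase 3: recall reads, reassemble, pick gene-complete candidates
  missing0 <- missing_genes(chrom_table)
  gene_outcomes <- stats::setNames(rep("skipped_not_fillable", length(missing0)),
                                   missing0)
  gene_outcomes[fillable] <- "skipped_no_candidate"
  selections <- list()
  if (length(regions) > 0) {
    aln_reads_ctg <- adapters$aligner(reads, merged_contigs)
    aln_reads_chrom <- adapters$aligner(reads, chrom_asm)
    for (ri in seq_along(regions)) {
      region <- regions[[ri]]
      rs <- recall_reads(region, aln_reads_ctg, aln_reads_chrom, reads,
                         flank_bp = config$flank_bp,
                         min_overlap_bp = config$min_overlap_bp)
      log_msg("region ", region$contig_id, ": recalled ", length(rs$reads),
              " reads for gene(s) ", paste(region$gene_ids, collapse = ","))
      if (length(rs$reads) == 0) next
      cands <- adapters$assembler(rs$reads)
      names(cands) <- sprintf("r%02d_%s", ri, names(cands))
      for (g in region$gene_ids) {
        sel <- select_candidate(cands, g, catalog,
                                scan_fn = function(seqs, cat1) adapters$assessor(seqs))
        if (!is.null(sel)) {
          selections[[g]] <- list(candidate = sel, region = region)
        }
      }
    }
  }
  tick("phase3_recall")

  # Phase 4: align candidates back, validate, splice in positional order
  events <- list()
  if (length(selections) > 0) {
    cand_bases <- vapply(selections, function(s) s$candidate$bases, "")
    cand_ids <- vapply(selections, function(s) s$candidate$id, "")
    keep <- !duplicated(cand_ids)
    cand_set <- as_dna(stats::setNames(cand_bases[keep], cand_ids[keep]))
    aln_cand_chrom <- adapters$aligner(cand_set, chrom_asm)
    sel_ord <- selections[order_selections(selections)]
    events <- lapply(seq_along(sel_ord), function(i) {
      s <- sel_ord[[i]]
      plan_replacement(s$candidate, names(sel_ord)[i], s$region$anchor,
                       aln_cand_chrom, config$min_query_coverage)
    })
  }
  edited <- apply_replacements(chrom_asm, events)
  for (ev in edited$ledger$events) gene_outcomes[[ev$gene_id]] <- ev$status
  tick("phase4_replace")

  after_table <- adapters$assessor(edited$assembly)
  verification <- verify_no_regression(chrom_table, after_table)
  recovered <- intersect(missing_genes(chrom_table),
                         setdiff(chrom_table$gene_id, missing_genes(after_table)))
  summary <- list(
    n_fillable = length(fillable), fillable = fillable,
    n_regions = length(regions),
    n_anchored = sum(vapply(regions, function(r) !is.null(r$anchor), logical(1))),
    recalls_attempted = length(fillable),
    recalls_succeeded = length(selections),
    events_by_status = table(vapply(edited$ledger$events, `[[`, "", "status")),
    gene_outcomes = gene_outcomes,
    recovered_genes = sort(recovered),
    n_recovered = length(recovered),
    missing_before = verification$missing_before,
    missing_after = verification$missing_after,
    regression_ok = verification$ok,
    phase_seconds = phase_times)
  tick("verify")

  if (!is.null(config$out_dir)) {
    if (verification$ok || isTRUE(config$force)) {
      write_pipeline_outputs(config$out_dir, edited, summary)
    } else {
      warning("regression check failed; final assembly not written ",
              "(use force = TRUE to override)", call. = FALSE)
    }
  }
  invisible(list(assembly = edited$assembly, ledger = edited$ledger,
                 summary = summary, before_table = chrom_table,
                 after_table = after_table, regions = regions,
                 verification = verification))
}

#' Process selections by (chromosome, anchor start), unanchored last
#' @noRd
order_selections <- function(selections) {
  key <- t(vapply(selections, function(s) {
    a <- s$region$anchor
    if (is.null(a)) c("~~unanchored", sprintf("%012d", 0)) else
      c(a$chrom_id, sprintf("%012d", a$start))
  }, character(2)))
  order(key[, 1], key[, 2], names(selections))
}

#' @noRd
load_sequences <- function(x) {
  if (!is.character(x)) return(as_dna(x))
  if (grepl("\\.(fq|fastq)$", x, ignore.case = TRUE)) read_fastq(x) else read_fasta(x)
}

#' @noRd
write_pipeline_outputs <- function(out_dir, edited, summary) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(edited$assembly, file.path(out_dir, "final_assembly.fasta"))
  ev <- edited$ledger$events
  ev_df <- data.frame(
    gene_id = vapply(ev, `[[`, "", "gene_id"),
    status = vapply(ev, `[[`, "", "status"),
    chrom_id = vapply(ev, function(e) e$chrom_id %||% NA_character_, ""),
    old_start = vapply(ev, function(e) as.integer(e$start %||% NA), integer(1)),
    old_end = vapply(ev, function(e) as.integer(e$end %||% NA), integer(1)),
    new_len = vapply(ev, function(e)
      if (is.na(e$new_bases)) NA_integer_ else nchar(e$new_bases), integer(1)),
    candidate_id = vapply(ev, function(e) e$candidate_id %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  utils::write.table(ev_df, file.path(out_dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(events = ev_df,
         offsets = edited$ledger$offsets,
         summary = summary[c("n_fillable", "fillable", "n_regions",
                             "n_anchored", "recalls_succeeded",
                             "gene_outcomes", "recovered_genes",
                             "missing_before", "missing_after",
                             "regression_ok")]),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    force = TRUE)
  invisible(out_dir)
}
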