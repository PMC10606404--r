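REPLACEMENT_STATUSES <- c("applied", "skipped_no_alignment",
                          "skipped_gene_outside_alignment",
                          "skipped_low_coverage", "skipped_overlap",
                          "skipped_no_candidate")

#' @noRd
replacement_event <- function(gene_id, status, chrom_id = NA_character_,
                              start = NA_integer_, end = NA_integer_,
                              new_bases = NA_character_,
                              candidate_id = NA_character_,
                              strand = NA_character_) {
  assert_that(status %in% REPLACEMENT_STATUSES, "unknown replacement status ", status)
  structure(list(gene_id = gene_id, status = status, chrom_id = chrom_id,
                 start = as.integer(start), end = as.integer(end),
                 new_bases = new_bases, candidate_id = candidate_id,
                 strand = strand),
            class = "replacement_event")
}

#' Plan the splice of a candidate sequence into the chromosome assembly
#'
#' Chooses the candidate-to-chromosome alignment with most residue matches
#' among those overlapping the region's anchor interval (genome-wide when
#' the region is unanchored), then validates it: the alignment's query span
#' must cover at least `min_query_coverage` of the candidate (guarding
#' against repeat-arm-only alignments), and the gene interval must lie
#' fully inside the aligned query span — a gene outside the alignment is
#' the method's named failure mode and yields a skip, never a splice. On
#' success the event replaces the alignment's target interval with the
#' candidate's aligned bases, reverse-complemented for minus-strand
#' alignments so `new_bases` is always on the chromosome forward strand.
#'
#' @param candidate A `candidate_sequence` from [select_candidate()].
#' @param gene_id Target gene id.
#' @param anchor `chromosome_anchor` of the region, or `NULL`.
#' @param cand_to_chrom Candidate-to-chromosome alignment data frame.
#' @param min_query_coverage Minimum fraction of the candidate covered by
#'   the chosen alignment's query span.
#' @return A `replacement_event`; all failure modes are statuses, not
#'   errors.
#' @export
plan_replacement <- function(candidate, gene_id, anchor, cand_to_chrom,
                             min_query_coverage = 0.8) {
  assert_that(identical(candidate$gene_status, "Complete"),
              "candidate gene status must be Complete before planning a splice")
  aln <- cand_to_chrom[cand_to_chrom$query_id == candidate$id, , drop = FALSE]
  if (!is.null(anchor)) {
    aln <- aln[aln$target_id == anchor$chrom_id &
                 interval_overlap(aln$target_start, aln$target_end,
                                  anchor$start, anchor$end) > 0, , drop = FALSE]
  }
  if (nrow(aln) == 0)
    return(replacement_event(gene_id, "skipped_no_alignment",
                             candidate_id = candidate$id))
  best <- aln[order(-aln$residue_matches, -aln$block_len, aln$target_id,
                    aln$target_start)[1], , drop = FALSE]
  qspan <- best$query_end - best$query_start
  if (qspan < min_query_coverage * best$query_len)
    return(replacement_event(gene_id, "skipped_low_coverage",
                             chrom_id = best$target_id,
                             candidate_id = candidate$id))
  if (candidate$gene_start < best$query_start ||
      candidate$gene_end > best$query_end)
    return(replacement_event(gene_id, "skipped_gene_outside_alignment",
                             chrom_id = best$target_id,
                             candidate_id = candidate$id))
  new_bases <- substr(candidate$bases, best$query_start + 1L, best$query_end)
  if (best$strand == "-") new_bases <- reverse_complement(new_bases)
  replacement_event(gene_id, "applied", chrom_id = best$target_id,
                    start = best$target_start, end = best$target_end,
                    new_bases = new_bases, candidate_id = candidate$id,
                    strand = best$strand)
}

#' Apply planned replacements to the assembly with offset bookkeeping
#'
#' Events are processed in the order given (the pipeline orders them by
#' chromosome and anchor position, unanchored last). An applied event whose
#' target interval overlaps an earlier accepted event on the same
#' chromosome is demoted to `skipped_overlap`. Splices are then performed
#' left-to-right per chromosome; untouched bases are preserved exactly and
#' the returned ledger records, per chromosome, the offset segments mapping
#' pre-edit to post-edit coordinates for untouched loci.
#'
#' @param assembly [Biostrings::DNAStringSet] of chromosomes.
#' @param events List of `replacement_event`s (see [plan_replacement()]).
#' @return List with `assembly` (edited DNAStringSet) and `ledger`
#'   (class `edit_ledger`: `events` — all events, demotions included — and
#'   `offsets`, a per-chromosome data frame of untouched segments
#'   old_start/old_end/shift).
#' @export
apply_replacements <- function(assembly, events) {
  assembly_chars <- as.character(as_dna(assembly))
  accepted <- list()
  out_events <- events
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$status != "applied") next
    if (!ev$chrom_id %in% names(assembly_chars))
      abort("replacement targets unknown chromosome ", ev$chrom_id)
    clen <- nchar(assembly_chars[[ev$chrom_id]])
    if (ev$start < 0 || ev$end > clen || ev$start >= ev$end)
      abort("replacement interval [", ev$start, ",", ev$end,
            ") out of bounds on ", ev$chrom_id, " (length ", clen, ")")
    clash <- any(vapply(accepted, function(a) {
      a$chrom_id == ev$chrom_id &&
        interval_overlap(a$start, a$end, ev$start, ev$end) > 0
    }, logical(1)))
    if (clash) {
      ev$status <- "skipped_overlap"
      ev$new_bases <- NA_character_
      out_events[[i]] <- ev
      next
    }
    accepted[[length(accepted) + 1L]] <- ev
  }

  offsets <- list()
  for (ch in names(assembly_chars)) {
    evs <- Filter(function(a) a$chrom_id == ch, accepted)
    clen <- nchar(assembly_chars[[ch]])
    if (length(evs) == 0) {
      offsets[[ch]] <- data.frame(old_start = 0L, old_end = clen, shift = 0L)
      next
    }
    ord <- order(vapply(evs, `[[`, integer(1), "start"))
    evs <- evs[ord]
    pieces <- character(0)
    seg <- list()
    cursor <- 0L
    shift <- 0L
    for (ev in evs) {
      pieces <- c(pieces, substr(assembly_chars[[ch]], cursor + 1L, ev$start))
      seg[[length(seg) + 1L]] <- data.frame(old_start = cursor,
                                            old_end = ev$start, shift = shift)
      pieces <- c(pieces, ev$new_bases)
      shift <- shift + nchar(ev$new_bases) - (ev$end - ev$start)
      cursor <- ev$end
    }
    pieces <- c(pieces, substring(assembly_chars[[ch]], cursor + 1L))
    seg[[length(seg) + 1L]] <- data.frame(old_start = cursor, old_end = clen,
                                          shift = shift)
    assembly_chars[[ch]] <- paste(pieces, collapse = "")
    offsets[[ch]] <- do.call(rbind, seg)
  }
  ledger <- structure(list(events = out_events, offsets = offsets),
                      class = "edit_ledger")
  list(assembly = as_dna(assembly_chars), ledger = ledger)
}

#' Map a pre-edit position to its post-edit coordinate
#'
#' @param ledger An `edit_ledger` from [apply_replacements()].
#' @param chrom_id Chromosome id.
#' @param pos 0-based pre-edit position(s).
#' @return Integer post-edit position(s); `NA` for loci inside a replaced
#'   interval (no well-defined image).
#' @export
ledger_map_position <- function(ledger, chrom_id, pos) {
  seg <- ledger$offsets[[chrom_id]]
  if (is.null(seg)) abort("no ledger entry for chromosome ", chrom_id)
  out <- rep(NA_integer_, length(pos))
  for (r in seq_len(nrow(seg))) {
    inside <- pos >= seg$old_start[r] & pos < seg$old_end[r]
    out[inside] <- as.integer(pos[inside] + seg$shift[r])
  }
  out
}

#' Verify that an edit did not reduce completeness
#'
#' A gene worsened when its status moved down the lattice
#' Complete > Duplicated > Fragmented > Missing. The check passes when no
#' gene worsened and the Missing count did not increase.
#'
#' @param before,after [gene_status_table()]s over the same catalog.
#' @return List: `ok`, `worsened` (data frame gene_id/before/after),
#'   `missing_before`, `missing_after`.
#' @export
verify_no_regression <- function(before, after) {
  rank <- c(Complete = 3L, Duplicated = 2L, Fragmented = 1L, Missing = 0L)
  sb <- gene_statuses(before)
  sa <- gene_statuses(after)
  genes <- intersect(names(sb), names(sa))
  if (!setequal(names(sb), names(sa)))
    warning("before/after tables cover different gene universes; ",
            "comparing the intersection", call. = FALSE)
  worse <- genes[rank[sa[genes]] < rank[sb[genes]]]
  worsened <- data.frame(gene_id = worse, before = unname(sb[worse]),
                         after = unname(sa[worse]), stringsAsFactors = FALSE)
  mb <- length(missing_genes(before))
  ma <- length(missing_genes(after))
  list(ok = nrow(worsened) == 0 && ma <= mb, worsened = worsened,
       missing_before = mb, missing_after = ma)
}
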