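#' Locate a fillable gene on its host contig
#'
#' A Complete gene has a unique hit; a Duplicated gene (the common case in
#' a merged multi-assembler contig set, where each assembler recovers its
#' own copy of the region) is resolved to one host contig deterministically
#' by taking the hit with the highest score, ties broken by
#' lexicographically smaller contig id and smaller start.
#'
#' @param gene_id Gene identifier.
#' @param contig_table [gene_status_table()] of the merged contig set.
#' @return List with `contig_id`, `start`, `end`, `strand` (0-based
#'   half-open interval of the gene on the contig).
#' @export
locate_gene_in_contigs <- function(gene_id, contig_table) {
  hits <- gene_hits(contig_table, gene_id)
  if (nrow(hits) == 0) abort("gene ", gene_id, " not present in the contig table")
  if (!all(hits$status %in% c("Complete", "Duplicated")))
    abort("gene ", gene_id, " is ", hits$status[1],
          " in the contig set; only full-length genes have a usable location")
  best <- hits[order(-hits$score, hits$sequence_id, hits$start)[1], , drop = FALSE]
  list(contig_id = best$sequence_id, start = best$start,
       end = best$end, strand = best$strand)
}

#' Select the chromosome anchor alignment for a lost contig
#'
#' Among contig-to-chromosome records for `contig_id`, primary alignments
#' (`tp:A:P`, or all records when no `tp` flag is present) passing the
#' `min_anchor_matches` floor are ranked by residue matches, ties broken by
#' greater block length, then lexicographically smaller target id, then
#' smaller target start. A pure function of its inputs.
#'
#' @param contig_id Contig identifier.
#' @param alignments Contig-to-chromosome alignment data frame.
#' @param min_anchor_matches Minimum residue matches for a usable anchor.
#' @return List of class `chromosome_anchor` (`chrom_id`, `start`, `end`,
#'   `strand`, `chrom_len`, `alignment`), or `NULL` when no alignment
#'   qualifies.
#' @export
select_anchor_alignment <- function(contig_id, alignments,
                                    min_anchor_matches = 500) {
  cand <- alignments[alignments$query_id == contig_id, , drop = FALSE]
  if (any(!is.na(cand$tp))) cand <- cand[!is.na(cand$tp) & cand$tp == "P", , drop = FALSE]
  cand <- cand[cand$residue_matches >= min_anchor_matches, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ord <- order(-cand$residue_matches, -cand$block_len, cand$target_id,
               cand$target_start)
  best <- cand[ord[1], , drop = FALSE]
  structure(list(chrom_id = best$target_id, start = best$target_start,
                 end = best$target_end, strand = best$strand,
                 chrom_len = best$target_len, alignment = best),
            class = "chromosome_anchor")
}

#' Build missing genomic regions from fillable genes
#'
#' The missing genomic region is defined as the whole contig hosting at
#' least one fillable gene (so that read recall later captures the entire
#' lost segment, not just the gene). Genes on the same contig are grouped
#' into one region; each region carries a chromosome anchor when one of its
#' contig's alignments qualifies, and is retained unanchored otherwise.
#'
#' @param fillable Character vector of fillable gene ids
#'   (see [fillable_genes()]).
#' @param contig_table [gene_status_table()] of the merged contig set.
#' @param contigs [Biostrings::DNAStringSet] of the merged contig set.
#' @param contig_to_chrom Contig-to-chromosome alignment data frame.
#' @param min_anchor_matches Passed to [select_anchor_alignment()].
#' @return List of `missing_region` objects, ordered by contig id; each has
#'   `contig_id`, `contig_len`, `gene_ids`, `gene_intervals` (data frame)
#'   and `anchor` (a `chromosome_anchor` or `NULL`).
#' @export
build_missing_regions <- function(fillable, contig_table, contigs,
                                  contig_to_chrom, min_anchor_matches = 500) {
  if (length(fillable) == 0) return(list())
  locs <- lapply(sort(fillable), locate_gene_in_contigs, contig_table = contig_table)
  loc_df <- data.frame(
    gene_id = sort(fillable),
    contig_id = vapply(locs, `[[`, "", "contig_id"),
    start = vapply(locs, `[[`, integer(1), "start"),
    end = vapply(locs, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE)
  missing_ctg <- setdiff(unique(loc_df$contig_id), names(contigs))
  if (length(missing_ctg) > 0)
    abort("contig(s) named in the contig table are absent from the contig set: ",
          paste(missing_ctg, collapse = ", "))
  lapply(sort(unique(loc_df$contig_id)), function(ctg) {
    rows <- loc_df[loc_df$contig_id == ctg, , drop = FALSE]
    clen <- Biostrings::width(contigs)[match(ctg, names(contigs))]
    if (any(rows$end > clen))
      abort("gene interval exceeds contig length on ", ctg)
    anchor <- select_anchor_alignment(ctg, contig_to_chrom, min_anchor_matches)
    structure(list(contig_id = ctg, contig_len = as.integer(clen),
                   gene_ids = rows$gene_id,
                   gene_intervals = rows[, c("gene_id", "start", "end")],
                   anchor = anchor),
              class = "missing_region")
  })
}
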