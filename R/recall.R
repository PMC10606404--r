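#' Reads whose alignments overlap a target interval
#'
#' @param alignments Read-to-target alignment data frame.
#' @param target_id Target sequence id.
#' @param interval Numeric length-2 vector, 0-based half-open.
#' @param min_overlap_bp Minimum overlap in bp for a read to count.
#' @return Character vector of unique query (read) ids.
#' @export
reads_overlapping_interval <- function(alignments, target_id, interval,
                                       min_overlap_bp = 1) {
  keep <- alignments$target_id == target_id &
    interval_overlap(alignments$target_start, alignments$target_end,
                     interval[1], interval[2]) >= min_overlap_bp
  sort(unique(alignments$query_id[keep]))
}

#' Recall the reads associated with a missing genomic region
#'
#' Unions reads aligned anywhere on the lost contig with, when the region is
#' anchored, reads aligned to the anchor's chromosome neighborhood (the
#' anchor interval widened by `flank_bp` on both sides, clamped to the
#' chromosome). Reads recalled from both sources are merged once with
#' provenance `both`.
#'
#' @param region A `missing_region` (see [build_missing_regions()]).
#' @param reads_to_contigs Read-to-contig alignment data frame.
#' @param reads_to_chrom Read-to-chromosome alignment data frame.
#' @param reads [Biostrings::DNAStringSet] of all reads, ids unique.
#' @param flank_bp Neighborhood flank around the anchor interval.
#' @param min_overlap_bp Minimum alignment overlap for recall.
#' @return List of class `recall_set`: `region`, `reads` (DNAStringSet),
#'   `provenance` (data frame read_id/source with source in
#'   contig/chromosome_neighborhood/both).
#' @export
recall_reads <- function(region, reads_to_contigs, reads_to_chrom, reads,
                         flank_bp = 50000, min_overlap_bp = 1) {
  assert_that(!anyDuplicated(names(reads)), "read ids must be unique")
  from_ctg <- reads_overlapping_interval(reads_to_contigs, region$contig_id,
                                         c(0, region$contig_len), min_overlap_bp)
  from_chrom <- character()
  if (!is.null(region$anchor)) {
    a <- region$anchor
    win <- c(max(0, a$start - flank_bp), min(a$chrom_len, a$end + flank_bp))
    from_chrom <- reads_overlapping_interval(reads_to_chrom, a$chrom_id, win,
                                             min_overlap_bp)
  }
  ids <- sort(union(from_ctg, from_chrom))
  absent <- setdiff(ids, names(reads))
  if (length(absent) > 0)
    abort("recalled read id(s) absent from the read set: ",
          paste(utils::head(absent, 5), collapse = ", "))
  source <- ifelse(ids %in% from_ctg & ids %in% from_chrom, "both",
                   ifelse(ids %in% from_ctg, "contig", "chromosome_neighborhood"))
  structure(list(region = region, reads = reads[ids],
                 provenance = data.frame(read_id = ids, source = source,
                                         stringsAsFactors = FALSE)),
            class = "recall_set")
}

#' Greedy exact-overlap assembler for noise-free reads
#'
#' A deterministic overlap-layout assembler valid on exact (error-free)
#' reads: reads contained in another read are removed, then contigs are
#' grown seed-and-extend style. Seeds are taken longest-first (ties by
#' lexicographically smaller id); at each step the unused read with the
#' longest exact suffix-prefix overlap (>= `min_olap`, either end, either
#' strand) is merged, and reads that become contained in the growing contig
#' are retired. Terminates when no merge is possible; every input read is
#' accounted for by exactly one output contig.
#'
#' @param reads [Biostrings::DNAStringSet] or named character vector.
#' @param min_olap Minimum exact overlap in bp to merge two sequences.
#' @param id_prefix Prefix for output contig ids.
#' @return A [Biostrings::DNAStringSet] of assembled sequences, longest
#'   first.
#' @export
toy_assemble <- function(reads, min_olap = 500, id_prefix = "asmctg") {
  reads <- as.character(as_dna(reads))
  assert_that(length(reads) >= 1, "toy_assemble needs at least one read")
  ord <- order(-nchar(reads), names(reads))
  reads <- reads[ord]

  # containment pass: a read (either strand) inside a longer kept read is redundant
  kept <- character(0)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (length(kept) > 0 &&
        (any(grepl(r, kept, fixed = TRUE)) ||
         any(grepl(reverse_complement(r), kept, fixed = TRUE)))) next
    kept <- c(kept, stats::setNames(r, names(reads)[i]))
  }

  n <- length(kept)
  rc <- vapply(kept, reverse_complement, "", USE.NAMES = FALSE)
  lens <- nchar(kept)
  unused <- rep(TRUE, n)
  contigs <- character(0)
  while (any(unused)) {
    seed_i <- which(unused)[1]
    contig <- kept[[seed_i]]
    unused[seed_i] <- FALSE
    # containment re-checks only need the part of the contig that changed
    check_window <- contig
    repeat {
      if (any(unused)) {
        rem <- which(unused)
        contained <- vapply(rem, function(j) {
          grepl(kept[[j]], check_window, fixed = TRUE) ||
            grepl(rc[[j]], check_window, fixed = TRUE)
        }, logical(1))
        unused[rem[contained]] <- FALSE
      }
      if (!any(unused)) break
      rem <- which(unused)
      best_len <- 0L; best_j <- 0L; best_cfg <- 0L
      for (j in rem) {
        b <- kept[[j]]
        rb <- rc[[j]]
        cfgs <- c(suffix_prefix_overlap(contig, b, min_olap),
                  suffix_prefix_overlap(b, contig, min_olap),
                  suffix_prefix_overlap(contig, rb, min_olap),
                  suffix_prefix_overlap(rb, contig, min_olap))
        m <- max(cfgs)
        if (m > best_len) {
          best_len <- m; best_j <- j; best_cfg <- which.max(cfgs)
        }
      }
      if (best_len < min_olap) break
      b <- kept[[best_j]]
      rb <- rc[[best_j]]
      contig <- switch(best_cfg,
                       merge_overlap(contig, b, best_len),
                       merge_overlap(b, contig, best_len),
                       merge_overlap(contig, rb, best_len),
                       merge_overlap(rb, contig, best_len))
      wl <- lens[best_j] + max(c(lens[unused], 0L))
      check_window <- if (best_cfg %in% c(1L, 3L)) {
        substring(contig, max(1L, nchar(contig) - wl + 1L))
      } else {
        substr(contig, 1L, min(nchar(contig), wl))
      }
      unused[best_j] <- FALSE
    }
    contigs <- c(contigs, contig)
  }
  contigs <- contigs[order(-nchar(contigs))]
  as_dna(stats::setNames(contigs, sprintf("%s%03d", id_prefix, seq_along(contigs))))
}

#' Longest exact suffix(a)/prefix(b) overlap of length >= min_olap, else 0
#' @noRd
suffix_prefix_overlap <- function(a, b, min_olap) {
  na <- nchar(a); nb <- nchar(b)
  if (na < min_olap || nb < min_olap) return(0L)
  if (na > nb) {            # an overlap cannot exceed nchar(b)
    a <- substring(a, na - nb + 1L)
    na <- nb
  }
  probe <- substr(b, 1L, min_olap)
  hits <- gregexpr(probe, a, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  for (i in hits) {                       # ascending start => descending overlap
    len <- na - i + 1L
    if (len > nb) next                    # b would be contained, not a dovetail
    if (substring(a, i) == substr(b, 1L, len)) return(len)
  }
  0L
}

#' @noRd
merge_overlap <- function(a, b, olap) {
  paste0(a, substring(b, olap + 1L))
}

#' Assemble candidates from a recall set
#'
#' @param recall_set A `recall_set` from [recall_reads()].
#' @param assembler Function mapping a read DNAStringSet to an assembled
#'   DNAStringSet; defaults to the built-in [toy_assemble()]. External
#'   assemblers are wrapped via [external_assembler()].
#' @param ... Passed to the assembler.
#' @return [Biostrings::DNAStringSet] of candidate sequences.
#' @export
assemble_candidates <- function(recall_set, assembler = toy_assemble, ...) {
  assert_that(length(recall_set$reads) >= 1,
              "recall set for contig ", recall_set$region$contig_id,
              " contains no reads")
  assembler(recall_set$reads, ...)
}

#' Select the candidate sequence carrying an intact gene
#'
#' Scans every candidate for the target gene and returns the longest
#' candidate on which the gene is Complete (ties broken by
#' lexicographically smaller candidate id); `NULL` when no candidate
#' carries the intact gene (a failed recall for this gene).
#'
#' @param candidates [Biostrings::DNAStringSet] of assembled candidates.
#' @param gene_id Target gene id.
#' @param catalog A [marker_catalog()] containing `gene_id`.
#' @param scan_fn Completeness scan, `function(seqs, catalog)` returning a
#'   [gene_status_table()]; defaults to [toy_marker_scan()].
#' @return List of class `candidate_sequence` (`id`, `bases`,
#'   `gene_status`, `gene_start`, `gene_end`, `gene_strand`), or `NULL`.
#' @export
select_candidate <- function(candidates, gene_id, catalog,
                             scan_fn = toy_marker_scan) {
  if (length(candidates) == 0) return(NULL)
  cat1 <- catalog[catalog$gene_id == gene_id, , drop = FALSE]
  assert_that(nrow(cat1) == 1, "gene ", gene_id, " not in catalog")
  # integrity is judged per candidate: a gene carried by several candidates
  # is still Complete on each of them, not Duplicated across the pool
  per_cand <- lapply(seq_along(candidates), function(i) {
    tab <- scan_fn(candidates[i], cat1)
    tab[tab$gene_id == gene_id, , drop = FALSE]
  })
  tab <- do.call(rbind, per_cand)
  hits <- tab[tab$status == "Complete", , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  w <- Biostrings::width(candidates)[match(hits$sequence_id, names(candidates))]
  best <- hits[order(-w, hits$sequence_id)[1], , drop = FALSE]
  structure(list(id = best$sequence_id,
                 bases = as.character(candidates[[best$sequence_id]]),
                 gene_status = "Complete",
                 gene_start = best$start, gene_end = best$end,
                 gene_strand = best$strand),
            class = "candidate_sequence")
}
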