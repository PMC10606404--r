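#' Construct a single-copy marker catalog
#'
#' The catalog is the desk-scale stand-in for an ortholog lineage database:
#' each marker is a unique gene sequence expected exactly once per haploid
#' genome. `min_fragment_fraction` sets, per gene, the fraction of the
#' marker that must be found contiguously for a Fragmented call by
#' [toy_marker_scan()].
#'
#' @param gene_id Character vector of unique gene ids.
#' @param bases Character vector of unique, non-empty marker sequences.
#' @param min_fragment_fraction Fraction in (0, 1], recycled; default 0.5.
#' @return A data frame of class `marker_catalog`.
#' @export
marker_catalog <- function(gene_id, bases, min_fragment_fraction = 0.5) {
  assert_that(!anyDuplicated(gene_id), "marker gene_ids must be unique")
  assert_that(all(nzchar(bases)), "marker sequences must be non-empty")
  assert_that(!anyDuplicated(bases), "marker sequences must be unique")
  frac <- rep_len(min_fragment_fraction, length(gene_id))
  assert_that(all(frac > 0 & frac <= 1), "min_fragment_fraction must lie in (0, 1]")
  df <- data.frame(gene_id = as.character(gene_id), bases = toupper(as.character(bases)),
                   min_fragment_fraction = frac, stringsAsFactors = FALSE)
  class(df) <- c("marker_catalog", "data.frame")
  df
}

#' Write a marker catalog as FASTA (gene id as header)
#' @param catalog A [marker_catalog()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_marker_catalog <- function(catalog, path) {
  write_fasta(stats::setNames(catalog$bases, catalog$gene_id), path)
}

#' Read a marker catalog from FASTA
#' @param path FASTA path, one record per marker gene.
#' @param min_fragment_fraction Applied to every gene; default 0.5.
#' @return A [marker_catalog()].
#' @export
read_marker_catalog <- function(path, min_fragment_fraction = 0.5) {
  x <- read_fasta(path)
  marker_catalog(names(x), as.character(x), min_fragment_fraction)
}

#' Genes reported Missing by a completeness scan
#'
#' @param table A [gene_status_table()].
#' @return Character vector of gene ids with status Missing.
#' @export
missing_genes <- function(table) {
  sort(unique(table$gene_id[table$status == "Missing"]))
}

#' Genes that can be used to fill the chromosome assembly
#'
#' The set difference at the heart of the method's first phase: genes
#' Missing in the chromosome-level assembly but present full-length in the
#' merged contig set. Because the contig set merges several assemblies, a
#' recoverable gene typically appears on one contig per assembler and is
#' reported Duplicated rather than Complete; both statuses are therefore
#' eligible (any full-length copy carries the gene, and
#' [locate_gene_in_contigs()] picks a host contig deterministically).
#' Fragmented contig hits are excluded: no contig carries the whole gene.
#'
#' @param chrom_table Scan of the chromosome-level assembly.
#' @param contig_table Scan of the merged contig set.
#' @param include_fragmented Also treat genes Fragmented in the chromosome
#'   assembly as fillable (default `FALSE`: only strictly Missing genes).
#' @return Lexicographically ordered character vector of fillable gene ids.
#' @export
fillable_genes <- function(chrom_table, contig_table,
                           include_fragmented = FALSE) {
  u1 <- unique(chrom_table$gene_id)
  u2 <- unique(contig_table$gene_id)
  if (!setequal(u1, u2)) {
    warning("chromosome and contig tables cover different gene universes; ",
            "using the intersection", call. = FALSE)
  }
  universe <- intersect(u1, u2)
  want <- missing_genes(chrom_table)
  if (include_fragmented)
    want <- union(want, chrom_table$gene_id[chrom_table$status == "Fragmented"])
  miss <- intersect(want, universe)
  full <- unique(contig_table$gene_id[contig_table$status %in%
                                        c("Complete", "Duplicated")])
  sort(intersect(miss, full))
}

#' Exact-match completeness scan against a marker catalog
#'
#' A deterministic desk-scale substitute for an HMM-based completeness
#' assessor, valid on noise-free sequence: a marker is Complete when its
#' full sequence occurs exactly once in the assembly (either strand),
#' Duplicated when it occurs more than once, Fragmented when a contiguous
#' stretch of at least `min_fragment_fraction` of its length occurs, and
#' Missing otherwise. Locations are reported in 0-based half-open
#' coordinates for every non-Missing hit.
#'
#' @param assembly A [Biostrings::DNAStringSet] or named character vector.
#' @param catalog A [marker_catalog()].
#' @return A [gene_status_table()] with one row per hit.
#' @export
toy_marker_scan <- function(assembly, catalog) {
  assembly <- as_dna(assembly)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    scan_one_marker(assembly, catalog$gene_id[i], catalog$bases[i],
                    catalog$min_fragment_fraction[i])
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) return(gene_status_table(character(), character()))
  gene_status_table(df$gene_id, df$status, df$sequence_id, df$start, df$end,
                    df$strand, df$score, df$length)
}

#' @noRd
scan_one_marker <- function(assembly, gene_id, marker, frac) {
  pat_f <- Biostrings::DNAString(marker)
  pat_r <- Biostrings::reverseComplement(pat_f)
  mlen <- nchar(marker)
  hits <- list()
  for (j in seq_along(assembly)) {
    subj <- assembly[[j]]
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(if (strand == "+") pat_f else pat_r, subj)
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_id = names(assembly)[j],
          start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  n_full <- if (is.null(hits)) 0L else nrow(hits)
  if (n_full >= 1L) {
    status <- if (n_full == 1L) "Complete" else "Duplicated"
    return(data.frame(gene_id = gene_id, status = status,
                      sequence_id = hits$sequence_id, start = hits$start,
                      end = hits$end, strand = hits$strand,
                      score = as.numeric(mlen), length = mlen,
                      stringsAsFactors = FALSE))
  }
  frag <- find_marker_fragment(assembly, marker, max(1L, as.integer(ceiling(frac * mlen))))
  if (!is.null(frag)) {
    return(data.frame(gene_id = gene_id, status = "Fragmented",
                      sequence_id = frag$sequence_id, start = frag$start,
                      end = frag$end, strand = frag$strand,
                      score = as.numeric(frag$end - frag$start),
                      length = frag$end - frag$start, stringsAsFactors = FALSE))
  }
  data.frame(gene_id = gene_id, status = "Missing", sequence_id = NA_character_,
             start = NA_integer_, end = NA_integer_, strand = NA_character_,
             score = NA_real_, length = NA_integer_, stringsAsFactors = FALSE)
}

#' Locate one contiguous marker fragment of at least `width` bases, if any
#'
#' Slides every `width`-wide window of the marker over the assembly at once
#' (constant-width dictionary search) and reports the first window found,
#' preferring the forward strand and earlier assembly sequences.
#' @noRd
find_marker_fragment <- function(assembly, marker, width) {
  mlen <- nchar(marker)
  if (width > mlen) return(NULL)
  offs <- seq_len(mlen - width + 1L)
  wins <- substring(marker, offs, offs + width - 1L)
  keep <- !duplicated(wins)
  pd_f <- Biostrings::PDict(Biostrings::DNAStringSet(wins[keep]))
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(wins[keep])))
  for (j in seq_along(assembly)) {
    subj <- assembly[[j]]
    if (length(subj) < width) next
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_f else pd_r
      cnt <- Biostrings::countPDict(pd, subj)
      hit <- which(cnt > 0)
      if (length(hit) > 0) {
        m <- Biostrings::matchPattern(
          if (strand == "+") Biostrings::DNAString(wins[keep][hit[1]])
          else Biostrings::reverseComplement(Biostrings::DNAString(wins[keep][hit[1]])),
          subj)
        return(list(sequence_id = names(assembly)[j],
                    start = Biostrings::start(m)[1] - 1L,
                    end = Biostrings::end(m)[1], strand = strand))
      }
    }
  }
  NULL
}
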